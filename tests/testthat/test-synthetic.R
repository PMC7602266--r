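test_that("bilinear instance generation matches its stated contract", {
  inst0 <- generate_bilinear_instance(2, 3, 4, 5, 3, 2, seed = 1)
  expect_equal(bl_objective(inst0$Y, inst0), 0, tolerance = 1e-18)
  expect_equal(dim(inst0$Y$data), c(4 * 5, 3 * 2))

  # mean squared residual of the truth matches the injected noise variance
  sigma <- 0.4
  inst <- generate_bilinear_instance(2, 4, 10, 10, 10, 10, noise_sd = sigma,
                                     seed = 2)
  msr <- bl_objective(inst$Y, inst) / length(inst$Y$data)
  expect_lt(abs(msr / sigma^2 - 1), 0.1)

  # determinism in the seed
  again <- generate_bilinear_instance(2, 4, 10, 10, 10, 10, noise_sd = sigma,
                                      seed = 2)
  expect_identical(again$Y$data, inst$Y$data)
  other <- generate_bilinear_instance(2, 4, 10, 10, 10, 10, noise_sd = sigma,
                                      seed = 3)
  expect_false(identical(other$Y$data, inst$Y$data))
})

test_that("cohort generation is deterministic and structurally sound", {
  cfg <- emg_cohort_config(n_subjects = 2, n_motions = 3, n_trials = 2,
                           duration_s = 1, seed = 5)
  a <- generate_emg_cohort(cfg)
  b <- generate_emg_cohort(cfg)
  expect_length(a, 2 * 3 * 2)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  expect_equal(dim(a[[1]]$samples), c(200L, 8L))
  expect_true(all(vapply(a, function(t) all(is.finite(t$samples)), logical(1))))
  cfg2 <- emg_cohort_config(n_subjects = 2, n_motions = 3, n_trials = 2,
                            duration_s = 1, seed = 6)
  c_ <- generate_emg_cohort(cfg2)
  expect_false(identical(a[[1]]$samples, c_[[1]]$samples))
})

test_that("motions are separable in feature space when confounds are off", {
  cfg <- emg_cohort_config(n_subjects = 2, n_motions = 4, n_trials = 5,
                           gain_sdlog = 0, mixing_strength = 0,
                           rotation_max = 0, seed = 11)
  trials <- generate_emg_cohort(cfg)
  fc <- feature_config(window_samples = 300, stride_samples = 150)
  series <- lapply(trials, extract_features, config = fc)
  feats <- t(vapply(series, function(fs) colMeans(matrix(fs$values, nrow = dim(fs$values)[1])),
                    numeric(8 * 10)))
  feats <- scale(feats)
  labels <- vapply(series, `[[`, character(1), "motion_label")
  # silhouette-style check: within-motion distances below between-motion
  d <- as.matrix(dist(feats))
  same <- outer(labels, labels, `==`) & upper.tri(d)
  diff_ <- outer(labels, labels, `!=`) & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_]))

  # within-subject recognition is easy in this regime
  one_subject <- trials[vapply(trials, `[[`, character(1), "subject_id") == "S01"]
  res <- run_single_subject(one_subject, small_loso_config())
  expect_gte(res$eval$overall, 0.9)
})

test_that("stronger cross-talk never helps cross-subject recognition", {
  acc_at <- function(mix) {
    mean(vapply(1:5, function(seed) {
      cfg <- emg_cohort_config(n_subjects = 3, n_motions = 4, n_trials = 5,
                               gain_sdlog = 0, mixing_strength = mix,
                               rotation_max = 0, seed = seed)
      trials <- generate_emg_cohort(cfg)
      pc <- small_loso_config(bilinear = FALSE)
      run_loso(trials, pc)$aggregate_raw$overall
    }, numeric(1)))
  }
  expect_gte(acc_at(0) + 1e-9, acc_at(0.7))
})

test_that("duplicate archetypes are rejected", {
  cfg <- emg_cohort_config(n_subjects = 1, n_motions = 2, n_trials = 1,
                           duration_s = 1, seed = 3)
  arch <- withr::with_seed(3, emgsign:::draw_archetypes(cfg))
  arch[[2]] <- arch[[1]]
  expect_error(generate_emg_cohort(cfg, archetypes = arch),
               "duplicate motion archetypes")
})
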