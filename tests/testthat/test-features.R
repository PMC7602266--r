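test_that("time-domain features match their defining sums on fixed cases", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(-3, 10)), 3)
  expect_equal(emg_std(rep(7, 5)), 0)
  expect_equal(emg_std(c(1, -1)), 1)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2, 8)), 2)
  expect_equal(log_detector(rep(0.7, 9)), 0.7)
  expect_true(is.finite(log_detector(c(0, 1, 2))))
  expect_equal(aac(c(0, 1, 0, 1)), 1)
  expect_equal(aac(rep(5, 6)), 0)
  expect_error(mav(numeric(0)))
  expect_error(aac(3))
})

test_that("every feature matches its naive loop oracle on random windows", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(600, sd = runif(1, 0.1, 10))
    expect_equal(mav(x), oracle_mav(x), tolerance = 1e-10)
    expect_equal(emg_std(x), oracle_std(x), tolerance = 1e-10)
    expect_equal(rms(x), oracle_rms(x), tolerance = 1e-10)
    expect_equal(log_detector(x), oracle_log_detector(x), tolerance = 1e-10)
    expect_equal(aac(x), oracle_aac(x), tolerance = 1e-10)
    psd <- random_psd()
    f <- psd$frequencies; p <- psd$powers
    expect_equal(mnf(psd), oracle_mnf(f, p), tolerance = 1e-10)
    expect_equal(mdf(psd), oracle_mdf(f, p), tolerance = 1e-10)
    expect_equal(mnp(psd), oracle_mnp(f, p), tolerance = 1e-10)
    expect_equal(pkf(psd), oracle_pkf(f, p), tolerance = 1e-10)
    expect_equal(psr(psd, 10), oracle_psr(f, p, 10), tolerance = 1e-10)
  }
})

test_that("window statistics satisfy their algebraic identities", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(200, mean = runif(1, -2, 2), sd = runif(1, 0.1, 5))
    expect_equal(rms(x)^2, emg_std(x)^2 + mean(x)^2, tolerance = 1e-10)
    expect_lte(log_detector(x), mav(x) * (1 + 1e-12))
    expect_lte(mav(x), rms(x) * (1 + 1e-12))
  }
})

test_that("amplitude scaling acts on each feature as expected", {
  set.seed(12)
  x <- rnorm(600)
  s <- 3.7
  cfg <- feature_config()
  for (fun in list(mav, emg_std, rms, log_detector, aac)) {
    expect_equal(fun(s * x), s * fun(x), tolerance = 1e-10)
  }
  p1 <- welch_psd(x, 200)
  p2 <- welch_psd(s * x, 200)
  expect_equal(mnf(p2), mnf(p1), tolerance = 1e-10)
  expect_equal(mdf(p2), mdf(p1), tolerance = 1e-10)
  expect_equal(pkf(p2), pkf(p1), tolerance = 1e-10)
  expect_equal(psr(p2, 10), psr(p1, 10), tolerance = 1e-10)
  expect_equal(mnp(p2), s^2 * mnp(p1), tolerance = 1e-10)
})

test_that("Welch estimates localize tones and conserve power", {
  fs <- 200
  t <- (0:599) / fs
  psd <- welch_psd(sin(2 * pi * 25 * t), fs)
  df <- psd$frequencies[2] - psd$frequencies[1]
  expect_lte(abs(pkf(psd) - 25), df)

  set.seed(21)
  ratios <- replicate(20, {
    x <- rnorm(600)
    p <- welch_psd(x, fs)
    sum(p$powers) * df / mean(x^2)
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)

  zero <- welch_psd(rep(0, 600), fs)
  expect_true(all(zero$powers == 0))
  expect_error(mnf(zero), "zero")
  expect_error(mdf(zero), "zero")
  expect_error(welch_psd(rnorm(100), fs, segment = 128), "segment")
})

test_that("spectral features follow their stated conventions", {
  # single nonzero bin
  psd <- structure(list(frequencies = c(0, 10, 20, 30),
                        powers = c(0, 0, 5, 0)), class = "psd_estimate")
  expect_equal(mnf(psd), 20)
  expect_equal(mdf(psd), 20)
  expect_equal(pkf(psd), 20)
  expect_equal(psr(psd, 5), 1)
  expect_equal(mnp(psd), 20 * 5 / 60)

  # two equal bins: MNF averages; PKF tie goes to the lower frequency
  psd2 <- structure(list(frequencies = c(0, 10, 20, 30),
                         powers = c(0, 3, 0, 3)), class = "psd_estimate")
  expect_equal(mnf(psd2), 20)
  expect_equal(pkf(psd2), 10)

  # uniform powers: MDF is the first bin reaching half the total
  psd3 <- structure(list(frequencies = 0:9, powers = rep(1, 10)),
                    class = "psd_estimate")
  expect_equal(mdf(psd3), 4)

  # uniform PSD with an interior peak: PSR counts the bins inside the window
  p <- rep(1, 64)
  p[33] <- 1 + 1e-9
  psd4 <- structure(list(frequencies = 0:63, powers = p),
                    class = "psd_estimate")
  expect_equal(psr(psd4, 2), sum(p[31:35]) / sum(p), tolerance = 1e-6)

  # single DC bin makes the frequency-normalized mean power undefined
  dc <- structure(list(frequencies = 0, powers = 4), class = "psd_estimate")
  expect_error(mnp(dc), "undefined")
})

test_that("sliding-window extraction has the right shape and equivariance", {
  set.seed(5)
  tr <- emg_trial(matrix(rnorm(900 * 3), 900, 3), "S01", "M1", 0)
  cfg <- feature_config(window_samples = 600, stride_samples = 150)
  fs <- extract_features(tr, cfg)
  expect_equal(dim(fs$values), c(3L, 3L, 10L))
  expect_true(all(is.finite(fs$values)))

  cfg1 <- feature_config(window_samples = 600)
  tr600 <- emg_trial(tr$samples[1:600, ], "S01", "M1", 0)
  expect_equal(dim(extract_features(tr600, cfg1)$values)[1], 1L)

  # permuting channels permutes the channel axis identically
  perm <- c(3, 1, 2)
  tr_p <- emg_trial(tr$samples[, perm], "S01", "M1", 0)
  fs_p <- extract_features(tr_p, cfg)
  expect_equal(fs_p$values, fs$values[, perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  short <- emg_trial(matrix(rnorm(100 * 3), 100, 3), "S01", "M1", 0)
  expect_error(extract_features(short, cfg1), "shorter")
})

test_that("feature tables are tidy and complete", {
  set.seed(6)
  tr <- emg_trial(matrix(rnorm(600 * 2), 600, 2), "S01", "M3", 4)
  cfg <- feature_config(window_samples = 300, stride_samples = 150,
                        feature_set = c("RMS", "MDF"))
  tab <- features_to_table(list(extract_features(tr, cfg)))
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_setequal(unique(tab$feature), c("RMS", "MDF"))
  one <- tab[tab$window == 1 & tab$channel == 2 & tab$feature == "RMS", ]
  expect_equal(one$value, rms(tr$samples[1:300, 2]))
})
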