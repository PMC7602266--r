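# emgsign

User-independent hand-gesture recognition from multi-channel surface
electromyography (sEMG), built around a bilinear user × motion
factorization.

## The problem

A gesture recognizer trained on sEMG from one group of people usually fails
on a new person: electrode placement, skin impedance and muscle anatomy give
every user systematically different signals for the same motion (the
*individual difference* problem). This package implements a pipeline that
separates *who is moving* from *what the motion is*:

1. **Features.** Raw trials (default: 3 s of 8-channel sEMG at 200 Hz) are
   cut into sliding windows and summarized per channel by five time-domain
   statistics — mean absolute value (MAV), population standard deviation
   (STD), root mean square (RMS), log detector (LOG), average amplitude
   change (AAC) — and five frequency-domain statistics of the Welch power
   spectrum — mean frequency (MNF), median frequency (MDF), mean power
   (MNP), power spectrum ratio (PSR), peak frequency (PKF).
2. **Feature selection.** Permutation feature importance (shuffle one
   feature across held-out trials, measure the accuracy drop) ranks the ten
   features; the six usually retained are RMS, LOG, AAC, PSR, MNP, MDF.
3. **Bilinear factorization.** Each scalar observation for channel *c*,
   user *u*, motion *m*, repetition *n* is modeled as

   ```
   y_cn^um = z_u' W_c x_n^m ,      z_u ∈ R^I,  x_n^m ∈ R^J,  W_c ∈ R^{I×J}
   ```

   i.e. a user factor `z_u`, a motion factor `x_n^m`, and a per-channel
   interaction matrix `W_c`. Stacked over the cohort this is
   `Y = [W^ST Z]^ST X` with `Y ∈ R^{CU×MN}` and `ST` the *stacked
   transpose* (each channel block transposed independently). The factors are
   fitted by alternating truncated SVDs; the objective
   `E = Σ ||y − z'Wx||²` is non-increasing and converges in a handful of
   iterations.
4. **New-user adaptation.** A new user performs the repetitions of *one*
   calibration motion. A closed-form pseudo-inverse chain extracts their
   user factor `z_new`, a re-estimated interaction `W_new`, and calibration
   motion factors `X_new`; their remaining trials are then projected onto
   motion factors, which are (approximately) user-free.
5. **Classification.** Motion-factor (or raw-feature) sequences are
   classified by a single-layer LSTM (implemented in base R with full-batch
   Adam) or by a deterministic nearest-centroid fallback. Evaluation is
   leave-one-subject-out (LOSO): every fold trains without the test subject.

Because no public recording of this kind exists, the package ships a
synthetic cohort generator (band-limited amplitude-modulated noise with
motion archetypes and low-dimensional per-subject confounds: channel gains,
cross-talk, fractional electrode rotation), so the entire pipeline is
testable end to end.

## Worked example

Simulate a confounded 5-subject cohort and compare LOSO accuracy with and
without the bilinear stage (both arms share folds, features and seeds):

```r
library(emgsign)

trials <- generate_emg_cohort(emg_cohort_config(n_subjects = 5, n_motions = 6,
                                                n_trials = 10, seed = 42))
config <- pipeline_config(
  features = feature_config(window_samples = 300, stride_samples = 150),
  I = 4, J = 10, classifier = "centroid"
)
res <- run_loso(trials, config)
res$per_fold
#>   subject raw_accuracy bilinear_accuracy
#> 1     S01         0.26              1.00
#> 2     S02         1.00              1.00
#> 3     S03         0.00              1.00
#> 4     S04         0.84              1.00
#> 5     S05         0.96              0.96
c(raw = res$aggregate_raw$overall, bilinear = res$aggregate_bilinear$overall)
#>      raw bilinear
#>    0.612    0.992
```

Reading the numbers: subjects S01 and S03 have confounds far from the
training users, so classifying their raw feature sequences fails badly
(26% / 0% over 6 motions; chance is ~17%). After fitting the bilinear model
on the other four subjects and adapting to the held-out subject from their
ten M1 calibration trials, the projected motion factors are essentially
user-free and accuracy recovers to ≥ 96% on every fold.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/emgsign.R simulate --out cohort --subjects 5 --motions 6 --trials 10
Rscript inst/cli/emgsign.R loso --manifest cohort/manifest.csv --out results \
    --window 300 --stride 150 --i-dim 4 --j-dim 10
```

## Documentation

The methods vignette (`vignettes/bilinear-factorization.Rmd`) documents the
model, the fitting and adaptation algebra, all tunable parameters with their
defaults and units, what the synthetic generator does and does not emulate,
and the package's design choices and limitations.
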