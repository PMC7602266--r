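Package: emgsign
Title: User-Independent Surface EMG Gesture Recognition via Bilinear
    Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing hand gestures (a 20-phrase American Sign
    Language vocabulary) from multi-channel surface electromyography across
    users. Implements windowed time- and frequency-domain feature extraction
    (Welch power spectra), permutation feature importance, a stacked bilinear
    user-by-motion factorization fitted by alternating singular value
    decompositions with closed-form new-user adaptation, an LSTM sequence
    classifier with a deterministic nearest-centroid fallback,
    leave-one-subject-out evaluation, and a synthetic multi-subject EMG
    cohort generator with user-specific confounds for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
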