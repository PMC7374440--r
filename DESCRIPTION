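Package: myocoh
Title: EMG Biofeedback Metrics and Corticomuscular Coherence Statistics
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing surface electromyography (EMG) and
    electroencephalography (EEG) recorded during neurofeedback training of
    wrist extensor activation. Implements EMG conditioning (Butterworth
    band-pass filtering, rectified moving-window and Hilbert amplitude
    envelopes, power-grip and session Z-score normalisation), the
    extensor-ratio biofeedback engine with its adaptive threshold staircase,
    the static-hold tracking-error assessment based on the median absolute
    deviation of a feedback cursor, and corticomuscular coherence statistics:
    pooled magnitude-squared coherence on Hann-windowed overlapping segments,
    analytic confidence limits, Fisher-Z pre/post coherence differences, and
    Stouffer composite band Z-scores. A synthetic signal generator produces
    EMG/EEG pairs whose band-limited coherence is known in closed form, so
    the full pipeline can be exercised and validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
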