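Package: neosleep
Title: Multi-Scale Permutation Entropy and Automatic Sleep Staging for Neonatal Polysomnography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neonatal polysomnography (PSG): signal
    conditioning (down-sampling, zero-phase FIR band-pass filtering, montage
    reduction, 30-second epoching, artifact-epoch exclusion), multi-scale
    permutation entropy (MSPE) and Welch power-spectral-density features per
    epoch, random-forest sleep staging (NREM/REM/WAKE) with subject-level
    repeated two-fold cross-validation within and across recording sessions,
    shuffled-label empirical chance estimation, bootstrap state-level entropy
    summaries, and a synthetic two-session neonatal-PSG generator so the full
    pipeline is testable without clinical recordings. Includes a minimal EDF
    writer/reader and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
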