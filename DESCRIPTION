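Package: iedsleep
Title: Sleep-Stage Modulation of Interictal Epileptiform Discharges and
    Neuronal Firing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term intracranial recordings in
    focal epilepsy: patient-specific template-matching detection of
    interictal epileptiform discharges (IEDs) on multichannel depth-contact
    local field potentials (iterative epoch alignment, k-medoids waveform
    clustering, normalized cross-correlation scanning, deduplication and
    benchmark scoring), time-locked LFP and peri-stimulus time histogram
    analyses with cluster-based permutation statistics, 10-second
    sliding-window spectral (slow-wave and delta band) and spike-train
    metrics (CV2, bursts), circadian phase statistics (Rayleigh test), and
    stage-wise mixed-effects contrasts. Ships a seeded synthetic-data
    generator (hypnogram, LFP with embedded spike-wave discharges, unit
    spike trains) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
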