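Package: bphdisrupt
Title: Synthesis and Playback Analysis of Brown Planthopper Vibrational
    Courtship Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying vibrational courtship disruption in the brown
    planthopper (Nilaparvata lugens, BPH). Synthesizes the three natural BPH
    signal classes (female courtship, male courtship, male competition) as
    parametric pulse trains, generates the seven artificial disruptive signals
    (pure tones, continuous pulse signals and white Gaussian noise) and mixes
    them with courtship signals at uniform intensity. Extracts the standard
    descriptors of substrate-borne vibration signals (main vibration frequency,
    pulse rate, multi-part segmentation) via FFT spectra and Hilbert envelopes
    behind a zero-phase Chebyshev band-pass front end, and models playback
    screening experiments: active-reply-period checks, reply-rate and
    reply-delay summaries, Kruskal-Wallis and Dunn rank statistics, and a
    seeded behavioral simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
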