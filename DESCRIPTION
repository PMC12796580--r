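Package: whiskloop
Title: Corticothalamic Feedback Analysis of Whisker-Evoked Activity with
    Synthetic Awake-Mouse Recording Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of sweep-based optogenetic
    photoinactivation experiments in the mouse whisker system. Generates
    synthetic recording sessions (inhomogeneous Poisson spike trains, a
    band-limited local field potential, and an event log of light pulses
    and air puffs), segments brain state (quiet non-whisking versus
    whisking) from the LFP spectrogram, builds per-sweep-normalized
    peristimulus time histograms, classifies units (opto-tagged layer-6
    corticothalamic cells, fast-spiking interneurons, cortical layer by
    depth), quantifies whisker-evoked response onset latency, slope,
    biphasic components and photoinactivation rate changes, and runs the
    accompanying statistical battery (repeated-measures ANOVA with
    Bonferroni post-hoc tests, robust outlier removal, t tests, and
    linear-trend contrasts).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
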