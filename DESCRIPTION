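Package: optomap
Title: Behavior-Space Phenotyping of Optogenetically Stimulated Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised behavioral phenotyping for trial-structured
    optogenetic experiments on single flies. Builds a two-dimensional
    behavior space from fly-centered video via Radon-transform PCA of
    aligned frames, Morlet continuous wavelet spectra of the postural
    modes, and a Kullback-Leibler-distance t-SNE embedding with
    importance subsampling and out-of-sample re-embedding. Provides
    trial-aligned statistics over the map: per-cycle on/off densities,
    the chi difference statistic, Wilcoxon rank-sum significance maps
    with Sidak correction using an entropy-based comparison count,
    watershed regionization, stimulus-locked entropy curves and region
    time courses, and finite-size bias-corrected mutual information
    between pre-stimulus behavior-space density and the post-stimulus
    region. Includes a ground-truthed synthetic session generator
    (latent Markov behavior states, state-specific postural
    oscillations, LED schedules, optional rendered movies) so the whole
    pipeline is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
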