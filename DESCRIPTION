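Package: ecgidsp
Title: Spatial-Temporal Processing and Bipolar Electrograms for
    Electrocardiographic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conditioning and analysing meshed unipolar
    electrograms such as those estimated by electrocardiographic imaging
    (ECGI). Provides triangle-mesh neighborhood geometry, cubic-spline
    baseline-wander removal and zero-phase Butterworth low-pass filtering
    with residual autocorrelation diagnostics, M-mode (time-space)
    representations with two-dimensional spatial-temporal autocorrelation,
    a family of digital signal processing operators (DSPOs) that build
    bipolar electrograms from unipolar potentials on a mesh - including a
    delayed maximum-amplitude operator - and clinical voltage-map indices
    (peak-to-peak amplitude, scar/border/healthy classification,
    notch-based fragmentation). A synthetic wavefront simulator generates
    spatio-temporally structured potential fields with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
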