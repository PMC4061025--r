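Package: occupeakr
Title: Input-Free ChIP-Seq Peak Calling with an Internal Background Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls peaks in ChIP-seq alignment data without an input control.
    Overlapping tags are assembled into coverage regions, the cumulative counts
    of regions reaching each overlap depth are fitted with a geometric-decay
    background model N(n) = p^n * A + B estimated from the dataset itself, and
    regions whose observed count exceeds the background expectation by more
    than a user-chosen excess ratio are reported as peaks in BED format.
    Includes fragment-length reconstruction from strand-separated pileups,
    window-based local background fitting, a uniform-background ChIP-seq
    simulator that writes SAM, and interval-overlap comparison utilities with
    a two-sample proportion Z-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
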