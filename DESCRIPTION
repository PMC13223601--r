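Package: hommtm
Title: Identification and Quantification of Coexisting Peptide Isoforms
    from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies up to two coexisting posttranslational-modification
    isoforms of a peptide from a single tandem mass spectrum (a homogeneous
    multiplexed, "HomMTM", spectrum). A peptide isoform mass graph encodes all
    candidate modification placements, the spectrum is cast as a mass graph in
    neutral prefix-mass space, and a peak-error-correction alignment table is
    backtracked into a graph containing every candidate isoform-spectrum match,
    including matches with missing peaks. A two-path dynamic program over that
    graph finds the pair of isoforms and theoretical peak intensities
    minimizing the total peak-intensity error, yielding site assignments and
    relative abundances. Also provides a HomMTM spectrum simulator with
    ground-truth isoform pairs, an accuracy-versus-abundance-ratio benchmark
    harness, a peak-support-rate statistic, and readers and writers for MGF
    spectra, PSM tables and result files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
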