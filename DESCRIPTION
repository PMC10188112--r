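Package: finprintr
Title: Behavioral Fingerprinting and Differential Chromatin Accessibility
    Statistics for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative locomotor phenotyping of larval zebrafish
    and for the custom statistics used in pharmaco-behavioral and chromatin
    accessibility screens. Segments delta-pixel activity traces into active and
    inactive bouts, computes nine behavioral parameters per day and night
    epoch, converts them into sibling-referenced Z-score fingerprints with
    Euclidean phenotype distances, and ranks fingerprints against a
    psychoactive-compound library by Pearson correlation with
    correlation-distance clustergrams. A companion set of genomics utilities
    implements per-peak one-tailed Wilcoxon and Kolmogorov-Smirnov tests with
    a label-shuffling permutation null, bulk region classification from
    differential-accessibility tables, Tn5 read shifting, effective-fragment
    filtering, RPM coverage, condition-specific peak calls and promoter-peak
    association. A synthetic-data module generates bout-structured activity
    plates, fingerprint libraries with planted mimics, and two-condition peak
    intensity matrices with planted differential peaks, so that every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
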