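Package: haplodate
Title: Dating Founder Variants from Shared Haplotype Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the age of a founder (recurrent, identical-by-descent)
    pathogenic variant from phased haplotypes of unrelated carriers. For every
    pair of carriers the extent of the shared haplotype around the focal
    variant is determined by outward scan (with hard-stop handling for
    genotype-only comparisons and a filter for spurious double recombinants
    introduced by statistical phasing), converted from base pairs to
    centiMorgans through a recombination map, translated into
    generations-to-common-ancestor by Monte-Carlo simulation of recombination
    decay, and clustered by UPGMA into the carriers' extended genealogy, whose
    root height estimates the time to the most recent common ancestor. A
    censored-exponential maximum-likelihood age estimator provides an
    independent cross-check with confidence intervals. A cohort simulator with
    known genealogical truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
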