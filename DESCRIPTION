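Package: polesig
Title: Detection of POLE-Driven Hypermutation from RNA-Seq Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for identifying POLE-exonuclease-driven
    hypermutated tumors from expressed single-nucleotide variants (eSNVs)
    called in RNA sequencing. Implements eSNV quality/depth/population-allele-
    frequency/panel-of-normals filtering, capture-region and tumor-mutational-
    burden (TMB) computation, 96-trinucleotide-context mutational profile
    construction with pyrimidine-strand collapse, de novo non-negative matrix
    factorization of the profile matrix under the generalized Kullback-Leibler
    divergence, cosine-similarity matching of extracted signatures against a
    reference catalog, per-signature TMB attribution, Tukey-fence outlier
    calling of hypermutated samples, POLE hotspot confirmation, and the
    accompanying cohort statistics (exact Mann-Whitney and Fisher tests).
    A deterministic synthetic-cohort simulator with known ground truth makes
    every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
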