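Package: rthx
Title: Horizontal Transfer Detection for R2 Retrotransposons from
    Divergence-Versus-Host-Age Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects horizontal transfer (HT) of R2 non-LTR retrotransposons
    among congeneric host taxa. Provides structural characterization of
    element sequences (poly-A trimming, ORF and frameshift annotation,
    zinc-finger motif detection, large indel and duplication calls),
    uncorrected p-distance matrices with pairwise deletion and analytic
    standard errors, a dated host-tree model, neighbor-joining element trees
    with bootstrap support and calibration-based dating, a
    divergence-versus-host-split-age regression with candidate flagging and
    exclusion refit, lineage partitioning and patchy-distribution tests,
    element-versus-host topology conflict detection, and minimal HT event
    reconstruction. A forward simulator of element evolution along a dated
    host phylogeny, with injected HT events and sequence degradation,
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
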