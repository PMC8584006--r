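Package: phosflow
Title: Downstream Analysis of Quantitative Phosphoproteomics Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of site-level quantitative
    (TMT-style) phosphoproteomics data: differential phosphosite calling by
    fold-change and Student's t-test thresholds, iterative binomial
    phospho-motif discovery (motif-x style), kinase-substrate prediction by
    substitution-matrix similarity to exemplar substrate peptides with
    protein-protein interaction filtering, kinase-activity inference by
    gene-set enrichment (KSEA) with permutation-based normalised enrichment
    scores, bipartite kinase-substrate regulatory network assembly and
    export, and two-tailed Fisher annotation enrichment. A fully seeded
    synthetic-study generator produces proteomes, phosphosites, planted
    kinase motifs and TMT-like intensities with known ground truth, so every
    stage of the pipeline can be exercised and validated end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    fgsea
Config/testthat/edition: 3
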