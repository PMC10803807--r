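Package: wisentpanel
Title: Non-Invasive SNP Panel Genotyping and Pedigree Analytics for European Bison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reduced SNP-panel genetic assessment of the European bison
    (Bos bonasus) and related bovines from replicated, mostly non-invasive
    genotyping runs: replicate-based consensus genotype calling with allelic
    dropout / false allele error decomposition, Y-marker sex determination,
    individual discrimination via probability-of-identity curves and pairwise
    allele mismatches, parent-offspring assignment by Mendelian exclusion with an
    error-tolerant likelihood, Hardy-Weinberg / linkage-disequilibrium / FST-based
    marker subset selection, breeding-line assignment with two clustering methods
    and a dual probability threshold, cross-species detection by call-rate gating
    and principal coordinates analysis, and molecular as well as pedigree-based
    (kinship matrix and gene-drop) genetic diversity estimation. A synthetic-data
    generator emulates a bottlenecked two-breeding-line pedigree population with a
    replicate-level genotyping error model so every stage can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
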