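Package: trzsar
Title: Structure-Activity Analysis of Triazolopeptide Inhibitors of the
    NRP-1/VEGF-165 Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles branched peptidomimetics containing 1,2,3-triazole
    peptide-bond isosteres from a compact sequence notation into heavy-atom
    molecular graphs and elemental formulas, computes monoisotopic masses and
    m/z values for protonated ions, derives topological and indicator
    descriptors (guanidine-guanidine distance, triazole-position and
    free-amine indicators), and fits the ordinary-least-squares
    structure-activity models built on them. Also implements the
    competitive-ELISA percent-inhibition arithmetic, log-logistic IC50
    fitting, exponential stability-decay summarisation, and seeded synthetic
    generators for every assay input, so the whole analysis runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
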