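Package: twolibDE
Title: Two-Library RNA-Seq Differential Expression with the Audic-Claverie Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for unreplicated two-library
    RNA-seq designs (one pooled library per condition): RPKM quantification,
    the Audic-Claverie exact test with Benjamini-Hochberg FDR thresholding,
    detection of library-specific genes, hypergeometric GO/KEGG
    over-representation analysis with Bonferroni or BH correction, and
    2^-delta-delta-Ct qPCR relative quantification. Includes a synthetic count,
    annotation and Ct-panel generator with known ground truth for calibration
    studies, and a small pipeline driver that runs
    simulate -> quantify -> test -> enrich -> report reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
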