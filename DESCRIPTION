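Package: elutriomics
Title: Cell-Cycle Proteome and Transcriptome Analysis for Elutriated Cell Fractions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of label-free quantitative proteomics and
    RNA-Seq data from cells fractionated across the mitotic cell cycle by
    centrifugal elutriation. Provides in-silico proteolytic digestion and
    sequence-coverage accounting, peptide-to-protein-group aggregation with
    iBAQ absolute abundance estimation, a cell-count-weighted "checksum"
    self-consistency filter, twofold-cutoff detection and Ward clustering of
    cell-cycle-regulated proteins by peak phase, isoform-resolved spectral
    count profiling, phosphopeptide regulation analysis, protein-mRNA
    correlation and concordance classification, APC/C degron motif scanning,
    hypergeometric annotation enrichment, Watson-model DNA-content histogram
    deconvolution, and a synthetic-data generator that emulates the
    statistical structure of elutriation experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
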