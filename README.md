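# elutriomics

Cell-cycle proteome and transcriptome analysis for elutriated cell
fractions.

## The problem

Counterflow centrifugal elutriation separates an unsynchronized cell
culture by size into six fractions (F1–F6) enriched for successive
cell-cycle phases — F1/F2 for G1, F3/F4 for S, F5/F6 for G2&M — without
the artefacts of drug-based synchronization. Combining label-free
quantitative proteomics of each fraction (dual Lys-C / Lys-C+trypsin
digestion) with RNA-Seq of pooled fractions yields, per gene, a six-point
protein profile and a three-point mRNA profile across the cell cycle, plus
the asynchronous population as an internal control.

`elutriomics` implements the downstream analysis of such experiments for
computational biologists working from peptide evidence tables and FPKM
tables:

* **in-silico digestion & coverage** — Lys-C / trypsin(/P) digestion,
  peptide-to-isoform mapping, amino-acid coverage, protease
  complementarity, composition-bias checks;
* **quantification** — protein grouping (identical/subset peptide sets),
  razor aggregation, median-log-ratio normalization, iBAQ
  (`intensity / theoretical tryptic peptides`), cumulative abundance;
* **consistency filtering** — the "checksum" test: the asynchronous
  per-cell intensity must equal the cell-count-weighted mixture of
  fraction per-cell intensities, `|log2(pred/meas)| <= tau`; plus
  non-negative least-squares deconvolution of each profile onto G1/S/G2M
  phase compositions;
* **regulation** — twofold-cutoff detection (`max/min >= 2` on per-cell
  profiles), Ward clustering (16-cut) with a bimodal "G2M+G1" cluster and
  argmax-phase reassignment;
* **isoform & phospho analysis** — unique-peptide MS/MS-count profiles per
  isoform, pairwise concordance, aggregation-masking detection;
  phosphosite assembly, strict `> 2`-fold regulated-site detection, S/T/Y
  breakdown, phospho-vs-protein profile interpretation;
* **protein–mRNA integration** — gene-level merge (histones removed),
  Spearman correlation of log iBAQ vs log FPKM, 3-point profile
  concordance (`r >= 0.5`), the coordinated subset (protein fold `>= 2`
  and RNA fold `> 1.5`);
* **motifs & enrichment** — KEN and D-box (R-x-x-L) degron scanning,
  hypergeometric term enrichment with Benjamini–Hochberg, exact binomial
  TFBS frequency tests;
* **Watson model** — DNA-content histogram decomposition (Gaussian G1/G2
  peaks + error-function S-phase) into phase proportions;
* **synthetic data** — a generator with known ground truth (log-normal
  abundance, 5.5% regulated genes at a 17/27/49/7 peak-phase mix,
  protein–mRNA Gaussian copula at Spearman 0.63, degron-carrying
  coordinated genes, phosphopeptides at the 64/17/16 S/T/Y mix) used to
  validate every stage.

## Worked example

```r
library(elutriomics)

dir <- file.path(tempdir(), "demo")
cfg <- sim_config(n_genes = 300, seed = 7)     # 5.5% regulated by default
truth <- simulate_dataset(cfg, dir)            # writes evidence/FPKM/FASTA/...
res <- run_pipeline(pipeline_config(dir, file.path(dir, "out"), seed = 7))
str(res$summary)
```

```
List of 12
 $ n_evidence_rows           : int 70674
 $ n_protein_groups          : int 605
 $ n_filtered_groups         : int 580
 $ n_filtered_genes          : int 300
 $ n_regulated               : int 15
 $ regulated_pct             : num 5
 $ lysc_relative_increase_pct: num 38
 $ n_phospho_sites           : int 122
 $ phospho_regulated_pct     : int 8
 $ spearman_async            : num 0.648
 $ n_coordinated             : int 5
 $ n_discordant_isoform_genes: int 116
```

Reading the output: 300 simulated genes produce 605 isoform-level protein
groups; after cleaning and the checksum filter, 15 genes are called
cell-cycle regulated (5.0% of the filtered set, against 16 regulated in
the ground truth — `sum(truth$genes$regulated)`), Lys-C adds 38% to the
peptide identifications relative to the double digest, and the
protein–mRNA rank correlation in asynchronous cells is 0.648 (copula
target 0.63). The large discordant-isoform count is a screening list: with
six-point profiles, flat isoform pairs are "discordant" at chance level
(see the methods vignette, `vignettes/cell-cycle-elutriation.Rmd`).

A command-line wrapper with `simulate`, `run-all` and `filter` subcommands
is installed at `inst/scripts/elutriomics-cli.R`.

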