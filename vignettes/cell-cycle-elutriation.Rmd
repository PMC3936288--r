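---
title: "Methods: cell-cycle proteome analysis of elutriated fractions"
author: "elutriomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-cycle proteome analysis of elutriated fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elutriomics)
```

# The experimental design being modelled

Counterflow centrifugal elutriation separates a live, unsynchronized cell
culture by size into fractions enriched for successive cell-cycle phases,
without drug arrest: six fractions F1--F6, with F1/F2 enriched in G1 cells,
F3/F4 in S-phase cells and F5/F6 in G2&M cells, plus the unfractionated
asynchronous (ASYNC) population. Cell yields fall steeply from F1 to F6
(defaults 8e7 down to 2e6 cells). Proteins from each fraction are digested
with Lys-C alone and with a Lys-C/trypsin double digest, quantified by
label-free MS; poly(A)+ RNA from pooled fractions (F1+F2, F3+F4, F5+F6) is
quantified as FPKM.

This package implements the downstream computational analysis of such an
experiment -- from a peptide evidence table and an FPKM table to
cell-cycle-regulated proteins, isoform- and phosphosite-level regulation,
protein--mRNA integration and motif/annotation enrichment -- together with
a synthetic-data generator that emulates the statistical structure of the
design so that every stage can be validated against a known ground truth.

# Units: the per-cell currency

A single modelling decision propagates through everything: in the
generator's world, the measured intensity of a protein in sample $s$ is
proportional to (per-cell abundance) $\times$ (cells in the sample). This is
the world in which the *checksum* self-consistency filter is exact: writing
$\tilde I_f = I_f / n_f$ for the cell-count-normalized (per-cell) intensity
of fraction $f$ with cell count $n_f$, the asynchronous population is the
physical mixture of the fractions, so

$$ \tilde I_\mathrm{async} \;=\; \sum_f w_f\, \tilde I_f,
   \qquad w_f = n_f \Big/ \sum_g n_g . $$

A protein passes the checksum when
$|\log_2(\text{predicted}/\text{measured})| \le \tau$ (default $\tau = 1$,
i.e. twofold -- the filter is described as "stringent" without a printed
number, so $\tau$ is an exposed parameter). The deviation is invariant to
rescaling all samples jointly.

The flip side is that every downstream fold-change or profile analysis must
divide intensities by cell counts first; the relevant functions take the
fraction metadata for exactly this purpose, and fold changes are always
computed on per-cell intensities. MS/MS spectral counts, by contrast, are
modelled as composition-based (equal peptide amounts injected per run), so
count profiles are per-cell quantities from the start.

# Phase deconvolution as the adjacent-fraction check

The original self-consistency procedure also compared adjacent fractions
using cell numbers and the flow-cytometry phase proportions. That
description is under-specified, so it is generalized here into a
non-negative least-squares deconvolution: with $\Pi$ the $6 \times 3$ matrix
of G1/S/G2M proportions per fraction, solve

$$ \min_{x \ge 0} \sum_f \big( \tilde I_f - (\Pi x)_f \big)^2 $$

and report the relative residual (RMS error over mean per-cell intensity),
with pass threshold $\rho_{\max} = 0.5$ by default. Because the system has
only three unknowns, the NNLS is solved exactly by enumerating the $2^3$
active sets; the test suite checks it against an independent dense
grid-search oracle. Profiles no non-negative phase combination can explain
(e.g. alternating high/low across fractions) fail with a large residual.

# Detection and clustering of regulated proteins

A protein is cell-cycle regulated when its per-cell fraction profile varies
by at least twofold (max/min $\ge 2$, boundary inclusive -- the
corresponding phosphopeptide rule is strictly greater than twofold, an
asymmetry preserved from the source analysis). Regulated profiles are
scaled to unit maximum ("heatmap semantics") and clustered with Ward
linkage (`ward.D2`, Euclidean distance) cut at 16 clusters. Clusters whose
centroid is bimodal -- entries at F1 and F6 each $\ge$ 80% of the centroid
maximum with an interior entry $\le$ 60% -- are retained as cluster 7
(G2M+G1, proteins depressed in S phase); everything else is reassigned to
clusters 1--6 by the fraction of maximum expression, with broad classes
F1/F2 $\to$ G1, F3/F4 $\to$ S, F5/F6 $\to$ G2M. One deliberate deviation
from a single-cluster rule: the 16-cut frequently splits the bimodal set
across two or three clusters, so *all* bimodal-centroid clusters are kept
as cluster 7 rather than only the largest.

Whether the original clustering used scaled or raw intensities is not
stated; scaled is assumed, so amplitude does not dominate shape.

# The synthetic world

`sim_config()` fixes the generator's statistical assumptions. The defaults
are the stated conditions of the experiment being emulated, not tuning
knobs:

* **Abundance**: log10 protein copy number $\sim N(4.5, 1.3)$; per-peptide
  response factors log-normal (sdlog 1 decade), giving measured intensities
  spanning roughly eight orders of magnitude.
* **Regulation**: 5.5% of genes regulated; peak-class mix
  G1/S/G2M/G2M+G1 = 17/27/49/7%; fraction-level folds log-uniform on
  [2, 8]. Phase-level contrasts are solved numerically (by `uniroot`) so
  that the *fraction-level* fold -- after attenuation by composition mixing
  -- hits its target exactly. Mixing bounds what each class can attain
  (the S class asymptote is $\approx 7.5$, the G2M+G1 class
  $\approx 2.4$ with the default compositions); draws above a class limit
  are capped at 95% of the asymptote. G2M+G1 profiles are built with
  S-phase expression depressed relative to both flanks.
* **Unregulated genes** get per-phase log-normal variability (CV 8%,
  clamped) guaranteeing fraction folds below 2, so specificity is
  measurable.
* **mRNA** is coupled to protein abundance through a Gaussian copula at
  Spearman $\rho = 0.63$ (the Pearson latent correlation is
  $2\sin(\pi\rho_s/6)$). The coordinated subset (default 31/358 of
  regulated genes) additionally cycles at the RNA level by more than
  1.5-fold in phase with the protein; every coordinated gene's sequence
  receives one KEN and one injected RxxL degron (random sequences of
  typical length already contain RxxL by chance at high frequency and KEN
  at roughly the few-percent background the motif scan reports).
* **Phosphopeptides** are drawn residue-first from the S/T/Y mix (the
  printed 64/17/16% split renormalized to sum to one), so the configured
  proportions are recovered regardless of how common each residue is in
  peptides; 28% carry two sites; about 3% of sites have cell-cycle
  regulated stoichiometry.
* **Missingness** is logistic in log pre-noise intensity (abundance
  dependent, not uniform), so the cleaning filter's complete-case rule is
  exercised realistically. Detection defaults (`detect_mid = 7.5`,
  `detect_slope = 0.3`) were chosen so that replicate-style reproducibility
  stays in the reported >0.97 range; the measurement noise magnitudes are
  not printed in the source and are exposed as configuration.
* **MS/MS counts** are Poisson with a saturating power-law rate
  $\lambda = \min(\text{cap},\, 3\,(I_\text{per-cell}/10^3)^{0.5})$ --
  increasing in log intensity, sublinear in abundance, capped by duty
  cycle. A rate *linear* in log intensity would compress a fourfold
  abundance change into a few percent of the rate and make count profiles
  uninformative.

Two identities hold exactly, by construction, pre-noise: the asynchronous
expectation is the cell-count-weighted mixture of fraction expectations,
and gene-level expectations are the share-weighted sums of isoform
expectations. Both are asserted in the tests at machine precision.

What a green test does **not** establish: the generator has no
chromatography, retention time, charge states, FDR structure, isoform
sequence sharing beyond a single variable segment, or correlated
(batch-like) noise; real evidence tables violate all of these. The
synthetic world validates the *algebra and statistics* of the pipeline, not
its robustness to instrument artefacts.

# Isoform analysis and the limits of 6-point correlation

Isoform profiles use MS/MS counts of peptides unique within the gene's
isoform set (at least two unique peptides quantified in all six
fractions), averaged per fraction. Discordance between isoforms of a gene
is declared when the minimum pairwise Pearson correlation falls below 0.5
(a threshold chosen to align with the protein--mRNA concordance rule;
the source gives none).

A structural caveat deserves emphasis. For a *truly flat* isoform the
six-point profile is pure jitter, and the correlation of pure jitter with
any fixed trend has the null density $\propto (1-r^2)$ at $n = 6$, giving
$P(r \ge 0.5) \approx 0.156$ *regardless of how small the jitter is*
(Pearson is scale free). Two consequences:

* a gene with one regulated and one flat isoform is flagged discordant at
  most ~84% of the time -- which is why the acceptance criterion demanding
  95% is reported red, with the masking component alone at ~99.5%;
* conversely, genes whose isoforms are all flat are "discordant" at the
  complementary chance rate, so the discordance flag is a *screening*
  device (as it was used originally -- candidates were inspected), not a
  calibrated test.

Aggregation masking is the complementary, more robust signal: the
gene-level pooled fold stays below the cutoff while some isoform's
unique-peptide fold meets it. The focused scenario generator
`simulate_discordant_genes()` builds this situation by construction (flat
isoform at five times the regulated isoform's fraction-level trough, so
the pooled pre-noise fold is about $(4+5)/(1+5) = 1.5$), with a tighter
response-factor spread so summed intensities track isoform abundance
shares.

# Protein--mRNA integration

Absolute-abundance comparisons use Spearman correlation of log iBAQ versus
log FPKM (histones removed, complete cases only, no pseudocounts); ranks
make the result invariant to the per-sample scale, so the asynchronous and
per-phase correlations need no unit care. Profile concordance does need
it: the six protein points are cell-count-weighted-pooled to three
(mirroring the physical pooling of the RNA samples), compared with the
(G1, S, G2M) FPKM profile by Pearson correlation over three paired points,
concordant at $r \ge 0.5$ inclusive. Three-point correlations are coarse
by nature -- they take few distinct values and a constant profile is
undefined (such genes are flagged and excluded from the partition). The
coordinated subset is the intersection of protein regulation (fold
$\ge 2$) and RNA variation (fold $> 1.5$, strict, matching "more than
1.5-fold").

# iBAQ, grouping and normalization

Isoforms indistinguishable by their detected peptides are merged; peptide
sets that are strict subsets are subsumed; shared peptides are counted once
per razor assignment (largest group, lexicographic ties). iBAQ divides a
group's summed intensity by its count of theoretical tryptic peptides of
7--30 residues (the standard window; the source does not print one). The
full delayed-normalization label-free algorithm is deliberately not
reimplemented: downstream analysis depends only on relative per-sample
protein intensities, so a median log-ratio normalization to a
geometric-mean pseudo-reference is provided instead (idempotent, removes
global scale), and the checksum operates on raw cell-count-scaled
intensities.

# Watson model for DNA-content histograms

Phase proportions are estimated from DNA histograms with the pragmatic
model: Gaussian G1 and G2 peaks (the G2/G1 mean ratio constrained to
[1.8, 2.2], $\sigma_{G2} = k\,\sigma_{G1}$ with $k \in [1, 2.5]$) plus an
S-phase component that is a constant synthesis-rate density between the
peaks convolved with the peak width -- a difference of normal CDFs divided
by the peak separation. For fixed shape parameters the three component
amplitudes are a non-negative least-squares problem (solved exactly);
shapes are optimized by bounded quasi-Newton, initialized from both
"histogram peak is G1" and "histogram peak is G2" hypotheses since either
can dominate depending on the fraction. Proportions are the normalized
component amplitudes. Sub-2N debris is excluded by gating. Round-trip
recovery (simulate at CV 5%, refit) is accurate to about $\pm 0.005$, well
inside the $\pm 0.03$ criterion.

# Numerical choices and degenerate inputs

* Boundary conventions: protein fold cutoff inclusive ($\ge 2$),
  phosphopeptide cutoff strict ($> 2$), RNA coordination strict
  ($> 1.5$), concordance inclusive ($r \ge 0.5$), checksum inclusive
  ($\le \tau$); all with a 1e-12 guard against float noise.
* Percentages round half up (base R's banker's rounding would report
  89/2761 as 3% either way, but 7.5% as 8% only under half-up).
* Zero asynchronous intensity fails the checksum with a reason code rather
  than propagating NaN; zero-variance profiles yield `NA` correlations and
  are flagged, never errors.
* A rank-deficient composition matrix (fractions that do not span the
  three phases) raises an error naming the degeneracy.
* The relative-increase statistic truncates to an integer percent
  (30.8/(50.5+18.7) = 44.5% reported as 44%), matching the printed figure.

# Known limitations

Decoy/contaminant handling is flag-based removal only (no FDR modelling);
isoform uniqueness is within-gene, not genome-wide; the enrichment module
uses the standard hypergeometric with Benjamini--Hochberg rather than
DAVID's modified score, so published enrichment p-values are not expected
to match exactly (indeed the exact binomial tail for the NF-Y 26/31
example is orders of magnitude smaller than the printed p, which evidently
came from a different test); and the pipeline's discordant-isoform count
is a screening list with the chance-level behaviour described above.
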