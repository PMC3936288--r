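#' Phosphopeptide cell-cycle analysis
#'
#' Analysis of phosphopeptides detected without enrichment: assembly of
#' phosphosite records, detection of regulated phosphosites (strictly more
#' than twofold variation across fractions, among sites identified in all
#' six), residue breakdown, overlap with abundance-regulated proteins, and
#' paired phospho/protein profile interpretation.
#'
#' @name phospho_analysis
NULL

#' Assemble phosphosite records from evidence
#'
#' Phosphopeptides are keyed by protein, site position(s) and residue; rows
#' are summed per sample. Peptides mapping to several proteins (e.g. the
#' shared CDK1/CDK2 Tyr15 peptide) are assigned to all matches and flagged
#' ambiguous.
#'
#' @param evidence evidence table with phospho rows.
#' @param meta optional fraction metadata; when given, sample intensities
#'   are normalized by cell count to the per-cell scale, which is the
#'   meaningful currency when loading scales with fraction yield.
#' @return `data.table` with `site_key`, `gene_id`, `residue`, `position`,
#'   `multiplicity`, `ambiguous`, `complete` (identified in all six
#'   fractions), and per-sample intensity columns.
#' @export
phospho_sites <- function(evidence, meta = NULL) {
  ev <- data.table::as.data.table(evidence)
  ev <- ev[is_phospho == TRUE]
  if ("is_contaminant" %in% names(ev)) ev <- ev[is_contaminant == FALSE]
  if ("is_decoy" %in% names(ev)) ev <- ev[is_decoy == FALSE]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(site_key = character()))
  }
  ev[, ambiguous := lengths(gregexpr(";", isoform_ids, fixed = TRUE)) > 0 &
       grepl(";", isoform_ids, fixed = TRUE)]
  ev[, site_key := paste0(gene_id, ":", phospho_residue, phospho_site)]
  wide <- data.table::dcast(
    ev, site_key + gene_id + phospho_residue + phospho_site +
      phospho_multiplicity + ambiguous ~ sample,
    value.var = "intensity", fun.aggregate = sum, fill = NA)
  for (s in setdiff(SAMPLES, names(wide))) wide[, (s) := NA_real_]
  if (!is.null(meta)) {
    for (s in intersect(SAMPLES, meta$sample)) {
      wide[, (s) := get(s) / meta$cell_count[match(s, meta$sample)]]
    }
  }
  data.table::setnames(wide, c("phospho_residue", "phospho_site",
                               "phospho_multiplicity"),
                       c("residue", "position", "multiplicity"))
  wide[, complete := rowSums(is.na(.SD) | .SD <= 0) == 0,
       .SDcols = FRACTIONS]
  wide[]
}

#' Detect cell-cycle-regulated phosphosites
#'
#' Only sites identified in all six fractions are testable; a site is
#' regulated when its intensity varies by strictly more than `cutoff`
#' across the fractions (note the strict inequality, in contrast to the
#' inclusive protein-abundance cutoff).
#'
#' @param sites output of [phospho_sites()].
#' @param cutoff fold threshold (default 2).
#' @return list with `sites` (testable sites + `fold`, `regulated`),
#'   `n_tested`, `n_regulated`, `regulated_pct` (integer percent, rounded
#'   to nearest), `n_detected` (all sites incl. incomplete).
#' @export
detect_regulated_phospho <- function(sites, cutoff = 2.0) {
  st <- data.table::as.data.table(sites)
  n_detected <- nrow(st)
  test <- st[complete == TRUE]
  m <- as.matrix(test[, FRACTIONS, with = FALSE])
  if (any(m <= 0)) stop("nonpositive intensity in complete phosphosite")
  fold <- apply(m, 1, max) / apply(m, 1, min)
  test[, fold := fold]
  test[, regulated := fold > cutoff + 1e-12]
  list(sites = test[], n_tested = nrow(test),
       n_regulated = sum(test$regulated),
       regulated_pct = as.integer(round_half_up(
         100 * sum(test$regulated) / max(1L, n_detected))),
       n_detected = n_detected)
}

#' Residue breakdown and overlap with abundance-regulated proteins
#'
#' @param sites phosphosite table with `residue` (and optionally
#'   `regulated`) columns.
#' @param regulated_proteins character vector of gene ids whose protein
#'   abundance is cell-cycle regulated.
#' @return list with `residue_all` and `residue_regulated` tables
#'   (count + percent), `proteins_with_regulated_sites`, `overlap`
#'   (genes in both sets), `overlap_n`.
#' @export
residue_breakdown_and_overlap <- function(sites,
                                          regulated_proteins = character()) {
  st <- data.table::as.data.table(sites)
  tab <- function(d) {
    t <- table(factor(d$residue, levels = c("S", "T", "Y")))
    data.frame(residue = names(t), count = as.integer(t),
               pct = round_half_up(100 * as.integer(t) / max(1L, sum(t))))
  }
  reg <- if ("regulated" %in% names(st)) st[regulated == TRUE] else st[0]
  reg_genes <- unique(reg$gene_id)
  overlap <- intersect(reg_genes, regulated_proteins)
  list(residue_all = tab(st),
       residue_regulated = tab(reg),
       proteins_with_regulated_sites = length(reg_genes),
       overlap = overlap,
       overlap_n = length(overlap))
}

#' Paired phospho and protein profile interpretation
#'
#' Emits both max-scaled six-fraction profiles and their Pearson
#' correlation; the pair is "stoichiometry-constant" when the correlation
#' is at least 0.8 (phosphorylation tracks protein abundance) and
#' "site-regulated" when the protein fold is below the cutoff while the
#' phosphopeptide fold meets it (phosphorylation changes on a constant
#' protein background).
#'
#' @param site_profile,protein_profile numeric vectors named F1..F6.
#' @param cutoff fold cutoff (default 2).
#' @return list with `site_scaled`, `protein_scaled`, `r`, `site_fold`,
#'   `protein_fold`, `flag`.
#' @export
phospho_vs_protein_profiles <- function(site_profile, protein_profile,
                                        cutoff = 2.0) {
  s <- site_profile[FRACTIONS]
  p <- protein_profile[FRACTIONS]
  stopifnot(all(is.finite(s)), all(is.finite(p)), all(s > 0), all(p > 0))
  r <- safe_pearson(s, p)
  sf <- profile_fold(s)
  pf <- profile_fold(p)
  flag <- if (pf < cutoff && sf >= cutoff) "site-regulated"
    else if (!is.na(r) && r >= 0.8) "stoichiometry-constant"
    else "other"
  list(site_scaled = scale_max(s), protein_scaled = scale_max(p),
       r = r, site_fold = sf, protein_fold = pf, flag = flag)
}
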