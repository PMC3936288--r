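#' Isoform-resolved cell-cycle profiling
#'
#' Re-analysis of peptide evidence at isoform resolution: unique-peptide
#' MS/MS-count profiles per isoform, pairwise concordance scoring between
#' isoforms of the same gene, and detection of genes where aggregating all
#' peptides masks an isoform-specific regulation pattern.
#'
#' @name isoform_analysis
NULL

#' Per-isoform MS/MS-count profiles from unique peptides
#'
#' A peptide is unique when it maps to exactly one isoform within its
#' gene's isoform set (determined by exact substring matching against all of
#' the gene's isoform sequences). Isoforms qualify when at least two unique
#' peptides carry MS/MS counts in all six fractions; the profile is the
#' per-fraction mean of the unique peptides' MS/MS counts. Contaminant and
#' decoy rows are excluded.
#'
#' @param evidence evidence table (columns `sequence`, `sample`,
#'   `msms_count`, `gene_id`, plus flags).
#' @param sequences named character vector of isoform sequences
#'   (names in `GENE-n` style).
#' @param min_unique minimum unique peptides per isoform (default 2).
#' @return `data.table` with `isoform_id`, `gene_id`, `unique_peptides`, and
#'   profile columns F1..F6.
#' @export
isoform_profiles <- function(evidence, sequences, min_unique = 2L) {
  ev <- data.table::as.data.table(evidence)
  if ("is_contaminant" %in% names(ev)) ev <- ev[is_contaminant == FALSE]
  if ("is_decoy" %in% names(ev)) ev <- ev[is_decoy == FALSE]
  if ("is_phospho" %in% names(ev)) ev <- ev[is_phospho == FALSE]
  ev <- ev[sample %in% FRACTIONS]
  gene_of_iso <- isoform_gene(names(sequences))

  peps <- unique(ev[, .(sequence, gene_id)])
  rows <- vector("list", length(unique(peps$gene_id)))
  genes <- unique(peps$gene_id)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    iso_ids <- names(sequences)[gene_of_iso == g]
    if (!length(iso_ids)) next
    gp <- peps$sequence[peps$gene_id == g]
    hit <- map_peptides(gp, sequences[iso_ids])
    nh <- table(hit$peptide[!duplicated(paste(hit$peptide, hit$isoform))])
    uni <- names(nh)[nh == 1L]
    if (!length(uni)) next
    hu <- hit[hit$peptide %in% uni & !duplicated(hit$peptide), ]
    rows[[gi]] <- data.table::data.table(sequence = hu$peptide,
                                         isoform_id = hu$isoform)
  }
  umap <- data.table::rbindlist(rows)
  if (nrow(umap) == 0L) {
    return(data.table::data.table(isoform_id = character(),
                                  gene_id = character(),
                                  unique_peptides = integer()))
  }
  evu <- merge(ev, umap, by = "sequence", allow.cartesian = TRUE)
  # MS/MS counts per peptide x fraction (summing protease rows)
  pf <- evu[, .(msms = sum(msms_count)), by = .(isoform_id, sequence, sample)]
  wide <- data.table::dcast(pf, isoform_id + sequence ~ sample,
                            value.var = "msms")
  missing_cols <- setdiff(FRACTIONS, names(wide))
  for (mc in missing_cols) wide[, (mc) := NA_real_]
  complete <- stats::complete.cases(wide[, FRACTIONS, with = FALSE]) &
    rowSums(wide[, FRACTIONS, with = FALSE] > 0) == 6L
  wide <- wide[complete]
  prof <- wide[, c(list(unique_peptides = .N),
                   lapply(.SD, mean)),
               by = isoform_id, .SDcols = FRACTIONS]
  prof <- prof[unique_peptides >= min_unique]
  prof[, gene_id := isoform_gene(isoform_id)]
  data.table::setcolorder(prof, c("isoform_id", "gene_id",
                                  "unique_peptides"))
  prof[]
}

#' Concordance score between isoforms of one gene
#'
#' Pairwise Pearson correlation over the six-fraction profiles; the gene is
#' discordant when the minimum pairwise correlation falls below `r0`.
#' Constant profiles have undefined correlation: such pairs are skipped and
#' flagged.
#'
#' @param profiles `data.frame`/`data.table` of one gene's isoform profiles
#'   (columns `isoform_id` and F1..F6), at least two rows.
#' @param r0 discordance threshold (default 0.5).
#' @return list of class `concordance_score` with `gene_id`, `r_matrix`,
#'   `min_r`, `discordant`, `skipped_pairs`.
#' @export
concordance <- function(profiles, r0 = 0.5) {
  profiles <- data.table::as.data.table(profiles)
  if (nrow(profiles) < 2L) stop("need at least two isoform profiles")
  m <- as.matrix(profiles[, FRACTIONS, with = FALSE])
  rownames(m) <- profiles$isoform_id
  k <- nrow(m)
  R <- diag(1, k)
  dimnames(R) <- list(rownames(m), rownames(m))
  skipped <- character()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- safe_pearson(m[i, ], m[j, ])
      R[i, j] <- R[j, i] <- r
      if (is.na(r)) {
        skipped <- c(skipped, paste(rownames(m)[c(i, j)], collapse = "|"))
      }
    }
  }
  off <- R[upper.tri(R)]
  min_r <- if (all(is.na(off))) NA_real_ else min(off, na.rm = TRUE)
  list(gene_id = isoform_gene(rownames(m)[1L]),
       r_matrix = R, min_r = min_r,
       discordant = isTRUE(min_r < r0),
       skipped_pairs = skipped) |>
    structure(class = "concordance_score")
}

#' Gene-level aggregation masking of isoform regulation
#'
#' Compares the fold change of the pooled gene-level profile (all peptide
#' intensities summed per fraction) with the per-isoform fold changes from
#' unique-peptide intensities. Masking occurs when the pooled fold is below
#' the cutoff while at least one isoform's fold meets it: aggregating
#' peptides across discordant isoforms produces a flat apparent profile.
#'
#' @param evidence evidence table for one gene (or more; grouped by
#'   `gene_id`).
#' @param sequences isoform sequences of the gene(s).
#' @param cutoff regulated fold cutoff (default 2).
#' @param meta optional fraction metadata; when given, intensities are
#'   cell-count-normalized to the per-cell scale before fold computation.
#' @return `data.table` with one row per gene: `gene_id`, `gene_fold`,
#'   `max_isoform_fold`, `masked`, plus list column `isoform_folds`.
#' @export
aggregation_masking <- function(evidence, sequences, cutoff = 2.0,
                                meta = NULL) {
  ev <- data.table::as.data.table(evidence)
  if (!is.null(meta)) {
    nc <- meta$cell_count[match(ev$sample, meta$sample)]
    ev <- data.table::copy(ev)[, intensity := intensity / nc]
  }
  if ("is_contaminant" %in% names(ev)) ev <- ev[is_contaminant == FALSE]
  if ("is_decoy" %in% names(ev)) ev <- ev[is_decoy == FALSE]
  if ("is_phospho" %in% names(ev)) ev <- ev[is_phospho == FALSE]
  ev <- ev[sample %in% FRACTIONS]
  gene_of_iso <- isoform_gene(names(sequences))

  out <- vector("list", length(unique(ev$gene_id)))
  genes <- unique(ev$gene_id)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    sub <- ev[gene_id == g]
    pooled <- sub[, .(intensity = sum(intensity)), by = sample]
    pooled_v <- setNames(pooled$intensity, pooled$sample)[FRACTIONS]
    gene_fold <- if (any(is.na(pooled_v) | pooled_v <= 0)) NA_real_ else
      profile_fold(pooled_v)
    iso_ids <- names(sequences)[gene_of_iso == g]
    hit <- map_peptides(unique(sub$sequence), sequences[iso_ids])
    nh <- table(hit$peptide[!duplicated(paste(hit$peptide, hit$isoform))])
    uni <- names(nh)[nh == 1L]
    hu <- hit[hit$peptide %in% uni & !duplicated(hit$peptide), ]
    iso_folds <- c()
    for (id in unique(hu$isoform)) {
      peps <- hu$peptide[hu$isoform == id]
      si <- sub[sequence %in% peps,
                .(intensity = sum(intensity)), by = sample]
      v <- setNames(si$intensity, si$sample)[FRACTIONS]
      if (any(is.na(v) | v <= 0)) next
      iso_folds[id] <- profile_fold(v)
    }
    max_iso <- if (length(iso_folds)) max(iso_folds) else NA_real_
    out[[gi]] <- data.table::data.table(
      gene_id = g, gene_fold = gene_fold, max_isoform_fold = max_iso,
      masked = isTRUE(gene_fold < cutoff) && isTRUE(max_iso >= cutoff),
      isoform_folds = list(iso_folds))
  }
  data.table::rbindlist(out)
}
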