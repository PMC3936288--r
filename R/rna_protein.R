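#' Protein-mRNA integration
#'
#' Gene-level merging of protein (iBAQ) and mRNA (FPKM) quantitation,
#' Spearman correlation of absolute abundances globally and within scopes,
#' classification of profile concordance between protein and mRNA across
#' the cell cycle, and extraction of the coordinated subset whose protein
#' and mRNA both cycle.
#'
#' @name rna_protein
NULL

#' Merge protein groups and FPKM at gene level
#'
#' Protein abundances of isoforms/groups originating from the same gene are
#' aggregated by summation; FPKM replicates are averaged per pooled sample.
#' Histone genes are removed (poly(A)-selected RNA under-represents their
#' messages). Only genes with complete protein and RNA quantitation in all
#' required samples are retained in the complete-case set.
#'
#' @param ibaq matrix groups x samples of iBAQ (or intensity) values.
#' @param groups group table mapping `group_id` to `gene_id`.
#' @param fpkm long FPKM table (`gene_id`, `sample`, `bio_rep`, `tech_rep`,
#'   `fpkm`).
#' @param histone_genes character vector of histone gene ids to drop.
#' @return `data.table` keyed by `gene_id` with `protein_<sample>` and
#'   `fpkm_<G1/S/G2M/ASYNC>` columns and a `complete` flag; attribute
#'   `n_histone_removed` records dropped histones.
#' @export
merge_gene_level <- function(ibaq, groups, fpkm, histone_genes = character()) {
  stopifnot(all(rownames(ibaq) %in% groups$group_id))
  gid <- groups$gene_id[match(rownames(ibaq), groups$group_id)]
  prot <- rowsum(ibaq, gid, na.rm = TRUE)
  # rowsum(na.rm) turns all-NA cells into 0; restore NA where nothing summed
  cnt <- rowsum((!is.na(ibaq)) + 0, gid)
  prot[cnt == 0] <- NA
  pt <- data.table::as.data.table(prot, keep.rownames = "gene_id")
  data.table::setnames(pt, setdiff(names(pt), "gene_id"),
                       paste0("protein_", setdiff(names(pt), "gene_id")))

  fp <- data.table::as.data.table(fpkm)
  fp <- fp[, .(fpkm = mean(fpkm[fpkm > 0])), by = .(gene_id, sample)]
  fw <- data.table::dcast(fp, gene_id ~ sample, value.var = "fpkm")
  data.table::setnames(fw, setdiff(names(fw), "gene_id"),
                       paste0("fpkm_", setdiff(names(fw), "gene_id")))

  out <- merge(pt, fw, by = "gene_id")
  n_h <- sum(out$gene_id %in% histone_genes)
  out <- out[!gene_id %in% histone_genes]
  need <- intersect(c(paste0("protein_", SAMPLES),
                      paste0("fpkm_", c("G1", "S", "G2M", "ASYNC"))),
                    names(out))
  out[, complete := rowSums(is.na(.SD) | .SD <= 0) == 0, .SDcols = need]
  data.table::setattr(out, "n_histone_removed", n_h)
  out[]
}

#' Spearman correlation of protein and mRNA abundance
#'
#' Rank correlation of log protein versus log mRNA abundance within a
#' scope: the asynchronous samples or one of the pooled phases (protein
#' fractions pooled pairwise to match), or any gene subset.
#'
#' @param records merged gene table from [merge_gene_level()].
#' @param scope `"async"`, `"G1"`, `"S"`, or `"G2M"`.
#' @param genes optional gene-id subset (e.g. one cluster).
#' @param min_n minimum complete records required (default 10).
#' @return list with `rho`, `n`, `scope`.
#' @export
correlate_abundances <- function(records, scope = "async", genes = NULL,
                                 min_n = 10L) {
  rec <- data.table::as.data.table(records)
  if (!is.null(genes)) rec <- rec[gene_id %in% genes]
  pcol <- switch(scope,
    async = "protein_ASYNC",
    G1 = c("protein_F1", "protein_F2"),
    S = c("protein_F3", "protein_F4"),
    G2M = c("protein_F5", "protein_F6"),
    stop("unknown scope: ", scope))
  rcol <- switch(scope, async = "fpkm_ASYNC", paste0("fpkm_", scope))
  p <- rowSums(rec[, pcol, with = FALSE, drop = FALSE])
  r <- rec[[rcol]]
  ok <- is.finite(p) & is.finite(r) & p > 0 & r > 0
  if (sum(ok) < min_n) {
    stop("fewer than ", min_n, " complete records in scope ", scope)
  }
  list(rho = cor(log10(p[ok]), log10(r[ok]), method = "spearman"),
       n = sum(ok), scope = scope)
}

#' Pool a six-fraction protein profile to three phases
#'
#' Cell-count-weighted pooling of (F1,F2), (F3,F4), (F5,F6), mirroring the
#' physical pooling of fractions performed for the RNA samples.
#'
#' @param profile numeric vector or matrix with F1..F6 columns (per-cell
#'   intensities).
#' @param meta fraction metadata.
#' @return vector or matrix with columns G1, S, G2M.
#' @export
pool_protein_profile <- function(profile, meta) {
  if (is.null(dim(profile))) profile <- rbind(profile)
  ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
  pool <- function(cols) {
    w <- ncell[match(cols, FRACTIONS)]
    as.numeric(profile[, cols, drop = FALSE] %*% w / sum(w))
  }
  out <- cbind(G1 = pool(c("F1", "F2")), S = pool(c("F3", "F4")),
               G2M = pool(c("F5", "F6")))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Classify protein/mRNA profile concordance
#'
#' The six-fraction protein profile is pooled to three phase points
#' (cell-count weighted) and compared with the (G1, S, G2M) mRNA profile by
#' Pearson correlation over the three paired points; genes with r >= 0.5
#' are concordant (boundary inclusive). Constant profiles yield undefined
#' correlation and are flagged and excluded from the partition.
#'
#' @param records merged gene table (complete cases used).
#' @param meta fraction metadata.
#' @param r0 concordance threshold (default 0.5).
#' @return `data.table` with `gene_id`, `r`, `status`
#'   (concordant/discordant/undefined).
#' @export
classify_profile_correlation <- function(records, meta, r0 = 0.5) {
  rec <- data.table::as.data.table(records)
  rec <- rec[complete == TRUE]
  prot <- as.matrix(rec[, paste0("protein_", FRACTIONS), with = FALSE])
  colnames(prot) <- FRACTIONS
  ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
  prot <- sweep(prot, 2, ncell, `/`)        # per-cell scale
  pooled <- pool_protein_profile(prot, meta)
  if (is.null(dim(pooled))) pooled <- rbind(pooled)
  rna <- as.matrix(rec[, paste0("fpkm_", PHASES), with = FALSE])
  r <- vapply(seq_len(nrow(rec)),
              function(i) safe_pearson(pooled[i, ], rna[i, ]), numeric(1))
  status <- ifelse(is.na(r), "undefined",
                   ifelse(r >= r0 - 1e-12, "concordant", "discordant"))
  data.table::data.table(gene_id = rec$gene_id, r = r, status = status)
}

#' Coordinated protein + mRNA regulated subset
#'
#' Among abundance-regulated proteins, selects genes whose cognate mRNA
#' also varies across the pooled fractions by strictly more than
#' `rna_cutoff` (default 1.5-fold), and reports the mean max-scaled protein
#' and mRNA profiles with their Pearson correlation.
#'
#' @param regulated_genes character vector of regulated gene ids.
#' @param records merged gene table.
#' @param meta fraction metadata.
#' @param rna_cutoff mRNA fold threshold (default 1.5, strict).
#' @return list with `genes`, `n`, `rna_fold` (named), `mean_protein`,
#'   `mean_rna` (3-point scaled profiles), `profile_r`.
#' @export
coordinated_subset <- function(regulated_genes, records, meta,
                               rna_cutoff = 1.5) {
  rec <- data.table::as.data.table(records)
  rec <- rec[complete == TRUE & gene_id %in% regulated_genes]
  rna <- as.matrix(rec[, paste0("fpkm_", PHASES), with = FALSE])
  fold <- apply(rna, 1, function(v) max(v) / min(v))
  sel <- fold > rna_cutoff + 1e-12
  genes <- rec$gene_id[sel]
  if (!any(sel)) {
    return(list(genes = character(), n = 0L, rna_fold = numeric(),
                mean_protein = NULL, mean_rna = NULL, profile_r = NA_real_))
  }
  prot <- as.matrix(rec[sel, paste0("protein_", FRACTIONS), with = FALSE])
  colnames(prot) <- FRACTIONS
  ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
  prot <- sweep(prot, 2, ncell, `/`)        # per-cell scale
  pooled <- pool_protein_profile(prot, meta)
  if (is.null(dim(pooled))) pooled <- rbind(pooled)
  mp <- colMeans(t(apply(pooled, 1, scale_max)))
  mr <- colMeans(t(apply(rna[sel, , drop = FALSE], 1, scale_max)))
  list(genes = genes, n = length(genes),
       rna_fold = setNames(fold[sel], genes),
       mean_protein = mp, mean_rna = mr,
       profile_r = safe_pearson(mp, mr))
}
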