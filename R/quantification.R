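#' Protein-group quantification
#'
#' Aggregation of peptide-level evidence into protein groups (isoforms
#' indistinguishable by their detected peptides are merged; subset peptide
#' sets are subsumed), razor assignment of shared peptides, median-log-ratio
#' cross-sample normalization, iBAQ absolute abundance estimation, and
#' cumulative abundance accounting.
#'
#' @name quantification
NULL

#' Group isoforms by shared peptide evidence
#'
#' Isoforms with identical detected peptide sets are merged into one group;
#' an isoform whose peptide set is a strict subset of another's is subsumed
#' into that group; isoforms retaining unique peptides stay separate.
#'
#' @param evidence evidence table with `sequence` and `isoform_ids`
#'   (semicolon-separated) columns; contaminant/decoy flags are carried
#'   through to the groups.
#' @return `data.table` with one row per group: `group_id`, `members`
#'   (semicolon-separated isoform ids), `gene_id` (leading gene),
#'   `peptide_count` (distinct peptide sequences), `is_contaminant`,
#'   `is_decoy`.
#' @export
group_proteins <- function(evidence) {
  ev <- data.table::as.data.table(evidence)
  map <- ev[, .(sequence, isoform_ids)]
  map <- unique(map)
  iso_long <- map[, .(isoform = strsplit(isoform_ids, ";", fixed = TRUE)[[1]]),
                  by = sequence]
  sets <- split(iso_long$sequence, iso_long$isoform)
  sets <- lapply(sets, function(s) sort(unique(s)))
  iso_ids <- names(sets)
  sizes <- vapply(sets, length, 1L)
  keys <- vapply(sets, paste, "", collapse = "\r")

  # merge identical sets
  first_of_key <- !duplicated(keys)
  rep_ids <- iso_ids[first_of_key]
  group_of <- setNames(match(keys, keys[first_of_key]), iso_ids)

  # subsumption: representative whose set is a strict subset of another
  # representative's set joins that group (largest superset; ties broken
  # lexicographically by representative id)
  rep_sets <- sets[rep_ids]
  rep_sizes <- sizes[rep_ids]
  ord <- order(-rep_sizes, rep_ids)
  # peptide -> representatives index for candidate supersets
  pep_to_rep <- list()
  for (r in seq_along(rep_sets)) {
    for (p in rep_sets[[r]]) pep_to_rep[[p]] <- c(pep_to_rep[[p]], r)
  }
  target <- seq_along(rep_sets)            # group index each rep maps to
  for (r in seq_along(rep_sets)) {
    s <- rep_sets[[r]]
    cand <- unique(unlist(pep_to_rep[s], use.names = FALSE))
    cand <- cand[cand != r & rep_sizes[cand] > rep_sizes[r]]
    if (!length(cand)) next
    sup <- cand[vapply(cand, function(cc) all(s %in% rep_sets[[cc]]),
                       logical(1))]
    if (length(sup)) {
      sup <- sup[order(-rep_sizes[sup], rep_ids[sup])][1L]
      target[r] <- sup
    }
  }
  # follow one level of chaining (subset of a subset)
  target <- target[target]
  group_idx <- target[group_of]

  members <- split(iso_ids, group_idx)
  has_flags <- all(c("is_contaminant", "is_decoy") %in% names(ev))
  rows <- lapply(seq_along(members), function(i) {
    mem <- sort(members[[i]])
    peps <- sort(unique(unlist(sets[mem], use.names = FALSE)))
    data.table::data.table(
      members = paste(mem, collapse = ";"),
      gene_id = isoform_gene(mem[1L]),
      peptide_count = length(peps),
      peptides = paste(peps, collapse = ";"))
  })
  groups <- data.table::rbindlist(rows)
  data.table::setorder(groups, gene_id, members)
  groups[, group_id := sprintf("PG%05d", .I)]
  if (has_flags) {
    iso_flag <- unique(ev[, .(isoform_ids, is_contaminant, is_decoy)])
    iso_flag <- iso_flag[, .(
      is_contaminant = any(is_contaminant), is_decoy = any(is_decoy)),
      by = isoform_ids]
    iso_flag_long <- iso_flag[, .(
      isoform = strsplit(isoform_ids, ";", fixed = TRUE)[[1]],
      is_contaminant, is_decoy), by = isoform_ids]
    fl <- iso_flag_long[, .(is_contaminant = any(is_contaminant),
                            is_decoy = any(is_decoy)), by = isoform]
    groups[, is_contaminant := vapply(strsplit(members, ";", fixed = TRUE),
      function(m) any(fl$is_contaminant[match(m, fl$isoform)], na.rm = TRUE),
      logical(1))]
    groups[, is_decoy := vapply(strsplit(members, ";", fixed = TRUE),
      function(m) any(fl$is_decoy[match(m, fl$isoform)], na.rm = TRUE),
      logical(1))]
  } else {
    groups[, `:=`(is_contaminant = FALSE, is_decoy = FALSE)]
  }
  data.table::setcolorder(groups, c("group_id", "gene_id", "members",
                                    "peptide_count"))
  groups[]
}

#' Aggregate peptide intensities to protein groups and normalize samples
#'
#' Protein intensity per sample is the sum of member peptide intensities.
#' Shared peptides are assigned by the razor rule: to the group with the
#' most peptides, ties broken lexicographically by group id. Peptides with
#' modifications are excluded from quantitation except those known to occur
#' during sample processing (deamidation, pyro-Glu); phosphopeptide rows are
#' likewise excluded. Samples are then equalized by median log-ratio to a
#' geometric-mean pseudo-reference.
#'
#' @param evidence evidence table.
#' @param groups output of [group_proteins()].
#' @return list with `raw` and `normalized` matrices (groups x samples),
#'   `scale_factors`, and `assignment` (peptide -> group_id).
#' @export
aggregate_and_normalize <- function(evidence, groups) {
  ev <- data.table::as.data.table(evidence)
  allowed_mods <- c("Unmodified", "Deamidation (NQ)", "Gln->pyro-Glu")
  if ("modifications" %in% names(ev)) {
    ev <- ev[modifications %in% allowed_mods]
  }
  if ("is_phospho" %in% names(ev)) ev <- ev[is_phospho == FALSE]

  # razor assignment of peptides to groups
  pep_group <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    pep_group[[i]] <- data.table::data.table(
      sequence = strsplit(groups$peptides[i], ";", fixed = TRUE)[[1]],
      group_id = groups$group_id[i],
      peptide_count = groups$peptide_count[i])
  }
  pg <- data.table::rbindlist(pep_group)
  data.table::setorder(pg, sequence, -peptide_count, group_id)
  assignment <- pg[!duplicated(sequence)]

  ev <- merge(ev, assignment[, .(sequence, group_id)], by = "sequence")
  samples <- intersect(SAMPLES, unique(ev$sample))
  agg <- ev[, .(intensity = sum(intensity)), by = .(group_id, sample)]
  raw <- matrix(0, nrow(groups), length(samples),
                dimnames = list(groups$group_id, samples))
  raw[cbind(match(agg$group_id, groups$group_id),
            match(agg$sample, samples))] <- agg$intensity

  totals <- colSums(raw)
  if (any(totals == 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(samples[totals == 0], collapse = ", "))
  }
  # median log-ratio to geometric-mean pseudo-reference over complete rows
  lr <- log(raw)
  lr[!is.finite(lr)] <- NA
  ref <- rowMeans(lr, na.rm = FALSE)
  sf <- apply(lr - ref, 2, median, na.rm = TRUE)
  normalized <- sweep(raw, 2, exp(sf), `/`)
  list(raw = raw, normalized = normalized, scale_factors = exp(sf),
       assignment = assignment[, .(sequence, group_id)])
}

#' iBAQ absolute abundance
#'
#' iBAQ = summed protein intensity divided by the number of theoretically
#' observable tryptic peptides (fully cleaved, 7--30 residues by default).
#' Groups with zero theoretical peptides are flagged and get `NA`.
#'
#' @param intensity matrix groups x samples (raw or normalized).
#' @param groups group table from [group_proteins()].
#' @param sequences named character vector of isoform sequences (theoretical
#'   peptides are computed on the first member isoform of each group).
#' @param min_length,max_length theoretical peptide length window.
#' @return list with `ibaq` (matrix, same shape as `intensity`),
#'   `theoretical_peptides` (per group), `flagged` (group ids with zero
#'   theoretical peptides).
#' @export
compute_ibaq <- function(intensity, groups, sequences,
                         min_length = 7L, max_length = 30L) {
  spec <- digest_spec("TrypsinDD", missed_cleavages = 0L,
                      min_length = min_length, max_length = max_length)
  lead <- vapply(strsplit(groups$members, ";", fixed = TRUE),
                 `[`, "", 1L)
  theo <- vapply(lead, function(id) {
    if (!id %in% names(sequences)) return(NA_integer_)
    s <- sequences[[id]]
    if (is.null(s) || is.na(s)) return(NA_integer_)
    nrow(suppressWarnings(digest_sequence(s, spec)))
  }, integer(1))
  theo_full <- setNames(theo, groups$group_id)
  ib <- intensity / theo_full[rownames(intensity)]
  ib[is.na(theo_full[rownames(intensity)]) |
       theo_full[rownames(intensity)] == 0, ] <- NA
  flagged <- groups$group_id[!is.na(theo) & theo == 0]
  list(ibaq = ib, theoretical_peptides = theo_full, flagged = flagged)
}

#' Cumulative abundance accounting
#'
#' Sorts abundances in decreasing order and reports, for each requested
#' quantile of total abundance, the smallest number of proteins whose
#' cumulative share reaches it; also returns quartile bins of log10
#' abundance for enrichment reporting.
#'
#' @param abundance numeric vector (e.g. iBAQ values); names are carried
#'   through.
#' @param quantiles abundance shares to report (default 0.5 and 0.9).
#' @return list of class `abundance_summary` with `k` (named vector, one
#'   entry per quantile), `n`, `ranked` (sorted abundances), `share`
#'   (cumulative shares), and `quartile_bin` (factor over input order).
#' @export
cumulative_abundance <- function(abundance, quantiles = c(0.5, 0.9)) {
  abundance <- abundance[!is.na(abundance)]
  if (length(abundance) == 0L) stop("no abundances supplied")
  if (all(abundance == 0)) stop("all abundances are zero")
  o <- order(abundance, decreasing = TRUE)
  ranked <- abundance[o]
  share <- cumsum(ranked) / sum(ranked)
  k <- vapply(quantiles, function(q) which(share >= q - 1e-12)[1L], 1L)
  names(k) <- paste0("k", format(100 * quantiles, trim = TRUE), "pct")
  lg <- log10(abundance)
  lg[!is.finite(lg)] <- NA
  qs <- quantile(lg, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
  brk <- unique(c(-Inf, qs, Inf))
  bin <- cut(lg, breaks = brk,
             labels = paste0("Q", seq_len(length(brk) - 1L)))
  structure(list(k = k, n = length(abundance), ranked = ranked,
                 share = share, quartile_bin = bin),
            class = "abundance_summary")
}
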