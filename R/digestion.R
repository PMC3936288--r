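#' In-silico proteolytic digestion and sequence coverage
#'
#' Tools for digesting protein sequences with Lys-C or trypsin (double
#' digest), mapping observed peptides back to isoform sequences, accounting
#' amino-acid coverage, partitioning peptides by protease, and checking the
#' identified set for amino-acid composition bias against a reference
#' database.
#'
#' @name digestion
NULL

#' Digestion specification
#'
#' @param protease `"LysC"` (cleaves C-terminal to K) or `"TrypsinDD"`
#'   (Lys-C/trypsin double digest; cleaves C-terminal to K or R). The double
#'   digest is modelled as trypsin/P, i.e. cleavage occurs even when the next
#'   residue is proline, matching the usual database-search setting;
#'   set `trypsin_p = FALSE` for classic trypsin.
#' @param missed_cleavages maximum number of internal cleavage sites retained
#'   in a peptide (default 2).
#' @param min_length,max_length peptide length bounds in residues. Defaults
#'   keep every fragment; detection-oriented callers typically use 7--35.
#' @param trypsin_p logical; cleave before proline (default `TRUE`).
#' @return An object of class `digest_spec`.
#' @export
digest_spec <- function(protease = c("TrypsinDD", "LysC"),
                        missed_cleavages = 2L,
                        min_length = 1L, max_length = Inf,
                        trypsin_p = TRUE) {
  protease <- match.arg(protease)
  stopifnot(missed_cleavages >= 0, min_length >= 1, max_length >= min_length)
  structure(
    list(protease = protease, missed_cleavages = as.integer(missed_cleavages),
         min_length = min_length, max_length = max_length,
         trypsin_p = trypsin_p),
    class = "digest_spec"
  )
}

#' Digest one protein sequence in silico
#'
#' Lys-C cleaves C-terminal to lysine; the Lys-C/trypsin double digest
#' cleaves C-terminal to lysine or arginine (trypsin/P convention by
#' default, i.e. including before proline). Peptides containing up to
#' `spec$missed_cleavages` internal sites are enumerated.
#'
#' @param sequence a single amino-acid string using the 20 standard residues.
#' @param spec a [digest_spec()].
#' @return A `data.frame` with columns `peptide`, `start`, `end` (0-based,
#'   half-open residue coordinates) and `missed` (number of internal sites).
#'   Sequences containing non-standard residues are rejected with a warning
#'   and yield a zero-row result.
#' @examples
#' digest_sequence("MKAEKRPK", digest_spec("LysC", missed_cleavages = 0))
#' @export
digest_sequence <- function(sequence, spec = digest_spec()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n == 0L || any(!res %in% AA20)) {
    warning("sequence contains non-standard residues; record rejected")
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  targets <- if (spec$protease == "LysC") "K" else c("K", "R")
  cut_after <- which(res %in% targets)
  if (spec$protease == "TrypsinDD" && !spec$trypsin_p) {
    cut_after <- cut_after[res[pmin(cut_after + 1L, n)] != "P" | cut_after == n]
  }
  cut_after <- cut_after[cut_after < n]          # C-terminus is always an end
  bounds <- c(0L, cut_after, n)                  # fragment boundaries
  nfrag <- length(bounds) - 1L
  out <- vector("list", spec$missed_cleavages + 1L)
  for (m in 0:spec$missed_cleavages) {
    i <- seq_len(nfrag - m)
    if (length(i) == 0L) next
    start <- bounds[i]
    end <- bounds[i + m + 1L]
    out[[m + 1L]] <- data.frame(start = start, end = end, missed = m)
  }
  out <- do.call(rbind, out)
  len <- out$end - out$start
  out <- out[len >= spec$min_length & len <= spec$max_length, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed = integer()))
  }
  out$peptide <- substring(sequence, out$start + 1L, out$end)
  rownames(out) <- NULL
  out[, c("peptide", "start", "end", "missed")]
}

#' Map peptides to the sequences that contain them
#'
#' Exact substring matching of each peptide against each candidate sequence.
#' When a `candidates` list is supplied (peptide -> character vector of
#' isoform ids) only those sequences are searched, which keeps the mapping
#' near-linear for large evidence tables.
#'
#' @param peptides character vector of peptide sequences.
#' @param sequences named character vector of isoform sequences.
#' @param candidates optional named list restricting the search space.
#' @return `data.frame` with columns `peptide`, `isoform`, `start` (0-based).
#'   Peptides matching nothing are absent (see [compute_coverage()]
#'   diagnostics).
#' @export
map_peptides <- function(peptides, sequences, candidates = NULL) {
  peptides <- unique(peptides)
  rows <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    ids <- if (is.null(candidates)) names(sequences) else
      intersect(candidates[[pep]], names(sequences))
    hit_iso <- character(); hit_start <- integer()
    for (id in ids) {
      m <- gregexpr(pep, sequences[[id]], fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        hit_iso <- c(hit_iso, rep(id, length(m)))
        hit_start <- c(hit_start, as.integer(m) - 1L)
      }
    }
    if (length(hit_iso)) {
      rows[[i]] <- data.frame(peptide = pep, isoform = hit_iso,
                              start = hit_start)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(), isoform = character(),
                      start = integer())
  }
  out
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Amino-acid coverage of isoforms by observed peptides
#'
#' Maps each observed peptide to every isoform containing it (peptides shared
#' across isoforms contribute coverage to each), merges the covered residue
#' intervals, and reports per-isoform and mean coverage, optionally split by
#' protease.
#'
#' @param peptides a `data.frame` with a `peptide` column and optionally a
#'   `protease` column, or a character vector of peptides.
#' @param sequences named character vector of isoform sequences.
#' @param candidates optional peptide -> isoform-id candidate list passed to
#'   [map_peptides()].
#' @return A list of class `coverage_map` with elements
#'   `per_isoform` (data.frame: isoform, length, covered, coverage, and per-
#'   protease covered counts when protease labels are present), `intervals`
#'   (merged covered intervals per isoform), `mean_coverage` (over isoforms
#'   with at least one mapped peptide), `total_covered` residues, and
#'   `unmapped` (peptides matching no sequence).
#' @export
compute_coverage <- function(peptides, sequences, candidates = NULL) {
  if (is.character(peptides)) peptides <- data.frame(peptide = peptides)
  stopifnot("peptide" %in% names(peptides))
  has_prot <- "protease" %in% names(peptides)
  map <- map_peptides(unique(peptides$peptide), sequences, candidates)
  unmapped <- setdiff(unique(peptides$peptide), unique(map$peptide))
  pep_len <- nchar(map$peptide)

  cover_one <- function(m) {
    if (nrow(m) == 0L) return(NULL)
    iv <- split(seq_len(nrow(m)), m$isoform)
    res <- lapply(names(iv), function(id) {
      idx <- iv[[id]]
      mi <- merge_intervals(m$start[idx], m$start[idx] + nchar(m$peptide[idx]))
      data.frame(isoform = id, mi, covered = sum(mi$end - mi$start))
    })
    do.call(rbind, res)
  }

  all_iv <- cover_one(map)
  per_iso <- data.frame(isoform = names(sequences),
                        length = nchar(sequences),
                        row.names = NULL)
  # `covered` is constant within isoform, so the first row per isoform is exact
  cov_tab <- if (is.null(all_iv)) {
    data.frame(isoform = character(), covered = integer())
  } else {
    all_iv[!duplicated(all_iv$isoform), c("isoform", "covered")]
  }
  per_iso$covered <- cov_tab$covered[match(per_iso$isoform, cov_tab$isoform)]
  per_iso$covered[is.na(per_iso$covered)] <- 0L
  per_iso$coverage <- per_iso$covered / per_iso$length

  if (has_prot) {
    for (pr in unique(peptides$protease)) {
      peps <- unique(peptides$peptide[peptides$protease == pr])
      sub <- map[map$peptide %in% peps, , drop = FALSE]
      iv <- cover_one(sub)
      col <- paste0("covered_", pr)
      per_iso[[col]] <- 0L
      if (!is.null(iv)) {
        tab <- iv[!duplicated(iv$isoform), c("isoform", "covered")]
        per_iso[[col]] <- tab$covered[match(per_iso$isoform, tab$isoform)]
        per_iso[[col]][is.na(per_iso[[col]])] <- 0L
      }
    }
  }

  detected <- per_iso$covered > 0
  structure(list(
    per_isoform = per_iso,
    intervals = if (is.null(all_iv)) NULL else
      all_iv[, c("isoform", "start", "end")],
    mean_coverage = if (any(detected)) mean(per_iso$coverage[detected])
      else NA_real_,
    total_covered = sum(per_iso$covered),
    unmapped = unmapped
  ), class = "coverage_map")
}

#' Partition observed peptides by protease
#'
#' Classifies sequence-unique peptides as identified only by Lys-C, only by
#' the trypsin double digest, or by both, and reports the relative gain in
#' peptide identifications attributable to adding Lys-C:
#' `LysC-only / (TrypsinDD-only + shared)`, truncated to an integer percent.
#'
#' @param peptides `data.frame` with `peptide` and `protease` columns, or a
#'   list with precomputed counts `lysc_only`, `trypsindd_only`, `shared`.
#' @return list with `counts`, `percent` (of total unique peptides), `total`,
#'   and `relative_increase_pct`.
#' @export
partition_by_protease <- function(peptides) {
  if (is.data.frame(peptides)) {
    stopifnot(all(c("peptide", "protease") %in% names(peptides)))
    sets <- split(peptides$protease, peptides$peptide)
    lysc <- vapply(sets, function(s) "LysC" %in% s, logical(1))
    tryp <- vapply(sets, function(s) "TrypsinDD" %in% s, logical(1))
    counts <- c(lysc_only = sum(lysc & !tryp),
                trypsindd_only = sum(tryp & !lysc),
                shared = sum(lysc & tryp))
  } else {
    counts <- c(lysc_only = peptides$lysc_only,
                trypsindd_only = peptides$trypsindd_only,
                shared = peptides$shared)
  }
  total <- sum(counts)
  denom <- counts[["trypsindd_only"]] + counts[["shared"]]
  rel <- if (denom > 0) floor(100 * counts[["lysc_only"]] / denom) else 0
  list(counts = counts,
       percent = 100 * counts / total,
       total = total,
       relative_increase_pct = rel)
}

#' Residue frequency vector of a set of sequences
#' @param sequences character vector of amino-acid sequences.
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
residue_frequencies <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sequence set")
  res <- unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE)
  res <- res[res %in% AA20]
  tab <- table(factor(res, levels = AA20))
  as.numeric(tab) / sum(tab) -> p
  names(p) <- AA20
  p
}

#' Composition-bias check of an identified set against a reference database
#'
#' Compares the amino-acid frequency vectors of the identified protein set
#' and of the full search database; a high Pearson correlation indicates the
#' identified proteome samples the database without strong composition bias.
#' The same machinery applies to any paired frequency vectors (e.g.
#' annotation-term frequencies) via the `observed_freq`/`reference_freq`
#' return values.
#'
#' @param observed,reference character vectors of sequences (both non-empty).
#' @return list with `observed_freq`, `reference_freq` and `correlation`.
#' @export
composition_bias <- function(observed, reference) {
  if (length(observed) == 0L || length(reference) == 0L) {
    stop("composition_bias() requires non-empty sequence sets")
  }
  fo <- residue_frequencies(observed)
  fr <- residue_frequencies(reference)
  list(observed_freq = fo, reference_freq = fr,
       correlation = cor(fo, fr))
}
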