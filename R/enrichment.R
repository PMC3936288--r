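#' Degron motif scanning and annotation enrichment
#'
#' Scans protein sequences for APC/C degradation motifs (the KEN box and
#' the D-box R-x-x-L) and tests gene sets for enrichment of annotation
#' terms (GO-like terms, transcription-factor binding sites) by the
#' hypergeometric upper tail with Benjamini-Hochberg adjustment, plus an
#' exact binomial test against a fixed background rate.
#'
#' @name enrichment_motifs
NULL

DEGRON_PATTERNS <- c(KEN = "KEN", DBOX = "R..L")

#' Scan sequences for degron motifs
#'
#' All match start positions are reported, including overlapping matches
#' (scanning uses a zero-width lookahead). Per-gene flags are
#' existence-based over all isoforms of the gene.
#'
#' @param sequences named character vector of isoform sequences.
#' @param gene_set optional character vector of gene ids to restrict and to
#'   compute fold enrichment for (against all genes in `sequences`).
#' @param patterns named character vector of motif regexes (default KEN and
#'   R-x-x-L).
#' @return list with `hits` (`data.table`: isoform_id, motif, start
#'   (1-based), match), `per_gene` (gene_id, has_KEN, has_DBOX, has_both,
#'   has_any), and when `gene_set` given, `fold_enrichment` of the any-degron
#'   frequency in the set versus all genes.
#' @export
scan_degrons <- function(sequences, gene_set = NULL,
                         patterns = DEGRON_PATTERNS) {
  rows <- vector("list", length(sequences) * length(patterns))
  k <- 1L
  for (i in seq_along(sequences)) {
    for (m in names(patterns)) {
      pat <- patterns[[m]]
      starts <- gregexpr(paste0("(?=", pat, ")"), sequences[[i]],
                         perl = TRUE)[[1]]
      if (starts[1] != -1L) {
        width <- nchar(gsub("\\.", "x", pat))
        rows[[k]] <- data.table::data.table(
          isoform_id = names(sequences)[i], motif = m,
          start = as.integer(starts),
          match = substring(sequences[[i]], starts, starts + width - 1L))
      }
      k <- k + 1L
    }
  }
  hits <- data.table::rbindlist(rows)
  if (nrow(hits) == 0L) {
    hits <- data.table::data.table(isoform_id = character(),
                                   motif = character(), start = integer(),
                                   match = character())
  }
  gene_of <- isoform_gene(names(sequences))
  genes <- unique(gene_of)
  per_gene <- data.table::data.table(gene_id = genes)
  for (m in names(patterns)) {
    hit_genes <- if (nrow(hits)) unique(isoform_gene(
      hits$isoform_id[hits$motif == m])) else character()
    per_gene[, (paste0("has_", m)) := gene_id %in% hit_genes]
  }
  per_gene[, has_both := has_KEN & has_DBOX]
  per_gene[, has_any := has_KEN | has_DBOX]
  out <- list(hits = hits, per_gene = per_gene)
  if (!is.null(gene_set)) {
    inset <- per_gene$gene_id %in% gene_set
    bg_rate <- mean(per_gene$has_any)
    set_rate <- mean(per_gene$has_any[inset])
    out$fold_enrichment <- if (bg_rate > 0) set_rate / bg_rate else NA_real_
    out$set_rate <- set_rate
    out$background_rate <- bg_rate
  }
  out
}

#' Hypergeometric enrichment of annotation terms in a gene set
#'
#' For each term, tests whether the gene set contains more term-annotated
#' genes than expected by drawing without replacement from the background:
#' upper-tail hypergeometric p-value `P(X >= k)`, Benjamini-Hochberg
#' adjustment across terms. Terms absent from the background are skipped
#' with a warning.
#'
#' @param gene_set character vector (must be a subset of `background`).
#' @param annotations `data.frame` with `gene_id` and `term_id` (and
#'   optionally `term_type`) columns.
#' @param background character vector of all eligible gene ids.
#' @return `data.table` with `term_id`, `k` (in set), `n` (set size), `K`
#'   (in background), `N` (background size), `pct_in_set` (round half up),
#'   `p`, `q` (BH), sorted by `p`.
#' @export
enrich_terms <- function(gene_set, annotations, background) {
  stopifnot(all(gene_set %in% background))
  ann <- data.table::as.data.table(annotations)
  ann <- ann[gene_id %in% background]
  N <- length(unique(background))
  n <- length(unique(gene_set))
  terms <- unique(annotations$term_id)
  absent <- setdiff(terms, unique(ann$term_id))
  if (length(absent)) {
    warning("terms absent from background skipped: ",
            paste(absent, collapse = ", "))
  }
  res <- ann[, {
    K <- length(unique(gene_id))
    k <- length(unique(intersect(gene_id, gene_set)))
    .(k = k, n = n, K = K, N = N,
      pct_in_set = round_half_up(100 * k / max(1L, n)),
      p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  }, by = term_id]
  data.table::setorder(res, p, term_id)
  res[, q := p.adjust(p, method = "BH")]
  res[]
}

#' Binomial frequency test against a background rate
#'
#' Exact upper-tail binomial test of `k` successes in `n` trials against a
#' stated background rate; reports the observed percentage (round half up).
#'
#' @param k observed count in the gene set.
#' @param n gene-set size.
#' @param rate background success rate in (0, 1).
#' @return list with `k`, `n`, `observed_pct`, `p`.
#' @export
tfbs_frequency_test <- function(k, n, rate) {
  stopifnot(rate > 0, rate < 1, k >= 0, k <= n)
  list(k = k, n = n,
       observed_pct = round_half_up(100 * k / n),
       p = pbinom(k - 1L, n, rate, lower.tail = FALSE))
}
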