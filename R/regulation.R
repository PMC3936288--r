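#' Detection and clustering of cell-cycle-regulated proteins
#'
#' A protein is called cell-cycle regulated when its per-cell intensity
#' varies across the six elutriated fractions by at least a twofold cutoff.
#' Regulated proteins are Ward-clustered on max-scaled profiles into 16
#' clusters; the single bimodal cluster (peaks in both F1 and F6 with an
#' S-phase trough) is retained as the G2M+G1 cluster and all other proteins
#' are reassigned to six clusters by the fraction of maximum expression,
#' mapped to broad classes F1/F2 -> G1, F3/F4 -> S, F5/F6 -> G2M.
#'
#' @name cycle_regulation
NULL

BROAD_OF_FRACTION <- c(F1 = "G1", F2 = "G1", F3 = "S", F4 = "S",
                       F5 = "G2M", F6 = "G2M")

#' Detect regulated proteins by fold-change cutoff
#'
#' @param profiles matrix proteins x fractions (per-cell intensities,
#'   strictly positive), columns F1..F6.
#' @param cutoff fold-change threshold (default 2; boundary inclusive).
#' @return list with `fold` (named vector), `regulated` (logical vector),
#'   `ids` (regulated protein ids), `proportion` (regulated / total).
#' @export
detect_regulated <- function(profiles, cutoff = 2.0) {
  stopifnot(all(FRACTIONS %in% colnames(profiles)))
  m <- profiles[, FRACTIONS, drop = FALSE]
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("profiles must be strictly positive in all six fractions")
  }
  fold <- apply(m, 1, max) / apply(m, 1, min)
  regulated <- fold >= cutoff - 1e-12
  list(fold = fold, regulated = regulated,
       ids = rownames(m)[regulated],
       proportion = mean(regulated))
}

# is a centroid bimodal: ends within 80% of max, interior entry <= 60%
is_bimodal_centroid <- function(ctr) {
  m <- max(ctr)
  ctr[1] >= 0.8 * m && ctr[6] >= 0.8 * m && min(ctr[2:5]) <= 0.6 * m
}

#' Cluster regulated profiles by phase of maximum expression
#'
#' Ward linkage (Euclidean distance on max-scaled profiles), cut at 16
#' clusters. The cluster whose centroid is bimodal is kept as cluster 7
#' (broad class G2M+G1, preferring the largest such cluster); all remaining
#' proteins are reassigned to clusters 1-6 by argmax fraction.
#'
#' @param profiles matrix regulated-proteins x F1..F6.
#' @param k initial number of Ward clusters (default 16).
#' @return `data.frame` with `protein`, `cluster` (1-7), `broad_class`,
#'   `argmax_fraction`, `fold`, plus attribute `bimodal_found`.
#' @export
cluster_profiles <- function(profiles, k = 16L) {
  m <- profiles[, FRACTIONS, drop = FALSE]
  if (nrow(m) < k + 1L) {
    stop("need at least ", k + 1L, " regulated profiles to cut ", k,
         " clusters")
  }
  scaled <- t(apply(m, 1, scale_max))
  hc <- hclust(dist(scaled), method = "ward.D2")
  cl <- cutree(hc, k = k)
  centroids <- rowsum(scaled, cl) / as.vector(table(cl))
  # every cluster whose centroid is bimodal is retained as cluster 7
  # (typically a single cluster, as in the 16-cut procedure)
  bim <- which(apply(centroids, 1, is_bimodal_centroid))
  bimodal_found <- length(bim) > 0
  cluster7 <- bimodal_found & cl %in% bim
  amax <- FRACTIONS[apply(scaled, 1, which.max)]
  cluster <- match(amax, FRACTIONS)
  broad <- BROAD_OF_FRACTION[amax]
  cluster[cluster7] <- 7L
  broad[cluster7] <- "G2M+G1"
  out <- data.frame(protein = rownames(m), cluster = cluster,
                    broad_class = unname(broad), argmax_fraction = amax,
                    fold = apply(m, 1, profile_fold), row.names = NULL)
  attr(out, "bimodal_found") <- bimodal_found
  if (!bimodal_found) {
    message("no bimodal cluster found; cluster 7 left empty")
  }
  out
}

#' Summary of cell-cycle regulation
#'
#' @param assignments output of [cluster_profiles()].
#' @param filtered_size size of the filtered high-quality data set the
#'   regulated set was detected in.
#' @return list with `n_regulated`, `filtered_size`, `regulated_pct`
#'   (one decimal), `by_cluster` and `by_class` count/percentage tables.
#' @export
summarize_regulation <- function(assignments, filtered_size) {
  n <- nrow(assignments)
  pct <- if (filtered_size > 0) round_half_up(100 * n / filtered_size, 1) else 0
  by_cluster <- table(factor(assignments$cluster, levels = 1:7))
  by_class <- table(factor(assignments$broad_class,
                           levels = c("G1", "S", "G2M", "G2M+G1")))
  list(
    n_regulated = n,
    filtered_size = filtered_size,
    regulated_pct = pct,
    by_cluster = data.frame(cluster = names(by_cluster),
                            count = as.integer(by_cluster),
                            pct = if (n > 0)
                              round_half_up(100 * as.integer(by_cluster) / n, 1)
                            else 0),
    by_class = data.frame(class = names(by_class),
                          count = as.integer(by_class),
                          pct = if (n > 0)
                            round_half_up(100 * as.integer(by_class) / n, 1)
                          else 0)
  )
}
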