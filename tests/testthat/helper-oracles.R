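# Independent oracles and shared fixtures for the test suite.

# Dense grid-search oracle for 3-variable non-negative least squares:
# coarse grid with two refinement passes around the incumbent.
grid_nnls_rss <- function(A, b, hi = 30, n = 61, refine = 2) {
  gr <- seq(0, hi, length.out = n)
  g <- as.matrix(expand.grid(gr, gr, gr))
  rss <- rowSums((g %*% t(A) - matrix(b, nrow(g), length(b),
                                      byrow = TRUE))^2)
  best <- g[which.min(rss), ]
  w <- hi / (n - 1)
  for (r in seq_len(refine)) {
    gr2 <- seq(-w, w, length.out = 21)
    g2 <- as.matrix(expand.grid(best[1] + gr2, best[2] + gr2,
                                best[3] + gr2))
    g2[g2 < 0] <- 0
    rss2 <- rowSums((g2 %*% t(A) - matrix(b, nrow(g2), length(b),
                                          byrow = TRUE))^2)
    best <- g2[which.min(rss2), ]
    w <- w / 10
  }
  sum((as.numeric(A %*% best) - b)^2)
}

# Brute-force hypergeometric upper tail by subset enumeration: probability
# that a uniformly drawn size-n subset of 1..N contains at least k of the K
# marked elements.
brute_hyper_p <- function(k, K, N, n) {
  marked <- seq_len(K)
  subs <- utils::combn(N, n)
  mean(apply(subs, 2, function(s) sum(s %in% marked) >= k))
}

# Per-residue boolean-mask coverage oracle.
brute_coverage <- function(peptides, sequence) {
  mask <- rep(FALSE, nchar(sequence))
  for (p in peptides) {
    m <- gregexpr(p, sequence, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (s in as.integer(m)) mask[s:(s + nchar(p) - 1L)] <- TRUE
  }
  sum(mask)
}

# Shared moderate synthetic dataset, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_genes = 120L, seed = 42L)
    truth <- generate_ground_truth(cfg)
    evidence <- generate_evidence_table(truth)
    rna <- generate_rna_table(truth)
    sequences <- setNames(truth$isoforms$sequence, truth$isoforms$isoform_id)
    .fixture_env$sim <- list(cfg = cfg, truth = truth, evidence = evidence,
                             rna = rna, sequences = sequences)
  }
  .fixture_env$sim
}
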