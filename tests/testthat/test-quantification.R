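mk_ev <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(sequence = r$pep, isoform_ids = r$iso,
                           sample = r$sample %||% "F1",
                           intensity = r$int %||% 1,
                           modifications = r$mod %||% "Unmodified",
                           is_phospho = isTRUE(r$phos),
                           is_contaminant = FALSE, is_decoy = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("protein grouping merges, subsumes and separates correctly", {
  # A,B detected only via shared peptides -> one group
  ev <- mk_ev(list(pep = "PEPA", iso = "G1-1;G1-2"),
              list(pep = "PEPB", iso = "G1-1;G1-2"),
              list(pep = "PEPC", iso = "G1-1;G1-2"))
  g <- group_proteins(ev)
  expect_identical(nrow(g), 1L)
  expect_identical(g$members, "G1-1;G1-2")

  # A {p1,p2} subset of B {p1,p2,p3} -> A subsumed (exhaustive comparison)
  ev <- mk_ev(list(pep = "P1", iso = "G2-1;G2-2"),
              list(pep = "P2", iso = "G2-1;G2-2"),
              list(pep = "P3", iso = "G2-2"))
  g <- group_proteins(ev)
  expect_identical(nrow(g), 1L)
  expect_identical(g$members, "G2-1;G2-2")
  expect_identical(g$peptide_count, 3L)

  # unique peptides on both sides -> two groups
  ev <- mk_ev(list(pep = "P1", iso = "G3-1;G3-2"),
              list(pep = "P4", iso = "G3-1"),
              list(pep = "P5", iso = "G3-2"))
  g <- group_proteins(ev)
  expect_identical(nrow(g), 2L)
})

test_that("aggregation sums peptides and razor-assigns shared ones once", {
  ev <- mk_ev(list(pep = "P1", iso = "G1-1", int = 2),
              list(pep = "P2", iso = "G1-1", int = 3))
  g <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, g)
  expect_equal(unname(q$raw[1, "F1"]), 5)

  # shared peptide counted in exactly one (larger) group
  ev <- mk_ev(list(pep = "P1", iso = "GA-1", int = 1),
              list(pep = "P2", iso = "GA-1", int = 1),
              list(pep = "P3", iso = "GA-1;GB-1", int = 10),
              list(pep = "P4", iso = "GB-1", int = 1))
  g <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, g)
  expect_equal(sum(q$raw[, "F1"]), 13)  # conservation, nothing double-counted
  big <- g$group_id[g$gene_id == "GA"]
  expect_equal(unname(q$raw[big, "F1"]), 12)  # razor to the larger group
})

test_that("modified and phospho peptides are excluded except benign mods", {
  ev <- mk_ev(list(pep = "P1", iso = "G1-1", int = 5),
              list(pep = "P2", iso = "G1-1", int = 7,
                   mod = "Deamidation (NQ)"),
              list(pep = "P3", iso = "G1-1", int = 11,
                   mod = "Oxidation (M)"),
              list(pep = "P4", iso = "G1-1", int = 13, phos = TRUE))
  g <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, g)
  expect_equal(unname(q$raw[1, "F1"]), 12)  # 5 + 7; oxidation and phospho out
})

test_that("median-ratio normalization removes global scale, idempotently", {
  set.seed(21)
  ev <- data.table::rbindlist(lapply(1:12, function(i) {
    int <- rlnorm(1, 10, 1)
    data.table::data.table(
      sequence = paste0("PEP", i), isoform_ids = paste0("G", i, "-1"),
      sample = c("F1", "F2"), intensity = c(int, 2 * int),
      modifications = "Unmodified", is_phospho = FALSE,
      is_contaminant = FALSE, is_decoy = FALSE)
  }))
  g <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, g)
  expect_equal(unname(q$normalized[, "F1"]), unname(q$normalized[, "F2"]),
               tolerance = 1e-12)
  # idempotence: normalizing already-normalized values changes nothing
  lr <- log(q$normalized)
  sf <- apply(lr - rowMeans(lr), 2, median)
  expect_equal(unname(sf), rep(0, 2), tolerance = 1e-12)
})

test_that("iBAQ definition, linearity, and ground-truth rank agreement", {
  seqs <- c(`GX-1` = paste0(paste(rep("AGTLIEK", 10), collapse = ""), "R"))
  g <- data.table::data.table(group_id = "PG1", gene_id = "GX",
                              members = "GX-1", peptide_count = 2L,
                              peptides = "AGTLIEK;X",
                              is_contaminant = FALSE, is_decoy = FALSE)
  intensity <- matrix(1000, 1, 1, dimnames = list("PG1", "ASYNC"))
  ib <- compute_ibaq(intensity, g, seqs)
  expect_equal(unname(ib$theoretical_peptides["PG1"]), 10L)
  expect_equal(unname(ib$ibaq["PG1", "ASYNC"]), 100)
  ib2 <- compute_ibaq(intensity * 2, g, seqs)
  expect_equal(unname(ib2$ibaq[1, 1]), 200)

  # noiseless synthetic data: iBAQ ranks track true copy number
  cfg <- sim_config(n_genes = 60, seed = 13, noise_cv = 0,
                    detect_mid = -Inf, response_sdlog = 0,
                    phospho_rate = 0, contaminant_n = 0L, decoy_n = 0L,
                    isoform_rate = c(1, 0, 0, 0, 0))
  tr <- generate_ground_truth(cfg)
  ev <- generate_evidence_table(tr)
  grp <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, grp)
  seqs2 <- setNames(tr$isoforms$sequence, tr$isoforms$isoform_id)
  ib3 <- compute_ibaq(q$raw, grp, seqs2)
  truth_copy <- tr$genes$copy_number[match(grp$gene_id, tr$genes$gene_id)]
  rho <- cor(ib3$ibaq[, "ASYNC"], truth_copy, method = "spearman")
  expect_gte(rho, 0.99)
})

test_that("cumulative abundance accounting", {
  cs <- cumulative_abundance(c(50, 30, 10, 5, 5))
  expect_equal(unname(cs$k), c(1L, 3L))
  # uniform abundances: k(50%) = ceiling(n/2); k monotone in q
  for (n in c(7, 10, 13)) {
    cu <- cumulative_abundance(rep(2, n), quantiles = c(0.25, 0.5, 0.9))
    expect_equal(unname(cu$k[2]), ceiling(n / 2))
    expect_true(all(diff(cu$k) >= 0))
  }
  expect_error(cumulative_abundance(c(0, 0)), "zero")
})
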