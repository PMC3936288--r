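FR <- elutriomics:::FRACTIONS
meta <- fraction_meta_default()

mk_records <- function(n, seed = 1) {
  set.seed(seed)
  prot <- 10^rnorm(n, 5, 1)
  rna <- 10^(0.6 * (log10(prot) - 5) + rnorm(n, 1, 0.4))
  rec <- data.table::data.table(gene_id = sprintf("G%03d", 1:n))
  for (s in elutriomics:::SAMPLES) rec[[paste0("protein_", s)]] <- prot
  for (s in c("G1", "S", "G2M", "ASYNC")) rec[[paste0("fpkm_", s)]] <- rna
  rec$complete <- TRUE
  rec
}

test_that("gene-level merge sums isoforms and drops histones", {
  ib <- matrix(c(10, 5, 7), 3, 1,
               dimnames = list(c("PG1", "PG2", "PG3"), "ASYNC"))
  groups <- data.table::data.table(group_id = c("PG1", "PG2", "PG3"),
                                   gene_id = c("GA", "GA", "GH"))
  fpkm <- data.table::data.table(
    gene_id = rep(c("GA", "GH", "GM"), each = 4),
    sample = rep(c("G1", "S", "G2M", "ASYNC"), 3),
    bio_rep = 1L, tech_rep = 1L,
    fpkm = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 0, 12))
  out <- merge_gene_level(ib, groups, fpkm, histone_genes = "GH")
  expect_identical(out$gene_id, "GA")          # histone dropped, GM no protein
  expect_equal(out$protein_ASYNC, 15)          # 10 + 5 summed
  expect_identical(attr(out, "n_histone_removed"), 1L)

  # gene with zero FPKM in a phase is not complete
  ib2 <- matrix(c(10), 1, 1, dimnames = list("PG4", "ASYNC"))
  groups2 <- data.table::data.table(group_id = "PG4", gene_id = "GM")
  out2 <- merge_gene_level(ib2, groups2, fpkm)
  expect_true(is.na(out2$fpkm_G2M) || out2$fpkm_G2M <= 0 ||
                out2$complete == FALSE)
})

test_that("Spearman correlation: perfect concordance, reversal, invariance", {
  rec <- mk_records(60)
  rec$fpkm_ASYNC <- rec$protein_ASYNC          # rank-concordant
  expect_equal(correlate_abundances(rec, "async")$rho, 1)
  rec$fpkm_ASYNC <- 1 / rec$protein_ASYNC      # rank-reversed
  expect_equal(correlate_abundances(rec, "async")$rho, -1)
  # monotone transform invariance
  rec2 <- mk_records(60, seed = 2)
  r1 <- correlate_abundances(rec2, "async")$rho
  rec2$fpkm_ASYNC <- rec2$fpkm_ASYNC^3
  expect_equal(correlate_abundances(rec2, "async")$rho, r1)
  expect_error(correlate_abundances(rec2[1:5, ], "async"), "fewer than")
})

test_that("synthetic copula rho is recovered through the merge machinery", {
  tr <- generate_ground_truth(sim_config(n_genes = 3000, seed = 44),
                              sequences = FALSE)
  rec <- data.table::data.table(
    gene_id = tr$genes$gene_id,
    protein_ASYNC = tr$genes$copy_number,
    fpkm_ASYNC = tr$genes$fpkm_async, complete = TRUE)
  got <- correlate_abundances(rec, "async")
  expect_lt(abs(got$rho - 0.63), 0.05)
})

test_that("profile concordance classification with inclusive boundary", {
  rec <- mk_records(3)
  # per-cell flat protein, varying RNA shapes
  for (i in seq_along(FR)) {
    rec[[paste0("protein_", FR[i])]] <-
      meta$cell_count[match(FR[i], meta$sample)] * c(1, 1, 1)
  }
  rec$fpkm_G1 <- c(1, 2, 1); rec$fpkm_S <- c(1, 2, 1); rec$fpkm_G2M <- c(1, 2, 1)
  cls <- classify_profile_correlation(rec, meta)
  expect_identical(unique(cls$status), "undefined")  # flat protein profile

  # identical shapes -> r = 1 concordant; Cdt1-like anti-phase -> discordant
  shape <- c(2, 1, 3)
  rec2 <- mk_records(2)
  pool_w <- list(c("F1", "F2"), c("F3", "F4"), c("F5", "F6"))
  for (ph in 1:3) for (f in pool_w[[ph]]) {
    rec2[[paste0("protein_", f)]] <-
      meta$cell_count[match(f, meta$sample)] * shape[ph]
  }
  rec2$fpkm_G1 <- c(shape[1], 1); rec2$fpkm_S <- c(shape[2], 3)
  rec2$fpkm_G2M <- c(shape[3], 1)
  cls2 <- classify_profile_correlation(rec2, meta)
  expect_identical(cls2$status[1], "concordant")
  expect_equal(cls2$r[1], 1)
  expect_identical(cls2$status[2], "discordant")  # protein min where RNA max
  expect_lt(cls2$r[2], 0)
})

test_that("coordinated subset applies both cutoffs", {
  rec <- mk_records(4)
  rec$fpkm_G1 <- c(1.0, 1.0, 1.0, 1.0)
  rec$fpkm_S <- c(1.2, 1.2, 1.2, 1.2)
  rec$fpkm_G2M <- c(1.6, 1.4, 1.7, 1.2)   # folds 1.6, 1.4, 1.7, 1.2
  out <- coordinated_subset(rec$gene_id[c(1, 2, 3)], rec, meta)
  expect_setequal(out$genes, rec$gene_id[c(1, 3)])  # gene 2 below RNA cutoff,
                                                    # gene 4 not regulated
  expect_identical(out$n, 2L)
  expect_true(all(out$rna_fold > 1.5))
})

test_that("coordinated genes in the full synthetic world are recovered", {
  cfg <- sim_config(n_genes = 2500, frac_regulated = 0.08,
                    coordinated_frac = 0.3, noise_cv = 0.05, seed = 55,
                    rna_bio_sd = 0.03, rna_tech_sd = 0.02)
  tr <- generate_ground_truth(cfg, sequences = FALSE)
  rna <- generate_rna_table(tr)
  m <- simulate_protein_matrix(tr)
  groups <- data.table::data.table(group_id = tr$genes$gene_id,
                                   gene_id = tr$genes$gene_id)
  ibaq <- m  # per-gene matrix stands in for group-level iBAQ here
  rec <- merge_gene_level(ibaq, groups, rna)
  det <- detect_regulated(
    sweep(m[, FR], 2, tr$meta$cell_count[match(FR, tr$meta$sample)], `/`))
  out <- coordinated_subset(det$ids, rec, tr$meta)
  truth_coord <- tr$genes$gene_id[tr$genes$coordinated & tr$genes$regulated]
  sens <- mean(truth_coord %in% out$genes)
  expect_gte(sens, 0.9)
  # coordinated profiles move together
  expect_gt(out$profile_r, 0.8)
})
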