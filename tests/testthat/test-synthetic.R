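test_that("config validation enforces invariants", {
  expect_error(sim_config(peak_phase_mix = c(G1 = 0.5, S = 0.5, G2M = 0.2,
                                             `G2M+G1` = 0.2)), "sum to 1")
  expect_error(sim_config(fold_range = c(0.5, 8)), "lower bound")
  expect_error(generate_ground_truth(sim_config(n_genes = 5)), "at least 10")
})

test_that("async expectation equals the cell-count-weighted mixture exactly", {
  tr <- generate_ground_truth(sim_config(n_genes = 50, seed = 2),
                              sequences = FALSE)
  ncell <- tr$meta$cell_count[match(elutriomics:::FRACTIONS,
                                    tr$meta$sample)]
  w <- ncell / sum(ncell)
  pred <- as.numeric(tr$percell[, elutriomics:::FRACTIONS] %*% w)
  expect_equal(pred, unname(tr$percell[, "ASYNC"]), tolerance = 1e-12)
})

test_that("frac_regulated = 0 yields no fraction fold >= 2", {
  tr <- generate_ground_truth(sim_config(n_genes = 200, frac_regulated = 0,
                                         seed = 3), sequences = FALSE)
  expect_true(all(tr$genes$fold < 2))
})

test_that("regulated genes meet the fold floor; unregulated stay below 2", {
  tr <- generate_ground_truth(sim_config(n_genes = 400, seed = 4),
                              sequences = FALSE)
  expect_true(all(tr$genes$fold[tr$genes$regulated] >= 2))
  expect_true(all(tr$genes$fold[!tr$genes$regulated] < 2))
})

test_that("copula hits the target Spearman correlation", {
  tr <- generate_ground_truth(sim_config(n_genes = 5000, seed = 5),
                              sequences = FALSE)
  rho <- cor(log10(tr$genes$copy_number), log10(tr$genes$fpkm_async),
             method = "spearman")
  expect_lt(abs(rho - 0.63), 0.03)
})

test_that("generators are seed-deterministic (byte-identical TSVs)", {
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  cfg <- sim_config(n_genes = 30, seed = 9)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in c("evidence.tsv", "fpkm.tsv", "isoforms.fasta",
              "ground_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noiseless evidence reproduces expected profile shapes exactly", {
  cfg <- sim_config(n_genes = 15, seed = 6, noise_cv = 0,
                    detect_mid = -Inf, response_sdlog = 0,
                    phospho_rate = 0, contaminant_n = 0L, decoy_n = 0L,
                    isoform_rate = c(1, 0, 0, 0, 0))
  tr <- generate_ground_truth(cfg)
  ev <- generate_evidence_table(tr)
  g <- group_proteins(ev)
  q <- aggregate_and_normalize(ev, g)
  ncell <- tr$meta$cell_count[match(colnames(q$raw), tr$meta$sample)]
  for (i in seq_len(nrow(q$raw))) {
    gene <- g$gene_id[match(rownames(q$raw)[i], g$group_id)]
    expected <- tr$percell[gene, colnames(q$raw)] * ncell
    ratio <- q$raw[i, ] / expected
    # single-isoform, unit response, full detection: the protein profile is
    # the expected per-sample intensity times the peptide count
    expect_equal(unname(ratio / ratio[1]), rep(1, ncol(q$raw)),
                 tolerance = 1e-9)
  }
})

test_that("phospho S/T/Y proportions recover the configured mix", {
  cfg <- sim_config(n_genes = 250, seed = 8, phospho_rate = 0.25,
                    mean_seq_len = 350L)
  tr <- generate_ground_truth(cfg)
  ev <- generate_evidence_table(tr)
  ph <- unique(ev[ev$is_phospho == TRUE,
                  c("gene_id", "sequence", "phospho_residue")])
  expect_gt(nrow(ph), 500)
  emp <- table(factor(ph$phospho_residue, levels = c("S", "T", "Y")))
  emp <- as.numeric(emp) / sum(emp)
  expect_true(all(abs(emp - cfg$sty_mix) < 0.03))
})

test_that("RNA replicates correlate strongly and histones are present", {
  sim <- shared_sim()
  rna <- sim$rna
  w <- data.table::dcast(data.table::as.data.table(rna),
                         gene_id + sample ~ bio_rep + tech_rep,
                         value.var = "fpkm")
  pos <- w$`1_1` > 0 & w$`2_2` > 0
  r <- cor(log10(w$`1_1`[pos]), log10(w$`2_2`[pos]))
  expect_gt(r, 0.90)
  expect_true(any(sim$truth$genes$histone) || sim$cfg$histone_frac == 0)
  # coordinated genes cycle at the RNA level by construction
  coord <- sim$truth$genes[sim$truth$genes$coordinated == TRUE]
  if (nrow(coord)) expect_true(all(coord$rna_fold > 1.5))
})

test_that("coordinated genes carry KEN and D-box degrons", {
  sim <- shared_sim()
  coord <- sim$truth$genes$gene_id[sim$truth$genes$coordinated]
  skip_if(length(coord) == 0, "no coordinated genes at this n")
  deg <- scan_degrons(sim$sequences)
  pg <- deg$per_gene[deg$per_gene$gene_id %in% coord, ]
  expect_true(all(pg$has_KEN))
  expect_true(all(pg$has_DBOX))
})
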