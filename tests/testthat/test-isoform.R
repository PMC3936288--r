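FR <- elutriomics:::FRACTIONS

test_that("isoform profiles average unique-peptide MS/MS counts", {
  seqs <- c(`GI-1` = "AAAGTLKCCCWIDKDDDLLK",
            `GI-2` = "AAAGTLKEEEWINKDDDLLK")
  # AAAGTLK and DDDLLK shared; CCCWIDK unique to -1, EEEWINK unique to -2
  ev <- data.table::rbindlist(lapply(FR, function(s) data.table::data.table(
    sequence = c("CCCWIDK", "AAAGTLK", "EEEWINK", "DDDLLK"),
    gene_id = "GI",
    sample = s,
    msms_count = c(4L, 9L, 2L, 9L),
    intensity = 1,
    is_contaminant = FALSE, is_decoy = FALSE, is_phospho = FALSE)))
  # add a second unique peptide per isoform so both qualify
  seqs2 <- c(`GI-1` = paste0(seqs[["GI-1"]], "CCWIDKK"),
             `GI-2` = paste0(seqs[["GI-2"]], "EEWINKK"))
  ev3 <- data.table::rbindlist(lapply(FR, function(s) data.table::data.table(
    sequence = c("CCWIDKK", "EEWINKK"), gene_id = "GI", sample = s,
    msms_count = c(2L, 4L), intensity = 1,
    is_contaminant = FALSE, is_decoy = FALSE, is_phospho = FALSE)))
  evall <- rbind(ev, ev3)
  prof <- isoform_profiles(evall, seqs2)
  expect_setequal(prof$isoform_id, c("GI-1", "GI-2"))
  p1 <- prof[prof$isoform_id == "GI-1", ]
  expect_equal(unname(unlist(p1[, FR, with = FALSE])), rep(3, 6))  # mean(4,2)
  p2 <- prof[prof$isoform_id == "GI-2", ]
  expect_equal(unname(unlist(p2[, FR, with = FALSE])), rep(3, 6))  # mean(2,4)
  expect_identical(unique(prof$unique_peptides), 2L)
})

test_that("isoforms with one unique peptide are excluded", {
  seqs <- c(`GJ-1` = "CCCWIDKAAAGTLK", `GJ-2` = "EEEWINKAAAGTLK")
  ev <- data.table::rbindlist(lapply(FR, function(s) data.table::data.table(
    sequence = c("CCCWIDK", "AAAGTLK"), gene_id = "GJ", sample = s,
    msms_count = 3L, intensity = 1,
    is_contaminant = FALSE, is_decoy = FALSE, is_phospho = FALSE)))
  prof <- isoform_profiles(ev, seqs)
  expect_identical(nrow(prof), 0L)   # shared peptide counts for neither
})

test_that("concordance flags discordant pairs and skips constant ones", {
  mk_prof <- function(id, v) {
    d <- data.table::as.data.table(as.list(setNames(v, FR)))
    d[, isoform_id := id]
    d
  }
  # identical profiles -> concordant with min r = 1
  p <- rbind(mk_prof("GX-1", c(6, 5, 4, 3, 2, 1)),
             mk_prof("GX-2", c(6, 5, 4, 3, 2, 1)))
  cs <- concordance(p)
  expect_equal(cs$min_r, 1)
  expect_false(cs$discordant)

  # monotone vs flat-with-jitter (CASC4-like) -> discordant
  set.seed(3)
  p2 <- rbind(mk_prof("GY-1", c(10, 8, 6, 4, 3, 2)),
              mk_prof("GY-2", 5 + c(0.1, -0.2, 0.15, -0.05, 0.2, -0.1)))
  cs2 <- concordance(p2)
  expect_equal(cs2$min_r,
               cor(c(10, 8, 6, 4, 3, 2),
                   5 + c(0.1, -0.2, 0.15, -0.05, 0.2, -0.1)))
  expect_true(cs2$discordant)

  # three isoforms, one anti-correlated (SDCCAG8-like)
  p3 <- rbind(mk_prof("GZ-1", c(9, 7, 5, 4, 3, 2)),
              mk_prof("GZ-2", c(8, 7, 5, 4, 3, 2.5)),
              mk_prof("GZ-3", c(2, 4, 9, 8, 4, 2)))   # S-phase peak
  cs3 <- concordance(p3)
  expect_true(cs3$discordant)
  expect_lt(cs3$min_r, 0)

  # constant profile: pair skipped and flagged
  p4 <- rbind(mk_prof("GW-1", c(5, 5, 5, 5, 5, 5)),
              mk_prof("GW-2", c(1, 2, 3, 4, 5, 6)))
  cs4 <- concordance(p4)
  expect_identical(length(cs4$skipped_pairs), 1L)
  expect_false(cs4$discordant)

  # global rescaling of all profiles leaves the matrix unchanged
  p5 <- data.table::copy(p3)
  for (f in FR) p5[[f]] <- p5[[f]] * 7.3
  expect_equal(concordance(p5)$r_matrix, cs3$r_matrix, tolerance = 1e-12)
})

test_that("pooling dampens isoform folds; masking flag fires", {
  sim <- simulate_discordant_genes(n_genes = 12, seed = 19)
  ev <- generate_evidence_table(sim)
  seqs <- setNames(sim$isoforms$sequence, sim$isoforms$isoform_id)
  mask <- aggregation_masking(ev[grepl("DGENE", gene_id)], seqs,
                              meta = sim$meta)
  expect_true(all(mask$gene_fold < mask$max_isoform_fold))
  expect_gt(mean(mask$masked), 0.8)
})

test_that("single-isoform gene pools to its own fold", {
  seqs <- c(`GS-1` = "CCCWIDKAAAGTLKEEEWINK")
  ev <- data.table::rbindlist(lapply(seq_along(FR), function(i) {
    data.table::data.table(
      sequence = c("CCCWIDK", "AAAGTLK"), gene_id = "GS", sample = FR[i],
      intensity = c(10, 20) * i, msms_count = 1L,
      is_contaminant = FALSE, is_decoy = FALSE, is_phospho = FALSE)
  }))
  mask <- aggregation_masking(ev, seqs)
  expect_equal(mask$gene_fold, 6)
  expect_equal(mask$max_isoform_fold, 6)
  expect_false(mask$masked)
})
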