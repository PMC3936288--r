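test_that("digest_sequence implements the cleavage rules", {
  cases <- list(
    list(seq = "MKAEKRPK", spec = digest_spec("LysC", 0),
         expect = c("MK", "AEK", "RPK")),
    list(seq = "MKRP", spec = digest_spec("TrypsinDD", 0),
         expect = c("MK", "R", "P")),          # trypsin/P cleaves before P
    list(seq = "AKGK", spec = digest_spec("LysC", 1),
         expect = c("AK", "GK", "AKGK"))
  )
  for (cs in cases) {
    got <- digest_sequence(cs$seq, cs$spec)
    expect_setequal(got$peptide, cs$expect)
  }
  # classic trypsin does not cleave before proline
  got <- digest_sequence("MKRP", digest_spec("TrypsinDD", 0,
                                             trypsin_p = FALSE))
  expect_setequal(got$peptide, c("MK", "RP"))
})

test_that("0-missed-cleavage peptides concatenate to the input (partition)", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(elutriomics:::AA20, sample(20:120, 1), TRUE),
               collapse = "")
    for (pr in c("LysC", "TrypsinDD")) {
      d <- digest_sequence(s, digest_spec(pr, 0))
      d <- d[order(d$start), ]
      expect_identical(paste(d$peptide, collapse = ""), s)
      expect_identical(d$start[-1], d$end[-nrow(d)])
    }
  }
})

test_that("non-standard residues are rejected with a warning", {
  expect_warning(out <- digest_sequence("MKXB", digest_spec("LysC")),
                 "non-standard")
  expect_identical(nrow(out), 0L)
})

test_that("coverage matches interval union and the boolean-mask oracle", {
  # length-100 protein, peptides covering [0,50) and [25,75) -> 0.75
  s <- paste(rep("A", 100), collapse = "")
  s <- paste0(substr(s, 1, 24), "K", substr(s, 26, 100))  # anchor unique peps
  seqs <- c(`P1-1` = s)
  p1 <- substr(s, 1, 50)
  p2 <- substr(s, 26, 75)
  cov <- compute_coverage(c(p1, p2), seqs)
  expect_equal(cov$per_isoform$coverage, 0.75)

  # randomized instances vs the per-residue mask oracle
  set.seed(7)
  for (i in 1:15) {
    sq <- paste(sample(elutriomics:::AA20, 150, TRUE), collapse = "")
    d <- digest_sequence(sq, digest_spec("TrypsinDD", 1, 5, 25))
    peps <- sample(d$peptide, min(6, nrow(d)))
    cov <- compute_coverage(peps, c(`G-1` = sq))
    expect_identical(cov$per_isoform$covered, brute_coverage(peps, sq))
  }
})

test_that("combined coverage dominates per-protease coverage", {
  sim <- shared_sim()
  ev <- sim$evidence[sim$evidence$is_contaminant == FALSE &
                       sim$evidence$is_decoy == FALSE &
                       sim$evidence$is_phospho == FALSE, ]
  sub_iso <- sample(names(sim$sequences), 25)
  sub <- ev[ev$isoform_ids %in% sub_iso]
  cov <- compute_coverage(
    data.frame(peptide = sub$sequence, protease = sub$protease),
    sim$sequences[sub_iso])
  per <- cov$per_isoform
  expect_true(all(per$covered >= per$covered_LysC))
  expect_true(all(per$covered >= per$covered_TrypsinDD))
  expect_identical(cov$total_covered, sum(per$covered))
})

test_that("protease partition reproduces printed arithmetic", {
  # printed counts: 154,985 unique peptides, 30.8% LysC-only, 50.5%
  # TrypsinDD-only -> shared 18.7%, relative increase 44%
  total <- 154985
  counts <- list(lysc_only = round(0.308 * total),
                 trypsindd_only = round(0.505 * total))
  counts$shared <- total - counts$lysc_only - counts$trypsindd_only
  part <- partition_by_protease(counts)
  expect_equal(part$total, total)
  expect_equal(round(part$percent[["shared"]], 1), 18.7)
  expect_equal(part$relative_increase_pct, 44)

  # all shared -> zero relative increase; percentages sum to 100
  part2 <- partition_by_protease(data.frame(
    peptide = rep(c("AAK", "CCK"), 2),
    protease = c("LysC", "LysC", "TrypsinDD", "TrypsinDD")))
  expect_equal(part2$relative_increase_pct, 0)
  expect_equal(sum(part2$percent), 100)
  expect_equal(sum(part2$counts), part2$total)
})

test_that("composition bias machinery counts and correlates", {
  f <- residue_frequencies(c("AAK", "KAA"))
  expect_equal(unname(f[c("A", "K")]), c(4 / 6, 2 / 6))
  cb <- composition_bias(c("AAK", "KKA"), c("AAK", "KKA"))
  expect_equal(cb$correlation, 1)
  expect_error(composition_bias(character(), "AAK"), "non-empty")
})

test_that("unbiased synthetic detection has composition r > 0.98", {
  sim <- shared_sim()
  detected <- unique(unlist(strsplit(
    sim$evidence$isoform_ids[!sim$evidence$is_contaminant &
                               !sim$evidence$is_decoy], ";")))
  detected <- intersect(detected, names(sim$sequences))
  cb <- composition_bias(sim$sequences[detected], sim$sequences)
  expect_gt(cb$correlation, 0.98)
})
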