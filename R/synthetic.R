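#' Synthetic elutriation-experiment generator
#'
#' Generates a ground-truth "world" of genes, isoforms, peptides, elutriated
#' fractions, RNA and annotations with the statistical structure the
#' downstream analysis assumes: log-normal protein abundance spanning many
#' orders of magnitude, a small cell-cycle-regulated subset with a stated
#' peak-phase mix, asynchronous samples that are exact cell-count-weighted
#' mixtures of the six fractions, multi-isoform genes with occasional
#' discordant regulation, phosphopeptides with realistic S/T/Y proportions,
#' and mRNA coupled to protein abundance through a Gaussian copula at a
#' target rank correlation.
#'
#' @name synthetic_data
NULL

#' Default per-fraction metadata
#'
#' Cell counts decrease from F1 to F6 (8e7 to 2e6 cells) and the G1/S/G2M
#' phase compositions move from G1-enriched (F1/F2) through S-enriched
#' (F3/F4) to G2&M-enriched (F5/F6). The asynchronous sample's composition is
#' the cell-count-weighted mean of the fractions.
#'
#' @param async_cells cell count attributed to the asynchronous sample.
#' @return `data.frame` with columns `sample`, `cell_count`, `pi_G1`,
#'   `pi_S`, `pi_G2M`.
#' @export
fraction_meta_default <- function(async_cells = 1e8) {
  comp <- rbind(
    F1 = c(0.90, 0.08, 0.02),
    F2 = c(0.80, 0.17, 0.03),
    F3 = c(0.35, 0.55, 0.10),
    F4 = c(0.20, 0.60, 0.20),
    F5 = c(0.10, 0.30, 0.60),
    F6 = c(0.05, 0.15, 0.80)
  )
  counts <- c(8e7, 5e7, 3e7, 1.5e7, 6e6, 2e6)
  phi <- colSums(comp * counts) / sum(counts)
  data.frame(
    sample = SAMPLES,
    cell_count = c(counts, async_cells),
    pi_G1 = c(comp[, 1], phi[1]),
    pi_S = c(comp[, 2], phi[2]),
    pi_G2M = c(comp[, 3], phi[3]),
    row.names = NULL
  )
}

meta_matrix <- function(meta) {
  m <- as.matrix(meta[match(FRACTIONS, meta$sample),
                      c("pi_G1", "pi_S", "pi_G2M")])
  rownames(m) <- FRACTIONS
  colnames(m) <- PHASES
  m
}

#' Simulation configuration
#'
#' Defaults encode the experimental world being emulated: ~5.5% of genes
#' cell-cycle regulated, a peak-phase mix of 17/27/49/7% (G1/S/G2M/G2M+G1),
#' twofold to eightfold protein variation across fractions, protein-mRNA
#' rank correlation 0.63, phosphosites predominantly on serine, and a small
#' coordinated subset whose mRNA varies by more than 1.5-fold and whose
#' sequences carry KEN and RxxL (D-box) degrons.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_regulated proportion of genes with cell-cycle-regulated
#'   protein abundance (default 0.055).
#' @param peak_phase_mix proportions over peak classes G1/S/G2M/G2M+G1
#'   (must sum to 1).
#' @param fold_range linear-scale interval for the fraction-level fold
#'   change of regulated genes; folds are drawn log-uniformly and the lower
#'   bound must be >= 1. Classes whose composition mixing cannot reach the
#'   drawn fold are capped at 95% of their attainable maximum.
#' @param rna_protein_rho target Spearman correlation between log protein
#'   and log mRNA abundance (Gaussian copula).
#' @param rna_regulated_fold minimum (exclusive) phase-level mRNA fold for
#'   the coordinated subset.
#' @param coordinated_frac proportion of regulated genes in the coordinated
#'   (protein + mRNA) subset; default 31/358 as observed in elutriated
#'   myeloid cells.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise on protein intensities.
#' @param rna_bio_sd,rna_tech_sd log10-scale standard deviations of the
#'   biological and technical mRNA replicate noise.
#' @param bio_cv per-phase biological variability (log scale) of
#'   unregulated genes; clamped so unregulated fraction folds stay below 2.
#' @param isoform_rate probabilities of a gene having 1..5 isoforms.
#' @param discordant_iso_rate probability that a regulated multi-isoform
#'   gene carries one flat (non-regulated) isoform.
#' @param phospho_rate proportion of peptides carrying a phosphosite.
#' @param phospho_reg_rate proportion of phosphopeptides whose site
#'   stoichiometry is cell-cycle regulated.
#' @param multi_site_rate proportion of phosphopeptides with two sites.
#' @param sty_mix proportions of S/T/Y phospho-residues (must sum to 1; the
#'   default renormalises the observed 64/17/16% split).
#' @param copy_log_mean,copy_log_sd parameters of the log10 protein
#'   copy-number distribution.
#' @param response_sdlog log10-scale spread of fixed per-peptide response
#'   factors (0 makes peptide intensities exact multiples of protein
#'   abundance).
#' @param detect_mid,detect_slope logistic detection model on log10
#'   pre-noise intensity; `detect_mid = -Inf` detects everything.
#' @param msms_base,msms_gamma,msms_cap Poisson MS/MS-count rate
#'   `min(msms_cap, msms_base * (percell_intensity / 1e3)^msms_gamma)`: a
#'   saturating power law, increasing in log intensity, reflecting spectral
#'   sampling that is sublinear in abundance and limited by instrument duty
#'   cycle.
#' @param evidence_missed missed cleavages used for the detectable peptide
#'   universe.
#' @param peptide_min,peptide_max detectable peptide length bounds.
#' @param contaminant_n,decoy_n numbers of contaminant and reverse-decoy
#'   entries injected into the evidence table.
#' @param histone_frac proportion of genes flagged as histones.
#' @param mean_seq_len mean simulated protein length (residues).
#' @param async_cells cell count of the asynchronous sample.
#' @param seed integer RNG seed; fixed seed implies bit-identical outputs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       frac_regulated = 0.055,
                       peak_phase_mix = c(G1 = 0.17, S = 0.27,
                                          G2M = 0.49, `G2M+G1` = 0.07),
                       fold_range = c(2, 8),
                       rna_protein_rho = 0.63,
                       rna_regulated_fold = 1.5,
                       coordinated_frac = 31 / 358,
                       noise_cv = 0.05,
                       rna_bio_sd = 0.10,
                       rna_tech_sd = 0.05,
                       bio_cv = 0.08,
                       isoform_rate = c(0.50, 0.25, 0.12, 0.08, 0.05),
                       discordant_iso_rate = 0.05,
                       phospho_rate = 0.02,
                       phospho_reg_rate = 0.032,
                       multi_site_rate = 0.28,
                       sty_mix = c(S = 0.64, T = 0.17, Y = 0.16) / 0.97,
                       copy_log_mean = 4.5,
                       copy_log_sd = 1.3,
                       response_sdlog = 1.0,
                       detect_mid = 7.5,
                       detect_slope = 0.3,
                       msms_base = 3,
                       msms_gamma = 0.5,
                       msms_cap = 30,
                       evidence_missed = 0L,
                       peptide_min = 7L,
                       peptide_max = 35L,
                       contaminant_n = 5L,
                       decoy_n = 5L,
                       histone_frac = 0.02,
                       mean_seq_len = 300L,
                       async_cells = 1e8,
                       seed = 1L) {
  check_proportions(peak_phase_mix, "peak_phase_mix")
  check_proportions(sty_mix, "sty_mix")
  check_proportions(isoform_rate, "isoform_rate")
  if (length(fold_range) != 2L || fold_range[1] < 1 ||
      fold_range[2] < fold_range[1]) {
    stop("fold_range must be an interval with lower bound >= 1")
  }
  stopifnot(frac_regulated >= 0, frac_regulated <= 1,
            rna_protein_rho > -1, rna_protein_rho < 1,
            noise_cv >= 0, seed == as.integer(seed))
  cfg <- as.list(environment())
  cfg$n_genes <- as.integer(n_genes)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Phase-level expression shape (G1, S, G2M) for a peak class with contrast c.
# The G2M+G1 class depresses S-phase expression relative to both flanks.
class_shape <- function(class, c) {
  switch(class,
    G1 = c(c, sqrt(c), 1),
    S = c(1, c, c^0.3),
    G2M = c(1, sqrt(c), c),
    `G2M+G1` = c(c, 1, 0.95 * c),
    stop("unknown peak class: ", class)
  )
}

# Solve the phase contrast c such that the fraction-level profile
# Pi %*% shape(c) has max/min equal to `fold`. Composition mixing attenuates
# phase contrast, so c >= fold; classes that cannot attain `fold` are capped
# at 95% of their asymptotic maximum.
solve_contrast <- function(class, fold, Pi) {
  ffold <- function(c) {
    I <- as.numeric(Pi %*% class_shape(class, c))
    max(I) / min(I)
  }
  gmax <- ffold(1e6)
  target <- min(fold, 1 + 0.95 * (gmax - 1))
  if (target <= 1 + 1e-12) return(1)
  uniroot(function(u) ffold(exp(u)) - target,
          interval = c(1e-9, log(1e6)), tol = 1e-10)$root |> exp()
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE, prob = AA_FREQ_HUMAN),
        collapse = "")
}

inject_motif <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  if (n < w + 20L) return(seq)
  pos <- sample(10:(n - w - 10L), 1L)
  paste0(substr(seq, 1L, pos - 1L), motif, substr(seq, pos + w, n))
}

#' Generate the ground truth of a synthetic elutriation experiment
#'
#' Draws per-gene protein copy numbers, regulated/peak-class assignments,
#' per-isoform phase-level expression, mRNA abundances coupled by a Gaussian
#' copula, isoform sequences (with KEN and RxxL degrons injected into every
#' coordinated-subset gene), and annotation terms. Expected per-cell
#' intensities obey, exactly and by construction, the mixture identity
#' `async = sum_f n_f I_f / sum_f n_f`.
#'
#' @param config a [sim_config()].
#' @param sequences logical; generate isoform amino-acid sequences (needed
#'   for evidence generation and motif scanning, skippable for speed).
#' @return A list of class `sim_truth` with elements `config`, `meta`
#'   (fraction metadata), `genes`, `isoforms`, `percell` (gene x sample
#'   expected per-cell intensity), `percell_isoform`, and `annotations`.
#' @export
generate_ground_truth <- function(config = sim_config(), sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 10L) stop("n_genes must be at least 10")
  set.seed(config$seed)
  n <- config$n_genes
  meta <- fraction_meta_default(config$async_cells)
  Pi <- meta_matrix(meta)
  ncells <- meta$cell_count[match(FRACTIONS, meta$sample)]
  phi <- colSums(Pi * ncells) / sum(ncells)    # async phase composition

  gene_id <- sprintf("GENE%05d", seq_len(n))
  copy <- 10^rnorm(n, config$copy_log_mean, config$copy_log_sd)
  histone <- rbinom(n, 1, config$histone_frac) == 1

  n_reg <- round(config$frac_regulated * n)
  reg_idx <- sort(sample.int(n, n_reg))
  is_designed_reg <- seq_len(n) %in% reg_idx
  peak_class <- rep(NA_character_, n)
  peak_class[reg_idx] <- sample(names(config$peak_phase_mix), n_reg,
                                replace = TRUE,
                                prob = config$peak_phase_mix)
  lfr <- log(config$fold_range)
  fold_target <- rep(NA_real_, n)
  fold_target[reg_idx] <- exp(runif(n_reg, lfr[1], lfr[2]))

  # coordinated subset: regulated genes whose mRNA also cycles (> 1.5-fold)
  coordinated <- rep(FALSE, n)
  n_coord <- round(config$coordinated_frac * n_reg)
  if (n_coord > 0) coordinated[sample(reg_idx, n_coord)] <- TRUE

  niso <- sample.int(length(config$isoform_rate), n, replace = TRUE,
                     prob = config$isoform_rate)

  # phase-level expression per gene and isoform ----------------------------
  clamp <- function(z, b) pmin(pmax(z, -b), b)
  x_gene <- matrix(0, n, 3, dimnames = list(gene_id, PHASES))
  iso_rows <- vector("list", n)
  masked <- rep(FALSE, n)
  for (g in seq_len(n)) {
    if (is_designed_reg[g]) {
      cc <- solve_contrast(peak_class[g], fold_target[g], Pi)
      shape <- class_shape(peak_class[g], cc)
    } else {
      shape <- exp(clamp(rnorm(3, 0, config$bio_cv), 0.30))
    }
    x <- copy[g] * shape / sum(phi * shape)    # per-cell async == copy number
    k <- niso[g]
    share <- sort(rgamma(k, 2), decreasing = TRUE)
    share <- share / sum(share)
    flat <- rep(FALSE, k)
    if (is_designed_reg[g] && k >= 2L &&
        runif(1) < config$discordant_iso_rate) {
      flat[2L] <- TRUE                        # second-largest isoform flat
    }
    xi <- matrix(rep(x, each = k), k, 3) * share
    if (any(flat)) {
      xi[flat, ] <- share[flat] * copy[g]     # constant across phases
      x <- colSums(xi)
    }
    x_gene[g, ] <- x
    iso_rows[[g]] <- data.table::data.table(
      gene_id = gene_id[g],
      isoform_id = sprintf("%s-%d", gene_id[g], seq_len(k)),
      iso_index = seq_len(k), share = share, flat = flat
    )
  }
  isoforms <- data.table::rbindlist(iso_rows)

  # expected per-cell intensities ------------------------------------------
  I_frac <- x_gene %*% t(Pi)                   # genes x 6
  I_async <- as.numeric(x_gene %*% phi)
  percell <- cbind(I_frac, ASYNC = I_async)
  colnames(percell) <- SAMPLES

  # isoform phase matrix, reconstructed exactly as constructed above
  xi_all <- matrix(0, nrow(isoforms), 3)
  pos <- 1L
  for (g in seq_len(n)) {
    k <- niso[g]
    rows <- pos:(pos + k - 1L)
    share <- isoforms$share[rows]
    flat <- isoforms$flat[rows]
    base <- x_gene[g, ]
    if (any(flat)) {
      # reconstruct: flat isoforms are share * copy; the rest share the
      # gene residual profile proportionally
      resid <- base - colSums(matrix(share[flat] * copy[g], sum(flat), 3))
      w <- share[!flat] / sum(share[!flat])
      xm <- matrix(0, k, 3)
      xm[!flat, ] <- outer(w, resid)
      xm[flat, ] <- share[flat] * copy[g]
    } else {
      xm <- matrix(rep(base, each = k), k, 3) * share
    }
    xi_all[rows, ] <- xm
    pos <- pos + k
  }
  percell_iso <- cbind(xi_all %*% t(Pi), as.numeric(xi_all %*% phi))
  colnames(percell_iso) <- SAMPLES
  rownames(percell_iso) <- isoforms$isoform_id

  iso_fold <- apply(percell_iso[, FRACTIONS, drop = FALSE], 1, profile_fold)
  gene_fold <- apply(percell[, FRACTIONS, drop = FALSE], 1, profile_fold)
  regulated <- gene_fold >= config$fold_range[1]
  max_iso_fold <- as.numeric(tapply(iso_fold, isoforms$gene_id, max)[gene_id])
  masked <- !regulated & max_iso_fold >= config$fold_range[1]

  # mRNA via Gaussian copula against log protein abundance -----------------
  rho_p <- 2 * sin(pi * config$rna_protein_rho / 6)  # Spearman -> Pearson
  zp <- (log10(copy) - config$copy_log_mean) / config$copy_log_sd
  zr <- rho_p * zp + sqrt(1 - rho_p^2) * rnorm(n)
  fpkm_base <- 10^(1.0 + 0.8 * zr)
  rna_shape <- matrix(1, n, 3, dimnames = list(gene_id, PHASES))
  rna_fold <- rep(NA_real_, n)
  for (g in which(is_designed_reg)) {
    if (coordinated[g]) {
      f <- exp(runif(1, log(config$rna_regulated_fold * 1.05),
                     log(4)))
      rna_shape[g, ] <- class_shape(peak_class[g], f)
    } else {
      rna_shape[g, ] <- exp(clamp(rnorm(3, 0, 0.05), 0.18))
    }
  }
  for (g in which(!is_designed_reg)) {
    rna_shape[g, ] <- exp(clamp(rnorm(3, 0, 0.05), 0.18))
  }
  rna_phase <- fpkm_base * rna_shape / as.numeric(rna_shape %*% phi)
  colnames(rna_phase) <- PHASES
  rna_fold <- apply(rna_phase, 1, profile_fold)

  # sequences ---------------------------------------------------------------
  if (sequences) {
    base_len <- pmax(120L, round(rlnorm(n, log(config$mean_seq_len), 0.25)))
    seqs <- character(nrow(isoforms))
    pos <- 1L
    for (g in seq_len(n)) {
      base <- random_sequence(base_len[g])
      k <- niso[g]
      for (j in seq_len(k)) {
        s <- if (j == 1L) base else {
          w <- sample(30:(max(31L, base_len[g] - 90L)), 1L)
          ins <- random_sequence(60L)
          paste0(substr(base, 1L, w - 1L), ins,
                 substr(base, w + 60L, base_len[g]))
        }
        if (coordinated[g]) {
          s <- inject_motif(s, "KEN")
          s <- inject_motif(s, paste0("R", random_sequence(2L), "L"))
        }
        seqs[pos] <- s
        pos <- pos + 1L
      }
    }
    isoforms$sequence <- seqs
    isoforms$length <- nchar(seqs)
  }

  # annotations -------------------------------------------------------------
  ann <- local({
    draw <- function(p) runif(n) < p
    bc <- ifelse(is.na(peak_class), "", peak_class)
    mk <- function(g, type, id) {
      data.frame(gene_id = g, term_type = rep(type, length(g)),
                 term_id = rep(id, length(g)))
    }
    rows <- list(
      mk(gene_id[draw(ifelse(coordinated, 0.90,
           ifelse(regulated, 0.35, 0.08)))], "GO", "GO:CELL_CYCLE"),
      mk(gene_id[draw(ifelse(bc == "G2M", 0.15, 0.02))], "GO", "GO:M_PHASE"),
      mk(gene_id[draw(ifelse(bc == "S", 0.12, 0.02))], "GO",
         "GO:DNA_REPLICATION"),
      mk(gene_id[draw(0.10)], "GO", "GO:TRANSCRIPTION"),
      mk(gene_id[draw(ifelse(coordinated, 0.84,
           ifelse(bc == "G2M", 0.50, 0.20)))], "TFBS", "NFY"),
      mk(gene_id[draw(ifelse(bc == "S", 0.75, 0.20))], "TFBS", "E2F"),
      mk(gene_id[draw(ifelse(bc == "G2M+G1", 0.77, 0.25))], "TFBS", "STAT3"),
      mk(gene_id[histone], "FAMILY", "HISTONE")
    )
    data.table::rbindlist(rows)
  })

  genes <- data.table::data.table(
    gene_id = gene_id,
    copy_number = copy,
    regulated = regulated,
    designed_regulated = is_designed_reg,
    peak_class = peak_class,
    fold = gene_fold,
    fold_target = fold_target,
    coordinated = coordinated,
    masked = masked,
    histone = histone,
    n_isoforms = niso,
    x_G1 = x_gene[, 1], x_S = x_gene[, 2], x_G2M = x_gene[, 3],
    fpkm_async = fpkm_base,
    fpkm_G1 = rna_phase[, 1], fpkm_S = rna_phase[, 2],
    fpkm_G2M = rna_phase[, 3],
    rna_fold = rna_fold
  )
  isoforms$fold <- iso_fold

  structure(list(config = config, meta = meta, genes = genes,
                 isoforms = isoforms, percell = percell,
                 percell_isoform = percell_iso, annotations = ann),
            class = "sim_truth")
}

#' Simulate genes with one regulated and one flat isoform
#'
#' A focused scenario generator for isoform-masking analysis: every gene has
#' two isoforms with fully distinct sequences (so every peptide is
#' isoform-unique), one cell-cycle regulated with a fraction-level fold of
#' at least `iso_fold` (G1-peaking, decreasing towards G2&M), and one flat
#' isoform at `flat_ratio` times the regulated isoform's trough abundance.
#' With the default ratio the pooled gene-level fold stays below 2 while the
#' regulated isoform's fold is >= 4 -- the aggregation-masking situation.
#'
#' @param n_genes number of genes.
#' @param iso_fold minimum fraction-level fold of the regulated isoform
#'   (drawn log-uniformly in `[iso_fold, 1.2 * iso_fold]`).
#' @param flat_ratio abundance of the flat isoform relative to the regulated
#'   isoform's minimum (default 5, which keeps the pooled gene-level fold
#'   near `(flat_ratio + iso_fold) / (flat_ratio + 1)`, i.e. below 2, so the
#'   gene is masked by construction).
#' @param copy per-cell copy number scale of the regulated isoform trough.
#' @param response_sdlog per-peptide response spread; tighter than the
#'   global default so that summed peptide intensities track isoform
#'   abundance shares and the constructed masking is preserved.
#' @param seed RNG seed.
#' @param ... further arguments passed to [sim_config()] (e.g. `noise_cv`).
#' @return a `sim_truth` usable with [generate_evidence_table()].
#' @export
simulate_discordant_genes <- function(n_genes = 200L, iso_fold = 4,
                                      flat_ratio = 5, copy = 1e4,
                                      response_sdlog = 0.3,
                                      seed = 1L, ...) {
  config <- sim_config(n_genes = max(10L, n_genes), seed = seed,
                       response_sdlog = response_sdlog, ...)
  set.seed(seed)
  meta <- fraction_meta_default(config$async_cells)
  Pi <- meta_matrix(meta)
  ncells <- meta$cell_count[match(FRACTIONS, meta$sample)]
  phi <- colSums(Pi * ncells) / sum(ncells)
  gene_id <- sprintf("DGENE%04d", seq_len(n_genes))
  iso_rows <- vector("list", n_genes)
  xi <- matrix(0, 2L * n_genes, 3L)
  for (g in seq_len(n_genes)) {
    f <- exp(runif(1, log(iso_fold), log(1.2 * iso_fold)))
    cc <- solve_contrast("G1", f, Pi)
    x_reg <- copy * class_shape("G1", cc)
    # flat isoform sits at flat_ratio times the regulated isoform's
    # fraction-level trough, so the pooled pre-noise fold is
    # (f + flat_ratio) / (1 + flat_ratio) < 2
    x_flat <- rep(flat_ratio * min(Pi %*% x_reg), 3L)
    xi[2L * g - 1L, ] <- x_reg
    xi[2L * g, ] <- x_flat
    iso_rows[[g]] <- data.table::data.table(
      gene_id = gene_id[g],
      isoform_id = sprintf("%s-%d", gene_id[g], 1:2),
      iso_index = 1:2,
      share = c(sum(phi * x_reg), sum(phi * x_flat)) /
        sum(phi * (x_reg + x_flat)),
      flat = c(FALSE, TRUE),
      sequence = c(random_sequence(320L), random_sequence(320L)))
  }
  isoforms <- data.table::rbindlist(iso_rows)
  isoforms$length <- nchar(isoforms$sequence)
  percell_iso <- cbind(xi %*% t(Pi), as.numeric(xi %*% phi))
  colnames(percell_iso) <- SAMPLES
  rownames(percell_iso) <- isoforms$isoform_id
  isoforms$fold <- apply(percell_iso[, FRACTIONS, drop = FALSE], 1,
                         profile_fold)
  x_gene <- rowsum(xi, rep(seq_len(n_genes), each = 2L))
  percell <- cbind(x_gene %*% t(Pi), as.numeric(x_gene %*% phi))
  colnames(percell) <- SAMPLES
  rownames(percell) <- gene_id
  genes <- data.table::data.table(
    gene_id = gene_id,
    regulated = FALSE,
    masked = TRUE,
    fold = apply(percell[, FRACTIONS, drop = FALSE], 1, profile_fold),
    n_isoforms = 2L)
  structure(list(config = config, meta = meta, genes = genes,
                 isoforms = isoforms, percell = percell,
                 percell_isoform = percell_iso,
                 annotations = data.table::data.table()),
            class = "sim_truth")
}

#' Simulate measured protein-level intensity matrix
#'
#' Multiplies expected per-cell intensities by the loaded cell count of each
#' sample and by multiplicative log-normal measurement noise. This is the
#' protein-level shortcut past peptide evidence; [generate_evidence_table()]
#' plus aggregation converges to it in the noise-free limit.
#'
#' @param truth a `sim_truth`.
#' @param noise_cv overrides `truth$config$noise_cv` when not `NULL`.
#' @param seed RNG seed (default derived from the config seed).
#' @return matrix genes x samples of measured intensities.
#' @export
simulate_protein_matrix <- function(truth, noise_cv = NULL, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cv <- noise_cv %||% truth$config$noise_cv
  set.seed(seed %||% (truth$config$seed + 3L))
  ncell <- truth$meta$cell_count[match(SAMPLES, truth$meta$sample)]
  m <- sweep(truth$percell, 2, ncell, `*`)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    m <- m * matrix(rlnorm(length(m), -sdlog^2 / 2, sdlog),
                    nrow(m), ncol(m))
  }
  m
}

#' Generate a peptide-evidence table
#'
#' In-silico digests every isoform with Lys-C and with the Lys-C/trypsin
#' double digest, keeps peptides within the configured length bounds, and
#' emits one row per detectable peptide x protease x sample with intensity
#' (expected isoform-summed intensity x fixed per-peptide response factor x
#' log-normal noise), a Poisson MS/MS count whose rate increases with log
#' intensity, logistic abundance-dependent detection, phosphopeptide rows,
#' and injected contaminant and reverse-decoy rows.
#'
#' @param truth a `sim_truth` generated with sequences.
#' @param config defaults to `truth$config`.
#' @return `data.table` with MaxQuant-evidence-like columns: `sequence`,
#'   `modifications`, `protease`, `sample`, `intensity`, `msms_count`,
#'   `gene_id`, `isoform_ids`, `is_contaminant`, `is_decoy`, `is_phospho`,
#'   `phospho_residue`, `phospho_site`, `phospho_multiplicity`.
#' @export
generate_evidence_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"),
            !is.null(truth$isoforms$sequence))
  set.seed(config$seed + 1L)
  iso <- truth$isoforms
  ncell <- truth$meta$cell_count[match(SAMPLES, truth$meta$sample)]
  perc_iso <- truth$percell_isoform

  spec_t <- digest_spec("TrypsinDD", config$evidence_missed,
                        config$peptide_min, config$peptide_max)
  spec_l <- digest_spec("LysC", config$evidence_missed,
                        config$peptide_min, config$peptide_max)

  pep_rows <- vector("list", nrow(iso) * 2L)
  ri <- 1L
  for (i in seq_len(nrow(iso))) {
    for (spec in list(spec_t, spec_l)) {
      d <- digest_sequence(iso$sequence[i], spec)
      if (nrow(d)) {
        pep_rows[[ri]] <- data.table::data.table(
          gene_id = iso$gene_id[i], isoform_id = iso$isoform_id[i],
          peptide = d$peptide, start = d$start,
          protease = spec$protease)
      }
      ri <- ri + 1L
    }
  }
  peps <- data.table::rbindlist(pep_rows)
  # one record per gene x peptide x protease; isoform multiplicity retained
  # for intensity summation and the isoform_ids column
  data.table::setkey(peps, gene_id, peptide, protease)
  base_iso <- perc_iso[peps$isoform_id, , drop = FALSE] *
    rep(ncell, each = nrow(peps))
  agg <- peps[, .(isoform_ids = paste(unique(isoform_id), collapse = ";"),
                  start = start[1L],
                  first_iso = isoform_id[1L]),
              by = .(gene_id, peptide, protease)]
  bsum <- rowsum(base_iso,
                 group = paste(peps$gene_id, peps$peptide, peps$protease,
                               sep = "\r"),
                 reorder = FALSE)
  key <- paste(agg$gene_id, agg$peptide, agg$protease, sep = "\r")
  base <- bsum[key, , drop = FALSE]

  # fixed response factor per peptide sequence
  upep <- unique(agg$peptide)
  resp <- setNames(10^rnorm(length(upep), 0, config$response_sdlog), upep)
  base <- base * resp[agg$peptide]

  n_rec <- nrow(agg)
  long <- data.table::data.table(
    sequence = rep(agg$peptide, each = 7L),
    modifications = "Unmodified",
    protease = rep(agg$protease, each = 7L),
    sample = rep(SAMPLES, n_rec),
    expected = as.numeric(t(base)),
    gene_id = rep(agg$gene_id, each = 7L),
    isoform_ids = rep(agg$isoform_ids, each = 7L)
  )
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  noise <- if (config$noise_cv > 0)
    rlnorm(nrow(long), -sdlog^2 / 2, sdlog) else 1
  long[, intensity := expected * noise]
  p_det <- if (is.infinite(config$detect_mid) && config$detect_mid < 0) 1 else
    plogis((log10(long$expected) - config$detect_mid) / config$detect_slope)
  long <- long[runif(nrow(long)) < p_det]
  # MS/MS sampling reflects sample composition (per-cell abundance), not
  # the fraction's total yield: equal peptide amounts are injected per run
  ncell_of <- setNames(ncell, SAMPLES)
  lam <- pmin(config$msms_cap,
              config$msms_base *
                (long$intensity / ncell_of[long$sample] / 1e3)^
                  config$msms_gamma)
  long[, msms_count := rpois(.N, lam)]
  long[, expected := NULL]
  long[, `:=`(is_contaminant = FALSE, is_decoy = FALSE, is_phospho = FALSE,
              phospho_residue = NA_character_, phospho_site = NA_integer_,
              phospho_multiplicity = NA_integer_)]

  # occasional benign / excluded modifications, assigned per peptide (a
  # modified peptide species is modified in every sample it appears in)
  useq <- unique(long$sequence)
  md <- runif(length(useq))
  mod_of <- ifelse(md < 0.010, "Deamidation (NQ)",
                   ifelse(md < 0.015, "Oxidation (M)", "Unmodified"))
  long[, modifications := mod_of[match(sequence, useq)]]

  # phosphopeptides ---------------------------------------------------------
  # residue-first sampling: draw the phospho-residue class from sty_mix,
  # then a tryptic peptide containing that residue, so the configured S/T/Y
  # proportions are recovered empirically regardless of residue prevalence
  tryp <- agg[protease == "TrypsinDD"]
  Pi <- meta_matrix(truth$meta)
  phi_w <- with(truth$meta[truth$meta$sample != "ASYNC", ],
                colSums(cbind(pi_G1, pi_S, pi_G2M) * cell_count) /
                  sum(cell_count))
  occ_of <- function(pep, res) {
    r <- strsplit(pep, "", fixed = TRUE)[[1]]
    which(r == res)
  }
  n_ph <- round(config$phospho_rate * nrow(tryp))
  ph_rows <- vector("list", n_ph)
  if (n_ph > 0L) {
    has_res <- lapply(c(S = "S", T = "T", Y = "Y"), function(r)
      which(grepl(r, tryp$peptide, fixed = TRUE)))
    used <- integer()
    for (i in seq_len(n_ph)) {
      res <- sample(names(config$sty_mix), 1L, prob = config$sty_mix)
      cand <- setdiff(has_res[[res]], used)
      if (!length(cand)) next
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      used <- c(used, j)
      off <- occ_of(tryp$peptide[j], res)
      off <- if (length(off) == 1L) off else sample(off, 1L)
      mult <- 1L + (runif(1) < config$multi_site_rate)
      reg <- runif(1) < config$phospho_reg_rate
      if (reg) {
        cls <- sample(c("G1", "S", "G2M", "G2M+G1"), 1L)
        f <- exp(runif(1, log(2.2), log(6)))
        v <- class_shape(cls, f)
      } else {
        v <- exp(pmin(pmax(rnorm(3, 0, 0.05), -0.15), 0.15))
      }
      stoich <- 0.15 * c(as.numeric(Pi %*% v), sum(phi_w * v)) /
        sum(phi_w * v)
      base_i <- as.numeric(base[which(key == paste(tryp$gene_id[j],
                                                   tryp$peptide[j],
                                                   "TrypsinDD",
                                                   sep = "\r")), ])
      expected_i <- base_i * stoich
      noise_i <- if (config$noise_cv > 0)
        rlnorm(7L, -sdlog^2 / 2, sdlog) else 1
      inten <- expected_i * noise_i
      pd <- if (is.infinite(config$detect_mid)) rep(1, 7L) else
        plogis((log10(expected_i) - config$detect_mid) / config$detect_slope)
      keep <- runif(7L) < pd
      if (!any(keep)) next
      lam_i <- pmin(config$msms_cap,
                    config$msms_base *
                      (inten[keep] / ncell[keep] / 1e3)^config$msms_gamma)
      ph_rows[[i]] <- data.table::data.table(
        sequence = tryp$peptide[j], modifications = "Phospho (STY)",
        protease = "TrypsinDD", sample = SAMPLES[keep],
        intensity = inten[keep], gene_id = tryp$gene_id[j],
        isoform_ids = tryp$isoform_ids[j],
        msms_count = rpois(sum(keep), lam_i),
        is_contaminant = FALSE, is_decoy = FALSE, is_phospho = TRUE,
        phospho_residue = res,
        phospho_site = tryp$start[j] + off,
        phospho_multiplicity = mult)
    }
  }
  ph_dt <- data.table::rbindlist(ph_rows, use.names = TRUE)

  # contaminants and decoys -------------------------------------------------
  extra <- vector("list", config$contaminant_n + config$decoy_n)
  for (j in seq_len(config$contaminant_n + config$decoy_n)) {
    decoy <- j > config$contaminant_n
    id <- if (decoy) sprintf("REV__P%04d", j) else sprintf("CON__P%04d", j)
    npep <- sample(2:5, 1L)
    lvl <- 10^runif(1, 9, 12)
    extra[[j]] <- data.table::data.table(
      sequence = vapply(seq_len(npep),
                        function(z) random_sequence(sample(8:20, 1L)), ""),
      modifications = "Unmodified", protease = "TrypsinDD",
      sample = rep(SAMPLES, each = npep),
      intensity = lvl * rlnorm(npep * 7L, 0, 0.2),
      gene_id = id, isoform_ids = paste0(id, "-1"),
      msms_count = rpois(npep * 7L, 4),
      is_contaminant = !decoy, is_decoy = decoy, is_phospho = FALSE,
      phospho_residue = NA_character_, phospho_site = NA_integer_,
      phospho_multiplicity = NA_integer_)
  }
  extra_dt <- data.table::rbindlist(extra)

  out <- data.table::rbindlist(list(long, ph_dt, extra_dt),
                               use.names = TRUE, fill = TRUE)
  data.table::setorder(out, gene_id, sequence, protease, sample,
                       modifications)
  out[]
}

#' Generate an FPKM table
#'
#' FPKM per gene for the pooled G1, S, G2M and asynchronous samples, in two
#' biological and two technical replicates, with log-normal biological and
#' technical noise. Histone-flagged genes are included so that downstream
#' histone removal is exercisable; low-abundance genes drop out at random so
#' that complete-case filtering is exercised.
#'
#' @param truth a `sim_truth`.
#' @param config defaults to `truth$config`.
#' @return `data.table` with columns `gene_id`, `sample`
#'   (G1/S/G2M/ASYNC), `bio_rep`, `tech_rep`, `fpkm`.
#' @export
generate_rna_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  g <- truth$genes
  base <- cbind(G1 = g$fpkm_G1, S = g$fpkm_S, G2M = g$fpkm_G2M,
                ASYNC = g$fpkm_async)
  n <- nrow(g)
  rows <- vector("list", 4L)
  idx <- 1L
  for (b in 1:2) {
    bio <- matrix(10^rnorm(n * 4L, 0, config$rna_bio_sd), n, 4L)
    for (t in 1:2) {
      tech <- matrix(10^rnorm(n * 4L, 0, config$rna_tech_sd), n, 4L)
      val <- base * bio * tech
      dropout <- base < 0.2 & matrix(runif(n * 4L) < 0.3, n, 4L)
      val[dropout] <- 0
      rows[[idx]] <- data.table::data.table(
        gene_id = rep(g$gene_id, 4L),
        sample = rep(colnames(base), each = n),
        bio_rep = b, tech_rep = t,
        fpkm = signif(as.numeric(val), 6))
      idx <- idx + 1L
    }
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, gene_id, sample, bio_rep, tech_rep)
  out[]
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the files every downstream module consumes: `evidence.tsv`,
#' `fpkm.tsv`, `isoforms.fasta`, `fraction_meta.tsv`, `annotations.tsv`,
#' `ground_truth.tsv` (for tests), and `config.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) the `sim_truth` object.
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- generate_ground_truth(config)
  ev <- generate_evidence_table(truth)
  rna <- generate_rna_table(truth)
  # 6 significant digits on write: realistic reported precision, and keeps
  # TSV round-trips type-stable for readers
  ev <- data.table::copy(ev)[, intensity := signif(intensity, 6)]
  data.table::fwrite(ev, file.path(dir, "evidence.tsv"), sep = "\t")
  data.table::fwrite(rna, file.path(dir, "fpkm.tsv"), sep = "\t")
  data.table::fwrite(truth$meta, file.path(dir, "fraction_meta.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t")
  gt <- data.table::copy(truth$genes)
  data.table::fwrite(gt, file.path(dir, "ground_truth.tsv"), sep = "\t")
  write_fasta(setNames(truth$isoforms$sequence, truth$isoforms$isoform_id),
              file.path(dir, "isoforms.fasta"))
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
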