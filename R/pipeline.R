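#' End-to-end pipeline orchestration
#'
#' Runs digestion/coverage accounting, protein-group quantification, the
#' cleaning + checksum consistency filter, cell-cycle regulation detection
#' and clustering, isoform and phosphopeptide analysis, protein-mRNA
#' integration and motif/annotation enrichment in order, writing one TSV
#' report per stage plus a machine-readable summary and a provenance
#' record (config hash, seed, per-stage row counts).
#'
#' @name cli_reporting
NULL

#' Pipeline configuration
#'
#' Every threshold defaults to its module default; the configuration
#' round-trips losslessly through [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input_dir directory containing `evidence.tsv`, `fpkm.tsv`,
#'   `isoforms.fasta`, `fraction_meta.tsv`, `annotations.tsv` (as written
#'   by [simulate_dataset()]).
#' @param out_dir output directory for reports.
#' @param tau checksum log2 tolerance.
#' @param rho_max deconvolution relative-residual tolerance.
#' @param fold_cutoff protein regulation fold cutoff (inclusive).
#' @param phospho_cutoff phosphosite fold cutoff (strict).
#' @param r0 concordance threshold for isoforms and protein/mRNA profiles.
#' @param rna_cutoff coordinated-subset mRNA fold cutoff (strict).
#' @param seed integer seed recorded in provenance.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            tau = 1, rho_max = 0.5,
                            fold_cutoff = 2.0, phospho_cutoff = 2.0,
                            r0 = 0.5, rna_cutoff = 1.5, seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 tau = as.numeric(tau), rho_max = as.numeric(rho_max),
                 fold_cutoff = as.numeric(fold_cutoff),
                 phospho_cutoff = as.numeric(phospho_cutoff),
                 r0 = as.numeric(r0), rna_cutoff = as.numeric(rna_cutoff),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path; `.json` via jsonlite, `.yaml`/`.yml` via the yaml
#'   package when installed.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, lst)
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all stage results, the `summary` list of
#'   headline proportions, and the `provenance` record.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  outd <- config$out_dir
  if (!dir.exists(outd)) dir.create(outd, recursive = TRUE)
  need <- c("evidence.tsv", "fpkm.tsv", "isoforms.fasta",
            "fraction_meta.tsv", "annotations.tsv")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing)) {
    stop("missing pipeline input(s): ", paste(missing, collapse = ", "))
  }
  set.seed(config$seed)
  evidence <- read_tsv(file.path(ind, "evidence.tsv"))
  fpkm <- read_tsv(file.path(ind, "fpkm.tsv"))
  meta <- as.data.frame(read_tsv(file.path(ind, "fraction_meta.tsv")))
  annotations <- read_tsv(file.path(ind, "annotations.tsv"))
  sequences <- read_fasta(file.path(ind, "isoforms.fasta"))

  counts <- list(evidence_rows = nrow(evidence))

  # digestion / protease complementarity ------------------------------------
  part <- tryCatch(
    partition_by_protease(evidence[is_phospho == FALSE &
                                     is_contaminant == FALSE &
                                     is_decoy == FALSE,
                                   .(peptide = sequence, protease)]),
    error = function(e) stage_fail("digestion", e))

  # quantification -----------------------------------------------------------
  res_q <- tryCatch({
    groups <- group_proteins(evidence)
    quant <- aggregate_and_normalize(evidence, groups)
    ibaq <- compute_ibaq(quant$raw, groups, sequences)
    list(groups = groups, quant = quant, ibaq = ibaq)
  }, error = function(e) stage_fail("quantification", e))
  groups <- res_q$groups
  counts$protein_groups <- nrow(groups)

  # consistency filter -------------------------------------------------------
  res_f <- tryCatch({
    cleaned <- clean_evidence(groups, res_q$quant$raw)
    cons <- consistency_report(cleaned$intensity, meta,
                               tau = config$tau, rho_max = config$rho_max)
    list(cleaned = cleaned, cons = cons)
  }, error = function(e) stage_fail("filter", e))
  keep <- res_f$cons$pass
  filtered <- res_f$cleaned$intensity[keep, , drop = FALSE]
  counts$filtered_proteins <- sum(keep)
  data.table::fwrite(res_f$cons, file.path(outd, "consistency_report.tsv"),
                     sep = "\t")

  # regulation (gene level: isoform groups summed per gene) ------------------
  res_r <- tryCatch({
    gid <- res_f$cleaned$groups$gene_id[keep]
    gene_mat <- rowsum(filtered, gid)
    ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
    percell <- sweep(gene_mat[, FRACTIONS, drop = FALSE], 2, ncell, `/`)
    det <- detect_regulated(percell, cutoff = config$fold_cutoff)
    cl <- if (sum(det$regulated) >= 18L) {
      cluster_profiles(percell[det$regulated, , drop = FALSE])
    } else NULL
    summ <- if (!is.null(cl)) summarize_regulation(cl, nrow(percell)) else NULL
    list(det = det, clusters = cl, summary = summ, percell = percell,
         regulated_genes = rownames(percell)[det$regulated])
  }, error = function(e) stage_fail("regulate", e))
  if (!is.null(res_r$clusters)) {
    data.table::fwrite(res_r$clusters, file.path(outd, "clusters.tsv"),
                       sep = "\t")
  }
  counts$filtered_genes <- nrow(res_r$percell)
  counts$regulated_proteins <- sum(res_r$det$regulated)

  # isoforms -----------------------------------------------------------------
  res_i <- tryCatch({
    prof <- isoform_profiles(evidence, sequences)
    multi <- prof[, .N, by = gene_id][N >= 2L]$gene_id
    conc <- lapply(multi, function(g)
      concordance(prof[gene_id == g], r0 = config$r0))
    disc <- vapply(conc, `[[`, logical(1), "discordant")
    list(profiles = prof, concordance = conc,
         discordant_genes = multi[disc])
  }, error = function(e) stage_fail("isoforms", e))
  data.table::fwrite(res_i$profiles, file.path(outd, "isoform_profiles.tsv"),
                     sep = "\t")

  # phospho ------------------------------------------------------------------
  res_p <- tryCatch({
    sites <- phospho_sites(evidence, meta)
    if (nrow(sites)) {
      reg <- detect_regulated_phospho(sites, cutoff = config$phospho_cutoff)
      brk <- residue_breakdown_and_overlap(reg$sites, res_r$regulated_genes)
      list(sites = sites, reg = reg, breakdown = brk)
    } else list(sites = sites, reg = NULL, breakdown = NULL)
  }, error = function(e) stage_fail("phospho", e))
  counts$phospho_sites <- nrow(res_p$sites)

  # rna ----------------------------------------------------------------------
  res_rna <- tryCatch({
    histones <- unique(annotations$gene_id[annotations$term_id == "HISTONE"])
    merged <- merge_gene_level(res_q$ibaq$ibaq, groups, fpkm, histones)
    rho <- correlate_abundances(merged[complete == TRUE], "async")
    reg_genes <- res_r$regulated_genes
    coord <- coordinated_subset(reg_genes, merged, meta,
                                rna_cutoff = config$rna_cutoff)
    cls <- classify_profile_correlation(merged, meta, r0 = config$r0)
    list(merged = merged, rho_async = rho, coordinated = coord,
         classification = cls, regulated_genes = reg_genes)
  }, error = function(e) stage_fail("rna", e))
  counts$merged_genes <- sum(res_rna$merged$complete)

  # enrichment ---------------------------------------------------------------
  res_e <- tryCatch({
    deg <- scan_degrons(sequences, gene_set = res_rna$coordinated$genes)
    bg <- unique(res_rna$merged$gene_id)
    set <- intersect(res_rna$regulated_genes, bg)
    enr <- if (length(set) >= 1L) enrich_terms(set, annotations, bg) else NULL
    list(degrons = deg, enrichment = enr)
  }, error = function(e) stage_fail("enrich", e))
  if (!is.null(res_e$enrichment)) {
    data.table::fwrite(res_e$enrichment, file.path(outd, "enrichment.tsv"),
                       sep = "\t")
  }

  summary <- list(
    n_evidence_rows = counts$evidence_rows,
    n_protein_groups = counts$protein_groups,
    n_filtered_groups = counts$filtered_proteins,
    n_filtered_genes = counts$filtered_genes,
    n_regulated = counts$regulated_proteins,
    regulated_pct = round_half_up(
      100 * counts$regulated_proteins / max(1L, counts$filtered_genes), 1),
    lysc_relative_increase_pct = part$relative_increase_pct,
    n_phospho_sites = counts$phospho_sites,
    phospho_regulated_pct = if (!is.null(res_p$reg))
      res_p$reg$regulated_pct else NA,
    spearman_async = res_rna$rho_async$rho,
    n_coordinated = res_rna$coordinated$n,
    n_discordant_isoform_genes = length(res_i$discordant_genes)
  )
  provenance <- list(
    config = unclass(config),
    config_hash = paste0("sum", sum(utf8ToInt(paste(
      names(unlist(config)), unlist(config), collapse = "|")))),
    seed = config$seed,
    stage_rows = counts,
    timestamp = "deterministic"
  )
  jsonlite::write_json(summary, file.path(outd, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(provenance, file.path(outd, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(partition = part, quant = res_q, filter = res_f,
                 regulation = res_r, isoforms = res_i, phospho = res_p,
                 rna = res_rna, enrichment = res_e, summary = summary,
                 provenance = provenance))
}
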