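#' Data cleaning and elutriation self-consistency filtering
#'
#' Implements the cleaning rules (minimum two peptides, no contaminant or
#' decoy groups, no missing fraction intensities) and the "checksum"
#' self-consistency algorithm: the intensity measured in the asynchronous
#' population must be explainable as the cell-count-weighted linear
#' combination of the six elutriated fraction intensities, each normalized
#' by its measured cell count. A non-negative least-squares deconvolution of
#' the fraction profile onto G1/S/G2M phase compositions generalizes the
#' adjacent-fraction factor check.
#'
#' @name consistency_filter
NULL

#' Apply the cleaning rules to protein groups
#'
#' Removes groups with fewer than two peptide identifications, groups
#' flagged as contaminants or reverse (decoy) hits, and groups lacking
#' intensity in any of F1--F6 or the asynchronous sample.
#'
#' @param groups group table from [group_proteins()].
#' @param intensity matrix groups x samples (raw intensities); zero or `NA`
#'   counts as missing.
#' @param min_peptides minimum peptide identifications (default 2).
#' @return list with `groups` (filtered table), `intensity` (filtered
#'   matrix) and `removed` (data.frame of group id and reason).
#' @export
clean_evidence <- function(groups, intensity, min_peptides = 2L) {
  stopifnot(all(groups$group_id == rownames(intensity)))
  need <- intersect(SAMPLES, colnames(intensity))
  miss <- rowSums(is.na(intensity[, need, drop = FALSE]) |
                    intensity[, need, drop = FALSE] <= 0) > 0
  reason <- rep(NA_character_, nrow(groups))
  reason[miss] <- "missing_fraction"
  reason[groups$peptide_count < min_peptides] <- "few_peptides"
  reason[groups$is_decoy] <- "decoy"
  reason[groups$is_contaminant] <- "contaminant"
  keep <- is.na(reason)
  list(groups = groups[keep],
       intensity = intensity[keep, , drop = FALSE],
       removed = data.frame(group_id = groups$group_id[!keep],
                            reason = reason[!keep]))
}

#' Checksum self-consistency filter
#'
#' Load-normalized per-cell intensities are computed as
#' `I_f / n_f`; the predicted asynchronous per-cell intensity is the
#' cell-count-weighted mixture `sum_f w_f I_f/n_f` with `w_f = n_f / sum n_f`.
#' A protein passes when `|log2(predicted / measured)| <= tau`
#' (boundary inclusive). The deviation is invariant to rescaling all
#' samples jointly.
#'
#' @param intensity matrix (rows proteins, columns containing F1..F6 and
#'   ASYNC) of raw intensities.
#' @param meta fraction metadata ([fraction_meta_default()] format).
#' @param tau log2 tolerance (default 1, i.e. twofold).
#' @return `data.frame` of class `consistency_result` with `predicted`,
#'   `measured` (per-cell async), `deviation`, `pass`, `reason`.
#' @export
checksum_filter <- function(intensity, meta, tau = 1) {
  stopifnot(all(c(FRACTIONS, "ASYNC") %in% colnames(intensity)))
  ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
  n_async <- meta$cell_count[match("ASYNC", meta$sample)]
  if (any(is.na(ncell)) || any(ncell <= 0)) stop("invalid fraction cell counts")
  percell <- sweep(intensity[, FRACTIONS, drop = FALSE], 2, ncell, `/`)
  w <- ncell / sum(ncell)
  predicted <- as.numeric(percell %*% w)
  measured <- intensity[, "ASYNC"] / n_async
  deviation <- abs(log2(predicted / measured))
  reason <- rep(NA_character_, length(measured))
  bad <- !is.finite(measured) | measured <= 0
  reason[bad] <- "zero_async"
  pass <- !bad & deviation <= tau + 1e-12
  reason[!pass & !bad] <- "checksum_deviation"
  out <- data.frame(protein = rownames(intensity), predicted = predicted,
                    measured = measured, deviation = deviation,
                    pass = pass, reason = reason, row.names = NULL)
  class(out) <- c("consistency_result", class(out))
  out
}

#' Non-negative least squares by active-set enumeration
#'
#' Exact NNLS for small systems: enumerates all subsets of free variables,
#' solves each ordinary least-squares subproblem, and keeps the feasible
#' solution with minimal residual sum of squares. Intended for the 3-phase
#' deconvolution design (and the Watson mixture amplitudes), where the
#' number of columns is tiny.
#'
#' @param A design matrix (m x p, p small).
#' @param b response vector.
#' @return list with `x` (coefficients, >= 0) and `rss`.
#' @export
nnls_solve <- function(A, b) {
  p <- ncol(A)
  if (qr(A)$rank < p) {
    dep <- which(abs(diag(qr.R(qr(A)))) < 1e-10)
    stop("rank-deficient design; degenerate columns: ",
         paste(colnames(A)[dep] %||% dep, collapse = ", "))
  }
  best <- list(x = rep(0, p), rss = sum(b^2))
  for (mask in seq_len(2^p - 1L)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    fit <- qr.coef(qr(A[, free, drop = FALSE]), b)
    if (any(!is.finite(fit)) || any(fit < -1e-12)) next
    x <- rep(0, p)
    x[free] <- pmax(fit, 0)
    rss <- sum((b - A %*% x)^2)
    if (rss < best$rss - 1e-15) best <- list(x = x, rss = rss)
  }
  names(best$x) <- colnames(A)
  best
}

#' Phase-level deconvolution of a fraction profile
#'
#' Solves, per protein, the non-negative least-squares problem
#' `min_x sum_f (I_f/n_f - sum_p pi_fp x_p)^2` for phase-level per-cell
#' expression `x = (x_G1, x_S, x_G2M)`, and reports the relative residual
#' `RMS error / mean per-cell intensity`. Formalizes the adjacent-fraction
#' consistency factors computed from cell numbers and phase proportions.
#'
#' @param intensity matrix with F1..F6 columns (raw intensities) or a
#'   single profile vector named by fraction.
#' @param meta fraction metadata with phase compositions.
#' @param rho_max maximum relative residual to pass (default 0.5).
#' @param percell logical; set `TRUE` when `intensity` is already per-cell.
#' @return `data.frame` with `x_G1`, `x_S`, `x_G2M`, `residual`, `pass`.
#' @export
phase_deconvolution <- function(intensity, meta, rho_max = 0.5,
                                percell = FALSE) {
  if (is.null(dim(intensity))) {
    intensity <- matrix(intensity, 1L, length(intensity),
                        dimnames = list("profile", names(intensity)))
  }
  stopifnot(all(FRACTIONS %in% colnames(intensity)))
  Pi <- meta_matrix(meta)
  if (qr(Pi)$rank < 3L) {
    stop("phase composition matrix is rank deficient; fractions ",
         paste(FRACTIONS, collapse = ","), " do not span G1/S/G2M")
  }
  ncell <- meta$cell_count[match(FRACTIONS, meta$sample)]
  I <- intensity[, FRACTIONS, drop = FALSE]
  if (!percell) I <- sweep(I, 2, ncell, `/`)
  res <- apply(I, 1, function(b) {
    fit <- nnls_solve(Pi, b)
    rel <- sqrt(fit$rss / length(b)) / mean(b)
    c(fit$x, residual = rel)
  })
  out <- as.data.frame(t(res))
  names(out) <- c("x_G1", "x_S", "x_G2M", "residual")
  out$pass <- out$residual <= rho_max + 1e-12
  out$protein <- rownames(intensity)
  rownames(out) <- NULL
  out[, c("protein", "x_G1", "x_S", "x_G2M", "residual", "pass")]
}

#' Combined consistency report
#'
#' Runs [checksum_filter()] and [phase_deconvolution()] and combines the
#' pass flags (`pass` iff deviation <= tau AND residual <= rho_max).
#'
#' @inheritParams checksum_filter
#' @inheritParams phase_deconvolution
#' @return merged `data.frame` with both criteria and an overall `pass`.
#' @export
consistency_report <- function(intensity, meta, tau = 1, rho_max = 0.5) {
  cs <- checksum_filter(intensity, meta, tau)
  pd <- phase_deconvolution(intensity, meta, rho_max)
  out <- cbind(cs[, c("protein", "predicted", "measured", "deviation")],
               pd[, c("x_G1", "x_S", "x_G2M", "residual")])
  out$pass_checksum <- cs$pass
  out$pass_residual <- pd$pass
  out$pass <- cs$pass & pd$pass
  out$reason <- cs$reason
  out$reason[is.na(out$reason) & !pd$pass] <- "deconvolution_residual"
  out
}
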