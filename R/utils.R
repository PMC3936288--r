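#' @importFrom stats rnorm rlnorm rpois runif rbinom cor dnorm pnorm plogis
#'   median optim uniroot hclust cutree dist setNames aggregate phyper pbinom
#'   p.adjust quantile sd rmultinom
#' @importFrom utils head combn
NULL

SAMPLES <- c("F1", "F2", "F3", "F4", "F5", "F6", "ASYNC")
FRACTIONS <- SAMPLES[1:6]
PHASES <- c("G1", "S", "G2M")

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Approximate residue frequencies of the human proteome (UniProt statistics,
# rounded); used when drawing synthetic protein sequences.
AA_FREQ_HUMAN <- c(
  A = 0.0702, R = 0.0564, N = 0.0359, D = 0.0473, C = 0.0230,
  E = 0.0710, Q = 0.0477, G = 0.0657, H = 0.0263, I = 0.0433,
  L = 0.0996, K = 0.0572, M = 0.0213, F = 0.0365, P = 0.0631,
  S = 0.0833, T = 0.0536, W = 0.0122, Y = 0.0266, V = 0.0597
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fold change (max/min) of a positive profile
#'
#' @param x numeric vector of positive intensities.
#' @return max(x)/min(x).
#' @keywords internal
profile_fold <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("profile_fold() requires strictly positive, finite intensities")
  }
  max(x) / min(x)
}

#' Scale a profile to unit maximum
#' @param x numeric vector of positive values.
#' @keywords internal
scale_max <- function(x) x / max(x)

check_proportions <- function(p, name, tol = 1e-9) {
  if (any(p < 0)) stop(name, " must be non-negative")
  if (abs(sum(p) - 1) > tol) {
    stop(name, " must sum to 1 (got ", format(sum(p)), ")")
  }
  invisible(p)
}

# Round-half-up at `digits` decimal places. Base round() rounds half to even,
# which does not match the reporting convention for percentages.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Pearson correlation that returns NA (not an error/warning) for
#' zero-variance input
#' @keywords internal
safe_pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}
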