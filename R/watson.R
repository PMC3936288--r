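#' Watson pragmatic model for DNA-content histograms
#'
#' Estimates G1/S/G2M proportions from propidium-iodide-style DNA-content
#' histograms. The model comprises Gaussian G1 and G2&M peaks (with the G2
#' mean constrained near twice the G1 mean) plus an S-phase component
#' modeled as a constant synthesis-rate density between the two peaks
#' convolved with the peak width (a difference of normal CDFs). For fixed
#' peak shape parameters the three component amplitudes solve by
#' non-negative least squares; the shape parameters are then optimized by
#' bounded quasi-Newton least squares.
#'
#' @name facs_watson
NULL

watson_components <- function(x, mu1, sigma1, r, k, binwidth) {
  mu2 <- r * mu1
  sigma2 <- k * sigma1
  g1 <- dnorm(x, mu1, sigma1)
  g2 <- dnorm(x, mu2, sigma2)
  s <- (pnorm((x - mu1) / sigma1) - pnorm((x - mu2) / sigma2)) / (mu2 - mu1)
  cbind(G1 = g1, S = s, G2M = g2) * binwidth
}

#' Simulate a DNA-content histogram
#'
#' Per-cell DNA content is drawn as G1 ~ Normal(mu, cv*mu), G2&M ~
#' Normal(2*mu, 2*cv*mu), and S uniform on (mu, 2*mu) blurred with
#' Normal(0, cv*mu) measurement noise, then binned.
#'
#' @param proportions numeric length-3 (G1, S, G2M), summing to 1.
#' @param mu G1 peak position (arbitrary fluorescence units).
#' @param cv coefficient of variation of the G1 peak.
#' @param n_cells number of cells to draw.
#' @param n_bins number of histogram bins.
#' @param seed optional RNG seed.
#' @return list of class `dna_histogram` with `bin_center`, `count`,
#'   `binwidth`, and the generating parameters.
#' @export
simulate_histogram <- function(proportions, mu = 100, cv = 0.05,
                               n_cells = 1e5, n_bins = 256L, seed = NULL) {
  check_proportions(proportions, "proportions")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_cells)
  phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE, prob = proportions)
  x <- numeric(n)
  ng1 <- sum(phase == "G1"); ns <- sum(phase == "S"); ng2 <- sum(phase == "G2M")
  x[phase == "G1"] <- rnorm(ng1, mu, cv * mu)
  x[phase == "G2M"] <- rnorm(ng2, 2 * mu, 2 * cv * mu)
  x[phase == "S"] <- runif(ns, mu, 2 * mu) + rnorm(ns, 0, cv * mu)
  lo <- 0.5 * mu; hi <- 2.9 * mu
  x <- x[x >= lo & x <= hi]
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  structure(list(bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 count = counts, binwidth = diff(breaks[1:2]),
                 proportions = proportions, mu = mu, cv = cv),
            class = "dna_histogram")
}

#' Fit the Watson model to a DNA-content histogram
#'
#' @param hist a `dna_histogram` (or list with `bin_center`, `count`,
#'   `binwidth`).
#' @param gate optional length-2 numeric; bins outside are ignored
#'   (use to exclude sub-2N debris).
#' @return list of class `watson_fit` with `mu_G1`, `sigma_G1`, `mu_G2`,
#'   `sigma_G2`, `proportions` (named G1/S/G2M), `residual` (relative RMS),
#'   and `fitted` counts.
#' @export
fit_watson <- function(hist, gate = NULL) {
  x <- hist$bin_center
  y <- hist$count
  bw <- hist$binwidth %||% diff(x[1:2])
  if (!is.null(gate)) {
    keep <- x >= gate[1] & x <= gate[2]
    x <- x[keep]; y <- y[keep]
  }
  total <- sum(y)
  if (total <= 0) stop("empty histogram")
  f <- y / total

  # initialization: the strongest peak is G1 or G2; try both hypotheses
  peak <- x[which.max(y)]
  sig0 <- 0.05 * peak
  objective <- function(par) {
    mu1 <- par[1]; sigma1 <- exp(par[2]); r <- par[3]; k <- par[4]
    B <- watson_components(x, mu1, sigma1, r, k, bw)
    fit <- tryCatch(nnls_solve(B, f), error = function(e) NULL)
    if (is.null(fit)) return(1e6)
    fit$rss
  }
  fit_from <- function(mu1_0) {
    lower <- c(0.7 * mu1_0, log(0.015 * mu1_0), 1.8, 1.0)
    upper <- c(1.3 * mu1_0, log(0.20 * mu1_0), 2.2, 2.5)
    start <- c(mu1_0, log(sig0), 2.0, 2.0)
    start <- pmin(pmax(start, lower), upper)
    optim(start, objective, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 200))
  }
  cands <- list(fit_from(peak), fit_from(peak / 2))
  best <- cands[[which.min(vapply(cands, `[[`, 0, "value"))]]
  mu1 <- best$par[1]; sigma1 <- exp(best$par[2])
  r <- best$par[3]; k <- best$par[4]
  if (mu1 < min(x) || r * mu1 > max(x)) {
    stop("failed to bracket both G1 and G2 peaks; adjust gating bounds")
  }
  B <- watson_components(x, mu1, sigma1, r, k, bw)
  amp <- nnls_solve(B, f)
  # component areas: columns are normalized densities times binwidth, so
  # amplitudes are already proportional to areas over the gated range
  pr <- amp$x / sum(amp$x)
  fitted <- as.numeric(B %*% amp$x) * total
  structure(list(mu_G1 = mu1, sigma_G1 = sigma1,
                 mu_G2 = r * mu1, sigma_G2 = k * sigma1,
                 proportions = setNames(pr, PHASES),
                 residual = sqrt(amp$rss / length(f)) / mean(f),
                 fitted = fitted),
            class = "watson_fit")
}
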