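#' Quality-control markers on MAF and call rate
#'
#' Removes markers with minor allele frequency below `min_maf` (strict)
#' or call rate below `min_call` (strict); remaining missing codes are
#' imputed to the marker mean (kept as real values in downstream design
#' matrices).
#'
#' @param genotypes A `genotype_matrix` (possibly with missing codes).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param min_call Minimum call rate (default 0.90).
#' @return A `genotype_matrix` with an `imputed` numeric code matrix and
#'   only surviving markers.
#' @export
qc_markers <- function(genotypes, min_maf = 0.05, min_call = 0.90) {
  codes <- genotypes$codes
  call_rate <- colMeans(!is.na(codes))
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf & call_rate >= min_call
  if (!any(keep)) stop("QC removed all markers")
  codes <- codes[, keep, drop = FALSE]
  map <- genotypes$map[keep, , drop = FALSE]
  imputed <- impute_codes(codes)
  storage.mode(imputed) <- "double"
  obj <- list(codes = codes, imputed = imputed, map = map,
              allele_freq = unname(colMeans(imputed) / 2),
              n_removed = sum(!keep))
  class(obj) <- "genotype_matrix"
  obj
}

## numeric design matrix of a (possibly QC'd) genotype_matrix
design_matrix <- function(genotypes) {
  if (!is.null(genotypes$imputed)) return(genotypes$imputed)
  Z <- impute_codes(genotypes$codes)
  storage.mode(Z) <- "double"
  Z
}

#' Single-trait Bayes-B marker association
#'
#' Gibbs sampler for `y = 1*mu + sum_i Z_i g_i + e` with residual
#' covariance `diag(1/w) * sigma_e^2`: each marker effect is zero with
#' prior probability `pi` and otherwise carries its own variance with a
#' scaled inverse chi-square prior. Scale parameters follow
#' `S = sigma^2 (nu - 2) / nu` with `(nu = 4, sigma^2 = 5)` for the
#' marker variance and `(nu = 10, sigma^2 = 3)` for the residual.
#'
#' @param y Numeric response (de-regressed PTAs).
#' @param Z Genotype design matrix (bulls x markers) or a
#'   `genotype_matrix`.
#' @param weights Positive association weights (residual variance is
#'   `sigma_e^2 / w_i`); default all 1.
#' @param pi Prior null fraction, default 0.9.
#' @param chain_length,burn_in Gibbs chain settings (defaults 40000/5000).
#' @param nu_marker,s2_marker Marker-variance prior df and variance
#'   (defaults 4 and 5).
#' @param nu_resid,s2_resid Residual-variance prior df and variance
#'   (defaults 10 and 3).
#' @param common_variance Use one shared slab variance instead of
#'   per-marker variances (default FALSE, classic Bayes-B).
#' @param allele_freq Allele frequencies for `pvg`; taken from `Z` when it
#'   is a `genotype_matrix`.
#' @param seed Optional integer seed applied before sampling.
#' @return Object of class `bayesb` with per-marker posterior mean effects
#'   (`abar`, zeros included), `inclusion_freq`, `pvg`, chain summaries
#'   and settings.
#' @export
bayesb <- function(y, Z, weights = NULL, pi = 0.9,
                   chain_length = 40000, burn_in = 5000,
                   nu_marker = 4, s2_marker = 5,
                   nu_resid = 10, s2_resid = 3,
                   common_variance = FALSE, allele_freq = NULL,
                   seed = NULL) {
  if (inherits(Z, "genotype_matrix")) {
    if (is.null(allele_freq)) allele_freq <- Z$allele_freq
    marker_ids <- Z$map$marker
    Z <- design_matrix(Z)
  } else {
    marker_ids <- colnames(Z)
    Z <- as.matrix(Z)
  }
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y contains non-finite values")
  if (stats::sd(y) == 0) stop("y has zero variance")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) stop("weights must be positive")
  if (length(y) != nrow(Z) || length(weights) != length(y))
    stop("dimensions of y, Z and weights disagree")
  if (pi < 0 || pi >= 1) stop("pi must lie in [0, 1)")
  if (burn_in >= chain_length) stop("burn_in must be below chain_length")
  if (!is.null(seed)) set.seed(seed)

  S_g <- s2_marker * (nu_marker - 2) / nu_marker
  S_e <- s2_resid * (nu_resid - 2) / nu_resid
  fit <- .bayesb_gibbs(y, Z, weights, pi, as.integer(chain_length),
                       as.integer(burn_in), nu_marker, S_g, nu_resid, S_e,
                       common_variance)
  if (is.null(allele_freq)) allele_freq <- colMeans(Z) / 2
  pvg <- tryCatch(compute_pvg(fit$abar, allele_freq),
                  error = function(e) rep(NA_real_, ncol(Z)))
  out <- list(abar = stats::setNames(fit$abar, marker_ids),
              inclusion_freq = stats::setNames(fit$inclusion_freq, marker_ids),
              abar_conditional = stats::setNames(fit$abar_conditional,
                                                 marker_ids),
              pvg = stats::setNames(pvg, marker_ids),
              mu = fit$mu, sigma2e = fit$sigma2e,
              mean_model_fraction = fit$mean_model_fraction,
              allele_freq = allele_freq,
              settings = list(pi = pi, chain_length = chain_length,
                              burn_in = burn_in, nu_marker = nu_marker,
                              s2_marker = s2_marker, nu_resid = nu_resid,
                              s2_resid = s2_resid,
                              common_variance = common_variance))
  class(out) <- "bayesb"
  out
}

#' @export
print.bayesb <- function(x, ...) {
  cat(sprintf("bayesb fit: %d markers, pi = %.2f, chain %d/%d\n",
              length(x$abar), x$settings$pi, x$settings$chain_length,
              x$settings$burn_in))
  cat(sprintf("  mu = %.4f, sigma2e = %.4f, mean model fraction = %.3f\n",
              x$mu, x$sigma2e, x$mean_model_fraction))
  invisible(x)
}

#' @export
summary.bayesb <- function(object, n_top = 5, ...) {
  ord <- order(object$pvg, decreasing = TRUE)[seq_len(min(n_top,
                                                          length(object$pvg)))]
  cat("Top markers by PV_g:\n")
  print(data.frame(marker = names(object$pvg)[ord],
                   abar = unname(object$abar[ord]),
                   inclusion = unname(object$inclusion_freq[ord]),
                   pvg = unname(object$pvg[ord])))
  invisible(object)
}

#' @export
coef.bayesb <- function(object, ...) object$abar

#' Proportion of marker-explained genetic variance per SNP
#'
#' `PV_g[j] = 2 p_j (1 - p_j) abar_j^2 / sum_j 2 p_j (1 - p_j) abar_j^2`.
#' Monomorphic markers (p of 0 or 1) contribute zero.
#'
#' @param abar Posterior mean marker effects.
#' @param allele_freq Allele frequencies in `[0, 1]`.
#' @return Vector summing to 1.
#' @export
compute_pvg <- function(abar, allele_freq) {
  stopifnot(length(abar) == length(allele_freq))
  num <- 2 * allele_freq * (1 - allele_freq) * abar^2
  tot <- sum(num)
  if (!is.finite(tot) || tot <= 0)
    stop("PV_g undefined: all weighted squared effects are zero")
  num / tot
}

#' Retain the top fraction of markers by PV_g
#'
#' Flags markers at or above the given percentile of their trait's PV_g
#' distribution: with `percentile = 75` the top 25% are retained. Ties at
#' the threshold are all kept (inclusive rule).
#'
#' @param pvg Named numeric vector of PV_g values (one trait), or a list
#'   of such vectors (one per trait).
#' @param percentile Percentile threshold, default 75.
#' @return Character vector of retained marker ids (or a named list of
#'   them when `pvg` is a list).
#' @export
retain_top_fraction <- function(pvg, percentile = 75) {
  if (is.list(pvg)) return(lapply(pvg, retain_top_fraction, percentile))
  m <- length(pvg)
  k <- max(1L, floor(m * (1 - percentile / 100)))
  thr <- sort(pvg, decreasing = TRUE)[k]
  ids <- names(pvg)[pvg >= thr]
  if (is.null(names(pvg))) ids <- which(pvg >= thr)
  ids
}
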