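# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (triple loops, numerical solves,
# Monte-Carlo) kept separate from the package code paths they check.

# Brute-force PCIT: exhaustive trio enumeration with the trio tolerance
# eps = mean(partial/direct) and the direct-correlation elimination test.
pcit_oracle <- function(R, compare = "direct") {
  n <- nrow(R)
  elim <- matrix(FALSE, n, n)
  tol <- 1 - 1e-12
  if (n >= 3) {
    for (z in 1:n) {
      for (x in 1:(n - 1)) {
        for (y in (x + 1):n) {
          if (x == z || y == z) next
          rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
          if (rxy == 0 || rxz == 0 || ryz == 0) next
          if (abs(rxy) >= tol || abs(rxz) >= tol || abs(ryz) >= tol) next
          pxy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
          pxz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
          pyz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
          eps <- (pxy / rxy + pxz / rxz + pyz / ryz) / 3
          drop <- if (compare == "direct")
            abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)
          else
            abs(pxy) <= abs(eps * pxz) && abs(pxy) <= abs(eps * pyz)
          if (drop) elim[x, y] <- elim[y, x] <- TRUE
        }
      }
    }
  }
  keep <- abs(R) > 0 & !elim
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  if (!nrow(idx)) return(character(0))
  a <- rownames(R)[idx[, 1]]
  b <- rownames(R)[idx[, 2]]
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

edge_keys <- function(network) {
  if (!nrow(network$edges)) return(character(0))
  sort(paste(network$edges$a, network$edges$b, sep = "|"))
}

# random correlation matrix shaped like AWM row correlations:
# n standardized 6-vectors
random_awm_cor <- function(n, p = 6) {
  M <- matrix(rnorm(n * p), n, p)
  R <- cor(t(M))
  dimnames(R) <- list(paste0("g", 1:n), paste0("g", 1:n))
  R
}

# De-regression oracle: numerical solve of the two reliability equations
# of the PA/animal mixed-model pair, then the de-regression arithmetic.
dereg_oracle <- function(pta, rel, pa, rel_pa, h2, c = 0.5) {
  lam <- (1 - h2) / h2
  resid <- function(par) {
    C <- matrix(c(par[1] + 4 * lam, -2 * lam, -2 * lam, par[2] + 2 * lam), 2)
    Ci <- solve(C)
    c(0.5 - lam * Ci[1, 1] - rel_pa, 1 - lam * Ci[2, 2] - rel)
  }
  sol <- stats::optim(c(1, 1), function(p) sum(resid(p)^2),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  zz <- sol$par
  y2 <- -2 * lam * pa + (zz[2] + 2 * lam) * pta
  dpta <- y2 / zz[2]
  rel_d <- zz[2] / (zz[2] + lam)
  w <- (1 - h2) / ((c + (1 - rel_d) / rel_d) * h2)
  list(dpta = dpta, w = w, rel_dpta = rel_d)
}

# Monte-Carlo intersection-size tail for small universes
mc_intersection_tail <- function(sizes, universe, k, n_draws = 2e5) {
  hits <- 0L
  for (r in seq_len(n_draws)) {
    inter <- sample.int(universe, sizes[1])
    for (s in sizes[-1]) inter <- intersect(inter, sample.int(universe, s))
    if (length(inter) >= k) hits <- hits + 1L
  }
  hits / n_draws
}

# discrete power-law sample (pmf proportional to x^-alpha on 1..xmax)
rpowerlaw <- function(n, alpha = 2.5, xmax = 5000) {
  sample.int(xmax, n, replace = TRUE, prob = (1:xmax)^(-alpha))
}

# small sparse-QTL regression fixture with known truth (single trait)
make_gwas_fixture <- function(n = 300, m = 1000, n_qtl = 20, h2 = 0.5,
                              seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  Z <- sapply(p, function(pp) rbinom(n, 2, pp))
  colnames(Z) <- sprintf("M%04d", 1:m)
  a <- numeric(m)
  qtl <- sample.int(m, n_qtl)
  a[qtl] <- rnorm(n_qtl)
  g <- as.vector(scale(Z, center = 2 * p, scale = FALSE) %*% a)
  g <- g * sqrt(h2) / sd(g)
  a <- a * sqrt(h2) / sd(as.vector(scale(Z, center = 2 * p,
                                         scale = FALSE) %*% a))
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  list(y = y, Z = Z, effects = a, qtl = qtl, p = p)
}

# y drawn from the Bayes-B prior-predictive distribution
make_prior_predictive <- function(n, m, pi = 0.9, nu_g = 4, s2_g = 5,
                                  nu_e = 10, s2_e = 3, seed = 1) {
  set.seed(seed)
  S_g <- s2_g * (nu_g - 2) / nu_g
  S_e <- s2_e * (nu_e - 2) / nu_e
  p <- runif(m, 0.1, 0.5)
  Z <- sapply(p, function(pp) rbinom(n, 2, pp))
  colnames(Z) <- sprintf("M%04d", 1:m)
  delta <- runif(m) < (1 - pi)
  s2j <- nu_g * S_g / rchisq(m, nu_g)
  a <- ifelse(delta, rnorm(m, 0, sqrt(s2j)), 0)
  s2e <- nu_e * S_e / rchisq(1, nu_e)
  y <- as.vector(Z %*% a) + rnorm(n, 0, sqrt(s2e))
  list(y = y, Z = Z, frac_nonzero = mean(delta))
}

# small demo population shared by several tests
demo_population <- function(seed = 11, n_sires = 12, progeny = 15,
                            n_markers = 600, n_genes = 120) {
  simulate_population(sim_config(n_sires = n_sires,
                                 progeny_per_sire = progeny,
                                 n_markers = n_markers, n_genes = n_genes,
                                 seed = seed))
}
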