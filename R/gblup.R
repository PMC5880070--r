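#' Pedigree-clustered cross-validation folds
#'
#' Clusters bulls into `k` families by k-means on the rows of the
#' pedigree relationship matrix, so that relatives are kept together and
#' train/validation leakage through close pedigree ties is reduced.
#'
#' @param A A `grm` (pedigree A-matrix) or symmetric matrix with bull ids
#'   as dimnames.
#' @param k Number of folds (default 4).
#' @param seed Integer seed for the k-means start.
#' @param nstart Random starts (default 10).
#' @return Named integer vector assigning each bull to a fold in
#'   `1..k`.
#' @export
kmeans_families <- function(A, k = 4, seed = 1L, nstart = 10) {
  M <- if (inherits(A, "grm")) A$matrix else as.matrix(A)
  if (k > nrow(M)) stop("k exceeds the number of bulls")
  set.seed(seed)
  cl <- stats::kmeans(M, centers = k, nstart = nstart)
  stats::setNames(cl$cluster, rownames(M))
}

#' Bayesian GBLUP with one or more genomic kernels
#'
#' Gibbs sampler for `y = 1*mu + sum_k g_k + e` with
#' `g_k ~ N(0, G_k sigma_k^2)` and `e ~ N(0, diag(1/w) sigma_e^2)`,
#' reparameterized through the eigendecomposition of each kernel.
#' Individuals with weight 0 are treated as unobserved (masked) but still
#' receive genetic-value predictions. Variance components carry scaled
#' inverse chi-square priors (df `nu`, scales from an even split of
#' `h2_prior` of the phenotypic variance across kernels) unless fixed.
#'
#' @param y Numeric response; entries at masked positions are ignored.
#' @param kernels A `grm`, a matrix, or a list of them (1 or 2 kernels in
#'   the standard models).
#' @param weights Non-negative residual weights; 0 masks an individual.
#' @param chain_length,burn_in Chain settings (defaults 20000/5000).
#' @param nu Variance-prior degrees of freedom (default 5).
#' @param h2_prior Prior fraction of variance assigned to the genomic
#'   kernels jointly (default 0.5).
#' @param fix_var Optional list `list(s2k = ..., s2e = ...)` to run with
#'   fixed variance components.
#' @param seed Optional integer seed.
#' @return Object of class `gblup`: posterior means `mu`, `ghat`
#'   (bulls x kernels), variance components `s2k`, `s2e`, variance
#'   fractions, and the fitted predictor.
#' @export
gblup <- function(y, kernels, weights = NULL, chain_length = 20000,
                  burn_in = 5000, nu = 5, h2_prior = 0.5,
                  fix_var = NULL, seed = NULL) {
  if (!is.list(kernels) || inherits(kernels, "grm")) kernels <- list(kernels)
  Gs <- lapply(kernels, function(g) if (inherits(g, "grm")) g$matrix
               else as.matrix(g))
  labels <- vapply(seq_along(kernels), function(i) {
    if (inherits(kernels[[i]], "grm")) kernels[[i]]$label
    else paste0("K", i)
  }, "")
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative")
  obs <- weights > 0
  if (!any(obs)) stop("all individuals are masked")
  yy <- y
  yy[!obs] <- 0 # masked entries carry no likelihood
  for (G in Gs) if (nrow(G) != n) stop("kernel dimension mismatch")
  if (!is.null(seed)) set.seed(seed)

  eigs <- lapply(Gs, function(G) {
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    lam <- eg$values
    if (any(lam < -1e-6 * max(abs(lam))))
      warning("kernel has notably negative eigenvalues; clipped to zero")
    lam <- pmax(lam, 0)
    keep <- lam > 1e-10 * max(lam, 1)
    list(U = eg$vectors[, keep, drop = FALSE], lam = lam[keep])
  })

  vy <- stats::var(y[obs])
  K <- length(Gs)
  S_g <- rep(vy * h2_prior / K * (nu - 2) / nu, K)
  S_e <- vy * (1 - h2_prior) * (nu - 2) / nu
  fixed <- !is.null(fix_var)
  s2k_fixed <- if (fixed) rep_len(fix_var$s2k, K) else rep(0, K)
  s2e_fixed <- if (fixed) fix_var$s2e else 0

  fit <- .gblup_gibbs(yy, weights, lapply(eigs, `[[`, "U"),
                      lapply(eigs, `[[`, "lam"),
                      as.integer(chain_length), as.integer(burn_in),
                      nu, S_g, nu, S_e, fixed, s2k_fixed, s2e_fixed)
  ghat <- fit$ghat
  colnames(ghat) <- labels
  if (!is.null(names(y))) rownames(ghat) <- names(y)
  s2k <- stats::setNames(as.numeric(fit$s2k), labels)
  out <- list(mu = fit$mu, ghat = ghat, s2k = s2k, s2e = fit$s2e,
              var_fraction = s2k / (sum(s2k) + fit$s2e),
              fitted = fit$mu + rowSums(ghat),
              masked = !obs, labels = labels,
              settings = list(chain_length = chain_length,
                              burn_in = burn_in, nu = nu,
                              h2_prior = h2_prior, fixed = fixed))
  class(out) <- "gblup"
  out
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("gblup fit: %d bulls (%d masked), kernels: %s\n",
              length(x$fitted), sum(x$masked),
              paste(x$labels, collapse = "+")))
  cat(sprintf("  mu = %.4f, s2e = %.4f, var fractions: %s\n", x$mu, x$s2e,
              paste(sprintf("%s=%.3f", x$labels, x$var_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$ghat

#' @export
predict.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, y, ...) {
  y - object$fitted
}

model_kernel_map <- function() {
  list(`1` = "BASE", `2` = "TOP25", `3` = c("TOP25", "BOT75"),
       `4` = "NET", `5` = c("NET", "FREE"), `6` = "CONN",
       `7` = c("CONN", "FREE"))
}

## wide dpta / weight matrices (bulls x traits) from a long record table
eval_wide <- function(records, traits) {
  bulls <- sort(unique(records$bull))
  dpta <- matrix(NA_real_, length(bulls), length(traits),
                 dimnames = list(bulls, traits))
  w <- dpta
  dpta[cbind(records$bull, records$trait)] <- records$dpta
  w[cbind(records$bull, records$trait)] <- records$w
  list(bulls = bulls, dpta = dpta, w = w)
}

## GWAS -> AWM -> network -> marker partitions for one training set.
## Only phenotypes of `bulls` enter any step; allele frequencies for
## centering come from the same bulls.
training_analysis <- function(genotypes, dpta, w, bulls, genes, qtl,
                              groups, gwas_control, percentile = 75,
                              trim_threshold = 0.98, need_awm = TRUE,
                              seed = 1L) {
  Z <- design_matrix(genotypes)[bulls, , drop = FALSE]
  p <- colMeans(Z) / 2
  traits <- colnames(dpta)
  gwas <- list(); pvg <- list(); abar <- list(); sig <- list()
  for (t in traits) {
    fit <- do.call(bayesb, c(list(y = dpta[bulls, t], Z = Z,
                                  weights = w[bulls, t], allele_freq = p,
                                  seed = seed + match(t, traits)),
                             gwas_control))
    gwas[[t]] <- fit
    pvg[[t]] <- fit$pvg
    abar[[t]] <- fit$abar
    sig[[t]] <- retain_top_fraction(fit$pvg, percentile)
  }
  parts <- partition_top25(pvg, min_traits = 3, percentile = percentile)
  out <- list(gwas = gwas, pvg = pvg, abar = abar, significant = sig,
              allele_freq = p, top25 = parts$top25, bot75 = parts$bot75)
  if (!need_awm) return(out)

  snp_gene <- map_snp_to_genes(genotypes$map, genes)
  selected <- select_relevant_snp(sig, groups)
  awm_obj <- NULL; network <- NULL; trimmed <- NULL
  if (nrow(selected) >= 3) {
    assignment <- tryCatch(
      resolve_one_snp_per_gene(selected, snp_gene, pvg, genotypes$map),
      error = function(e) NULL)
    if (!is.null(assignment) && nrow(assignment) >= 3) {
      awm_obj <- tryCatch(build_awm(assignment, abar),
                          error = function(e) NULL)
    }
  }
  if (!is.null(awm_obj)) {
    R <- row_correlations(awm_obj)
    network <- pcit(R)
    trimmed <- trim_network(network, trim_threshold)
  }
  out$snp_gene <- snp_gene
  out$selected <- selected
  out$awm <- awm_obj
  out$network <- network
  out$trimmed <- trimmed
  if (!is.null(awm_obj)) {
    np <- partition_network(awm_obj, genotypes$map$marker)
    out$net <- np$net
    out$free <- np$free
    out$D <- network_d_matrix(awm_obj, trimmed, np$net)
  }
  out
}

## D for CONN: unit diagonal, trimmed-network edge weights between the
## genes whose source markers make up the NET set
network_d_matrix <- function(awm, trimmed, net_markers) {
  rows <- awm$rows
  gene_of <- stats::setNames(rows$row_id, rows$marker)
  g <- gene_of[net_markers]
  k <- length(net_markers)
  D <- diag(1, k)
  dimnames(D) <- list(net_markers, net_markers)
  if (!is.null(trimmed) && nrow(trimmed$edges)) {
    idx <- stats::setNames(seq_len(k), g)
    e <- trimmed$edges[trimmed$edges$a %in% g & trimmed$edges$b %in% g, ,
                       drop = FALSE]
    if (nrow(e)) {
      ia <- idx[e$a]; ib <- idx[e$b]
      D[cbind(ia, ib)] <- e$weight
      D[cbind(ib, ia)] <- e$weight
    }
  }
  D
}

build_model_grms <- function(genotypes, bulls_all, analysis, models) {
  need <- unique(unlist(model_kernel_map()[as.character(models)]))
  Z <- design_matrix(genotypes)[bulls_all, , drop = FALSE]
  p <- analysis$allele_freq
  out <- list()
  out$BASE <- vanraden_g(Z, allele_freq = p, label = "BASE")
  for (lab in setdiff(need, "BASE")) {
    mk <- switch(lab, TOP25 = analysis$top25, BOT75 = analysis$bot75,
                 NET = analysis$net, FREE = analysis$free, CONN = analysis$net)
    if (is.null(mk) || !length(mk)) {
      out[lab] <- list(NULL)
      next
    }
    out[[lab]] <- if (lab == "CONN") {
      ## drop network markers monomorphic in the training bulls
      pn <- p[match(analysis$net, colnames(Z))]
      ok <- !is.na(pn) & pn > 0 & pn < 1
      tryCatch(conn_g(Z, analysis$net[ok],
                      analysis$D[ok, ok, drop = FALSE], out$BASE,
                      allele_freq = pn[ok]),
               error = function(e) NULL)
    } else {
      sel <- match(mk, colnames(Z))
      g <- tryCatch(vanraden_g(Z[, sel, drop = FALSE],
                               allele_freq = p[sel], label = lab),
                    error = function(e) NULL)
      g
    }
  }
  out
}

#' Cross-validated genomic prediction with network-enriched matrices
#'
#' 4-fold cross-validation over pedigree-clustered families. Within each
#' fold the whole discovery chain (per-trait Bayes-B GWAS, marker
#' partitions, AWM, PCIT network, relationship matrices) is rebuilt on
#' the training bulls only; validation dPTAs are masked during fitting
#' and prediction accuracy is the Pearson correlation between predicted
#' and masked dPTA.
#'
#' Models: 1 BASE; 2 TOP25; 3 TOP25+BOT75; 4 NET; 5 NET+FREE; 6 CONN;
#' 7 CONN+FREE.
#'
#' @param genotypes QC'd `genotype_matrix` covering the analysis bulls.
#' @param records Filtered de-regressed record table (`bull`, `trait`,
#'   `dpta`, `w`).
#' @param pedigree Pedigree covering the bulls (for the A-matrix folds).
#' @param genes,qtl Annotation interval tables.
#' @param models Model ids to fit (subset of 1:7).
#' @param k Number of folds (default 4).
#' @param seed Integer seed controlling folds and chains.
#' @param gwas_control List of arguments passed to [bayesb()] (chain
#'   settings etc.).
#' @param gblup_control List of arguments passed to [gblup()].
#' @param groups Trait grouping (default [trait_groups()]).
#' @param percentile Significance percentile for marker retention.
#' @param trim_threshold Network trimming threshold (default 0.98).
#' @return Object of class `cv_result`: `results` (trait x model x fold
#'   accuracies), `summary` (mean and SE over folds), `varcomp`, `folds`.
#' @export
run_cross_validation <- function(genotypes, records, pedigree, genes, qtl,
                                 models = 1:7, k = 4, seed = 1L,
                                 gwas_control = list(),
                                 gblup_control = list(),
                                 groups = trait_groups(),
                                 percentile = 75, trim_threshold = 0.98) {
  traits <- unique(records$trait)
  wide <- eval_wide(records, traits)
  bulls <- intersect(rownames(genotypes$codes), wide$bulls)
  if (length(bulls) < 4 * k) stop("too few bulls for cross-validation")
  dpta <- wide$dpta[bulls, , drop = FALSE]
  w <- wide$w[bulls, , drop = FALSE]

  A <- a_matrix(pedigree)
  folds <- kmeans_families(A$matrix[bulls, bulls], k = k, seed = seed)
  need_awm <- any(models >= 4)
  need_gwas <- any(models >= 2)

  kmap <- model_kernel_map()
  res <- list(); vc <- list()
  for (f in sort(unique(folds))) {
    val <- bulls[folds == f]
    train <- setdiff(bulls, val)
    analysis <- if (need_gwas) {
      training_analysis(genotypes, dpta, w, train, genes, qtl, groups,
                        gwas_control, percentile, trim_threshold,
                        need_awm = need_awm, seed = seed * 100L + f)
    } else {
      Zt <- design_matrix(genotypes)[train, , drop = FALSE]
      list(allele_freq = colMeans(Zt) / 2)
    }
    grms <- build_model_grms(genotypes, bulls, analysis, models)
    for (t in traits) {
      y <- dpta[, t]
      wt <- w[, t]
      wt[bulls %in% val] <- 0 # mask validation dPTAs
      for (mdl in models) {
        labs <- kmap[[as.character(mdl)]]
        ks <- grms[labs]
        if (any(vapply(ks, is.null, TRUE))) {
          res[[length(res) + 1L]] <-
            data.frame(trait = t, model = mdl, fold = f,
                       accuracy = NA_real_, stringsAsFactors = FALSE)
          next
        }
        fit <- do.call(gblup, c(list(y = y, kernels = ks, weights = wt,
                                     seed = seed * 1000L + f * 10L + mdl),
                                gblup_control))
        pred <- predict(fit)[bulls %in% val]
        obs <- y[bulls %in% val]
        acc <- if (length(obs) < 3 || stats::sd(pred) == 0 ||
                   stats::sd(obs) == 0) {
          warning("fold ", f, " trait ", t, ": correlation undefined")
          NA_real_
        } else stats::cor(pred, obs)
        res[[length(res) + 1L]] <-
          data.frame(trait = t, model = mdl, fold = f, accuracy = acc,
                     stringsAsFactors = FALSE)
        vc[[length(vc) + 1L]] <-
          data.frame(trait = t, model = mdl, fold = f,
                     kernel = fit$labels, s2 = unname(fit$s2k),
                     fraction = unname(fit$var_fraction),
                     s2e = fit$s2e, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, res)
  varcomp <- do.call(rbind, vc)
  agg <- stats::aggregate(accuracy ~ trait + model, data = results,
                          FUN = mean, na.rm = TRUE, na.action = NULL)
  se <- stats::aggregate(accuracy ~ trait + model, data = results,
                         FUN = function(x) stats::sd(x, na.rm = TRUE) /
                           sqrt(sum(!is.na(x))), na.action = NULL)
  names(agg)[3] <- "mean_accuracy"
  agg$se <- se$accuracy
  out <- list(results = results, summary = agg, varcomp = varcomp,
              folds = folds)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated prediction accuracy (mean over folds):\n")
  wide <- stats::reshape(x$summary[, c("trait", "model", "mean_accuracy")],
                         idvar = "trait", timevar = "model",
                         direction = "wide")
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
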