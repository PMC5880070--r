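#' Node intersection of breed-specific networks
#'
#' @param networks Named list of `gene_network` objects (>= 2).
#' @return List with `shared` (node ids present in every network),
#'   `set_sizes` (per network) and `observed_k`.
#' @export
intersect_networks <- function(networks) {
  stopifnot(length(networks) >= 2)
  sets <- lapply(networks, function(x) x$nodes)
  shared <- Reduce(intersect, sets)
  list(shared = shared, set_sizes = vapply(sets, length, integer(1)),
       observed_k = length(shared))
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Exact tail probability of a multi-set intersection
#'
#' Probability of observing an intersection of at least `observed_k`
#' elements when sets of the given sizes are drawn independently and
#' uniformly without replacement from a universe of `universe_n`
#' elements. Computed exactly: the running intersection size after adding
#' each set is a Markov chain whose transition kernel is hypergeometric
#' (a uniformly drawn size-`s` set overlaps a fixed size-`t` set in
#' `Hypergeometric(universe_n, t, s)` elements), so the distribution is a
#' chain of hypergeometric convolutions, evaluated in log space. For two
#' sets this reduces to the hypergeometric tail.
#'
#' @param set_sizes Integer vector of set sizes (>= 2 sets).
#' @param universe_n Universe size.
#' @param observed_k Observed intersection size.
#' @return The p-value `P(intersection >= observed_k)`.
#' @export
exact_intersection_pvalue <- function(set_sizes, universe_n, observed_k) {
  set_sizes <- as.integer(set_sizes)
  universe_n <- as.integer(universe_n)
  stopifnot(length(set_sizes) >= 2, all(set_sizes <= universe_n),
            observed_k >= 0)
  if (observed_k > min(set_sizes)) {
    warning("observed_k exceeds the smallest set: impossible, p = 0")
    return(0)
  }
  sizes <- sort(set_sizes, decreasing = TRUE)
  tmax <- sizes[2] # intersection can never exceed the 2nd largest onward
  logp <- rep(-Inf, universe_n + 1L)
  logp[sizes[1] + 1L] <- 0
  for (s in sizes[-1]) {
    supp <- which(logp > -Inf) - 1L
    new <- rep(-Inf, universe_n + 1L)
    acc <- vector("list", length(supp))
    for (ii in seq_along(supp)) {
      t <- supp[ii]
      k <- 0:min(t, s)
      lp <- stats::dhyper(k, t, universe_n - t, s, log = TRUE) + logp[t + 1L]
      acc[[ii]] <- cbind(k, lp)
    }
    accm <- do.call(rbind, acc)
    for (kk in unique(accm[, 1]))
      new[kk + 1L] <- log_sum_exp(accm[accm[, 1] == kk, 2])
    logp <- new
  }
  tail_log <- log_sum_exp(logp[(observed_k + 1L):(universe_n + 1L)])
  min(1, exp(tail_log))
}

#' Edges shared by every network of a subset
#'
#' Edges are compared as unordered node pairs; weights are ignored.
#'
#' @param networks Named list of `gene_network` objects.
#' @param subset Names (or indices) of the networks to intersect;
#'   default all.
#' @return Data frame `a`, `b` of shared edges.
#' @export
shared_edges <- function(networks, subset = NULL) {
  if (is.null(subset)) subset <- seq_along(networks)
  nets <- networks[subset]
  stopifnot(length(nets) >= 2)
  keys <- lapply(nets, function(x) paste(x$edges$a, x$edges$b, sep = "\r"))
  common <- Reduce(intersect, keys)
  if (!length(common))
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(common, "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Power-law fit and Kolmogorov-Smirnov test on a degree sequence
#'
#' Maximum-likelihood fit of a discrete power law to the tail of the
#' degree distribution (lower cutoff chosen by KS minimization), with the
#' KS distance and its p-value; large p means the power-law null is not
#' rejected.
#'
#' @param degrees Integer degree sequence (>= 10 positive degrees
#'   required).
#' @param seed Seed for the stochastic refinement of the KS p-value
#'   (fixed so that repeated calls agree).
#' @return List with `alpha`, `xmin`, `ks_stat`, `p_value`.
#' @export
powerlaw_ks_test <- function(degrees, seed = 1L) {
  degrees <- degrees[degrees >= 1]
  if (length(degrees) < 10)
    stop("need at least 10 nodes with degree >= 1")
  if (length(unique(degrees)) == 1)
    stop("degenerate degree sequence: all degrees equal")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  fit <- igraph::fit_power_law(degrees, implementation = "plfit",
                               p.value = TRUE)
  list(alpha = fit$alpha, xmin = fit$xmin, ks_stat = fit$KS.stat,
       p_value = fit$KS.p)
}

#' Most-connected genes located within QTL
#'
#' Ranks nodes by degree, keeps the top fraction (ties at the threshold
#' included) and reports those carrying a QTL assignment.
#'
#' @param network A `gene_network`.
#' @param gene_qtl Data frame `gene`, `qtl` from [genes_in_qtl()].
#' @param top_fraction Fraction of nodes considered hubs (default 0.05).
#' @return Data frame `gene`, `degree`, `qtl` (comma-separated ids),
#'   ordered by decreasing degree.
#' @export
hub_report <- function(network, gene_qtl, top_fraction = 0.05) {
  deg <- network_degrees(network)
  if (!length(deg))
    return(data.frame(gene = character(), degree = integer(),
                      qtl = character(), stringsAsFactors = FALSE))
  k <- max(1L, ceiling(top_fraction * length(deg)))
  thr <- sort(deg, decreasing = TRUE)[k]
  hubs <- names(deg)[deg >= thr]
  sel <- gene_qtl[gene_qtl$gene %in% hubs, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(gene = character(), degree = integer(),
                      qtl = character(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(qtl ~ gene, data = sel,
                          FUN = function(x) paste(sort(x), collapse = ","))
  agg$degree <- deg[agg$gene]
  agg <- agg[order(-agg$degree, agg$gene), c("gene", "degree", "qtl")]
  rownames(agg) <- NULL
  agg
}
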