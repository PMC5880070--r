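#' Row-wise correlations of an AWM
#'
#' Pearson correlation between every pair of AWM rows (each row is the
#' standardized effect profile of a gene across the trait columns).
#'
#' @param awm An `awm` object or a numeric matrix (rows x traits).
#' @return Correlation matrix with unit diagonal.
#' @export
row_correlations <- function(awm) {
  M <- if (inherits(awm, "awm")) awm$matrix else as.matrix(awm)
  if (nrow(M) < 2) stop("need at least 2 rows")
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0))
    stop("constant AWM row(s): ",
         paste(rownames(M)[sds == 0], collapse = ", "))
  R <- stats::cor(t(M))
  diag(R) <- 1
  R
}

#' First-order partial correlation
#'
#' `r_xy|z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param r_xy,r_xz,r_yz Pairwise correlations, all in `[-1, 1]`.
#' @return Partial correlation of x and y given z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  if (any(den <= 0)) stop("partial correlation undefined: |r| = 1")
  (r_xy - r_xz * r_yz) / sqrt(den)
}

#' PCIT network inference
#'
#' For every trio (x, y, z) the three first-order partial correlations
#' and the local tolerance (the mean of the partial/direct correlation
#' ratios) are computed; the edge x-y is eliminated when, for some z,
#' its correlation is at or below the tolerance-scaled strength of both
#' legs through z. Surviving pairs form an undirected network weighted by
#' their direct correlation.
#'
#' @param R Correlation matrix (rows of the AWM).
#' @param compare `"direct"` (default): the elimination test compares
#'   direct correlations; `"partial"`: it compares the partial
#'   correlations instead.
#' @return Object of class `gene_network`: list with `nodes` and `edges`
#'   (`a`, `b`, `weight`, with `a < b`).
#' @export
pcit <- function(R, compare = c("direct", "partial")) {
  compare <- match.arg(compare)
  R <- as.matrix(R)
  n <- nrow(R)
  if (is.null(rownames(R))) rownames(R) <- colnames(R) <- paste0("n", 1:n)
  if (n < 3) {
    warning("fewer than 3 nodes: no trios, all nonzero edges retained")
    keep <- abs(R) > 0 & upper.tri(R)
  } else {
    km <- .pcit_keep(R, if (compare == "direct") 0L else 1L)
    keep <- km & upper.tri(km)
  }
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(a = rownames(R)[idx[, 1]], b = rownames(R)[idx[, 2]],
                      weight = R[idx], stringsAsFactors = FALSE)
  gene_network(rownames(R), edges)
}

#' Construct a gene network object
#'
#' @param nodes Character vector of node ids.
#' @param edges Data frame `a`, `b`, `weight`; self-edges forbidden.
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(nodes, edges) {
  stopifnot(all(edges$a %in% nodes), all(edges$b %in% nodes),
            !any(edges$a == edges$b),
            all(abs(edges$weight) <= 1), all(edges$weight != 0))
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "gene_network"
  out
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Trim a network to high-correlation edges
#'
#' Keeps edges with `|weight| >= threshold` (or signed
#' `weight >= threshold` when `signed = TRUE`). Nodes left without edges
#' are dropped from the node set.
#'
#' @param network A `gene_network`.
#' @param threshold Correlation threshold, default 0.98.
#' @param signed Use the signed weight instead of its magnitude.
#' @param keep_isolated Keep nodes that lose all their edges.
#' @return A trimmed `gene_network`.
#' @export
trim_network <- function(network, threshold = 0.98, signed = FALSE,
                         keep_isolated = FALSE) {
  w <- if (signed) network$edges$weight else abs(network$edges$weight)
  edges <- network$edges[w >= threshold, , drop = FALSE]
  nodes <- if (keep_isolated) network$nodes
           else sort(unique(c(edges$a, edges$b)))
  gene_network(nodes, edges)
}

#' Node degrees of a gene network
#'
#' @param network A `gene_network`.
#' @return Named integer vector of degrees over `network$nodes`.
#' @export
network_degrees <- function(network) {
  d <- table(factor(c(network$edges$a, network$edges$b),
                    levels = network$nodes))
  stats::setNames(as.integer(d), names(d))
}

#' Write a network edge list as TSV
#'
#' @param network A `gene_network`.
#' @param path Output path.
#' @export
write_network <- function(network, path) write_tsv(network$edges, path)

#' Export a gene network as GraphML for external viewers
#'
#' @param network A `gene_network`.
#' @param path Output path (.graphml).
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
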