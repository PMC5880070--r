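#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 * sum_j p_j (1 - p_j))` with `M = code - 2p` per marker.
#' Monomorphic markers are excluded with a warning.
#'
#' @param genotypes A `genotype_matrix` or numeric code matrix (bulls x
#'   markers).
#' @param markers Optional marker ids to restrict to.
#' @param allele_freq Frequencies used for centering; defaults to the
#'   frequencies of the supplied bulls.
#' @param label Construction label stored on the result.
#' @return Object of class `grm`: list with `matrix`, `label`, `markers`.
#' @export
vanraden_g <- function(genotypes, markers = NULL, allele_freq = NULL,
                       label = "BASE") {
  Z <- if (inherits(genotypes, "genotype_matrix")) design_matrix(genotypes)
       else as.matrix(genotypes)
  if (!is.null(markers)) {
    sel <- match(markers, colnames(Z))
    if (anyNA(sel)) stop("unknown marker id(s) in `markers`")
    Z <- Z[, sel, drop = FALSE]
    if (!is.null(allele_freq)) allele_freq <- allele_freq[sel]
  }
  p <- if (is.null(allele_freq)) colMeans(Z) / 2 else allele_freq
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded")
    Z <- Z[, poly, drop = FALSE]
    p <- p[poly]
  }
  M <- sweep(Z, 2, 2 * p)
  G <- tcrossprod(M) / (2 * sum(p * (1 - p)))
  grm(G, label, colnames(Z))
}

grm <- function(G, label, markers = NULL) {
  stopifnot(isTRUE(all.equal(G, t(G), tolerance = 1e-10)))
  out <- list(matrix = G, label = label, markers = markers)
  class(out) <- "grm"
  out
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm [%s]: %d bulls, %s markers; mean diag %.3f\n",
              x$label, nrow(x$matrix),
              if (is.null(x$markers)) "?" else length(x$markers),
              mean(diag(x$matrix))))
  invisible(x)
}

#' Partition markers into TOP25 and BOT75 sets
#'
#' TOP25 holds the markers ranking in the top quartile for PV_g in at
#' least `min_traits` of the traits; BOT75 is the complement of the
#' panel.
#'
#' @param pvg_by_trait Named list of per-trait PV_g vectors (named by
#'   marker) on a common panel.
#' @param min_traits Minimum number of traits (default 3).
#' @param percentile Quantile defining the top set (default 75).
#' @return List with `top25` and `bot75` marker id vectors.
#' @export
partition_top25 <- function(pvg_by_trait, min_traits = 3, percentile = 75) {
  panel <- names(pvg_by_trait[[1]])
  sets <- retain_top_fraction(pvg_by_trait, percentile)
  cnt <- table(factor(unlist(sets), levels = panel))
  top <- panel[cnt >= min_traits]
  list(top25 = top, bot75 = setdiff(panel, top))
}

#' Partition markers into NET and FREE sets
#'
#' NET holds the source markers of the AWM rows; FREE is the remainder of
#' the panel.
#'
#' @param awm An `awm` object.
#' @param panel Character vector of all panel marker ids.
#' @return List with `net` and `free` marker id vectors.
#' @export
partition_network <- function(awm, panel) {
  if (!inherits(awm, "awm") || nrow(awm$rows) == 0) stop("empty AWM")
  net <- intersect(panel, unique(awm$rows$marker))
  if (!length(net)) stop("no AWM source markers found on the panel")
  list(net = net, free = setdiff(panel, net))
}

## nearest PSD projection of a correlation-like matrix:
## eigenvalue clipping at zero, diagonal restored to 1
psd_repair <- function(D) {
  eg <- eigen((D + t(D)) / 2, symmetric = TRUE)
  if (min(eg$values) >= -1e-10) return(list(D = D, dist = 0))
  vals <- pmax(eg$values, 0)
  Dp <- eg$vectors %*% (vals * t(eg$vectors))
  diag(Dp) <- 1
  list(D = (Dp + t(Dp)) / 2, dist = norm(D - Dp, "F"))
}

#' Network-connectivity relationship matrix (CONN)
#'
#' `G = Z D Z'` with `Z` the centered-and-scaled genotypes of the network
#' markers and `D` the gene-gene correlation structure (unit diagonal,
#' network correlations off-diagonal). An indefinite `D` is replaced by
#' its nearest PSD projection (eigenvalue clipping, diagonal restored).
#' The result is rescaled with the allele-frequency-free method: an
#' affine adjustment matching its mean diagonal and mean off-diagonal to
#' the reference matrix.
#'
#' @param genotypes A `genotype_matrix` or code matrix.
#' @param markers Network marker ids (columns of `D`, in order).
#' @param D Square matrix, unit diagonal, entries in `[-1, 1]`.
#' @param reference A `grm` (typically BASE) giving the target scale.
#' @param allele_freq Frequencies for centering/scaling, aligned with
#'   `markers`; defaults to the supplied bulls'.
#' @return Object of class `grm` with label `CONN`; carries `raw` (the
#'   unscaled `ZDZ'`) and `psd_distance` attributes.
#' @export
conn_g <- function(genotypes, markers, D, reference, allele_freq = NULL) {
  Z <- if (inherits(genotypes, "genotype_matrix")) design_matrix(genotypes)
       else as.matrix(genotypes)
  sel <- match(markers, colnames(Z))
  if (anyNA(sel)) stop("unknown marker id(s)")
  Z <- Z[, sel, drop = FALSE]
  p <- if (is.null(allele_freq)) colMeans(Z) / 2 else allele_freq
  if (length(p) != length(markers))
    stop("allele_freq must align with `markers`")
  if (anyNA(p) || any(p <= 0 | p >= 1)) stop("monomorphic network marker")
  D <- as.matrix(D)
  if (nrow(D) != length(markers) || ncol(D) != length(markers))
    stop("dimension mismatch between Z and D")
  if (any(abs(diag(D) - 1) > 1e-8)) stop("D must have unit diagonal")
  Zs <- sweep(sweep(Z, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  rep_ <- psd_repair(D)
  raw <- Zs %*% rep_$D %*% t(Zs)
  raw <- (raw + t(raw)) / 2
  ref <- reference$matrix
  md_ref <- mean(diag(ref))
  mo_ref <- (sum(ref) - sum(diag(ref))) / (length(ref) - nrow(ref))
  md_raw <- mean(diag(raw))
  mo_raw <- (sum(raw) - sum(diag(raw))) / (length(raw) - nrow(raw))
  b <- (md_ref - mo_ref) / (md_raw - mo_raw)
  a <- md_ref - b * md_raw
  G <- a + b * raw
  out <- grm(G, "CONN", markers)
  out$raw <- raw
  out$psd_distance <- rep_$dist
  out$scaling <- c(a = a, b = b)
  out
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' @param pedigree Data frame `animal`, `sire`, `dam` (NA for unknown
#'   parents), parents before offspring; reordered automatically when
#'   possible.
#' @return Object of class `grm` with label `A`.
#' @export
a_matrix <- function(pedigree) {
  ped <- pedigree
  ids <- ped$animal
  if (anyDuplicated(ids)) stop("duplicated animal ids")
  ## topological order: parents before offspring
  ord <- integer(0)
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining)) {
    ok <- (is.na(remaining$sire) | remaining$sire %in% placed) &
      (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ok))
      stop("pedigree cycle detected involving: ",
           paste(utils::head(remaining$animal, 5), collapse = ", "))
    placed <- c(placed, remaining$animal[ok])
    remaining <- remaining[!ok, , drop = FALSE]
  }
  ped <- ped[match(placed, ped$animal), ]
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    as_ <- if (!is.na(si[i])) A[prev, si[i]] else numeric(i - 1L)
    ad_ <- if (!is.na(di[i])) A[prev, di[i]] else numeric(i - 1L)
    if (i > 1) {
      A[prev, i] <- 0.5 * (as_ + ad_)
      A[i, prev] <- A[prev, i]
    }
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i]))
      0.5 * A[si[i], di[i]] else 0
  }
  ## restore input order
  A <- A[ids, ids]
  grm(A, "A")
}
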