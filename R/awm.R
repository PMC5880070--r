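#' Select relevant SNPs by the three significance criteria
#'
#' A marker is relevant when it is significant (a) in all traits, (b) in
#' all functional traits (DCD, MCD, GL), or (c) in all type traits (STAT,
#' STR, RW); each marker is labelled with every criterion it meets.
#'
#' @param significant_sets Named list (one element per trait) of
#'   significant marker id vectors.
#' @param groups Trait grouping as from [trait_groups()].
#' @return Data frame `marker`, `crit_a`, `crit_b`, `crit_c` (logicals);
#'   one row per relevant marker.
#' @export
select_relevant_snp <- function(significant_sets, groups = trait_groups()) {
  traits <- names(significant_sets)
  stopifnot(all(unlist(groups) %in% traits))
  inter <- function(tr) Reduce(intersect, significant_sets[tr])
  a <- inter(traits)
  b <- inter(groups$functional)
  c_ <- inter(groups$type)
  mk <- union(a, union(b, c_))
  data.frame(marker = mk,
             crit_a = mk %in% a,
             crit_b = mk %in% b,
             crit_c = mk %in% c_,
             stringsAsFactors = FALSE)
}

#' Enforce the one-SNP-one-gene rule
#'
#' Each gene mapped by one or more relevant SNPs receives the SNP with
#' the largest PV_g averaged across traits (ties broken by genomic
#' order). Relevant SNPs not mapped to any gene are kept as their own
#' rows only when they meet criterion (a).
#'
#' @param selected Output of [select_relevant_snp()].
#' @param snp_gene_map Output of [map_snp_to_genes()].
#' @param pvg_by_trait Named list of per-trait PV_g vectors over the
#'   marker panel.
#' @param map Marker map (`marker`, `chrom`, `bp`) for tie-breaking.
#' @return Data frame `row_id` (gene id or marker id), `marker`,
#'   `mapped` (logical), plus the criterion labels.
#' @export
resolve_one_snp_per_gene <- function(selected, snp_gene_map, pvg_by_trait,
                                     map) {
  mean_pvg <- rowMeans(do.call(cbind, lapply(pvg_by_trait,
                                             function(v) v[selected$marker])))
  names(mean_pvg) <- selected$marker
  hits <- snp_gene_map[snp_gene_map$marker %in% selected$marker, ,
                       drop = FALSE]
  rows <- list()
  if (nrow(hits)) {
    hits$mean_pvg <- mean_pvg[hits$marker]
    ord <- match(hits$marker, map$marker)
    hits$chrom <- map$chrom[ord]
    hits$bp <- map$bp[ord]
    ## per gene: max mean PV_g, then lower (chrom, bp)
    hits <- hits[order(hits$gene, -hits$mean_pvg, hits$chrom, hits$bp), ]
    best <- hits[!duplicated(hits$gene), , drop = FALSE]
    rows$mapped <- data.frame(row_id = best$gene, marker = best$marker,
                              mapped = TRUE, stringsAsFactors = FALSE)
  }
  unmapped <- setdiff(selected$marker, snp_gene_map$marker)
  keep_unmapped <- unmapped[selected$crit_a[match(unmapped,
                                                  selected$marker)]]
  if (length(keep_unmapped))
    rows$unmapped <- data.frame(row_id = keep_unmapped,
                                marker = keep_unmapped, mapped = FALSE,
                                stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no AWM rows: no relevant SNP mapped to a gene or met criterion a")
  out <- merge(out, selected, by = "marker", sort = FALSE)
  out$mean_pvg <- mean_pvg[out$marker]
  rownames(out) <- NULL
  out[, c("row_id", "marker", "mapped", "crit_a", "crit_b", "crit_c",
          "mean_pvg")]
}

#' Build the association weight matrix
#'
#' Rows are genes (plus unmapped criterion-a SNPs), columns are traits;
#' each cell is the z-score-normalized posterior mean effect of the row's
#' source SNP for that trait, standardized over AWM rows with the
#' population (n-denominator) standard deviation. Effect signs are
#' preserved.
#'
#' @param assignment Output of [resolve_one_snp_per_gene()].
#' @param abar_by_trait Named list of per-trait posterior mean effect
#'   vectors (named by marker).
#' @return Object of class `awm`: list with `matrix` (rows x traits),
#'   `rows` (the assignment table).
#' @export
build_awm <- function(assignment, abar_by_trait) {
  if (nrow(assignment) < 3)
    stop("AWM needs at least 3 rows")
  traits <- names(abar_by_trait)
  M <- sapply(abar_by_trait, function(v) unname(v[assignment$marker]))
  dimnames(M) <- list(assignment$row_id, traits)
  for (t in traits) {
    s <- stats::sd(M[, t]) * sqrt((nrow(M) - 1) / nrow(M))
    if (!is.finite(s) || s == 0)
      stop("AWM column has zero variance for trait ", t)
    M[, t] <- (M[, t] - mean(M[, t])) / s
  }
  out <- list(matrix = M, rows = assignment)
  class(out) <- "awm"
  out
}

#' @export
print.awm <- function(x, ...) {
  cat(sprintf("awm: %d rows (%d genes, %d unmapped SNP) x %d traits\n",
              nrow(x$matrix), sum(x$rows$mapped), sum(!x$rows$mapped),
              ncol(x$matrix)))
  invisible(x)
}
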