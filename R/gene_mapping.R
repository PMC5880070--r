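#' Map SNPs to nearby genes
#'
#' A marker maps to every gene whose 1-based inclusive interval, extended
#' by `max_dist` bp on both sides, contains the marker position; all such
#' genes are retained (no strand logic). Markers on chromosomes absent
#' from the annotation are unmapped.
#'
#' @param map Marker map (`marker`, `chrom`, `bp`).
#' @param genes Gene annotation (`chrom`, `start`, `end`, `id`).
#' @param max_dist Maximum distance to the gene boundary (default 2500).
#' @param nearest_only Keep only the single closest gene per marker
#'   (ties broken by gene order); default FALSE.
#' @return Data frame `marker`, `gene`, `distance` (0 inside the gene).
#' @export
map_snp_to_genes <- function(map, genes, max_dist = 2500,
                             nearest_only = FALSE) {
  out <- vector("list", length(unique(map$chrom)))
  i <- 0L
  for (chr in unique(map$chrom)) {
    mk <- map[map$chrom == chr, , drop = FALSE]
    gn <- genes[genes$chrom == chr, , drop = FALSE]
    i <- i + 1L
    if (!nrow(gn)) next
    gn <- gn[order(gn$start), , drop = FALSE]
    ## interval search: for each marker find genes with
    ## start - max_dist <= bp <= end + max_dist
    hits <- lapply(seq_len(nrow(mk)), function(r) {
      bp <- mk$bp[r]
      sel <- which(gn$start - max_dist <= bp & bp <= gn$end + max_dist)
      if (!length(sel)) return(NULL)
      d <- pmax(0, pmax(gn$start[sel] - bp, bp - gn$end[sel]))
      data.frame(marker = mk$marker[r], gene = gn$id[sel], distance = d,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(marker = character(), gene = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nearest_only && nrow(res)) {
    res <- res[order(res$marker, res$distance), ]
    res <- res[!duplicated(res$marker), ]
  }
  rownames(res) <- NULL
  res
}

#' Assign genes to QTL intervals by containment
#'
#' A gene is assigned to a QTL when the gene interval is wholly contained
#' in the QTL interval (`overlap = "within"`, the default) or when the two
#' intervals overlap at all (`overlap = "any"`). All qualifying QTL are
#' reported.
#'
#' @param genes Gene annotation (`chrom`, `start`, `end`, `id`).
#' @param qtl QTL interval table (`chrom`, `start`, `end`, `id`).
#' @param overlap `"within"` or `"any"`.
#' @return Data frame `gene`, `qtl`.
#' @export
genes_in_qtl <- function(genes, qtl, overlap = c("within", "any")) {
  overlap <- match.arg(overlap)
  if (!nrow(qtl) || !nrow(genes))
    return(data.frame(gene = character(), qtl = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (chr in unique(genes$chrom)) {
    gn <- genes[genes$chrom == chr, , drop = FALSE]
    qt <- qtl[qtl$chrom == chr, , drop = FALSE]
    if (!nrow(qt)) next
    for (r in seq_len(nrow(gn))) {
      sel <- if (overlap == "within")
        which(qt$start <= gn$start[r] & gn$end[r] <= qt$end)
      else
        which(qt$start <= gn$end[r] & gn$start[r] <= qt$end)
      if (length(sel))
        out[[length(out) + 1L]] <- data.frame(gene = gn$id[r],
                                              qtl = qt$id[sel],
                                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), qtl = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
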