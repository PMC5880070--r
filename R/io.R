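#' File dialects
#'
#' All tables are plain tab-separated text with a header line. Genotypes
#' use a PLINK-RAW-like layout (`FID IID` then one column per marker with
#' \{0, 1, 2\} minor-allele counts, `NA` for missing) plus a `.map`-like
#' table (`marker chrom bp`). Interval tables (genes, QTL) are BED-like
#' but 1-based inclusive (`chrom start end id`). Evaluations are long
#' (`bull trait pta rel sire_pta mgs_pta ayb_pta rel_pa`). Pedigrees are
#' `animal sire dam mgs birth_year`.
#'
#' @name dystnet-io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write/read genotypes in the PLINK-RAW-like dialect
#'
#' @param genotypes A `genotype_matrix`.
#' @param raw_path,map_path Paths for the genotype table and marker map.
#' @return `write_genotypes` returns the paths invisibly; `read_genotypes`
#'   returns a `genotype_matrix`.
#' @export
write_genotypes <- function(genotypes, raw_path, map_path) {
  df <- data.frame(FID = "F0", IID = rownames(genotypes$codes),
                   genotypes$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, raw_path)
  write_tsv(genotypes$map, map_path)
  invisible(c(raw_path, map_path))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(raw_path, map_path) {
  raw <- read_tsv(raw_path)
  map <- read_tsv(map_path)
  codes <- as.matrix(raw[, -(1:2), drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- raw$IID
  colnames(codes) <- map$marker
  genotype_matrix(codes, map)
}

#' Write/read interval tables (genes or QTL), 1-based inclusive
#'
#' @param intervals Data frame `chrom start end id`.
#' @param path File path.
#' @export
write_intervals <- function(intervals, path) {
  write_tsv(intervals[, c("chrom", "start", "end", "id")], path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) read_tsv(path)

#' Write/read evaluation tables
#'
#' @param evaluations Long evaluation data frame.
#' @param path File path.
#' @export
write_evaluations <- function(evaluations, path) write_tsv(evaluations, path)

#' @rdname write_evaluations
#' @export
read_evaluations <- function(path) read_tsv(path)

#' Write/read pedigrees
#'
#' @param pedigree Pedigree data frame.
#' @param path File path.
#' @export
write_pedigree <- function(pedigree, path) write_tsv(pedigree, path)

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv(path)
  for (col in intersect(c("animal", "sire", "dam", "mgs"), names(ped)))
    ped[[col]] <- as.character(ped[[col]])
  ped
}
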