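#' Estimate the parent average from available ancestor PTAs
#'
#' When the parent average (PA) of a bull is not stored, it is
#' reconstructed from the sire PTA, the maternal-grandsire (MGS) PTA and
#' the birth-cohort mean PTA (AYB) using one of three fallback
#' combinations, in order of preference:
#' `0.5*sire + 0.25*mgs + 0.25*ayb`, `0.5*sire + 0.5*ayb`, or
#' `0.25*mgs + 0.75*ayb`.
#'
#' All arguments are vectorized; `NA` marks an absent value.
#'
#' @param sire_pta,mgs_pta,ayb_pta Ancestor PTAs (trait units) or `NA`.
#' @param id Optional record labels used in error messages.
#' @return Numeric vector of estimated parent averages.
#' @export
estimate_parent_average <- function(sire_pta = NA, mgs_pta = NA,
                                    ayb_pta = NA, id = NULL) {
  n <- max(length(sire_pta), length(mgs_pta), length(ayb_pta))
  s <- rep_len(as.numeric(sire_pta), n)
  m <- rep_len(as.numeric(mgs_pta), n)
  a <- rep_len(as.numeric(ayb_pta), n)
  pa <- rep(NA_real_, n)
  full <- !is.na(s) & !is.na(m) & !is.na(a)
  pa[full] <- 0.5 * s[full] + 0.25 * m[full] + 0.25 * a[full]
  sa <- !full & !is.na(s) & !is.na(a)
  pa[sa] <- 0.5 * s[sa] + 0.5 * a[sa]
  ma <- !full & !sa & !is.na(m) & !is.na(a)
  pa[ma] <- 0.25 * m[ma] + 0.75 * a[ma]
  if (anyNA(pa)) {
    bad <- which(is.na(pa))
    lab <- if (is.null(id)) paste(bad, collapse = ", ")
           else paste(rep_len(id, n)[bad], collapse = ", ")
    stop("no parent-average fallback satisfiable for record(s): ", lab)
  }
  pa
}

## Information-content algebra for one record: recover the effective
## record counts (Z'Z) of the parent-average and own-information sources
## from the PTA and PA reliabilities, through the 2x2 mixed-model
## equations for [PA, animal] with A = [[0.5, 0.5], [0.5, 1]].
## Conventions (verified by round-trip): r2_own = 1 - lambda*Cinv[2,2],
## r2_pa = 0.5 - lambda*Cinv[1,1], with lambda = (1 - h2)/h2.
dereg_info <- function(rel, rel_pa, h2) {
  lambda <- (1 - h2) / h2
  alpha <- 1 / (0.5 - rel_pa)
  delta <- (0.5 - rel_pa) / (1 - rel)
  zz_pa <- lambda * (0.5 * alpha - 4) + 0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  zz_i <- delta * zz_pa + 2 * lambda * (2 * delta - 1)
  list(lambda = lambda, zz_pa = zz_pa, zz_i = zz_i)
}

#' De-regress PTAs into independent pseudo-phenotypes
#'
#' Removes the parent-average contribution and the shrinkage from each
#' PTA, yielding a de-regressed PTA (dPTA), its reliability, and an
#' association weight `w = (1 - h2) / ((c + (1 - r2_d)/r2_d) * h2)` where
#' `r2_d` is the dPTA reliability and `c` is the fraction of genetic
#' variance assumed not captured by the markers (default 0.5).
#'
#' The de-regression separates the parent-average information from the
#' bull's own information through the 2x2 mixed-model equations of the
#' PA/animal pair; records whose own information content is non-positive
#' (reliability at or below what the parent average alone implies) are
#' flagged `excluded` with a reason instead of producing a dPTA.
#'
#' @param records Data frame with columns `bull`, `trait`, `pta`, `rel`
#'   and either `pa` or the ancestor columns (`sire_pta`, `mgs_pta`,
#'   `ayb_pta`); optional `rel_pa`.
#' @param h2 Named per-trait heritability used in the information algebra
#'   and weights (proxy values; defaults 0.1 for calving traits, 0.5 for
#'   GL, 0.4 for type traits).
#' @param c Weight parameter, default 0.5.
#' @param default_rel_pa Reliability assumed for the parent average when
#'   `rel_pa` is absent (default 0.25; PA reliability is bounded by 0.5).
#' @return The input with added columns `pa`, `rel_pa`, `dpta`, `w`,
#'   `rel_dpta`, `excluded` (logical) and `exclude_reason`.
#' @export
deregress <- function(records, h2 = c(DCD = 0.1, MCD = 0.1, GL = 0.5,
                                      STAT = 0.4, STR = 0.4, RW = 0.4),
                      c = 0.5, default_rel_pa = 0.25) {
  stopifnot(all(c("bull", "trait", "pta", "rel") %in% names(records)))
  out <- records
  if (is.null(out$pa) || anyNA(out$pa)) {
    need <- if (is.null(out$pa)) rep(TRUE, nrow(out)) else is.na(out$pa)
    if (is.null(out$pa)) out$pa <- NA_real_
    out$pa[need] <- estimate_parent_average(
      out$sire_pta[need], out$mgs_pta[need], out$ayb_pta[need],
      id = paste(out$bull[need], out$trait[need]))
  }
  if (is.null(out$rel_pa)) out$rel_pa <- default_rel_pa
  out$rel_pa[is.na(out$rel_pa)] <- default_rel_pa
  out$rel_pa <- pmin(pmax(out$rel_pa, 1e-6), 0.5 - 1e-6)

  h2t <- h2[out$trait]
  if (anyNA(h2t)) stop("h2 must be named for every trait present")
  rel <- pmin(pmax(out$rel, 1e-6), 1 - 1e-6)
  info <- dereg_info(rel, out$rel_pa, h2t)

  excluded <- info$zz_i <= 0 | out$rel <= out$rel_pa
  reason <- ifelse(excluded, "no own information beyond parent average", "")

  ## right-hand sides of the 2x2 MME evaluated at the blended solutions
  lam <- info$lambda
  y2 <- -2 * lam * out$pa + (info$zz_i + 2 * lam) * out$pta
  dpta <- ifelse(excluded, NA_real_, y2 / info$zz_i)
  rel_d <- ifelse(excluded, NA_real_, info$zz_i / (info$zz_i + lam))
  w <- ifelse(excluded, NA_real_,
              (1 - h2t) / ((c + (1 - rel_d) / rel_d) * h2t))

  out$dpta <- dpta
  out$w <- unname(w)
  out$rel_dpta <- unname(rel_d)
  out$excluded <- excluded
  out$exclude_reason <- reason
  if (any(excluded))
    message(sum(excluded), " record(s) excluded: no own information")
  out
}

#' Filter de-regressed records on reliability and trait completeness
#'
#' Keeps records whose dPTA reliability strictly exceeds `min_rel`
#' (boundary behaviour configurable), then drops every record of any bull
#' that is missing one or more of the configured traits, to avoid an
#' animal-trait confounding effect.
#'
#' @param records Output of [deregress()].
#' @param min_rel Reliability threshold (default 0.2).
#' @param require_all_traits Drop bulls without all traits (default TRUE).
#' @param traits Trait set defining completeness (default: traits present).
#' @param strict Use strict inequality at the threshold (default TRUE).
#' @return Filtered data frame.
#' @export
filter_records <- function(records, min_rel = 0.2,
                           require_all_traits = TRUE, traits = NULL,
                           strict = TRUE) {
  stopifnot("rel_dpta" %in% names(records))
  keep <- !is.na(records$rel_dpta) &
    (if (strict) records$rel_dpta > min_rel else records$rel_dpta >= min_rel)
  if (!is.null(records$excluded)) keep <- keep & !records$excluded
  out <- records[keep, , drop = FALSE]
  if (require_all_traits) {
    if (is.null(traits)) traits <- unique(records$trait)
    cnt <- tapply(out$trait, out$bull,
                  function(x) all(traits %in% x))
    ok_bulls <- names(cnt)[cnt]
    out <- out[out$bull %in% ok_bulls, , drop = FALSE]
  }
  if (nrow(out) == 0)
    stop("no records survive filtering; review the reliability threshold")
  rownames(out) <- NULL
  out
}
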