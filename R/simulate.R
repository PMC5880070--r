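#' Trait names and groups used throughout the package
#'
#' Six dystocia-related traits: the functional group holds direct calving
#' difficulty (DCD), maternal calving difficulty (MCD) and gestation length
#' (GL); the type group holds stature (STAT), strength (STR) and rump width
#' (RW).
#'
#' @return Named list with elements `functional` and `type`.
#' @export
trait_groups <- function() {
  list(functional = c("DCD", "MCD", "GL"),
       type       = c("STAT", "STR", "RW"))
}

default_traits <- function() unlist(trait_groups(), use.names = FALSE)

#' Simulation configuration for a synthetic bull population
#'
#' Defines one breed's half-sib population: unrelated founder sires, each
#' with a set of progeny-tested sons, biallelic markers gene-dropped through
#' the pedigree, sparse pleiotropic QTL effects for six genetically
#' correlated traits, and PTAs whose squared correlation with half the true
#' breeding value equals a per-bull reliability.
#'
#' @param n_sires Number of founder sires.
#' @param progeny_per_sire Progeny-tested sons per sire.
#' @param n_markers Number of biallelic markers.
#' @param n_genes Number of annotated genes to place on the genome.
#' @param genome Data frame with columns `chrom` and `length` (bp).
#' @param maf_range Founder minor-allele-frequency range, within (0, 0.5].
#' @param pi_qtl Fraction of markers with zero effect (the Bayes-B prior
#'   null fraction analogue); default 0.9.
#' @param traits Trait names (default the six dystocia traits).
#' @param genetic_correlations Trait genetic correlation matrix (symmetric
#'   positive definite, unit diagonal).
#' @param heritabilities Named per-trait heritabilities in (0, 1).
#' @param reliability_range Per-bull PTA reliability range, within (0, 1].
#' @param frac_near_gene Target fraction of markers lying within
#'   `2500` bp of a gene (exact at 0 and 1, approximate otherwise).
#' @param qtl_cover_frac Fraction of each chromosome covered by QTL
#'   intervals.
#' @param missing_rate Pre-QC genotype missingness rate.
#' @param ld_blocks Optional founder haplotype-block size (markers) to
#'   induce block LD among founders; `NULL` (default) for linkage
#'   equilibrium founders.
#' @param birth_years Number of progeny birth cohorts.
#' @param seed Integer seed; same seed gives bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 20,
                       progeny_per_sire = 20,
                       n_markers = 2000,
                       n_genes = 300,
                       genome = data.frame(chrom = paste0("chr", 1:5),
                                           length = rep(10e6, 5)),
                       maf_range = c(0.05, 0.5),
                       pi_qtl = 0.9,
                       traits = default_traits(),
                       genetic_correlations = default_genetic_correlations(),
                       heritabilities = c(DCD = 0.10, MCD = 0.08, GL = 0.50,
                                          STAT = 0.45, STR = 0.40, RW = 0.40),
                       reliability_range = c(0.3, 0.95),
                       frac_near_gene = 0.75,
                       qtl_cover_frac = 0.15,
                       missing_rate = 0,
                       ld_blocks = NULL,
                       birth_years = 3,
                       seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires),
              progeny_per_sire = as.integer(progeny_per_sire),
              n_markers = as.integer(n_markers),
              n_genes = as.integer(n_genes),
              genome = genome,
              maf_range = maf_range,
              pi_qtl = pi_qtl,
              traits = traits,
              genetic_correlations = genetic_correlations,
              heritabilities = heritabilities,
              reliability_range = reliability_range,
              frac_near_gene = frac_near_gene,
              qtl_cover_frac = qtl_cover_frac,
              missing_rate = missing_rate,
              ld_blocks = ld_blocks,
              birth_years = as.integer(birth_years),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default trait genetic correlation matrix
#'
#' Moderate correlation within the functional and type groups, weaker
#' across groups.
#'
#' @param traits Trait names.
#' @param within,across Within-group and across-group correlations.
#' @return Symmetric positive-definite correlation matrix.
#' @export
default_genetic_correlations <- function(traits = default_traits(),
                                         within = 0.5, across = 0.2) {
  grp <- trait_groups()
  k <- length(traits)
  R <- matrix(across, k, k, dimnames = list(traits, traits))
  for (g in grp) R[g, g] <- within
  diag(R) <- 1
  R
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sires > 0, cfg$progeny_per_sire > 0,
            cfg$n_markers > 0, cfg$n_genes > 0,
            all(c("chrom", "length") %in% names(cfg$genome)))
  if (!(cfg$maf_range[1] > 0 && cfg$maf_range[1] <= cfg$maf_range[2] &&
        cfg$maf_range[2] <= 0.5))
    stop("maf_range must be ordered and within (0, 0.5]")
  if (cfg$pi_qtl < 0 || cfg$pi_qtl > 1) stop("pi_qtl must lie in [0, 1]")
  k <- length(cfg$traits)
  R <- cfg$genetic_correlations
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-12))
    stop("genetic_correlations must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("genetic_correlations is not positive definite")
  if (nrow(R) != k) stop("genetic_correlations dimension must match traits")
  h2 <- cfg$heritabilities[cfg$traits]
  if (anyNA(h2) || any(h2 <= 0) || any(h2 >= 1))
    stop("heritabilities must be named per trait and lie in (0, 1)")
  rr <- cfg$reliability_range
  if (!(rr[1] > 0 && rr[1] <= rr[2] && rr[2] <= 1))
    stop("reliability_range must be ordered and within (0, 1]")
  invisible(cfg)
}

#' Simulate a half-sib pedigree
#'
#' Founder sires are unrelated; each sire gets `progeny_per_sire` sons out
#' of unrecorded dams (paternal half-sib families). Every dam is assigned a
#' maternal grandsire (MGS) sampled among the founder sires; the MGS is
#' recorded on the progeny row because the dam herself is not in the
#' pedigree.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `animal`, `sire`, `dam`, `mgs`,
#'   `birth_year`; parents precede offspring.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  sires <- sprintf("S%03d", seq_len(config$n_sires))
  n_prog <- config$n_sires * config$progeny_per_sire
  prog <- sprintf("B%05d", seq_len(n_prog))
  ped <- rbind(
    data.frame(animal = sires, sire = NA_character_, dam = NA_character_,
               mgs = NA_character_, birth_year = 2000L,
               stringsAsFactors = FALSE),
    data.frame(animal = prog,
               sire = rep(sires, each = config$progeny_per_sire),
               dam = NA_character_,
               mgs = sample(sires, n_prog, replace = TRUE),
               birth_year = 2005L + sample.int(config$birth_years, n_prog,
                                               replace = TRUE) - 1L,
               stringsAsFactors = FALSE)
  )
  rownames(ped) <- NULL
  ped
}

## one gamete per animal per marker from its genotype code (no linkage)
gamete_from_code <- function(codes) {
  (stats::runif(length(codes)) < codes / 2) + 0L
}

#' Gene-drop genotypes through a half-sib pedigree
#'
#' Founders are drawn in Hardy-Weinberg proportions at marker-specific
#' allele frequencies uniform in `maf_range`. Each progeny receives one
#' allele from its sire and one from an (unrecorded) dam; the dam is
#' composed of a gamete from the progeny's maternal grandsire and a
#' population gamete, so MGS relationships are genetically real.
#'
#' @param pedigree Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return An object of class `genotype_matrix`: list with `codes`
#'   (bulls x markers, minor-allele counts in \{0, 1, 2\}, `NA` where
#'   missing), `map` (marker, chrom, bp) and `allele_freq` (realized).
#' @export
simulate_genotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  m <- config$n_markers
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  map <- place_markers(config$genome, m)

  sires <- pedigree$animal[is.na(pedigree$sire)]
  prog <- pedigree[!is.na(pedigree$sire), ]
  hwe_geno <- function(n) {
    g <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      g[, j] <- stats::rbinom(n, 2L, maf[j])
    }
    g
  }
  sire_g <- hwe_geno(length(sires))
  rownames(sire_g) <- sires
  if (!is.null(config$ld_blocks)) {
    sire_g <- founder_ld_genotypes(length(sires), maf, config$ld_blocks)
    rownames(sire_g) <- sires
  }

  prog_g <- matrix(0L, nrow(prog), m)
  dam_g <- matrix(0L, nrow(prog), m)
  for (i in seq_len(nrow(prog))) {
    pat <- gamete_from_code(sire_g[prog$sire[i], ])
    dam <- gamete_from_code(sire_g[prog$mgs[i], ]) +
      (stats::runif(m) < maf) # dam = MGS gamete + population gamete
    dam_g[i, ] <- dam
    mat <- gamete_from_code(dam)
    prog_g[i, ] <- pat + mat
  }
  rownames(prog_g) <- prog$animal
  rownames(dam_g) <- prog$animal
  codes <- rbind(sire_g, prog_g)
  storage.mode(codes) <- "integer"
  colnames(codes) <- map$marker

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(codes)) < config$missing_rate
    codes[miss] <- NA_integer_
  }
  out <- genotype_matrix(codes, map)
  # dams are not genotyped output, but their codes feed true parent
  # averages in the trait simulation
  attr(out, "dam_codes") <- dam_g
  out
}

## founders with block LD: haplotypes copied from a small per-block pool
founder_ld_genotypes <- function(n, maf, block) {
  m <- length(maf)
  pool_n <- 8L
  g <- matrix(0L, n, m)
  starts <- seq(1L, m, by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1L, m)
    pool <- matrix((stats::runif(pool_n * length(idx)) <
                      rep(maf[idx], each = pool_n)) + 0L, pool_n)
    h1 <- pool[sample.int(pool_n, n, replace = TRUE), , drop = FALSE]
    h2 <- pool[sample.int(pool_n, n, replace = TRUE), , drop = FALSE]
    g[, idx] <- h1 + h2
  }
  g
}

place_markers <- function(genome, m) {
  per <- diff(round(seq(0, m, length.out = nrow(genome) + 1)))
  out <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    bp <- sort(sample.int(genome$length[i], per[i]))
    out[[i]] <- data.frame(chrom = genome$chrom[i], bp = bp,
                           stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  map$marker <- sprintf("M%05d", seq_len(nrow(map)))
  map[, c("marker", "chrom", "bp")]
}

#' Construct a genotype matrix object
#'
#' @param codes Integer matrix, bulls x markers, values in \{0, 1, 2\} or
#'   `NA`.
#' @param map Data frame with columns `marker`, `chrom`, `bp` (1-based),
#'   positions strictly increasing within chromosome.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, map) {
  stopifnot(ncol(codes) == nrow(map),
            all(codes %in% c(0L, 1L, 2L) | is.na(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- map$marker
  ord_ok <- all(tapply(map$bp, map$chrom, function(x) all(diff(x) > 0)))
  if (!ord_ok) stop("marker positions must be strictly increasing within chromosome")
  p <- colMeans(codes, na.rm = TRUE) / 2
  obj <- list(codes = codes, map = map, allele_freq = unname(p))
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d bulls x %d markers on %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  cat(sprintf("  allele freq range: %.3f-%.3f; missing: %.2f%%\n",
              min(x$allele_freq), max(x$allele_freq),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Simulate gene and QTL annotation intervals
#'
#' Gene intervals are placed so that approximately `frac_near_gene` of the
#' markers lie within 2,500 bp of a gene (exactly all markers at 1, exactly
#' none at 0); QTL intervals cover about `qtl_cover_frac` of each
#' chromosome. Coordinates are 1-based inclusive.
#'
#' @param config A [sim_config()].
#' @param map Marker map (`marker`, `chrom`, `bp`) from the simulated
#'   genotypes.
#' @return List with data frames `genes` and `qtl`, both with columns
#'   `chrom`, `start`, `end`, `id`.
#' @export
simulate_annotation <- function(config, map) {
  set.seed(config$seed + 2L)
  genes <- place_genes(config, map)
  qtl <- place_qtl(config)
  list(genes = genes, qtl = qtl)
}

place_genes <- function(config, map) {
  near_dist <- 2500
  frac <- config$frac_near_gene
  n_genes <- config$n_genes
  chroms <- config$genome$chrom
  if (frac <= 0) {
    iv <- empty_gap_genes(config, map, n_genes, near_dist)
  } else {
    ## anchor genes on contiguous runs of markers per chromosome
    n_near <- max(1L, round(frac * nrow(map)))
    per_chr <- table(factor(map$chrom, levels = chroms))
    take <- round(n_near * as.numeric(per_chr) / nrow(map))
    gene_alloc <- pmax(1L, round(n_genes * as.numeric(per_chr) / nrow(map)))
    iv <- list()
    for (i in seq_along(chroms)) {
      bp <- map$bp[map$chrom == chroms[i]]
      if (!length(bp) || take[i] < 1) next
      k <- min(take[i], length(bp))
      start_idx <- if (frac >= 1) 1L else
        sample.int(length(bp) - k + 1L, 1L)
      run <- sort(bp[start_idx:(start_idx + k - 1L)])
      ng <- min(gene_alloc[i], k)
      grp <- cut(seq_along(run), ng, labels = FALSE)
      st <- tapply(run, grp, min); en <- tapply(run, grp, max)
      iv[[i]] <- data.frame(chrom = chroms[i],
                            start = pmax(1, as.numeric(st) - 100),
                            end = as.numeric(en) + 100,
                            stringsAsFactors = FALSE)
    }
    iv <- do.call(rbind, iv)
    if (nrow(iv) > n_genes) iv <- iv[seq_len(n_genes), ]
  }
  if (nrow(iv) < 1) stop("gene placement failed: no room on genome")
  iv$id <- sprintf("G%04d", seq_len(nrow(iv)))
  rownames(iv) <- NULL
  iv[, c("chrom", "start", "end", "id")]
}

## genes placed in marker-free gaps, > 2500 bp away from every marker
empty_gap_genes <- function(config, map, n_genes, near_dist) {
  len <- 1000
  out <- list()
  for (i in seq_len(nrow(config$genome))) {
    chrom <- config$genome$chrom[i]
    bp <- sort(map$bp[map$chrom == chrom])
    bounds <- c(0, bp, config$genome$length[i])
    gl <- diff(bounds)
    ok <- which(gl > 2 * (near_dist + 1) + len + 2)
    for (g in ok) {
      st <- bounds[g] + near_dist + 2
      en <- st + len
      if (en < bounds[g + 1] - near_dist - 1)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = st,
                                              end = en,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("gene placement failed: no marker-free gaps")
  iv <- do.call(rbind, out)
  if (nrow(iv) < n_genes)
    stop(sprintf("gene count %d exceeds what fits on genome (%d gaps)",
                 n_genes, nrow(iv)))
  iv[seq_len(n_genes), ]
}

place_qtl <- function(config) {
  out <- list()
  for (i in seq_len(nrow(config$genome))) {
    chrom <- config$genome$chrom[i]
    len <- config$genome$length[i]
    qlen <- max(2e5, round(len / 20))
    nq <- max(1L, round(config$qtl_cover_frac * len / qlen))
    starts <- sort(sample.int(len - qlen, nq))
    ## drop overlaps, keep first of each overlapping pair
    keep <- c(TRUE, diff(starts) > qlen)
    starts <- starts[keep]
    out[[i]] <- data.frame(chrom = chrom, start = starts,
                           end = starts + qlen - 1,
                           stringsAsFactors = FALSE)
  }
  qtl <- do.call(rbind, out)
  qtl$id <- sprintf("QTL%03d", seq_len(nrow(qtl)))
  rownames(qtl) <- NULL
  qtl
}

#' Simulate true breeding values and bull evaluations
#'
#' A fraction `1 - pi_qtl` of markers receives a multivariate-normal effect
#' across traits with the configured genetic correlation; effects are
#' scaled per trait so that the population variance of the true breeding
#' value (TBV) equals the trait heritability on a unit phenotypic scale.
#' Evaluations mimic national-evaluation PTAs: for each progeny bull the
#' PTA is the mixed-model blend of a parent-average information source
#' (built from the true parent average, i.e. the sire and dam breeding
#' values) and an own-information source `TBV/2 + noise`, with the two
#' information contents chosen so that the blend's squared correlation
#' with TBV/2 equals the bull's reliability, drawn uniformly in
#' `reliability_range`. Sire, MGS and birth-cohort mean PTAs are emitted
#' for the de-regression fallbacks, along with the blended parent
#' average `pa` and its reliability `rel_pa`.
#'
#' @param genotypes A `genotype_matrix` covering all pedigree bulls.
#' @param pedigree Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return List with `true` (list: `tbv` bulls x traits, `effects` markers
#'   x traits) and `evaluations` (long data frame, progeny bulls only:
#'   `bull`, `trait`, `pta`, `rel`, `sire_pta`, `mgs_pta`, `ayb_pta`,
#'   `rel_pa`).
#' @export
simulate_traits <- function(genotypes, pedigree, config) {
  set.seed(config$seed + 3L)
  R <- config$genetic_correlations
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("genetic_correlations is not positive definite")
  traits <- config$traits
  k <- length(traits)
  m <- config$n_markers
  h2 <- config$heritabilities[traits]

  nz <- stats::runif(m) < (1 - config$pi_qtl)
  eff <- matrix(0, m, k, dimnames = list(genotypes$map$marker, traits))
  if (any(nz))
    eff[nz, ] <- matrix(stats::rnorm(sum(nz) * k), sum(nz), k) %*% chol(R)
  p <- genotypes$allele_freq
  M <- sweep(impute_codes(genotypes$codes), 2, 2 * p)
  tbv <- M %*% eff
  if (any(nz) && sum(nz) > k + 1) {
    # recolor in TBV space so the realized genetic correlations and the
    # per-trait TBV variances match the configuration (TBV stays an
    # exact genotype-weighted sum of the adjusted effects)
    W <- tryCatch(solve(chol(stats::cov(tbv))), error = function(e) NULL)
    if (!is.null(W)) {
      Bcol <- chol(R) * rep(sqrt(h2 * nrow(tbv) / (nrow(tbv) - 1)),
                            each = k)
      eff <- eff %*% (W %*% Bcol)
      tbv <- M %*% eff
    }
  } else if (any(nz)) {
    for (t in seq_len(k)) {
      s <- stats::sd(tbv[, t]) * sqrt((nrow(tbv) - 1) / nrow(tbv))
      if (s > 0) eff[, t] <- eff[, t] * sqrt(h2[t]) / s
    }
    tbv <- M %*% eff
  }
  colnames(tbv) <- traits
  colnames(eff) <- traits

  bulls <- rownames(tbv)
  rel <- matrix(stats::runif(length(bulls) * k, config$reliability_range[1],
                             config$reliability_range[2]),
                length(bulls), k, dimnames = list(bulls, traits))
  half <- tbv / 2

  prog <- pedigree[!is.na(pedigree$sire), ]
  sires <- pedigree$animal[is.na(pedigree$sire)]
  # founder sires carry plain own-information PTAs (no parents)
  sire_pta <- half[sires, , drop = FALSE]
  for (t in seq_len(k)) {
    vg4 <- h2[t] / 4
    noise_sd <- sqrt(vg4 * (1 - rel[sires, t]) / rel[sires, t])
    sire_pta[, t] <- half[sires, t] +
      stats::rnorm(length(sires), 0, noise_sd)
  }

  # true parent average on the PTA scale from sire and dam TBVs
  dam_codes <- attr(genotypes, "dam_codes")
  dam_tbv <- if (!is.null(dam_codes))
    sweep(dam_codes, 2, 2 * p) %*% eff else half[prog$sire, ] * 0
  pa_true <- (tbv[prog$sire, , drop = FALSE] + dam_tbv) / 4
  rownames(pa_true) <- prog$animal

  idxp <- seq_len(nrow(prog))
  pta <- matrix(NA_real_, nrow(prog), k,
                dimnames = list(prog$animal, traits))
  pa_hat <- pta
  rel_pa <- pmin(pmax(0.25 * rel[prog$sire, , drop = FALSE] +
                        0.0625 * rel[prog$mgs, , drop = FALSE],
                      0.01), 0.49)
  dimnames(rel_pa) <- dimnames(pta)
  for (t in seq_len(k)) {
    lam <- (1 - h2[t]) / h2[t]
    s2e <- lam * h2[t] / 4 # record variance on the TBV/2 scale
    r <- pmin(rel[prog$animal, t], 1 - 1e-9)
    exact <- rel[prog$animal, t] >= 1 - 1e-9
    # PA information content from its stand-alone reliability
    # (zz_pa = 2*lam*rp/(0.5 - rp)), capped so that the target blended
    # reliability stays reachable with positive own information
    rp <- rel_pa[, t]
    rcap <- pmin(pmax(r - 0.02, 0.001), 0.499)
    zz_pa_cap <- 4 * lam * rcap / (1 - 2 * rcap)
    zz_pa <- pmin(2 * lam * rp / (0.5 - rp), pmax(zz_pa_cap, 1e-6))
    # own information content solving the blended-reliability identity
    zz_i <- lam / (1 - r) + 4 * lam^2 / (zz_pa + 4 * lam) - 2 * lam
    y_pa <- pa_true[, t] + stats::rnorm(nrow(prog), 0, sqrt(s2e / zz_pa))
    y_i <- half[prog$animal, t] +
      stats::rnorm(nrow(prog), 0, sqrt(s2e / zz_i))
    # blend through the 2x2 PA/animal mixed-model equations (vectorized
    # closed-form inverse); the emitted rel_pa is the joint-system PA
    # reliability, so de-regressing the blend recovers y_i exactly
    det <- (zz_pa + 4 * lam) * (zz_i + 2 * lam) - 4 * lam^2
    pa_hat[, t] <- ((zz_i + 2 * lam) * zz_pa * y_pa +
                      2 * lam * zz_i * y_i) / det
    pta[, t] <- (2 * lam * zz_pa * y_pa +
                   (zz_pa + 4 * lam) * zz_i * y_i) / det
    rel_pa[, t] <- 0.5 - lam * (zz_i + 2 * lam) / det
    if (any(exact)) {
      pta[exact, t] <- half[prog$animal[exact], t]
      pa_hat[exact, t] <- pa_true[exact, t]
      rel_pa[exact, t] <- pmin(rel_pa[exact, t], 0.499)
    }
  }

  pta_all <- rbind(sire_pta, pta)
  recs <- expand.grid(bull = prog$animal, trait = traits,
                      stringsAsFactors = FALSE)
  idx <- match(recs$bull, prog$animal)
  recs$pta <- pta[cbind(recs$bull, recs$trait)]
  recs$rel <- rel[cbind(recs$bull, recs$trait)]
  recs$sire_pta <- pta_all[cbind(prog$sire[idx], recs$trait)]
  recs$mgs_pta <- pta_all[cbind(prog$mgs[idx], recs$trait)]
  recs$ayb_pta <- stats::ave(recs$pta, recs$trait, prog$birth_year[idx])
  recs$pa <- pa_hat[cbind(recs$bull, recs$trait)]
  recs$rel_pa <- rel_pa[cbind(recs$bull, recs$trait)]
  recs <- recs[order(recs$bull, match(recs$trait, traits)), ]
  rownames(recs) <- NULL
  list(true = list(tbv = tbv, effects = eff), evaluations = recs)
}

impute_codes <- function(codes) {
  if (!anyNA(codes)) return(codes)
  mns <- colMeans(codes, na.rm = TRUE)
  idx <- which(is.na(codes), arr.ind = TRUE)
  codes[idx] <- mns[idx[, 2]]
  codes
}

#' Simulate a complete single-breed population
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_annotation()] and [simulate_traits()] under one seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_population`: list with `config`,
#'   `pedigree`, `genotypes`, `genes`, `qtl`, `true`, `evaluations`.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  ann <- simulate_annotation(config, gen$map)
  tr <- simulate_traits(gen, ped, config)
  out <- list(config = config, pedigree = ped, genotypes = gen,
              genes = ann$genes, qtl = ann$qtl,
              true = tr$true, evaluations = tr$evaluations)
  class(out) <- "sim_population"
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(paste0("sim_population: %d sires, %d progeny bulls, ",
                     "%d markers, %d genes, %d QTL, %d traits (seed %d)\n"),
              x$config$n_sires,
              sum(!is.na(x$pedigree$sire)), x$config$n_markers,
              nrow(x$genes), nrow(x$qtl), length(x$config$traits),
              x$config$seed))
  invisible(x)
}

#' Simulate a multi-breed study
#'
#' @param configs Named list of [sim_config()] objects, one per breed.
#' @return Named list of `sim_population` objects.
#' @export
simulate_study <- function(configs) {
  stopifnot(length(names(configs)) == length(configs))
  lapply(configs, simulate_population)
}
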