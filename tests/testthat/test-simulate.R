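test_that("pedigree construction gives the configured family structure", {
  cfg <- sim_config(n_sires = 4, progeny_per_sire = 10, n_markers = 50,
                    n_genes = 10, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 44) # 4 sires + 40 progeny
  expect_equal(sum(is.na(ped$sire)), 4)
  expect_equal(unname(table(ped$sire[!is.na(ped$sire)])),
               rep(10L, 4), ignore_attr = TRUE)
  # named parents precede offspring
  pos <- match(ped$animal, ped$animal)
  sire_pos <- match(ped$sire, ped$animal)
  expect_true(all(sire_pos < pos, na.rm = TRUE))
  # sire-progeny additive relationship is 0.5
  cfg1 <- sim_config(n_sires = 1, progeny_per_sire = 1, n_markers = 10,
                     n_genes = 2, seed = 1)
  A <- a_matrix(simulate_pedigree(cfg1))
  expect_equal(A$matrix[1, 2], 0.5)
  # determinism
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
})

test_that("gene-drop genotypes respect Mendelian constraints and HWE", {
  cfg <- sim_config(n_sires = 10, progeny_per_sire = 30, n_markers = 400,
                    n_genes = 50, seed = 4)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  expect_true(all(gen$codes %in% 0:2))
  prog <- ped[!is.na(ped$sire), ]
  for (i in sample(nrow(prog), 50)) {
    sg <- gen$codes[prog$sire[i], ]
    pg <- gen$codes[prog$animal[i], ]
    # sire coded 0 passes no minor allele; coded 2 always passes one
    expect_true(all(pg[sg == 0] <= 1))
    expect_true(all(pg[sg == 2] >= 1))
  }
  # founders at MAF 0.5: mean code ~ 1 within 3 binomial SE
  cfg2 <- sim_config(n_sires = 500, progeny_per_sire = 1, n_markers = 60,
                     n_genes = 10, maf_range = c(0.5, 0.5), seed = 5)
  gen2 <- simulate_genotypes(simulate_pedigree(cfg2), cfg2)
  founders <- gen2$codes[1:500, ]
  se <- sqrt(2 * 0.5 * 0.5 / 500)
  expect_true(all(abs(colMeans(founders) - 1) < 3 * se))
  # positions strictly increasing within chromosome
  expect_true(all(tapply(gen$map$bp, gen$map$chrom,
                         function(x) all(diff(x) > 0))))
  # determinism
  expect_identical(gen$codes, simulate_genotypes(ped, cfg)$codes)
})

test_that("paternal half-sibs show the expected mean genomic relationship", {
  cfg <- sim_config(n_sires = 6, progeny_per_sire = 30, n_markers = 3000,
                    n_genes = 100, seed = 6)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  G <- vanraden_g(gen)$matrix
  prog <- ped[!is.na(ped$sire), ]
  fam <- split(prog$animal, prog$sire)
  within_rel <- unlist(lapply(fam, function(ids) {
    g <- G[ids, ids]
    g[upper.tri(g)]
  }))
  # half sibs: A = 0.25 plus a small MGS contribution
  expect_gt(mean(within_rel), 0.18)
  expect_lt(mean(within_rel), 0.40)
})

test_that("annotation placement honours the near-gene fraction limits", {
  cfg1 <- sim_config(n_sires = 5, progeny_per_sire = 5, n_markers = 300,
                     n_genes = 60, frac_near_gene = 1, seed = 8)
  ped <- simulate_pedigree(cfg1)
  gen <- simulate_genotypes(ped, cfg1)
  ann <- simulate_annotation(cfg1, gen$map)
  mp <- map_snp_to_genes(gen$map, ann$genes, max_dist = 2500)
  expect_setequal(unique(mp$marker), gen$map$marker)

  cfg0 <- sim_config(n_sires = 5, progeny_per_sire = 5, n_markers = 40,
                     n_genes = 10, frac_near_gene = 0, seed = 9)
  gen0 <- simulate_genotypes(ped, cfg0)
  ann0 <- simulate_annotation(cfg0, gen0$map)
  mp0 <- map_snp_to_genes(gen0$map, ann0$genes, max_dist = 2500)
  expect_equal(nrow(mp0), 0)

  # seeded rerun gives a byte-identical interval table
  f1 <- tempfile(); f2 <- tempfile()
  write_intervals(simulate_annotation(cfg1, gen$map)$genes, f1)
  write_intervals(simulate_annotation(cfg1, gen$map)$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("trait simulation calibrates heritability, correlations and reliability", {
  cfg <- sim_config(n_sires = 100, progeny_per_sire = 20, n_markers = 800,
                    n_genes = 100, seed = 12)
  pop <- simulate_population(cfg)
  h2 <- cfg$heritabilities[cfg$traits]
  # realized TBV variance (phenotypic scale 1) within 0.05 of h2
  expect_true(all(abs(apply(pop$true$tbv, 2, var) - h2) < 0.05))
  # realized genetic correlations within 0.07 of configured
  Rr <- cor(pop$true$tbv)
  expect_lt(max(abs(Rr - cfg$genetic_correlations)), 0.07)
  # nonzero-effect fraction within binomial 99% bounds of 1 - pi_qtl
  nz <- mean(rowSums(pop$true$effects != 0) > 0)
  bounds <- qbinom(c(0.005, 0.995), cfg$n_markers, 1 - cfg$pi_qtl) /
    cfg$n_markers
  expect_gte(nz, bounds[1])
  expect_lte(nz, bounds[2])

  # fixed reliability 0.6: squared correlation with TBV/2 within 0.05
  for (s in c(1, 2)) {
    cfgr <- sim_config(n_sires = 100, progeny_per_sire = 20,
                       n_markers = 400, n_genes = 50,
                       reliability_range = c(0.6, 0.6), seed = s)
    popr <- simulate_population(cfgr)
    ev <- popr$evaluations[popr$evaluations$trait == "STAT", ]
    r2 <- cor(ev$pta, popr$true$tbv[ev$bull, "STAT"] / 2)^2
    expect_lt(abs(r2 - 0.6), 0.05)
  }

  # degenerate cases
  cfg_null <- sim_config(n_sires = 5, progeny_per_sire = 5, n_markers = 60,
                         n_genes = 10, pi_qtl = 1, seed = 3)
  pop_null <- simulate_population(cfg_null)
  expect_true(all(pop_null$true$tbv == 0))
  cfg_rel1 <- sim_config(n_sires = 5, progeny_per_sire = 5, n_markers = 60,
                         n_genes = 10, reliability_range = c(1, 1), seed = 3)
  pop1 <- simulate_population(cfg_rel1)
  ev1 <- pop1$evaluations
  expect_equal(ev1$pta, pop1$true$tbv[cbind(ev1$bull, ev1$trait)] / 2)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(maf_range = c(0.3, 0.1)), "maf_range")
  expect_error(sim_config(heritabilities = c(DCD = 1.2)), "heritabilities")
  bad <- default_genetic_correlations()
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999
  bad[2, 3] <- bad[3, 2] <- 0.999
  expect_error(sim_config(genetic_correlations = bad), "positive definite")
})
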