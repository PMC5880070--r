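test_that("parent-average fallbacks follow the three printed formulas", {
  expect_equal(estimate_parent_average(2.0, 1.0, 0.0), 1.25)
  expect_equal(estimate_parent_average(1.0, NA, 1.0), 1.0)
  expect_equal(estimate_parent_average(NA, 0.0, 0.0), 0.0)
  expect_equal(estimate_parent_average(NA, 2.0, 1.0), 0.25 * 2 + 0.75)
  expect_error(estimate_parent_average(NA, NA, NA, id = "bullX"), "bullX")
  expect_error(estimate_parent_average(1.0, 1.0, NA), "fallback")
})

test_that("de-regression matches the independently solved information algebra", {
  rec <- data.frame(bull = "b1", trait = "STAT", pta = 2.0, rel = 0.64,
                    pa = 0.5, rel_pa = 0.36, stringsAsFactors = FALSE)
  got <- deregress(rec, h2 = c(STAT = 0.4), c = 0.5)
  want <- dereg_oracle(pta = 2.0, rel = 0.64, pa = 0.5, rel_pa = 0.36,
                       h2 = 0.4, c = 0.5)
  expect_equal(got$dpta, want$dpta, tolerance = 1e-6)
  expect_equal(got$w, want$w, tolerance = 1e-6)
  expect_equal(got$rel_dpta, want$rel_dpta, tolerance = 1e-6)

  # cross-check a second parameter point
  rec2 <- data.frame(bull = "b2", trait = "DCD", pta = -1.2, rel = 0.8,
                     pa = -0.3, rel_pa = 0.2, stringsAsFactors = FALSE)
  got2 <- deregress(rec2, h2 = c(DCD = 0.1))
  want2 <- dereg_oracle(-1.2, 0.8, -0.3, 0.2, 0.1)
  expect_equal(got2$dpta, want2$dpta, tolerance = 1e-6)
  expect_equal(got2$w, want2$w, tolerance = 1e-6)

  # determinism: identical inputs give identical outputs
  both <- deregress(rbind(rec, rec), h2 = c(STAT = 0.4))
  expect_equal(both$dpta[1], both$dpta[2])
})

test_that("de-regression limits, equivariance and weight monotonicity hold", {
  # rel -> 1 with pa = 0: dPTA approaches the PTA
  rec <- data.frame(bull = "b", trait = "GL", pta = 3.1, rel = 0.9999,
                    pa = 0, rel_pa = 0.3, stringsAsFactors = FALSE)
  got <- deregress(rec, h2 = c(GL = 0.5))
  expect_equal(got$dpta, 3.1, tolerance = 1e-3)

  # scale equivariance: k * (pta, pa) -> k * dpta, same w
  base <- data.frame(bull = "b", trait = "GL", pta = 1.7, rel = 0.7,
                     pa = 0.4, rel_pa = 0.25, stringsAsFactors = FALSE)
  scaled <- transform(base, pta = 10 * pta, pa = 10 * pa)
  a <- deregress(base, h2 = c(GL = 0.5))
  b <- deregress(scaled, h2 = c(GL = 0.5))
  expect_equal(b$dpta, 10 * a$dpta)
  expect_equal(b$w, a$w)

  # w strictly increases with rel_dpta (decreases as information drops)
  rels <- seq(0.3, 0.95, by = 0.05)
  recs <- data.frame(bull = paste0("b", seq_along(rels)), trait = "GL",
                     pta = 1, rel = rels, pa = 0, rel_pa = 0.2,
                     stringsAsFactors = FALSE)
  out <- deregress(recs, h2 = c(GL = 0.5))
  expect_true(all(diff(out$rel_dpta) > 0))
  expect_true(all(diff(out$w) > 0))

  # no own information: record flagged, not silently de-regressed
  weak <- data.frame(bull = "b0", trait = "GL", pta = 1, rel = 0.2,
                     pa = 0.5, rel_pa = 0.35, stringsAsFactors = FALSE)
  suppressMessages(outw <- deregress(weak, h2 = c(GL = 0.5)))
  expect_true(outw$excluded)
  expect_true(is.na(outw$dpta))
})

test_that("record filtering applies the strict threshold and all-traits rule", {
  traits <- c("T1", "T2")
  recs <- data.frame(
    bull = c("a", "a", "b", "b", "c"),
    trait = c("T1", "T2", "T1", "T2", "T1"),
    dpta = 1, w = 1,
    rel_dpta = c(0.21, 0.50, 0.20, 0.90, 0.95),
    stringsAsFactors = FALSE)
  out <- filter_records(recs, min_rel = 0.2, traits = traits)
  # bull a: both kept (0.21 > 0.2 strictly); bull b: T1 at the boundary is
  # dropped, so the whole bull goes; bull c misses T2 entirely
  expect_setequal(out$bull, "a")
  expect_equal(nrow(out), 2)

  # identity when everything passes
  full <- data.frame(bull = rep(c("a", "b"), each = 2),
                     trait = rep(traits, 2), dpta = 1, w = 1,
                     rel_dpta = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_records(full, traits = traits)), 4)

  # empty result is an error, not an empty frame
  low <- transform(full, rel_dpta = 0.1)
  expect_error(filter_records(low, traits = traits), "threshold")
})

test_that("de-regression preserves signal against true breeding values", {
  # progeny-tested bulls: own information dominates the parent average,
  # so removing the PA costs almost no predictive correlation
  pop <- simulate_population(sim_config(n_sires = 50, progeny_per_sire = 20,
                                        n_markers = 300, n_genes = 50,
                                        reliability_range = c(0.7, 0.95),
                                        seed = 21))
  ev <- pop$evaluations[pop$evaluations$trait == "STAT", ]
  d <- deregress(pop$evaluations)
  d <- d[d$trait == "STAT" & !d$excluded, ]
  half <- pop$true$tbv[d$bull, "STAT"] / 2
  r_dpta <- cor(d$dpta, half)
  r_pta <- cor(ev$pta[match(d$bull, ev$bull)], half)
  expect_gte(r_dpta, r_pta - 0.02)
})
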