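sig_fixture <- function() {
  # marker "all6" significant everywhere; "func" only in DCD/MCD/GL;
  # "type" only in type traits; "five" in 5 of 6 spanning both groups
  # "four" is significant in 4 traits spanning both groups but completes
  # neither group, so it meets no criterion
  list(DCD = c("all6", "func", "four"),
       MCD = c("all6", "func", "four"),
       GL = c("all6", "func"),
       STAT = c("all6", "type", "four"),
       STR = c("all6", "type", "four"),
       RW = c("all6", "type"))
}

test_that("relevant-SNP selection implements the a/b/c criteria", {
  sel <- select_relevant_snp(sig_fixture())
  row <- function(m) sel[sel$marker == m, ]
  expect_true(all(unlist(row("all6")[c("crit_a", "crit_b", "crit_c")])))
  expect_equal(unlist(row("func")[c("crit_a", "crit_b", "crit_c")]),
               c(crit_a = FALSE, crit_b = TRUE, crit_c = FALSE))
  expect_equal(unlist(row("type")[c("crit_a", "crit_b", "crit_c")]),
               c(crit_a = FALSE, crit_b = FALSE, crit_c = TRUE))
  # significant across both groups without completing either: excluded
  expect_false("four" %in% sel$marker)
})

awm_fixture <- function() {
  markers <- c("m1", "m2", "m3", "m4", "m5")
  traits <- unlist(trait_groups(), use.names = FALSE)
  sel <- data.frame(marker = markers, crit_a = c(TRUE, TRUE, FALSE, TRUE,
                                                 FALSE),
                    crit_b = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                    crit_c = TRUE, stringsAsFactors = FALSE)
  snp_gene <- data.frame(marker = c("m1", "m2", "m3"),
                         gene = c("gA", "gA", "gB"),
                         distance = 0, stringsAsFactors = FALSE)
  pvg <- lapply(setNames(seq_along(traits), traits), function(i) {
    setNames(c(0.01, 0.02, 0.05, 0.03, 0.04), markers)
  })
  abar <- lapply(setNames(seq_along(traits), traits), function(i) {
    setNames(c(1, 2, 3, 4, 5) * i, markers)
  })
  map <- data.frame(marker = markers, chrom = "c1", bp = 1:5,
                    stringsAsFactors = FALSE)
  list(sel = sel, snp_gene = snp_gene, pvg = pvg, abar = abar, map = map)
}

test_that("one-SNP-one-gene keeps the largest mean PV_g and criterion-a orphans", {
  fx <- awm_fixture()
  asg <- resolve_one_snp_per_gene(fx$sel, fx$snp_gene, fx$pvg, fx$map)
  # gA mapped by m1 (0.01) and m2 (0.02): m2 wins
  expect_equal(asg$marker[asg$row_id == "gA"], "m2")
  expect_equal(asg$marker[asg$row_id == "gB"], "m3")
  # unmapped m4 has criterion a: kept as own row; m5 (b only): dropped
  expect_true("m4" %in% asg$row_id)
  expect_false("m5" %in% asg$row_id)

  # exact PV_g tie broken by genomic order (lower bp wins)
  fx$pvg <- lapply(fx$pvg, function(v) {
    v[c("m1", "m2")] <- 0.02
    v
  })
  asg2 <- resolve_one_snp_per_gene(fx$sel, fx$snp_gene, fx$pvg, fx$map)
  expect_equal(asg2$marker[asg2$row_id == "gA"], "m1")
})

test_that("AWM columns are z-scored with the population SD, signs kept", {
  fx <- awm_fixture()
  asg <- resolve_one_snp_per_gene(fx$sel, fx$snp_gene, fx$pvg, fx$map)
  awm <- build_awm(asg, fx$abar)
  expect_equal(colMeans(awm$matrix), rep(0, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  pop_sd <- apply(awm$matrix, 2, function(x)
    sd(x) * sqrt((length(x) - 1) / length(x)))
  expect_equal(unname(pop_sd), rep(1, 6), tolerance = 1e-10)
  # (1, 2, 3) standardizes to the known closed form
  z <- (c(1, 2, 3) - 2) / (sd(c(1, 2, 3)) * sqrt(2 / 3))
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # effect ordering (hence sign structure) survives standardization
  expect_true(all(diff(awm$matrix[order(awm$matrix[, 1]), 1]) >= 0))

  # degenerate column is an error naming the trait
  const <- lapply(fx$abar, function(v) setNames(rep(1, 5), names(v)))
  expect_error(build_awm(asg, const), "DCD")
  # fewer than 3 rows is an error
  expect_error(build_awm(asg[1:2, ], fx$abar), "3 rows")
})

test_that("AWM construction is deterministic and row-order invariant", {
  fx <- awm_fixture()
  asg <- resolve_one_snp_per_gene(fx$sel, fx$snp_gene, fx$pvg, fx$map)
  a1 <- build_awm(asg, fx$abar)
  a2 <- build_awm(asg[sample(nrow(asg)), ], fx$abar)
  expect_equal(a1$matrix[sort(rownames(a1$matrix)), ],
               a2$matrix[sort(rownames(a2$matrix)), ])
})
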