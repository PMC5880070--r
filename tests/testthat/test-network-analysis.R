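toy_net <- function(nodes, pairs) {
  if (!length(pairs))
    return(gene_network(nodes, data.frame(a = character(),
                                          b = character(),
                                          weight = numeric())))
  gene_network(nodes, data.frame(a = vapply(pairs, `[`, "", 1),
                                 b = vapply(pairs, `[`, "", 2),
                                 weight = 0.99, stringsAsFactors = FALSE))
}

test_that("network intersection is plain node-set algebra", {
  nets <- list(HO = toy_net(c("A", "B", "C"), list(c("A", "B"))),
               BS = toy_net(c("B", "C", "D"), list(c("B", "C"))),
               JE = toy_net(c("C", "E"), list(c("C", "E"))))
  got <- intersect_networks(nets)
  expect_equal(got$shared, "C")
  expect_equal(got$observed_k, 1)
  expect_equal(unname(got$set_sizes), c(3, 3, 2))
  same <- intersect_networks(list(a = nets$HO, b = nets$HO))
  expect_setequal(same$shared, c("A", "B", "C"))
  disj <- intersect_networks(list(a = nets$HO,
                                  b = toy_net(c("X", "Y"), list())))
  expect_equal(disj$observed_k, 0)
})

test_that("two-set intersection tail equals the hypergeometric survival", {
  cases <- list(c(10, 7, 30, 4), c(100, 50, 400, 20), c(5, 5, 10, 3))
  for (cs in cases) {
    got <- exact_intersection_pvalue(cs[1:2], cs[3], cs[4])
    want <- phyper(cs[4] - 1, cs[1], cs[3] - cs[1], cs[2],
                   lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("multi-set intersection tail matches Monte-Carlo and is monotone", {
  set.seed(7)
  mc <- mc_intersection_tail(c(10, 10, 10), 20, 8, n_draws = 2e5)
  p <- exact_intersection_pvalue(c(10, 10, 10), 20, 8)
  se <- sqrt(mc * (1 - mc) / 2e5)
  expect_lt(abs(p - mc), 3 * se + 1e-12)
  # monotone non-increasing in the observed overlap
  ps <- vapply(0:10, function(k)
    exact_intersection_pvalue(c(10, 10, 10), 20, k), 0)
  expect_true(all(diff(ps) <= 1e-12))
  # boundary: sets equal to the universe intersect completely
  expect_equal(exact_intersection_pvalue(c(20, 20, 20), 20, 20), 1)
  # infeasible overlap
  expect_warning(p0 <- exact_intersection_pvalue(c(5, 5), 20, 6),
                 "impossible")
  expect_equal(p0, 0)
})

test_that("shared edges are presence-based and monotone in the subset", {
  nets <- list(
    HO = toy_net(c("A", "B", "C"), list(c("A", "B"), c("B", "C"))),
    BS = toy_net(c("A", "B", "C"), list(c("A", "B"))),
    JE = toy_net(c("A", "B"), list(c("A", "B"))))
  # weight differences are ignored: pair presence decides
  nets$BS$edges$weight <- -0.985
  all3 <- shared_edges(nets)
  expect_equal(nrow(all3), 1)
  pair <- shared_edges(nets, c("HO", "BS"))
  expect_true(nrow(pair) >= nrow(all3))
  same <- shared_edges(list(nets$HO, nets$HO))
  expect_equal(nrow(same), 2)
})

test_that("power-law degree sequences pass the KS fit, degenerate ones error", {
  set.seed(3)
  deg <- rpowerlaw(500, alpha = 2.5)
  fit <- powerlaw_ks_test(deg)
  expect_gt(fit$p_value, 0.1)
  expect_gt(fit$alpha, 1.5)
  # determinism of the fit
  fit2 <- powerlaw_ks_test(deg)
  expect_identical(fit, fit2)
  # a path graph's degree sequence still yields a finite estimate
  path_deg <- c(1, rep(2, 18), 1)
  smoke <- powerlaw_ks_test(path_deg)
  expect_true(is.finite(smoke$alpha))
  expect_error(powerlaw_ks_test(rep(3, 20)), "degenerate")
  expect_error(powerlaw_ks_test(c(1, 2, 3)), "at least 10")
})

test_that("hub report returns top-degree genes that carry QTL assignments", {
  # star graph: hub connected to 19 leaves
  leaves <- sprintf("L%02d", 1:19)
  star <- toy_net(c("hub", leaves),
                  lapply(leaves, function(l) c("hub", l)))
  gq <- data.frame(gene = c("hub", "L01"), qtl = c("Q1", "Q2"),
                   stringsAsFactors = FALSE)
  top5 <- hub_report(star, gq, top_fraction = 0.05)
  expect_equal(top5$gene, "hub")
  expect_equal(top5$degree, 19)
  all_assigned <- hub_report(star, gq, top_fraction = 1)
  expect_setequal(all_assigned$gene, c("hub", "L01"))
  none <- hub_report(star, gq[0, ], top_fraction = 1)
  expect_equal(nrow(none), 0)
})
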