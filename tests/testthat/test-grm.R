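test_that("VanRaden method-1 matrix matches hand arithmetic", {
  Z <- rbind(b1 = 0, b2 = 2)
  colnames(Z) <- "m1"
  G <- vanraden_g(Z, allele_freq = 0.5)
  expect_equal(unname(G$matrix), matrix(c(2, -2, -2, 2), 2))
  # identical genotype rows give identical G rows
  Z2 <- rbind(b1 = c(0, 1, 2), b2 = c(0, 1, 2), b3 = c(2, 1, 0))
  colnames(Z2) <- paste0("m", 1:3)
  G2 <- vanraden_g(Z2)
  expect_equal(G2$matrix[1, ], G2$matrix[2, ], ignore_attr = TRUE)
  expect_equal(G2$matrix[1, 1], G2$matrix[2, 2])
  # monomorphic markers are excluded with a warning
  Z3 <- cbind(Z2, m4 = c(2, 2, 2))
  expect_warning(G3 <- vanraden_g(Z3), "monomorphic")
  expect_equal(G3$matrix, G2$matrix)
  expect_error(vanraden_g(cbind(m = c(2, 2))), "polymorphic")
})

test_that("HWE founders give mean diagonal near 1 and PSD structure", {
  set.seed(51)
  p <- runif(5000, 0.1, 0.5)
  Z <- sapply(p, function(pp) rbinom(200, 2, pp))
  colnames(Z) <- paste0("m", seq_along(p))
  G <- vanraden_g(Z)
  expect_equal(mean(diag(G$matrix)), 1, tolerance = 0.02)
  ev <- eigen(G$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("TOP25/BOT75 and NET/FREE are exact panel partitions", {
  set.seed(52)
  panel <- sprintf("m%03d", 1:100)
  pvg <- lapply(setNames(1:6, unlist(trait_groups())), function(i) {
    setNames(runif(100), panel)
  })
  # force marker m001 into the top quartile for exactly 3 traits,
  # m002 for exactly 2 (and out of it everywhere else)
  for (t in names(pvg)) pvg[[t]][c("m001", "m002")] <- -1
  for (t in names(pvg)[1:3]) pvg[[t]]["m001"] <- 2
  for (t in names(pvg)[1:2]) pvg[[t]]["m002"] <- 2
  parts <- partition_top25(pvg)
  expect_true("m001" %in% parts$top25)
  expect_true("m002" %in% parts$bot75)
  expect_setequal(c(parts$top25, parts$bot75), panel)
  expect_length(intersect(parts$top25, parts$bot75), 0)

  asg <- data.frame(row_id = c("g1", "g2", "m050"),
                    marker = c("m010", "m020", "m050"),
                    mapped = c(TRUE, TRUE, FALSE),
                    crit_a = TRUE, crit_b = TRUE, crit_c = TRUE,
                    mean_pvg = 0.01, stringsAsFactors = FALSE)
  abar <- lapply(pvg, function(v) setNames(rnorm(100), panel))
  awm <- build_awm(asg, abar)
  np <- partition_network(awm, panel)
  expect_setequal(np$net, c("m010", "m020", "m050"))
  expect_setequal(c(np$net, np$free), panel)
  expect_length(intersect(np$net, np$free), 0)
})

test_that("CONN with identity D reproduces the scaled-genotype numerator", {
  set.seed(53)
  p <- runif(30, 0.1, 0.5)
  Z <- sapply(p, function(pp) rbinom(40, 2, pp))
  colnames(Z) <- paste0("m", 1:30)
  rownames(Z) <- paste0("b", 1:40)
  base <- vanraden_g(Z)
  net <- paste0("m", 1:10)
  D <- diag(10)
  cg <- conn_g(Z, net, D, base)
  pf <- colMeans(Z[, net]) / 2
  Zs <- sweep(sweep(Z[, net], 2, 2 * pf), 2, sqrt(2 * pf * (1 - pf)), "/")
  expect_equal(cg$raw, tcrossprod(Zs), tolerance = 1e-12)
  # allele-frequency-free scaling matches reference means
  expect_equal(mean(diag(cg$matrix)), mean(diag(base$matrix)),
               tolerance = 1e-8)
  off <- function(M) (sum(M) - sum(diag(M))) / (length(M) - nrow(M))
  expect_equal(off(cg$matrix), off(base$matrix), tolerance = 1e-8)
})

test_that("a single off-diagonal D entry only perturbs its marker pair", {
  set.seed(54)
  Z <- matrix(rbinom(15, 2, 0.4), 5, 3,
              dimnames = list(paste0("b", 1:5), paste0("m", 1:3)))
  Z[1, 1] <- 0; Z[2, 1] <- 2 # ensure polymorphic
  base <- vanraden_g(Z)
  D0 <- diag(3)
  D1 <- D0; D1[1, 2] <- D1[2, 1] <- 1
  g0 <- conn_g(Z, paste0("m", 1:3), D0, base)
  g1 <- conn_g(Z, paste0("m", 1:3), D1, base)
  p <- colMeans(Z) / 2
  Zs <- sweep(sweep(Z, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  # direct matrix-algebra oracle for the D difference
  delta_oracle <- Zs[, 1] %o% Zs[, 2] + Zs[, 2] %o% Zs[, 1]
  expect_equal(g1$raw - g0$raw, delta_oracle, tolerance = 1e-10)
  # indefinite D gets repaired with a logged distance
  Dbad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  gb <- conn_g(Z, paste0("m", 1:3), Dbad, base)
  expect_gt(gb$psd_distance, 0)
  expect_error(conn_g(Z, paste0("m", 1:3), diag(2), base), "mismatch")
})

test_that("pedigree A-matrix reproduces closed-form relationships", {
  ped <- data.frame(
    animal = c("s", "d", "x", "y", "hs_dam", "z"),
    sire = c(NA, NA, "s", "s", NA, "s"),
    dam = c(NA, NA, "d", "d", NA, "hs_dam"),
    stringsAsFactors = FALSE)
  A <- a_matrix(ped)$matrix
  expect_equal(A["s", "x"], 0.5)   # parent-offspring
  expect_equal(A["x", "y"], 0.5)   # full sibs
  expect_equal(A["x", "z"], 0.25)  # paternal half sibs
  expect_equal(A["s", "s"], 1)     # non-inbred founder
  expect_equal(A, t(A))
  # order independence: shuffled rows give the same matrix
  shuf <- ped[c(3, 1, 6, 2, 5, 4), ]
  expect_equal(a_matrix(shuf)$matrix[rownames(A), colnames(A)], A)
  # cycles are detected
  cyc <- data.frame(animal = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), stringsAsFactors = FALSE)
  expect_error(a_matrix(cyc), "cycle")
})
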