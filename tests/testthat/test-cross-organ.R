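test_that("independence model reproduces published expected cells", {
  pla <- organ_class_counts(2844, 2978, 17634, "placenta")
  lun <- organ_class_counts(3642, 4418, 15396, "lung")
  kid <- organ_class_counts(772, 1040, 21644, "kidney")
  cc <- expected_counts(pla, lun)
  expect_equal(cc$N, 23456)
  expect_equal(round(cc$expected["up", "up"]), 442)
  expect_equal(round(cc$expected["down", "down"]), 561)
  expect_equal(round(cc$expected["up", "down"]), 536)
  expect_equal(round(cc$expected["down", "up"]), 462)
  expect_equal(round(expected_counts(pla, kid)$expected["up", "up"]), 94)
  expect_equal(sum(cc$expected), cc$N)  # exact, rounding only at report
})

test_that("concordance observed/expected agree with joint labels and are symmetric", {
  set.seed(5)
  a <- classify(make_signal_table(400, organ = "a"))
  b <- classify(make_signal_table(400, organ = "b"))
  cc <- expected_counts(a, b)
  expect_equal(sum(cc$observed), cc$N)
  expect_equal(rowSums(cc$observed), rowSums(cc$expected), tolerance = 1e-12)
  expect_equal(colSums(cc$observed), colSums(cc$expected), tolerance = 1e-12)
  cc2 <- expected_counts(b, a)
  expect_equal(cc2$observed, t(cc$observed), ignore_attr = TRUE)
  expect_equal(cc2$expected, t(cc$expected), ignore_attr = TRUE)
})

test_that("degenerate marginals give zero expected and observed up-up", {
  ids <- sprintf("g%03d", 1:100)
  a <- classify(expression_table(ids, c(rep(1.5, 10), rep(-1.5, 10), rep(0, 80)), "a"))
  b <- classify(expression_table(ids, rep(0, 100), "b"))
  cc <- expected_counts(a, b)
  expect_equal(cc$expected["up", "up"], 0)
  expect_equal(cc$observed["up", "up"], 0L)
})

test_that("under independence, counts rarely leave the Poisson 99% envelope", {
  set.seed(99)
  outside <- 0L
  total <- 0L
  for (s in 1:15) {
    a <- classify(make_signal_table(600, 0.15, 0.15, organ = "a"))
    b <- classify(make_signal_table(600, 0.15, 0.15, organ = "b"))
    cc <- expected_counts(a, b)
    e <- cc$expected
    o <- cc$observed
    lo <- qpois(0.005, e)
    hi <- qpois(0.995, e)
    outside <- outside + sum(o < lo | o > hi)
    total <- total + length(e)
  }
  expect_lt(outside / total, 0.025)
})

test_that("correlation matrix has unit diagonal and exact trivial values", {
  ids <- sprintf("g%03d", 1:50)
  x <- rnorm(50)
  ta <- expression_table(ids, x, "a")
  tb <- expression_table(ids, -x, "b")
  r <- organ_correlation_matrix(list(ta, tb))
  expect_equal(diag(r), c(a = 1, b = 1))
  expect_equal(r["a", "b"], -1)
  const <- expression_table(ids, rep(0.2, 50), "c")
  expect_error(organ_correlation_matrix(list(ta, const)), "c")
})

test_that("coupled two-group simulation yields within-group positive, between-group negative r", {
  set.seed(12)
  sim <- sim_study(sim_config(small = TRUE), seed = 12)
  r <- organ_correlation_matrix(sim$tables)
  g1 <- c("placenta", "kidney")
  g2 <- c("liver", "lung", "heart")
  expect_gt(r["placenta", "kidney"], 0)
  expect_true(all(r[g2, g2][upper.tri(diag(3))] > 0))
  expect_true(all(r[g1, g2] < 0))
})

test_that("clustering splits a block correlation matrix at the first partition", {
  organs <- c("P", "K", "Li", "Lu", "H")
  r <- matrix(-0.5, 5, 5, dimnames = list(organs, organs))
  r[c("P", "K"), c("P", "K")] <- 0.9
  r[c("Li", "Lu", "H"), c("Li", "Lu", "H")] <- 0.9
  diag(r) <- 1
  dend <- cluster_organs(r)
  sp <- top_split(dend)
  sizes <- sort(vapply(sp, length, integer(1)))
  expect_equal(sizes, c(2L, 3L), ignore_attr = TRUE)
  two <- sp[[which(vapply(sp, length, integer(1)) == 2)]]
  expect_setequal(two, c("K", "P"))
  # brute-force check: max within-pair distance < min between-pair distance,
  # so any agglomerative linkage must merge within-group first
  d <- 1 - r
  expect_lt(max(d["P", "K"], max(d[c("Li", "Lu", "H"), c("Li", "Lu", "H")])),
            min(d[c("P", "K"), c("Li", "Lu", "H")]))
})

test_that("clustering degenerate cases have the expected heights", {
  organs <- c("a", "b", "c")
  r <- diag(3)
  dimnames(r) <- list(organs, organs)
  dend <- cluster_organs(r)
  expect_equal(dend$height, c(1, 1))
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cluster_organs(r2)$height, 0.6)
  r2ns <- r2
  r2ns[1, 2] <- 0.2
  expect_error(cluster_organs(r2ns), "symmetric")
})

test_that("dendrogram heights are non-decreasing and export as newick", {
  set.seed(8)
  sim <- sim_study(sim_config(small = TRUE), seed = 8)
  dend <- cluster_organs(organ_correlation_matrix(sim$tables))
  expect_true(all(diff(dend$height) >= 0))
  p <- tempfile(fileext = ".nwk")
  write_newick(dend, p)
  tree <- ape::read.tree(p)
  expect_setequal(tree$tip.label, names(sim$tables))
})

test_that("cophenetic correlation is exactly 1 on ultrametric distances", {
  organs <- c("a", "b", "c", "d", "e")
  # build an ultrametric distance from a known tree structure
  d <- matrix(1, 5, 5, dimnames = list(organs, organs))
  d[1:2, 1:2] <- 0.2
  d[3:5, 3:5] <- 0.4
  diag(d) <- 0
  dend <- cluster_organs(1 - d)
  res <- cophenetic_test(dend, d)
  expect_equal(res$r_cophenetic, 1)
  expect_equal(res$p_value, 0)
})

test_that("the t approximation reproduces the closed form at r = 0.993, 5 leaves", {
  r <- 0.993
  t_expect <- r * sqrt(8 / (1 - r^2))
  expect_equal(t_expect, 23.78, tolerance = 1e-3)
  p_expect <- 2 * pt(-t_expect, 8)
  expect_lt(p_expect, 1e-7)
  expect_gt(p_expect, 1e-9)
})

test_that("permutation p-values put the observed cophenetic r in the upper tail", {
  set.seed(21)
  sim <- sim_study(sim_config(small = TRUE), seed = 21)
  dend <- cluster_organs(organ_correlation_matrix(sim$tables))
  res <- cophenetic_test(dend, method = "permutation", n_perm = 999)
  expect_gt(res$r_cophenetic, 0.5)
  expect_lt(res$p_value, 0.2)  # only 5! label permutations exist at n = 5
  expect_gte(res$p_value, 1 / 1000)
})

test_that("constant distances flag an undefined cophenetic r", {
  organs <- c("a", "b", "c", "d")
  d <- matrix(1, 4, 4, dimnames = list(organs, organs))
  diag(d) <- 0
  dend <- cluster_organs(1 - d)
  res <- cophenetic_test(dend, d)
  expect_false(res$defined)
  expect_true(is.na(res$r_cophenetic))
})
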