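test_that("cophenetic distances are path sums of branch lengths", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  D <- cophenetic_distances(cherry)
  expect_equal(unname(D["A", "B"]), 2)
  expect_true(all(diag(D) == 0))

  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  D4 <- cophenetic_distances(bal)
  expect_equal(unname(D4["A", "B"]), 2)
  expect_equal(unname(D4["C", "D"]), 2)
  expect_equal(unname(D4["A", "C"]), 4)
  expect_equal(unname(D4["B", "D"]), 4)

  expect_error(cophenetic_distances(
    structure(list(tip.label = "A"), class = "phylo")), "two leaves")
})

test_that("inverse-distance weights are elementwise reciprocals off-diagonal", {
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  W <- inverse_distance_weights(cophenetic_distances(bal))
  expect_equal(unname(W["A", "B"]), 0.5)
  expect_equal(unname(W["A", "C"]), 0.25)
  expect_true(all(diag(W) == 0))
  D0 <- matrix(c(0, 0, 0, 0), 2, 2)
  expect_error(inverse_distance_weights(D0), "[Dd]eduplicate")
})

test_that("uniform weights collapse Moran's I to -1/(n-1)", {
  n <- 4L
  W <- matrix(1, n, n); diag(W) <- 0
  for (seed in 1:5) {
    set.seed(seed)
    y <- stats::rnorm(n)
    expect_equal(morans_i(y, W), -1 / (n - 1), tolerance = 1e-12)
  }
})

test_that("Moran's I rejects constant traits and tiny samples", {
  W <- matrix(1, 4, 4); diag(W) <- 0
  expect_error(morans_i(rep(2, 4), W), "constant")
  expect_error(morans_i(c(1, 2), matrix(1, 2, 2)), "at least 3")
})

test_that("Moran's I matches a brute-force double loop on random trees", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(6:10, 1L)
    tree <- ape::rtree(n)
    W <- inverse_distance_weights(cophenetic_distances(tree))
    y <- stats::rnorm(n)
    expect_equal(morans_i(y, W), moran_bruteforce(y, W), tolerance = 1e-12)
  }
})

test_that("analytic test agrees with the ape reference implementation", {
  set.seed(3)
  tree <- ape::rtree(25)
  W <- inverse_distance_weights(cophenetic_distances(tree))
  y <- stats::rnorm(25)
  # ape::Moran.I row-normalizes its weight matrix internally, so feed the
  # row-normalized matrix to our implementation for the comparison
  Wn <- W / rowSums(W)
  ours <- morans_i_test(y, Wn, method = "analytic")
  ref <- ape::Moran.I(y, W, alternative = "two.sided")
  expect_equal(ours$I, ref$observed, tolerance = 1e-10)
  expect_equal(ours$expected_I, ref$expected, tolerance = 1e-10)
  expect_equal(sqrt(ours$variance_I), ref$sd, tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("NA leaves are dropped in tandem from trait and weights", {
  set.seed(5)
  tree <- ape::rtree(8)
  W <- inverse_distance_weights(cophenetic_distances(tree))
  y <- stats::rnorm(8)
  y_na <- y; y_na[c(2, 6)] <- NA
  keep <- !is.na(y_na)
  expect_equal(morans_i(y_na, W), morans_i(y[keep], W[keep, keep]))
  res <- morans_i_test(y_na, W)
  expect_equal(res$n, 6L)
  expect_equal(res$expected_I, -1 / 5)
})

test_that("permutation p at n=6 equals the exhaustive enumeration tail mass", {
  set.seed(9)
  tree <- ape::read.tree(text =
    "(((A:1,B:1):1,C:2):3,((D:1,E:1):1,F:2):3);")
  W <- inverse_distance_weights(cophenetic_distances(tree))
  y <- c(1, 1.2, 0.9, -1, -1.1, -0.8)  # trait clustered within the 2 clades
  expect_gt(morans_i(y, W), 0)
  E <- -1 / 5
  perms <- all_permutations(6L)
  I_all <- apply(perms, 1L, function(p) morans_i(y[p], W))
  I_obs <- morans_i(y, W)
  p_exact <- mean(abs(I_all - E) >= abs(I_obs - E) - 1e-12)
  res <- morans_i_test(y, W, method = "permutation", n_permutations = 9999,
                       seed = 1)
  expect_equal(res$p_value, p_exact, tolerance = 0.02)
  expect_equal(res$expected_I, E)
  expect_error(morans_i_test(y, W, method = "permutation",
                             n_permutations = 50), "99")
})

test_that("I is invariant to trait scale/shift and weight scale", {
  set.seed(11)
  tree <- ape::rtree(12)
  W <- inverse_distance_weights(cophenetic_distances(tree))
  y <- stats::rnorm(12)
  I0 <- morans_i(y, W)
  expect_equal(morans_i(3.7 * y - 2, W), I0, tolerance = 1e-12)
  expect_equal(morans_i(-0.5 * y + 10, W), I0, tolerance = 1e-12)
  expect_equal(morans_i(y, 8.1 * W), I0, tolerance = 1e-12)
})

test_that("permutation mean of I converges to -1/(n-1)", {
  set.seed(13)
  n <- 30L
  tree <- ape::rtree(n)
  W <- inverse_distance_weights(cophenetic_distances(tree))
  y <- stats::rnorm(n)
  B <- 10000L
  I_perm <- vapply(seq_len(B), function(b) morans_i(sample(y), W), 0)
  se <- stats::sd(I_perm) / sqrt(B)
  expect_lt(abs(mean(I_perm) - (-1 / (n - 1))), 3 * se)
  # analytic randomization variance within Monte-Carlo error of empirical
  v <- tcmepi:::moran_randomization_variance(y, W)
  expect_equal(v, stats::var(I_perm), tolerance = 0.05)
})

test_that("lineage cladograms give edge-count cophenetic distances", {
  cat <- make_catalog(c("A", "B", "C"),
                      lineages = list(c("ord", "famA", "genA", "spA"),
                                      c("ord", "famA", "genA", "spB"),
                                      c("ord", "famB", "genB", "spC")))
  tree <- build_tree_from_lineages(cat)
  D <- cophenetic_distances(tree)
  # same genus: one edge each to the genus node
  expect_equal(unname(D["A", "B"]), 2)
  # different families under one order: three rank edges per side
  expect_equal(unname(D["A", "C"]), 6)
  expect_equal(unname(D["B", "C"]), 6)

  expect_error(build_tree_from_lineages(cat[1L, ]), "at least 2")
  bad <- make_catalog(c("A", "B"),
                      lineages = list(c("f1", "g"), c("f2", "g")))
  expect_error(build_tree_from_lineages(bad), "two parents")
})

test_that("medicinals sharing a full lineage become sibling leaves", {
  cat <- make_catalog(c("A", "B", "C"),
                      lineages = list(c("f", "g", "s"), c("f", "g", "s"),
                                      c("f", "g2", "s2")))
  D <- cophenetic_distances(build_tree_from_lineages(cat))
  expect_equal(unname(D["A", "B"]), 2)
  expect_equal(unname(D["A", "C"]), unname(D["B", "C"]))
})
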