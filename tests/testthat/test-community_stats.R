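test_that("sample standardization rescales rows to percent totals", {
  x <- rbind(a = c(2, 2), b = c(1, 3))
  s <- standardize_samples(x)
  expect_equal(unname(s["a", ]), c(50, 50))
  expect_equal(unname(s["b", ]), c(25, 75))
  expect_equal(unname(rowSums(s)), c(100, 100))
  expect_error(standardize_samples(rbind(a = c(0, 0))), "a")
})

test_that("Bray-Curtis similarity matches hand values and vegan", {
  x <- rbind(s1 = c(1, 1), s2 = c(3, 1), s3 = c(1, 1))
  bc <- bray_curtis(x)
  expect_equal(bc["s1", "s2"], 100 * (1 - 2 / 6))
  expect_equal(bc["s1", "s3"], 100)
  disjoint <- bray_curtis(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(disjoint["a", "b"], 0)
  # random matrices agree with the vegan implementation
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(rlnorm(24), 4, 6)
    rownames(m) <- paste0("s", 1:4)
    ours <- 100 - unclass(bray_curtis(m))
    ref <- as.matrix(vegan::vegdist(m, method = "bray")) * 100
    expect_equal(unclass(ours), unclass(ref), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("Bray-Curtis is scale-invariant and handles all-zero pairs", {
  set.seed(52)
  m <- matrix(rlnorm(20), 4, 5)
  expect_equal(unclass(bray_curtis(m)), unclass(bray_curtis(m * 37)),
               tolerance = 1e-10)
  z <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_warning(bz <- bray_curtis(z), "all-zero")
  expect_equal(bz["a", "b"], 0)
})

test_that("group-average heights match the O(n^3) oracle", {
  set.seed(53)
  for (i in 1:50) {
    m <- matrix(rlnorm(36), 6, 6)
    rownames(m) <- paste0("s", 1:6)
    bc <- bray_curtis(m)
    hc <- cluster_group_average(bc)
    d <- 100 - unclass(bc)
    expect_equal(sort(hc$height),
                 sort(oracle_average_linkage_heights(d)),
                 tolerance = 1e-9)
  }
  # two samples merge at their dissimilarity
  two <- bray_curtis(rbind(a = c(1, 1), b = c(3, 1)))
  hc2 <- cluster_group_average(two)
  expect_equal(hc2$height, 100 - two["a", "b"])
})

test_that("SIMPROF finds structure between separated groups only", {
  set.seed(54)
  x <- rbind(matrix(rlnorm(30, 0, 0.1), 3, 10),
             matrix(rlnorm(30, 3, 0.1), 3, 10))
  rownames(x) <- paste0("s", 1:6)
  sp <- simprof(x, n_expected = 499, n_null = 499, seed = 2)
  root <- sp$nodes[sp$nodes$n == 6, ]
  expect_true(root$significant)
  kids <- sp$nodes[sp$nodes$n == 3, ]
  expect_true(all(!kids$significant))
  # nodes with fewer than 3 samples are untested with p = 1
  expect_true(all(sp$nodes$p[sp$nodes$n < 3] == 1))
  expect_true(all(!sp$nodes$tested[sp$nodes$n < 3]))
})

test_that("SIMPROF is reproducible under a fixed seed", {
  set.seed(55)
  x <- matrix(rlnorm(60), 6, 10)
  rownames(x) <- paste0("s", 1:6)
  a <- simprof(x, n_expected = 99, n_null = 99, seed = 4)
  b <- simprof(x, n_expected = 99, n_null = 99, seed = 4)
  expect_identical(a$nodes, b$nodes)
})

test_that("NMDS recovers embeddable configurations at near-zero stress", {
  set.seed(56)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts))
  sim <- 100 * (1 - d / (max(d) * 1.1))
  diag(sim) <- 100
  rownames(sim) <- colnames(sim) <- paste0("s", 1:7)
  fit <- nmds(structure(sim, class = c("resemblance", "matrix")),
              n_restarts = 20, seed = 3)
  expect_lt(fit$stress, 0.01)
  expect_equal(unname(colMeans(fit$points)), c(0, 0), tolerance = 1e-9)
  # the returned stress is the best over all restarts
  expect_equal(fit$stress, min(fit$all_stresses))
  # equilateral case: three mutually equidistant samples embed perfectly
  eq <- matrix(50, 3, 3); diag(eq) <- 100
  rownames(eq) <- colnames(eq) <- c("a", "b", "c")
  fit3 <- nmds(structure(eq, class = c("resemblance", "matrix")),
               n_restarts = 10, seed = 5)
  expect_lt(fit3$stress, 1e-4)
})

test_that("Spearman matrix matches the brute-force midrank oracle", {
  expect_equal(spearman_matrix(cbind(x = c(1, 2, 3), y = c(2, 4, 6)))$r["x", "y"], 1)
  expect_equal(spearman_matrix(cbind(x = c(1, 2, 3), y = c(6, 4, 2)))$r["x", "y"], -1)
  set.seed(57)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    a <- sample(1:5, n, replace = TRUE)  # heavy ties
    b <- sample(1:5, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    got <- spearman_matrix(cbind(a = a, b = b))
    want <- oracle_spearman(a, b)
    expect_equal(got$r["a", "b"], unname(want["r"]), tolerance = 1e-10)
    if (abs(want["r"]) < 1)
      expect_equal(got$p["a", "b"], unname(want["p"]), tolerance = 1e-8)
  }
})

test_that("Spearman matrix skips pairs with too few observations", {
  x <- cbind(a = c(1, 2, 3, NA, NA), b = c(2, 1, NA, NA, NA),
             c = c(5, 1, 2, 3, 4))
  expect_warning(ct <- spearman_matrix(x), "a:b")
  expect_true(is.na(ct$r["a", "b"]))
  expect_false(is.na(ct$r["a", "c"]))
})

test_that("vector overlay reports axis correlations on the unit circle", {
  set.seed(58)
  sim <- bray_curtis(matrix(rlnorm(50), 5, 10))
  fit <- nmds(sim, n_restarts = 10, seed = 1)
  vars <- cbind(ax1 = fit$points[, 1], const = rep(1, 5),
                noise = rnorm(5))
  expect_warning(ov <- vector_overlay(fit, vars), "const")
  expect_false("const" %in% ov$variable)
  expect_equal(abs(ov$r1[ov$variable == "ax1"]), 1)
  expect_true(all(abs(ov$r1) <= 1 & abs(ov$r2) <= 1))
  lens <- sqrt(ov$x^2 + ov$y^2)
  expect_true(all(abs(lens - 1) < 1e-9 | lens == 0))
})
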