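make_records <- function(marker, layer, dna, cdna, mat = 1, na = 1,
                         lod = FALSE) {
  data.frame(
    marker = marker, layer = layer,
    replicate = seq_along(dna),
    template = rep(c("DNA", "cDNA"), each = length(dna)),
    raw_copies = c(dna, cdna), mat_mass_g = mat, na_mass_ng = na,
    below_lod = lod, stringsAsFactors = FALSE
  )
}

test_that("normalization divides by each mass basis and validates input", {
  rec <- make_records("m", 1, dna = 1000, cdna = 1000, mat = 1, na = 10)
  norm <- normalize_copies(rec)
  expect_equal(norm$copies_per_g, c(1000, 1000))
  expect_equal(norm$copies_per_ng, c(100, 100))
  rec0 <- make_records("m", 1, dna = 0, cdna = 0)
  expect_equal(normalize_copies(rec0)$copies_per_g, c(0, 0))
  bad <- rec; bad$mat_mass_g[1] <- 0
  expect_error(normalize_copies(bad), "row")
})

test_that("cDNA/DNA ratios reproduce quotients of layer-3 peak values", {
  rec <- rbind(
    make_records("Archaeal-amoA", 3, dna = 7.5e4, cdna = 1.3e5),
    make_records("Bacterial-amoA", 3, dna = 4.2e6, cdna = 1.4e7)
  )
  rat <- expression_ratio(normalize_copies(rec), basis = "per_g")
  expect_equal(rat$ratio[rat$marker == "Archaeal-amoA"], 1.3e5 / 7.5e4,
               tolerance = 1e-12)
  expect_equal(rat$ratio[rat$marker == "Bacterial-amoA"], 1.4e7 / 4.2e6,
               tolerance = 1e-12)
  # identity when transcript pool equals gene pool
  eq <- expression_ratio(normalize_copies(
    make_records("x", 1, dna = c(10, 20), cdna = c(10, 20))))
  expect_equal(eq$ratio, 1)
})

test_that("undefined ratios carry reason codes instead of infinities", {
  rec <- make_records("m", 1, dna = c(500, 600), cdna = c(700, 800))
  rec$below_lod[rec$template == "DNA"] <- TRUE
  rat <- expression_ratio(normalize_copies(rec))
  expect_true(is.na(rat$ratio))
  expect_equal(rat$reason, "dna_below_lod")
  rec2 <- make_records("m", 1, dna = c(0, 0), cdna = c(10, 10))
  rat2 <- expression_ratio(normalize_copies(rec2))
  expect_true(is.na(rat2$ratio))
  expect_equal(rat2$reason, "dna_zero")
})

test_that("ratio aggregation is the ratio of replicate means", {
  rec <- make_records("m", 2, dna = c(10, 30), cdna = c(60, 20))
  rat <- expression_ratio(normalize_copies(rec), aggregate = "mean")
  expect_equal(rat$ratio, mean(c(60, 20)) / mean(c(10, 30)))
})

test_that("Shapiro screen reports W and p, skipping degenerate markers", {
  set.seed(11)
  vals <- rbind(
    data.frame(marker = "skewed", value = rlnorm(50, 0, 2)),
    data.frame(marker = "flat", value = rep(1, 10))
  )
  expect_warning(sw <- shapiro_screen(vals), "flat")
  expect_equal(sw$marker, "skewed")
  expect_lt(sw$p, 0.01)  # heavy skew is rejected
})

test_that("Shapiro screen has nominal type-I error on Gaussian samples", {
  set.seed(21)
  rej <- mean(vapply(1:200, function(i) {
    shapiro_screen(data.frame(marker = "g", value = rnorm(50)))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("Kruskal-Wallis matches the rank-sum formula and the oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kruskal_wallis(groups)$H, 7.2, tolerance = 1e-12)
  # tied data against the independent midrank oracle
  set.seed(5)
  for (i in 1:20) {
    g <- lapply(1:3, function(j) sample(1:4, sample(3:8, 1), replace = TRUE))
    expect_equal(kruskal_wallis(g)$H, oracle_kw(g), tolerance = 1e-10)
  }
  # identical values across groups
  same <- list(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(kruskal_wallis(same)$H, 0)
  expect_equal(kruskal_wallis(same)$p, 1)
})

test_that("H is invariant under monotone transformation of the data", {
  set.seed(6)
  g <- lapply(1:4, function(i) rnorm(6, mean = i))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, exp))$H,
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis keeps its nominal size under a lognormal null", {
  set.seed(31)
  rej <- mean(vapply(1:400, function(i) {
    g <- lapply(1:5, function(j) rlnorm(10))
    kruskal_wallis(g)$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Conover-Iman matches the brute-force oracle on random data", {
  set.seed(7)
  for (i in 1:50) {
    g <- lapply(1:sample(3:5, 1),
                function(j) round(rlnorm(sample(3:7, 1)), 1))
    p <- conover_iman(g)
    expect_equal(max(abs(p - t(p))), 0)
    expect_equal(unname(diag(p)), rep(1, length(g)))
    i1 <- sample(length(g), 1)
    i2 <- sample(setdiff(seq_along(g), i1), 1)
    expect_equal(p[i1, i2], unname(oracle_conover_pair(g, i1, i2)),
                 tolerance = 1e-10)
  }
})

test_that("Conover-Iman separates the widest rank gap most strongly", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  p <- conover_iman(g)
  off <- p[upper.tri(p)]
  expect_equal(min(off), p[1, 3])
  # identical groups cannot separate
  same <- list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_true(all(conover_iman(same) == 1))
})

test_that("compact letters are minimal and consistent with the p matrix", {
  # fully separated: three distinct letters
  p_all <- matrix(0.001, 3, 3); diag(p_all) <- 1
  lt <- compact_letters(p_all, means = c(3, 2, 1))
  expect_equal(unname(lt), c("a", "b", "c"))
  # nothing separated: single letter
  p_none <- matrix(0.9, 3, 3); diag(p_none) <- 1
  expect_equal(unname(unique(compact_letters(p_none))), "a")
  # only pair (1,2) significant
  p_one <- matrix(1, 3, 3)
  p_one[1, 2] <- p_one[2, 1] <- 0.01
  lt2 <- compact_letters(p_one, means = c(3, 2, 1))
  expect_equal(unname(lt2), c("a", "b", "ab"))
})

test_that("letter display is consistent on random p matrices", {
  set.seed(8)
  for (i in 1:100) {
    k <- sample(3:7, 1)
    p <- matrix(1, k, k)
    up <- upper.tri(p)
    p[up] <- runif(sum(up))
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    lt <- compact_letters(p, alpha = 0.3, means = runif(k))
    expect_true(letters_consistent(lt, p, alpha = 0.3))
  }
})

test_that("per-marker driver ties the pieces together on simulated data", {
  panel <- simulate_qpcr_panel(sim_config(seed = 12))
  norm <- normalize_copies(panel)
  vals <- data.frame(marker = norm$marker, layer = norm$layer,
                     value = norm$copies_per_g,
                     below_lod = norm$below_lod)[norm$template == "cDNA", ]
  suppressWarnings(tests <- test_layers(vals))
  expect_true(length(tests) >= 5)
  for (t in tests) {
    expect_true(all(dim(t$pairwise_p) == length(t$letters)))
    expect_true(letters_consistent(unname(t$letters), t$pairwise_p, 0.05))
  }
})
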