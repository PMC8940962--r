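#' Sample-total standardization
#'
#' Divides each sample (row) by its total and scales to percent, the
#' standardization applied to biotic data before computing Bray-Curtis
#' resemblance.
#'
#' @param x Numeric matrix, samples in rows, nonnegative.
#' @return Matrix of the same shape; rows sum to 100.
#' @export
standardize_samples <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("values must be nonnegative")
  tot <- rowSums(x)
  zero <- which(tot == 0)
  if (length(zero)) {
    ids <- rownames(x)[zero]
    if (is.null(ids)) ids <- zero
    stop("zero-total sample(s): ", paste(ids, collapse = ", "))
  }
  sweep(x, 1, tot, "/") * 100
}

# Pairwise Bray-Curtis similarity (0-100) between two rows.
.bc_pair <- function(a, b) {
  s <- sum(a + b)
  if (s == 0) return(NA_real_)
  100 * (1 - sum(abs(a - b)) / s)
}

#' Bray-Curtis resemblance matrix
#'
#' Similarity between samples on the 0-100 PRIMER scale:
#' `100 * (1 - sum|x - y| / sum(x + y))`. A pair of all-zero samples has an
#' undefined similarity; the configurable convention (default 0) is applied
#' with a warning.
#'
#' @param x Numeric matrix, samples in rows, nonnegative.
#' @param zero_zero Similarity assigned to a pair of all-zero samples.
#' @return Symmetric similarity matrix with 100 on the diagonal, class
#'   `resemblance`.
#' @export
bray_curtis <- function(x, zero_zero = 0) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("values must be nonnegative")
  n <- nrow(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  sim <- matrix(100, n, n, dimnames = list(ids, ids))
  undef <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- .bc_pair(x[i, ], x[j, ])
      if (is.na(s)) {
        undef <- TRUE
        s <- zero_zero
      }
      sim[i, j] <- sim[j, i] <- s
    }
  }
  if (undef)
    warning("all-zero sample pair(s): similarity set to ", zero_zero)
  structure(sim, class = c("resemblance", "matrix"))
}

#' Group-average agglomerative clustering of a resemblance matrix
#'
#' Unweighted average linkage (UPGMA-style agglomeration) on Bray-Curtis
#' dissimilarity (100 - similarity), via [stats::hclust()]. Samples are
#' ordered lexicographically by id beforehand so that merge order under ties
#' is deterministic.
#'
#' @param resemblance Similarity matrix from [bray_curtis()].
#' @return An [stats::hclust] object; heights are dissimilarities (0-100).
#' @export
cluster_group_average <- function(resemblance) {
  stopifnot(nrow(resemblance) >= 2)
  ord <- order(rownames(resemblance))
  d <- stats::as.dist(100 - unclass(resemblance)[ord, ord])
  stats::hclust(d, method = "average")
}

# Ordered vector of pairwise Bray-Curtis similarities (the similarity
# profile) of the rows of x.
.similarity_profile <- function(x) {
  n <- nrow(x)
  out <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      k <- k + 1L
      s <- .bc_pair(x[i, ], x[j, ])
      out[k] <- if (is.na(s)) 0 else s
    }
  }
  sort(out)
}

# Permute each variable (column) independently across rows.
.permute_within_variables <- function(x) {
  n <- nrow(x)
  for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(n), j]
  x
}

#' Similarity-profile (SIMPROF) test on a cluster dendrogram
#'
#' Tests, at each node of the group-average dendrogram, whether the samples
#' under the node contain multivariate structure. The test statistic is
#' `pi = sum |observed ordered similarity profile - expected profile|`, where
#' the expected profile is the mean ordered profile over permutations that
#' shuffle values independently within each variable across the node's
#' samples. The null distribution of `pi` comes from a second, independent
#' permutation pool; `p = (1 + #{pi* >= pi}) / (1 + n_null)`. Testing starts
#' at the root and descends only below significant nodes; nodes with fewer
#' than 3 samples are untested (p = 1).
#'
#' @param x Data matrix (samples x variables) the dendrogram was built from.
#' @param hc Optional [stats::hclust] from [cluster_group_average()]; rebuilt
#'   from `bray_curtis(x)` when missing.
#' @param n_expected Permutations for the expected profile (default 999).
#' @param n_null Permutations for the null distribution of pi (default 999).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for the permutation streams.
#' @return Object of class `simprof_clust`: list with `hclust` and `nodes`, a
#'   data.frame with one row per internal node (`node`, `height`, `n`,
#'   `members`, `tested`, `pi`, `p`, `significant`), plus the parameters.
#' @export
simprof <- function(x, hc = NULL, n_expected = 999, n_null = 999,
                    alpha = 0.05, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 2)
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(n))
  if (is.null(hc)) hc <- cluster_group_average(bray_curtis(x))
  merge <- hc$merge
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    kids <- merge[k, ]
    members[[k]] <- sort(unlist(lapply(kids, function(ch)
      if (ch < 0) hc$labels[-ch] else members[[ch]])))
  }
  nodes <- data.frame(
    node = seq_len(n_nodes), height = hc$height,
    n = lengths(members),
    members = vapply(members, paste, character(1), collapse = ","),
    tested = FALSE, pi = NA_real_, p = NA_real_, significant = FALSE,
    stringsAsFactors = FALSE
  )
  nodes$p[nodes$n < 3L] <- 1  # too small to test, by the boundary rule
  test_node <- function(sub) {
    obs <- .similarity_profile(sub)
    withr::with_seed(seed, {
      pool <- replicate(n_expected,
                        .similarity_profile(.permute_within_variables(sub)))
      expected <- rowMeans(pool)
      pi_obs <- sum(abs(obs - expected))
      pi_null <- replicate(n_null, sum(abs(
        .similarity_profile(.permute_within_variables(sub)) - expected)))
    })
    list(pi = pi_obs, p = (1 + sum(pi_null >= pi_obs)) / (1 + n_null))
  }
  # root-down traversal, stopping below non-significant nodes
  visit <- function(k) {
    idx <- which(nodes$node == k)
    if (nodes$n[idx] < 3L) {
      nodes$tested[idx] <<- FALSE
      nodes$p[idx] <<- 1
      return(invisible())
    }
    sub <- x[members[[k]], , drop = FALSE]
    res <- test_node(sub)
    nodes$tested[idx] <<- TRUE
    nodes$pi[idx] <<- res$pi
    nodes$p[idx] <<- res$p
    nodes$significant[idx] <<- res$p <= alpha
    if (nodes$significant[idx]) {
      for (ch in merge[k, ]) if (ch > 0) visit(ch)
    }
  }
  visit(n_nodes)
  structure(
    list(hclust = hc, nodes = nodes, alpha = alpha,
         n_expected = n_expected, n_null = n_null, seed = seed),
    class = "simprof_clust"
  )
}

#' @export
print.simprof_clust <- function(x, ...) {
  cat("SIMPROF on group-average dendrogram (",
      x$n_expected, "+", x$n_null, " permutations, alpha = ",
      x$alpha, ")\n", sep = "")
  print(x$nodes[, c("node", "height", "n", "tested", "pi", "p",
                    "significant")], row.names = FALSE)
  invisible(x)
}

#' Non-metric multidimensional scaling of a resemblance matrix
#'
#' Kruskal stress-1 minimization with monotone regression (via
#' [vegan::monoMDS()]), restarted from a metric-scaling start plus random
#' configurations; the lowest-stress solution is returned with centered
#' coordinates.
#'
#' @param resemblance Similarity matrix from [bray_curtis()] (0-100 scale).
#' @param k Ordination dimensions (default 2).
#' @param n_restarts Number of random restarts in addition to the metric
#'   start (default 50).
#' @param seed Seed for the random starts.
#' @return list of class `nmds_fit`: `points` (samples x k, centered),
#'   `stress` (stress-1, in \[0,1\]), `n_restarts`, `seed`.
#' @export
nmds <- function(resemblance, k = 2, n_restarts = 50, seed = 1L) {
  n <- nrow(resemblance)
  stopifnot(n >= 3)
  d <- stats::as.dist((100 - unclass(resemblance)) / 100)
  fits <- list()
  withr::with_seed(seed, {
    y0 <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
    if (!is.null(y0) && ncol(y0) == k)
      fits[[1]] <- vegan::monoMDS(d, y = y0, k = k, model = "global")
    for (r in seq_len(n_restarts)) {
      y <- matrix(stats::runif(n * k, -1, 1), n, k)
      fits[[length(fits) + 1]] <-
        vegan::monoMDS(d, y = y, k = k, model = "global")
    }
  })
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  best <- fits[[which.min(stresses)]]
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(unclass(resemblance))
  colnames(pts) <- paste0("MDS", seq_len(k))
  structure(
    list(points = pts, stress = min(stresses),
         all_stresses = stresses, n_restarts = n_restarts, seed = seed),
    class = "nmds_fit"
  )
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("NMDS (", ncol(x$points), " dimensions, ", x$n_restarts,
      " random restarts): stress = ", signif(x$stress, 4), "\n", sep = "")
  print(x$points)
  invisible(x)
}

# Spearman p-value by the t approximation used throughout (two-sided).
.spearman_test <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) return(c(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(
    stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
  c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Spearman rank correlation matrix across biotic and abiotic variables
#'
#' Computes the full matrix of Spearman rank correlations (midranks;
#' two-sided p by the t approximation) across the columns of the biotic
#' table and, optionally, an environmental table aligned on the same rows
#' (layers). Pairs with fewer than 3 complete observations are skipped with
#' a warning (r and p reported NA).
#'
#' @param biotic data.frame or matrix, rows = layers, columns = variables
#'   (e.g. cDNA/DNA ratios per marker).
#' @param env Optional environmental table aligned on the same rows.
#' @return list of class `cor_table` with matrices `r` and `p` and the
#'   sample-size matrix `n`.
#' @export
spearman_matrix <- function(biotic, env = NULL) {
  x <- as.matrix(biotic)
  if (!is.null(env)) {
    env <- as.matrix(env)
    if (nrow(env) != nrow(x))
      stop("biotic and env tables must have the same number of rows")
    x <- cbind(x, env)
  }
  v <- ncol(x)
  nm <- colnames(x)
  r <- p <- nmat <- matrix(NA_real_, v, v, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  skipped <- character()
  for (i in seq_len(v - 1)) {
    for (j in seq(i + 1, v)) {
      st <- .spearman_test(x[, i], x[, j])
      if (is.na(st["r"]))
        skipped <- c(skipped, paste0(nm[i], ":", nm[j]))
      r[i, j] <- r[j, i] <- st["r"]
      p[i, j] <- p[j, i] <- st["p"]
      nmat[i, j] <- nmat[j, i] <- st["n"]
    }
  }
  if (length(skipped))
    warning("pair(s) with < 3 complete observations skipped: ",
            paste(skipped, collapse = ", "))
  structure(list(r = r, p = p, n = nmat), class = "cor_table")
}

#' Spearman vector overlay for an NMDS ordination
#'
#' Correlates each variable with the two ordination axes (Spearman rank) and
#' returns per-variable vectors, normalized onto the unit circle for
#' plotting. Constant variables are skipped with a warning.
#'
#' @param fit [nmds()] result.
#' @param variables data.frame or matrix aligned row-wise with the ordinated
#'   samples.
#' @return data.frame `variable`, `r1`, `r2` (axis correlations), `x`, `y`
#'   (unit-circle vector coordinates).
#' @export
vector_overlay <- function(fit, variables) {
  stopifnot(inherits(fit, "nmds_fit"))
  v <- as.matrix(variables)
  if (nrow(v) != nrow(fit$points))
    stop("variables must align with the ordinated samples")
  rows <- list()
  skipped <- character()
  for (nm in colnames(v)) {
    vals <- v[, nm]
    if (stats::sd(vals, na.rm = TRUE) == 0 || all(!is.finite(vals))) {
      skipped <- c(skipped, nm)
      next
    }
    r1 <- suppressWarnings(
      stats::cor(vals, fit$points[, 1], method = "spearman",
                 use = "pairwise.complete.obs"))
    r2 <- suppressWarnings(
      stats::cor(vals, fit$points[, 2], method = "spearman",
                 use = "pairwise.complete.obs"))
    len <- sqrt(r1^2 + r2^2)
    rows[[nm]] <- data.frame(
      variable = nm, r1 = r1, r2 = r2,
      x = if (len > 0) r1 / len else 0,
      y = if (len > 0) r2 / len else 0,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped))
    warning("constant variable(s) skipped: ", paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variable = character(), r1 = numeric(), r2 = numeric(),
                      x = numeric(), y = numeric())
  rownames(out) <- NULL
  out
}
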