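# Independent brute-force oracles used to validate the statistical routines.
# These are deliberately written from the defining formulas, not by calling
# the implementation under test.

# midranks computed from scratch (average position of tied values)
oracle_midrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Kruskal-Wallis H with tie correction, from the rank-sum formula
oracle_kw <- function(groups) {
  x <- unlist(groups)
  n <- lengths(groups)
  N <- length(x)
  r <- oracle_midrank(x)
  g <- rep(seq_along(groups), n)
  Rj <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Conover-Iman two-sided p for one pair, from the defining t statistic
oracle_conover_pair <- function(groups, i, j) {
  x <- unlist(groups)
  n <- lengths(groups)
  N <- length(x)
  k <- length(groups)
  r <- oracle_midrank(x)
  g <- rep(seq_along(groups), n)
  rbar <- tapply(r, g, mean)
  H <- oracle_kw(groups)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  se <- sqrt(S2 * (N - 1 - H) / (N - k) * (1 / n[i] + 1 / n[j]))
  2 * pt(-abs((rbar[i] - rbar[j]) / se), df = N - k)
}

# Spearman r and two-sided t-approximation p from scratch
oracle_spearman <- function(a, b) {
  ra <- oracle_midrank(a)
  rb <- oracle_midrank(b)
  r <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  n <- length(a)
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# O(n^3) unweighted average-linkage agglomeration: merge heights in order
oracle_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# scan-and-count mapping of an ungapped position to its alignment column
oracle_anchor_column <- function(row, pos) {
  chars <- strsplit(row, "")[[1]]
  seen <- 0
  for (i in seq_along(chars)) {
    if (chars[i] != "-") {
      seen <- seen + 1
      if (seen == pos) return(i)
    }
  }
  NA_integer_
}

# letter-display consistency: groups share a letter iff non-significant
letters_consistent <- function(letters_vec, pmat, alpha) {
  k <- length(letters_vec)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                strsplit(letters_vec[j], "")[[1]])) > 0
      sig <- pmat[i, j] <= alpha
      if (share == sig) return(FALSE)
    }
  }
  TRUE
}

# reference alignment class label -> generator truth label
clade_to_truth <- c(
  "AOB-HAO" = "oxidative-HAO-like",
  "epsilonHao" = "epsilonHao-like"
)
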