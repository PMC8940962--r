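#' Normalize qPCR copy numbers on two bases
#'
#' Gene copy numbers quantified by qPCR depend on the nucleic acid extraction,
#' so copies are expressed both per gram of mat and per nanogram of nucleic
#' acid. Below-detection flags are propagated unchanged.
#'
#' @param records data.frame of raw copy records with columns `raw_copies`,
#'   `mat_mass_g`, `na_mass_ng` (and any identifying columns, which are
#'   preserved).
#' @return The input with added columns `copies_per_g` and `copies_per_ng`.
#' @export
normalize_copies <- function(records) {
  need <- c("raw_copies", "mat_mass_g", "na_mass_ng")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(records$mat_mass_g <= 0 | records$na_mass_ng <= 0)
  if (length(bad))
    stop("non-positive mass in row(s): ", paste(bad, collapse = ", "))
  if (any(records$raw_copies < 0))
    stop("negative raw_copies in row(s): ",
         paste(which(records$raw_copies < 0), collapse = ", "))
  records$copies_per_g <- records$raw_copies / records$mat_mass_g
  records$copies_per_ng <- records$raw_copies / records$na_mass_ng
  records
}

#' cDNA/DNA expression ratios per marker and layer
#'
#' Aggregates replicate copy numbers within each marker x layer x template and
#' forms the transcript-to-gene ratio (cDNA aggregate / DNA aggregate), the
#' expression proxy plotted in depth profiles. Aggregation is the ratio of
#' means by default (robust when a single replicate is near zero); the median
#' is available. Replicates flagged below the detection limit are excluded
#' from aggregation; a layer whose DNA (or cDNA) values are all below
#' detection, or whose DNA aggregate is zero, yields no ratio and carries a
#' reason code instead.
#'
#' @param normalized Output of [normalize_copies()] with columns `marker`,
#'   `layer`, `template`, `below_lod` and the chosen basis column.
#' @param basis `"per_g"` (copies per gram of mat) or `"per_ng"` (copies per
#'   ng nucleic acid).
#' @param aggregate `"mean"` or `"median"` across replicates.
#' @return data.frame with columns `marker`, `layer`, `basis`, `ratio`
#'   (NA when undefined) and `reason` (NA when defined; otherwise
#'   `"dna_below_lod"`, `"cdna_below_lod"` or `"dna_zero"`).
#' @export
expression_ratio <- function(normalized,
                             basis = c("per_g", "per_ng"),
                             aggregate = c("mean", "median")) {
  basis <- match.arg(basis)
  aggregate <- match.arg(aggregate)
  col <- paste0("copies_", basis)
  if (!col %in% names(normalized))
    stop("normalized table lacks column ", col,
         "; run normalize_copies() first")
  agg_fun <- if (aggregate == "mean") mean else stats::median
  if (is.null(normalized$below_lod)) normalized$below_lod <- FALSE

  combos <- unique(normalized[, c("marker", "layer")])
  combos <- combos[order(combos$marker, combos$layer), ]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- normalized[normalized$marker == combos$marker[i] &
                        normalized$layer == combos$layer[i], ]
    dna <- sub[sub$template == "DNA" & !sub$below_lod, col]
    cdna <- sub[sub$template == "cDNA" & !sub$below_lod, col]
    ratio <- NA_real_
    reason <- NA_character_
    if (!length(dna)) {
      reason <- "dna_below_lod"
    } else if (!length(cdna)) {
      reason <- "cdna_below_lod"
    } else if (agg_fun(dna) == 0) {
      reason <- "dna_zero"
    } else {
      ratio <- agg_fun(cdna) / agg_fun(dna)
    }
    data.frame(marker = combos$marker[i], layer = combos$layer[i],
               basis = basis, ratio = ratio, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality screen per marker
#'
#' Run before the layer comparisons to document departure from normality;
#' the pipeline always takes the nonparametric path, this screen records why.
#'
#' @param values data.frame with columns `marker` and `value`.
#' @return data.frame `marker`, `n`, `W`, `p`. Markers with fewer than 3
#'   values or zero variance are skipped with a warning.
#' @export
shapiro_screen <- function(values) {
  stopifnot(all(c("marker", "value") %in% names(values)))
  out <- lapply(split(values$value, values$marker), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3L || stats::var(v) == 0) return(NULL)
    sw <- stats::shapiro.test(v)
    c(n = length(v), W = unname(sw$statistic), p = sw$p.value)
  })
  skipped <- names(out)[vapply(out, is.null, logical(1))]
  if (length(skipped))
    warning("skipped marker(s) with n < 3 or zero variance: ",
            paste(skipped, collapse = ", "))
  keep <- out[!vapply(out, is.null, logical(1))]
  if (!length(keep))
    return(data.frame(marker = character(), n = integer(),
                      W = numeric(), p = numeric()))
  data.frame(marker = names(keep), do.call(rbind, keep),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across layers
#'
#' Thin wrapper around [stats::kruskal.test()] (midranks, tie correction,
#' chi-square reference with k-1 df), with the degenerate all-identical case
#' defined as H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per layer.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n == 0L))
    stop("empty group(s): ", paste(which(n == 0L), collapse = ", "))
  if (sum(n) < 3L) stop("need at least 3 observations in total")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), n))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Conover-Iman pairwise rank comparisons
#'
#' All-pairs post hoc test following a Kruskal-Wallis test on the same
#' groups: t statistics on mean ranks with the pooled rank variance scaled by
#' (N - 1 - H)/(N - k), referred to a t distribution with N - k degrees of
#' freedom; two-sided p-values. Reported unadjusted by default (a Holm
#' adjustment is available).
#'
#' @param groups List of numeric vectors, one per layer.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Symmetric matrix of two-sided p-values with unit diagonal.
#' @export
conover_iman <- function(groups, p_adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  k <- length(groups)
  n <- lengths(groups)
  if (any(n == 0L))
    stop("empty group(s): ", paste(which(n == 0L), collapse = ", "))
  N <- sum(n)
  if (N <= k) stop("need more observations than groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), n)
  r <- rank(x)  # midranks
  rbar <- tapply(r, g, mean)
  H <- kruskal_wallis(groups)$H
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale <- S2 * (N - 1 - H) / (N - k)
  p <- matrix(1, k, k)
  lab <- names(groups)
  if (is.null(lab)) lab <- as.character(seq_len(k))
  dimnames(p) <- list(lab, lab)
  if (scale <= 0) return(p)  # complete separation of ranks is impossible
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      t_ij <- (rbar[i] - rbar[j]) / sqrt(scale * (1 / n[i] + 1 / n[j]))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(t_ij), df = N - k)
    }
  }
  if (p_adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair, split each letter containing both members into
#' two (one without each member), then delete letters whose group set is a
#' subset of another's. Two groups share a letter iff they are not
#' significantly different at `alpha`. Letters are assigned in a
#' deterministic order: groups ranked by descending `means` (ties by original
#' index), letters named after the highest-ranked group they contain.
#'
#' @param pairwise_p Symmetric matrix of pairwise p-values.
#' @param alpha Significance level (default 0.05).
#' @param means Optional group means used only to order letter assignment.
#' @return Named character vector: letter string per group.
#' @export
compact_letters <- function(pairwise_p, alpha = 0.05, means = NULL) {
  stopifnot(is.matrix(pairwise_p), nrow(pairwise_p) == ncol(pairwise_p))
  if (max(abs(pairwise_p - t(pairwise_p))) > 1e-12)
    stop("pairwise_p must be symmetric")
  k <- nrow(pairwise_p)
  lab <- rownames(pairwise_p)
  if (is.null(lab)) lab <- as.character(seq_len(k))
  if (is.null(means)) means <- rep(0, k)
  ord <- order(-means, seq_len(k))  # descending mean, then index

  cols <- list(rep(TRUE, k))  # each letter = logical membership over groups
  sig <- which(pairwise_p <= alpha & upper.tri(pairwise_p), arr.ind = TRUE)
  if (nrow(sig)) {
    # process pairs in the deterministic display order
    sig <- sig[order(sig[, 1], sig[, 2]), , drop = FALSE]
    for (s in seq_len(nrow(sig))) {
      i <- sig[s, 1]; j <- sig[s, 2]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a == b || !keep[a]) next
          sub_a <- !any(newcols[[a]] & !newcols[[b]])
          if (sub_a && (any(newcols[[b]] & !newcols[[a]]) || a > b))
            keep[a] <- FALSE
        }
      }
      cols <- newcols[keep]
    }
  }
  # order letters by the display rank of their top member
  top <- vapply(cols, function(col) min(match(which(col), ord)), numeric(1))
  cols <- cols[order(top)]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    lt <- letters[(ci - 1) %% 26 + 1]
    if (ci > 26) lt <- paste0(lt, (ci - 1) %/% 26)
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]], lt)
  }
  stats::setNames(letters_out, lab)
}

#' Per-marker layer comparison driver
#'
#' For each marker: Kruskal-Wallis global test across layers, Conover-Iman
#' pairwise comparisons, and the compact letter display (letters ordered by
#' descending layer mean). Values flagged below the detection limit are
#' excluded.
#'
#' @param values data.frame with columns `marker`, `layer`, `value` and
#'   optionally `below_lod`.
#' @param alpha Significance level for the letter display.
#' @param p_adjust Passed to [conover_iman()].
#' @return Named list per marker: `H`, `df`, `p_global`, `pairwise_p`,
#'   `letters`, `layer_means`. Markers with fewer than 2 layers observed are
#'   skipped with a warning.
#' @export
test_layers <- function(values, alpha = 0.05, p_adjust = "none") {
  stopifnot(all(c("marker", "layer", "value") %in% names(values)))
  if (!is.null(values$below_lod)) values <- values[!values$below_lod, ]
  out <- list()
  skipped <- character()
  for (m in unique(values$marker)) {
    sub <- values[values$marker == m & is.finite(values$value), ]
    groups <- split(sub$value, sub$layer)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2L || sum(lengths(groups)) < 3L) {
      skipped <- c(skipped, m)
      next
    }
    kw <- kruskal_wallis(groups)
    pw <- conover_iman(groups, p_adjust = p_adjust)
    mns <- vapply(groups, mean, numeric(1))
    out[[m]] <- list(
      H = kw$H, df = kw$df, p_global = kw$p,
      pairwise_p = pw,
      letters = compact_letters(pw, alpha = alpha, means = mns),
      layer_means = mns
    )
  }
  if (length(skipped))
    warning("marker(s) skipped (too few quantifiable layers): ",
            paste(skipped, collapse = ", "))
  out
}
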