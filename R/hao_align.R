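#' Global alignment of a query protein to a reference alignment profile
#'
#' Aligns a query sequence against the column profile of the reference
#' alignment by global (Needleman-Wunsch) dynamic programming with affine gap
#' costs. Column match scores are position-specific: the BLOSUM62 score of
#' the query residue against each reference residue observed in the column,
#' weighted by the column's residue frequencies (gaps excluded). Reference
#' columns are immutable: query residues that fall between reference columns
#' (insertions) are recorded separately and never shift column indexing, so
#' anchor columns computed on the reference remain valid for the aligned
#' query row.
#'
#' A gap of length L costs `gap_open + gap_extend * L`.
#'
#' @param query Protein sequence (single string, 20-letter alphabet, `X`
#'   allowed).
#' @param refaln A [load_hao_reference()] object.
#' @param gap_open,gap_extend Affine gap parameters (default 11 and 1, the
#'   BLOSUM62 convention).
#' @return Object of class `hao_alignment`: list with `aligned` (query row
#'   over the reference columns, `-` for deletions), `query_index` (per
#'   column, the 1-based index of the query residue placed there, NA at
#'   gaps), `insertions` (data.frame `after_column`, `position`, `residue`),
#'   `score`, and `query` (the input sequence).
#' @export
align_query_to_reference <- function(query, refaln,
                                     gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(refaln, "hao_refaln"))
  if (!nzchar(query)) stop("empty query sequence")
  q <- strsplit(toupper(query), "")[[1]]
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  if (!all(q %in% alphabet))
    stop("query contains non-amino-acid characters: ",
         paste(unique(setdiff(q, alphabet)), collapse = ", "))

  blosum <- .blosum62()
  rows <- do.call(rbind, strsplit(unname(refaln$aln), ""))
  n <- ncol(rows)
  m <- length(q)

  # position-specific score: mean BLOSUM62 score of residue a against the
  # column's non-gap residues
  score_col <- matrix(0, n, m)
  for (i in seq_len(n)) {
    res <- rows[, i]
    res <- res[res != "-"]
    if (!length(res)) next
    score_col[i, ] <- colMeans(blosum[res, q, drop = FALSE])
  }

  go <- gap_open + gap_extend
  ge <- gap_extend
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- -(gap_open + ge * seq_len(n))
  if (m >= 1) Y[1, 2:(m + 1)] <- -(gap_open + ge * seq_len(m))
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    diagbest <- pmax(prevM[jj], prevX[jj], prevY[jj])
    M[i + 1, jj + 1] <- score_col[i, ] + diagbest
    X[i + 1, ] <- pmax(pmax(prevM, prevY) - go, prevX - ge)
    base <- pmax(M[i + 1, ], X[i + 1, ])
    idx <- 0:m
    run <- cummax(base + ge * idx)
    Y[i + 1, jj + 1] <- run[jj] - gap_open - ge * jj
    Y[i + 1, 1] <- NEG
  }

  # traceback (prefer M > X > Y under ties)
  aligned <- character(n)
  qindex <- rep(NA_integer_, n)
  insertions <- list()
  i <- n; j <- m
  vals <- c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
  state <- c("M", "X", "Y")[which.max(vals)]
  score <- max(vals)
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      aligned[i] <- q[j]
      qindex[i] <- j
      tgt <- M[i + 1, j + 1] - score_col[i, j]
      cand <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which(abs(cand - tgt) < tol)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      aligned[i] <- "-"
      tgt <- X[i + 1, j + 1]
      cand <- c(M[i, j + 1] - go, X[i, j + 1] - ge, Y[i, j + 1] - go)
      state <- c("M", "X", "Y")[which(abs(cand - tgt) < tol)[1]]
      i <- i - 1
    } else {
      insertions[[length(insertions) + 1]] <-
        data.frame(after_column = i, position = j, residue = q[j],
                   stringsAsFactors = FALSE)
      tgt <- Y[i + 1, j + 1]
      cand <- c(M[i + 1, j] - go, X[i + 1, j] - go, Y[i + 1, j] - ge)
      state <- c("M", "X", "Y")[which(abs(cand - tgt) < tol)[1]]
      j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (i == 0 && state != "Y") state <- "Y"
    if (j == 0 && state != "X") state <- "X"
  }
  ins <- if (length(insertions))
    do.call(rbind, rev(insertions))
  else data.frame(after_column = integer(), position = integer(),
                  residue = character(), stringsAsFactors = FALSE)
  structure(
    list(aligned = paste(aligned, collapse = ""), query_index = qindex,
         insertions = ins, score = score, query = query),
    class = "hao_alignment"
  )
}

# BLOSUM62 with an X row/column (score of X against anything = -1, X/X = -1),
# sourced from Biostrings' packaged matrix.
.blosum62 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    b <- env$BLOSUM62
    keep <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
    cache <<- b[keep, keep]
    cache
  }
})
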