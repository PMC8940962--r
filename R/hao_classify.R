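#' Classify an aligned HAO query by its active-site motif
#'
#' Reads the residue at the anchor column (the column homologous to the
#' cross-linking tyrosine of oxidative HAO). A tyrosine calls the query
#' oxidative-HAO-like. A tryptophan calls it epsilonHao-like and triggers the
#' second diagnostic: whether a methionine sits eight residues before the
#' anchor residue in the query's own ungapped coordinates (`met_minus8`;
#' insertion residues count, since the motif is a property of the query
#' sequence itself). A gap, an `X`, or any other residue yields an ambiguous
#' call with the observed residue reported.
#'
#' @param alignment An [align_query_to_reference()] result, or a bare aligned
#'   query row (string over reference columns with `-` gaps; assumed to
#'   contain no insertions).
#' @param anchor_col Alignment column of the anchor residue (from
#'   [map_anchor_column()]).
#' @return list of class `motif_call`: `anchor_residue`, `met_minus8`,
#'   `call` (one of `"oxidative-HAO-like"`, `"epsilonHao-like"`,
#'   `"ambiguous"`).
#' @export
classify_hao <- function(alignment, anchor_col) {
  if (is.character(alignment) && length(alignment) == 1L) {
    row <- strsplit(alignment, "")[[1]]
    qindex <- cumsum(row != "-")
    qindex[row == "-"] <- NA_integer_
    alignment <- list(aligned = alignment, query_index = qindex,
                      query = gsub("-", "", alignment))
  }
  row <- strsplit(alignment$aligned, "")[[1]]
  if (anchor_col < 1L || anchor_col > length(row))
    stop("anchor column ", anchor_col, " beyond alignment width ",
         length(row))
  res <- row[anchor_col]
  met <- NA
  call <- "ambiguous"
  if (res == "Y") {
    call <- "oxidative-HAO-like"
  } else if (res == "W") {
    call <- "epsilonHao-like"
  }
  if (res %in% c("Y", "W")) {
    qi <- alignment$query_index[anchor_col]
    met <- if (!is.na(qi) && qi > 8L)
      substr(alignment$query, qi - 8L, qi - 8L) == "M" else FALSE
  }
  structure(
    list(anchor_residue = res, met_minus8 = met, call = call),
    class = "motif_call"
  )
}

#' Motif classification of a set of HAO query proteins
#'
#' Aligns each query to the reference profile, reads the anchor-column
#' residue, and returns the per-query motif calls.
#'
#' @param queries Named character vector of protein sequences.
#' @param refaln A [load_hao_reference()] object.
#' @param anchor_col Anchor column; defaults to
#'   `map_anchor_column(refaln)`.
#' @return data.frame `id`, `anchor_residue`, `met_minus8`, `call`, `score`.
#'   The alignments are attached as attribute `"alignments"`.
#' @export
classify_hao_set <- function(queries, refaln,
                             anchor_col = map_anchor_column(refaln)) {
  stopifnot(length(queries) >= 1L, !is.null(names(queries)))
  alns <- lapply(queries, align_query_to_reference, refaln = refaln)
  calls <- lapply(alns, classify_hao, anchor_col = anchor_col)
  out <- data.frame(
    id = names(queries),
    anchor_residue = vapply(calls, `[[`, character(1), "anchor_residue"),
    met_minus8 = vapply(calls, function(x) isTRUE(x$met_minus8), logical(1)),
    call = vapply(calls, `[[`, character(1), "call"),
    score = vapply(alns, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "alignments") <- alns
  out
}
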