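#' Load an anchored HAO reference alignment
#'
#' Reads a reference protein alignment (FASTA with `-` gaps) together with a
#' sidecar table assigning each row a family label (`AOB-HAO`, `anammox-HAO`,
#' `epsilonHao`, `nitrate-reductase-like`) and designating the anchor row and
#' the ungapped position of its active-site tyrosine. The alignment shipped
#' with the package (`hao_reference_synthetic.afa`) is a synthetic stand-in
#' for a curated HAO-family alignment: its rows are generated sequences that
#' reproduce the diagnostic features of the real families (the cross-linking
#' tyrosine column of oxidative and anammox HAO; tryptophan at that column
#' plus a methionine eight residues upstream in the epsilon and
#' nitrate-reductase-like rows) without being real proteins.
#'
#' @param fasta Path to the aligned FASTA (default: packaged synthetic
#'   reference).
#' @param sidecar Path to the TSV sidecar with columns `id`, `class`,
#'   `anchor_ref`, `anchor_pos`.
#' @return Object of class `hao_refaln`: list with `aln` (named character
#'   vector of aligned rows), `class` (named character), `anchor_ref` (id)
#'   and `anchor_pos` (1-based ungapped position in the anchor row).
#' @export
load_hao_reference <- function(
    fasta = system.file("extdata", "hao_reference_synthetic.afa",
                        package = "nitromat"),
    sidecar = system.file("extdata", "hao_reference_synthetic.tsv",
                          package = "nitromat")) {
  aln <- read_fasta(fasta)
  widths <- nchar(aln)
  if (length(unique(widths)) != 1L)
    stop("reference alignment rows differ in length")
  meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  need <- c("id", "class", "anchor_ref", "anchor_pos")
  if (!all(need %in% names(meta)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  if (!setequal(meta$id, names(aln)))
    stop("sidecar ids do not match alignment ids")
  anchor_row <- meta$id[meta$anchor_ref]
  if (length(anchor_row) != 1L)
    stop("exactly one anchor_ref row required")
  anchor_pos <- meta$anchor_pos[meta$anchor_ref]
  ungapped_len <- sum(strsplit(aln[[anchor_row]], "")[[1]] != "-")
  if (anchor_pos < 1L || anchor_pos > ungapped_len)
    stop("anchor_pos beyond the anchor reference sequence")
  structure(
    list(
      aln = aln,
      class = stats::setNames(meta$class, meta$id),
      anchor_ref = anchor_row,
      anchor_pos = as.integer(anchor_pos)
    ),
    class = "hao_refaln"
  )
}

#' Map an ungapped anchor position to its alignment column
#'
#' Returns the alignment column that holds the anchor reference row's Nth
#' non-gap residue (1-based on both sides).
#'
#' @param refaln A [load_hao_reference()] object.
#' @param ref_id Reference row id (default: the designated anchor row).
#' @param pos Ungapped position (default: the annotated anchor position).
#' @return Integer column index.
#' @export
map_anchor_column <- function(refaln, ref_id = refaln$anchor_ref,
                              pos = refaln$anchor_pos) {
  row <- strsplit(refaln$aln[[ref_id]], "")[[1]]
  nongap <- which(row != "-")
  if (pos < 1L || pos > length(nongap))
    stop("position ", pos, " beyond sequence ", ref_id,
         " (", length(nongap), " residues)")
  nongap[pos]
}
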