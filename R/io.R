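#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with the pipeline's validation:
#' wrapped lines are joined, stop characters `*` are stripped with a warning,
#' duplicate ids and empty files are errors. Ids are the first whitespace-
#' delimited token of each header.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("\\*", seqs))) {
    warning("stop character(s) '*' stripped")
    seqs <- gsub("\\*", "", seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)))
  # written manually so aligned FASTA (with '-') round-trips unchanged
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# Column schemas for the pipeline's TSV inputs: name -> list(type, min).
qpcr_schema <- function() list(
  marker = list(type = "character"),
  layer = list(type = "integer", min = 1),
  replicate = list(type = "integer", min = 1),
  template = list(type = "character", values = c("DNA", "cDNA")),
  raw_copies = list(type = "numeric", min = 0),
  mat_mass_g = list(type = "numeric", min = 1e-12),
  na_mass_ng = list(type = "numeric", min = 1e-12),
  below_lod = list(type = "logical")
)

annotation_schema <- function() list(
  gene_id = list(type = "character"),
  ko = list(type = "character"),
  symbol = list(type = "character"),
  category = list(type = "character"),
  taxon = list(type = "character")
)

coverage_schema <- function() list(
  gene_id = list(type = "character"),
  layer = list(type = "integer", min = 1),
  coverage = list(type = "numeric", min = 0)
)

env_schema <- function() list(
  layer = list(type = "integer", min = 1),
  o2_um = list(type = "numeric"),
  nh4_um = list(type = "numeric", min = 0),
  no3_um = list(type = "numeric", min = 0),
  po4_um = list(type = "numeric", min = 0)
)

#' Read and validate a TSV table against a schema
#'
#' Tables are tab-delimited UTF-8 with a header row and `.` decimal marks.
#' Declared columns are checked for presence, coerced to their declared type,
#' and range-checked with row-level diagnostics; extra columns are preserved
#' with a warning.
#'
#' @param path Path to the TSV file.
#' @param schema Named list: per column, `type` (`character`, `integer`,
#'   `numeric`, `logical`), optional `min` and `values`. See
#'   `qpcr_schema()`, `annotation_schema()`, `coverage_schema()`,
#'   `env_schema()`.
#' @return Validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         "; expected schema: ", paste(names(schema), collapse = ", "))
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    warning("extra column(s) preserved: ", paste(extra, collapse = ", "))
  for (col in names(schema)) {
    spec <- schema[[col]]
    df[[col]] <- switch(spec$type,
      character = as.character(df[[col]]),
      integer = {
        v <- suppressWarnings(as.integer(df[[col]]))
        if (anyNA(v) && !anyNA(df[[col]]))
          stop("column ", col, ": non-integer value(s) in row(s) ",
               paste(which(is.na(v)), collapse = ", "))
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (sum(is.na(v)) > sum(is.na(df[[col]])))
          stop("column ", col, ": non-numeric value(s)")
        v
      },
      logical = as.logical(df[[col]]),
      stop("unknown type for column ", col)
    )
    if (!is.null(spec$min)) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < spec$min)
      if (length(bad))
        stop("column ", col, ": value(s) below ", spec$min,
             " in row(s) ", paste(bad, collapse = ", "))
    }
    if (!is.null(spec$values)) {
      bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% spec$values))
      if (length(bad))
        stop("column ", col, ": invalid value(s) in row(s) ",
             paste(bad, collapse = ", "))
    }
  }
  df
}

#' Write a table as canonical TSV
#'
#' Tab-delimited, UTF-8, unquoted, no row names; numeric columns serialized
#' at 17 significant digits so that rereading reproduces the values exactly
#' and determinism is testable on the files themselves.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
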