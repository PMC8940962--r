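#' Filter a gene catalog down to nitrogen-pathway genes
#'
#' Keeps genes whose KO belongs to the packaged nitrogen-metabolism KO set
#' and maps each to its gene symbol and pathway category. KOs shared between
#' enzymes (K00370 narG/narZ/nxrA, K00371 narH/narY/nxrB) keep the combined
#' symbol. Rows whose KO does not look like a KO identifier (Kddddd) are
#' dropped with a warning.
#'
#' @param annotations data.frame with at least `gene_id` and `ko` columns.
#' @param ko_map KO map, default [nitrogen_ko_map()].
#' @return data.frame `gene_id`, `ko`, `symbol`, `category`, `taxon`.
#' @export
filter_nitrogen_genes <- function(annotations, ko_map = nitrogen_ko_map()) {
  if (!"ko" %in% names(annotations))
    stop("annotation table lacks a 'ko' column")
  ok_format <- grepl("^K[0-9]{5}$", annotations$ko)
  if (any(!ok_format)) {
    warning(sum(!ok_format), " row(s) with malformed KO dropped")
    annotations <- annotations[ok_format, , drop = FALSE]
  }
  hit <- annotations$ko %in% ko_map$ko
  out <- annotations[hit, , drop = FALSE]
  idx <- match(out$ko, ko_map$ko)
  out$symbol <- ko_map$symbol[idx]
  out$category <- ko_map$category[idx]
  if (is.null(out$taxon)) out$taxon <- NA_character_
  rownames(out) <- NULL
  out[, c("gene_id", "ko", "symbol", "category", "taxon")]
}

#' Nitrogen-focused Coverage per Million (N-CPM)
#'
#' Normalizes per-layer gene coverage so that each layer's nitrogen-pathway
#' genes sum to one million: `ncpm(g, l) = coverage(g, l) / sum over nitrogen
#' genes of coverage(., l) * 1e6`. The denominator is the nitrogen gene set
#' by default (the metric is nitrogen-focused); set `denominator = "all"` to
#' normalize against all genes in the coverage table instead.
#'
#' @param coverage Long data.frame `gene_id`, `layer`, `coverage`.
#' @param nitrogen_genes Output of [filter_nitrogen_genes()] (or any
#'   data.frame with a `gene_id` column naming the nitrogen genes).
#' @param denominator `"nitrogen"` (default) or `"all"`.
#' @return data.frame `gene_id`, `layer`, `ncpm`, restricted to nitrogen
#'   genes.
#' @export
compute_ncpm <- function(coverage, nitrogen_genes,
                         denominator = c("nitrogen", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("gene_id", "layer", "coverage") %in% names(coverage)))
  if (any(coverage$coverage < 0)) stop("coverage must be nonnegative")
  ids <- unique(nitrogen_genes$gene_id)
  nit <- coverage[coverage$gene_id %in% ids, , drop = FALSE]
  denom_tab <- if (denominator == "nitrogen") nit else coverage
  totals <- tapply(denom_tab$coverage, denom_tab$layer, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("zero total nitrogen coverage in layer(s): ",
         paste(zero, collapse = ", "))
  nit$ncpm <- as.numeric(nit$coverage / totals[as.character(nit$layer)]) * 1e6
  nit <- nit[order(nit$gene_id, nit$layer),
             c("gene_id", "layer", "ncpm")]
  rownames(nit) <- NULL
  nit
}

#' Fraction of Depth-Integrated Coverage (FDIC)
#'
#' Expresses each gene's per-layer value as a fraction of its total across
#' layers: `fdic(g, l) = value(g, l) / sum over layers of value(g, .)`, so
#' each gene's profile sums to 1. Computed on N-CPM values by default in the
#' pipeline (relative coverage across depths); any nonnegative long table
#' works. Genes with all-zero values are excluded and reported in the
#' `"all_zero_genes"` attribute.
#'
#' @param x Long data.frame `gene_id`, `layer` and a value column (`ncpm` or
#'   `coverage`, auto-detected; or name it via `value_col`).
#' @param value_col Optional name of the value column.
#' @return data.frame `gene_id`, `layer`, `fdic` with attribute
#'   `all_zero_genes`.
#' @export
compute_fdic <- function(x, value_col = NULL) {
  stopifnot(all(c("gene_id", "layer") %in% names(x)))
  if (is.null(value_col))
    value_col <- intersect(c("ncpm", "coverage", "value"), names(x))[1]
  if (is.na(value_col) || is.null(value_col))
    stop("no value column found (expected ncpm, coverage or value)")
  v <- x[[value_col]]
  if (any(v < 0)) stop("values must be nonnegative")
  totals <- tapply(v, x$gene_id, sum)
  zero_ids <- names(totals)[totals == 0]
  keep <- !(x$gene_id %in% zero_ids)
  out <- data.frame(
    gene_id = x$gene_id[keep], layer = x$layer[keep],
    fdic = as.numeric(v[keep] / totals[x$gene_id[keep]]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$layer), ]
  rownames(out) <- NULL
  attr(out, "all_zero_genes") <- zero_ids
  out
}

#' Unique-gene accounting per pathway
#'
#' Counts unique genes per gene symbol, per pathway category, and overall.
#' Categories partition the gene set, so the overall total equals the sum of
#' the category counts. When narI/narV genes are present, a footnote records
#' that they are counted under denitrification although they also participate
#' in DNRA.
#'
#' @param nitrogen_genes Output of [filter_nitrogen_genes()].
#' @return list with `per_symbol` (symbol, category, n_genes), `per_category`
#'   (category, n_genes), `total` and `footnote` (possibly NA); class
#'   `pathway_summary`.
#' @export
pathway_summary <- function(nitrogen_genes) {
  stopifnot(all(c("gene_id", "symbol", "category") %in% names(nitrogen_genes)))
  if (anyNA(nitrogen_genes$category))
    stop("gene(s) without a category: ",
         paste(nitrogen_genes$gene_id[is.na(nitrogen_genes$category)],
               collapse = ", "))
  genes <- nitrogen_genes[!duplicated(nitrogen_genes$gene_id), ]
  per_symbol <- as.data.frame(
    table(symbol = genes$symbol), stringsAsFactors = FALSE)
  names(per_symbol)[2] <- "n_genes"
  per_symbol$category <-
    genes$category[match(per_symbol$symbol, genes$symbol)]
  per_symbol <- per_symbol[order(per_symbol$category, per_symbol$symbol),
                           c("symbol", "category", "n_genes")]
  rownames(per_symbol) <- NULL
  per_category <- as.data.frame(
    table(category = genes$category), stringsAsFactors = FALSE)
  names(per_category)[2] <- "n_genes"
  footnote <- if ("narI/narV" %in% genes$symbol)
    paste("narI/narV genes are counted under denitrification;",
          "they are also associated with DNRA.") else NA_character_
  structure(
    list(per_symbol = per_symbol, per_category = per_category,
         total = nrow(genes), footnote = footnote),
    class = "pathway_summary"
  )
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat("Nitrogen pathway gene accounting:", x$total, "unique genes\n\n")
  print(x$per_category, row.names = FALSE)
  if (!is.na(x$footnote)) cat("\nNote:", x$footnote, "\n")
  invisible(x)
}

#' Depth trend of normalized coverage between two layers
#'
#' Fold change of mean N-CPM over a gene selection between two layers, with a
#' direction label (`increasing`, `decreasing`, or `flat` within a relative
#' tolerance around fold = 1).
#'
#' @param ncpm data.frame `gene_id`, `layer`, `ncpm`.
#' @param genes Character vector of gene ids to average over (default: all).
#' @param layer_a,layer_b The two layers compared; the fold is
#'   mean(layer_a) / mean(layer_b).
#' @param flat_tol Relative tolerance within which the profile is called flat
#'   (default 0.05).
#' @return list with `fold`, `direction` and `infinite` flag (TRUE when the
#'   layer_b mean is zero).
#' @export
depth_trend <- function(ncpm, genes = NULL, layer_a, layer_b,
                        flat_tol = 0.05) {
  stopifnot(all(c("gene_id", "layer", "ncpm") %in% names(ncpm)))
  if (!is.null(genes)) ncpm <- ncpm[ncpm$gene_id %in% genes, , drop = FALSE]
  va <- ncpm$ncpm[ncpm$layer == layer_a]
  vb <- ncpm$ncpm[ncpm$layer == layer_b]
  if (!length(va) || !length(vb))
    stop("layer ", if (!length(va)) layer_a else layer_b,
         " absent from table")
  ma <- mean(va); mb <- mean(vb)
  if (mb == 0)
    return(list(fold = Inf, direction = "increasing", infinite = TRUE))
  fold <- ma / mb
  direction <- if (abs(fold - 1) <= flat_tol) "flat"
  else if (fold > 1) "increasing" else "decreasing"
  list(fold = fold, direction = direction, infinite = FALSE)
}
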