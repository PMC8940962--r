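#' Pairwise p-distances between aligned protein rows
#'
#' Proportion of mismatching residues over compared columns; columns with a
#' gap in either row are excluded from the comparison (pairwise deletion).
#'
#' @param rows Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix of distances in \[0, 1\] with zero
#'   diagonal.
#' @export
pdistance_matrix <- function(rows) {
  stopifnot(length(rows) >= 3L, !is.null(names(rows)))
  w <- nchar(rows)
  if (length(unique(w)) != 1L) stop("rows differ in length")
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns for pair ", names(rows)[i], " / ",
             names(rows)[j])
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()], followed by a post-pass that
#' clamps negative branch lengths to zero and moves each clamped deficit onto
#' the first sibling branch (deterministic by edge order), preserving
#' path-length sums between the affected leaves' subtrees.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal (or a
#'   `dist`).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be nonnegative")
  tree <- ape::nj(stats::as.dist(d))
  # clamp negatives one at a time; moving a deficit can turn a sibling
  # negative or positive, so recheck until none remain
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs))
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
  }
  tree
}

#' Assign each query leaf to a reference clade
#'
#' Walks from each query tip toward the root and finds the smallest clade
#' containing the query and at least one labeled reference. If all
#' references inside that clade belong to one class, the query is assigned
#' that class; otherwise it is `"unresolved"`. Operates on the tree's rooted
#' representation; [build_hao_tree()] roots at a nitrate-reductase-like
#' reference (outgroup) when one is present.
#'
#' @param tree An [ape::phylo] tree containing reference and query leaves.
#' @param ref_labels Named character vector: class per reference leaf.
#' @param queries Query leaf names (default: all non-reference leaves).
#' @return data.frame `id`, `clade`.
#' @export
assign_clade <- function(tree, ref_labels, queries = NULL) {
  tips <- tree$tip.label
  refs <- intersect(names(ref_labels), tips)
  if (!length(refs)) stop("tree contains no labeled reference leaves")
  if (is.null(queries)) queries <- setdiff(tips, refs)
  edge <- tree$edge
  parent_of <- function(node) {
    p <- edge[edge[, 2] == node, 1]
    if (length(p)) p else NA_integer_
  }
  clade_tips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- edge[edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  out <- lapply(queries, function(qt) {
    node <- which(tips == qt)
    if (!length(node)) stop("query leaf not in tree: ", qt)
    clade <- "unresolved"
    cur <- parent_of(node)
    while (!is.na(cur)) {
      ct <- clade_tips(cur)
      refs_in <- intersect(ct, refs)
      if (length(refs_in)) {
        cls <- unique(ref_labels[refs_in])
        clade <- if (length(cls) == 1L) unname(cls) else "unresolved"
        break
      }
      cur <- parent_of(cur)
    }
    data.frame(id = qt, clade = clade, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the HAO protein tree and assign query clades
#'
#' Combines the reference alignment rows with the profile-aligned query rows
#' (reference columns only; insertions are excluded by construction),
#' computes p-distances, builds a neighbor-joining tree, roots it at the
#' first nitrate-reductase-like reference when present, and assigns each
#' query to a reference clade.
#'
#' @param queries Named character vector of query protein sequences.
#' @param refaln A [load_hao_reference()] object.
#' @return list of class `hao_tree`: `tree` ([ape::phylo]), `newick`
#'   (string), `clades` (data.frame `id`, `clade`), `distances`.
#' @export
build_hao_tree <- function(queries, refaln) {
  stopifnot(inherits(refaln, "hao_refaln"))
  alns <- lapply(queries, align_query_to_reference, refaln = refaln)
  qrows <- vapply(alns, `[[`, character(1), "aligned")
  rows <- c(refaln$aln, qrows)
  d <- pdistance_matrix(rows)
  tree <- nj_tree(d)
  outgroup <- names(refaln$class)[refaln$class == "nitrate-reductase-like"]
  outgroup <- intersect(outgroup, tree$tip.label)
  if (length(outgroup))
    tree <- ape::root(tree, outgroup = outgroup[1], resolve.root = TRUE)
  clades <- assign_clade(tree, refaln$class, queries = names(queries))
  structure(
    list(tree = tree, newick = ape::write.tree(tree), clades = clades,
         distances = d),
    class = "hao_tree"
  )
}

#' @export
print.hao_tree <- function(x, ...) {
  cat("HAO neighbor-joining tree:", length(x$tree$tip.label), "leaves\n")
  print(table(x$clades$clade))
  invisible(x)
}
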