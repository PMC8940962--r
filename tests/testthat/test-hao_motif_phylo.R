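ref <- load_hao_reference()

test_that("anchor-column mapping matches the scan-and-count oracle", {
  # ungapped row: position equals column
  plain <- structure(list(aln = c(r = "ACDEF"), class = c(r = "AOB-HAO"),
                          anchor_ref = "r", anchor_pos = 3L),
                     class = "hao_refaln")
  expect_equal(map_anchor_column(plain), 3L)
  gapped <- plain
  gapped$aln <- c(r = "AC-DE")
  expect_equal(map_anchor_column(gapped), 4L)  # third residue is D
  expect_error(map_anchor_column(plain, pos = 9), "beyond")
  # random gapped rows
  set.seed(61)
  for (i in 1:1000) {
    chars <- sample(c("-", "A", "C", "G"), 30, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2))
    row <- paste(chars, collapse = "")
    nres <- sum(chars != "-")
    if (nres == 0) next
    pos <- sample(nres, 1)
    fake <- plain
    fake$aln <- c(r = row)
    expect_equal(map_anchor_column(fake, pos = pos),
                 oracle_anchor_column(row, pos))
  }
})

test_that("the packaged anchor column holds the reference tyrosine", {
  col <- map_anchor_column(ref)
  row <- strsplit(ref$aln[[ref$anchor_ref]], "")[[1]]
  expect_equal(row[col], "Y")
  # epsilon references carry tryptophan at the same column
  for (id in names(ref$class)[ref$class == "epsilonHao"]) {
    expect_equal(strsplit(ref$aln[[id]], "")[[1]][col], "W")
  }
})

test_that("profile alignment reproduces reference gap patterns", {
  col <- map_anchor_column(ref)
  for (id in names(ref$aln)) {
    ungapped <- gsub("-", "", ref$aln[[id]])
    aln <- align_query_to_reference(ungapped, ref)
    expect_identical(aln$aligned, unname(ref$aln[[id]]))
    expect_equal(nrow(aln$insertions), 0)
  }
})

test_that("deletions shift gaps without moving reference columns", {
  id <- names(ref$aln)[1]
  ungapped <- gsub("-", "", ref$aln[[id]])
  # delete residue 20: one extra gap, anchor column still classifies
  del <- paste0(substr(ungapped, 1, 19), substr(ungapped, 21, nchar(ungapped)))
  aln <- align_query_to_reference(del, ref)
  expect_equal(nchar(aln$aligned), nchar(ref$aln[[id]]))
  gaps_ref <- lengths(regmatches(ref$aln[[id]], gregexpr("-", ref$aln[[id]])))
  gaps_query <- lengths(regmatches(aln$aligned, gregexpr("-", aln$aligned)))
  expect_equal(gaps_query, gaps_ref + 1)
  # insertions are recorded separately and excluded from columns
  ins <- paste0(substr(ungapped, 1, 40), "AAAA",
                substr(ungapped, 41, nchar(ungapped)))
  aln_ins <- align_query_to_reference(ins, ref)
  expect_equal(nchar(aln_ins$aligned), nchar(ref$aln[[id]]))
  expect_equal(nrow(aln_ins$insertions), 4)
  expect_error(align_query_to_reference("", ref), "empty")
})

test_that("the DP score is optimal over alternative placements", {
  # score an explicit gap placement of the query under the same model:
  # mean BLOSUM62 of the residue against each column's non-gap residues,
  # affine gaps open 11 extend 1 (length-L gap costs 11 + L)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b62 <- env$BLOSUM62
  score_placement <- function(aligned_row, refaln) {
    cols <- do.call(rbind, strsplit(unname(refaln$aln), ""))
    chars <- strsplit(aligned_row, "")[[1]]
    sc <- 0
    run <- 0
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        run <- run + 1
      } else {
        if (run > 0) { sc <- sc - 11 - run; run <- 0 }
        res <- cols[, i]; res <- res[res != "-"]
        if (length(res)) sc <- sc + mean(b62[res, chars[i]])
      }
    }
    if (run > 0) sc <- sc - 11 - run
    sc
  }
  set.seed(77)
  id <- names(ref$aln)[1]
  q <- gsub("-", "", ref$aln[[id]])
  dp <- align_query_to_reference(q, ref)
  expect_equal(dp$score, score_placement(dp$aligned, ref), tolerance = 1e-9)
  # random alternative placements of the same residues never score higher
  m <- nchar(q)
  n <- nchar(ref$aln[[id]])
  qchars <- strsplit(q, "")[[1]]
  for (i in 1:20) {
    slots <- sort(sample(n, m))
    alt <- rep("-", n)
    alt[slots] <- qchars
    expect_lte(score_placement(paste(alt, collapse = ""), ref), dp$score)
  }
})

test_that("motif calls follow the anchor residue rules", {
  col <- map_anchor_column(ref)
  # the oxidative reference classifies as oxidative against itself
  id_ox <- names(ref$class)[ref$class == "AOB-HAO"][1]
  call_ox <- classify_hao(
    align_query_to_reference(gsub("-", "", ref$aln[[id_ox]]), ref), col)
  expect_equal(call_ox$call, "oxidative-HAO-like")
  expect_equal(call_ox$anchor_residue, "Y")
  # an epsilon reference has W and the -8 methionine
  id_ep <- names(ref$class)[ref$class == "epsilonHao"][1]
  call_ep <- classify_hao(
    align_query_to_reference(gsub("-", "", ref$aln[[id_ep]]), ref), col)
  expect_equal(call_ep$call, "epsilonHao-like")
  expect_true(call_ep$met_minus8)
  # a gap at the anchor column is ambiguous
  row <- strsplit(unname(ref$aln[[id_ox]]), "")[[1]]
  row[col] <- "-"
  expect_equal(classify_hao(paste(row, collapse = ""), col)$call, "ambiguous")
  # X at the anchor column is ambiguous, not an error
  row[col] <- "X"
  expect_equal(classify_hao(paste(row, collapse = ""), col)$call, "ambiguous")
  expect_error(classify_hao(paste(row, collapse = ""), 10000), "beyond")
})

test_that("motif calls are invariant to query renaming and order", {
  cfg <- sim_config(seed = 71, n_oxidative_hao = 3, n_epsilon_hao = 3)
  pr <- generate_hao_proteins(cfg, ref)
  calls <- classify_hao_set(pr$sequences, ref)
  shuffled <- rev(pr$sequences)
  names(shuffled) <- paste0("q", seq_along(shuffled))
  calls2 <- classify_hao_set(shuffled, ref)
  expect_equal(rev(calls2$call), calls$call)
})

test_that("p-distance counts mismatches over comparable columns", {
  rows <- c(a = "AAAA", b = "AATT", c = "A-CD", d = "ABCD")
  d <- pdistance_matrix(rows)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "a"], 0)
  # gapped pair compares 3 columns (A.CD vs A.CD without col 2)
  expect_equal(d["c", "d"], 0)
  rows2 <- c(a = "A--", b = "-A-", c = "AAA")
  expect_error(pdistance_matrix(rows2), "a / b")
})

test_that("neighbor joining matches the three-point closed form", {
  d <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(d)
  # closed form: bx = (dxy + dxz - dyz)/2, etc.
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(unname(lens["x"]), (3 + 8 - 9) / 2)
  expect_equal(unname(lens["y"]), (3 + 9 - 8) / 2)
  expect_equal(unname(lens["z"]), (8 + 9 - 3) / 2)
})

test_that("NJ reconstructs additive trees exactly", {
  set.seed(62)
  for (i in 1:50) {
    true_tree <- ape::rtree(sample(5:10, 1))
    d <- ape::cophenetic.phylo(true_tree)
    d <- d[order(rownames(d)), order(colnames(d))]
    got <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative NJ branches are clamped with the deficit moved over", {
  # a non-additive matrix known to produce a negative internal branch
  set.seed(63)
  repeat {
    n <- 6
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    if (sum(ape::nj(as.dist(d))$edge.length < 0) == 1) break
  }
  raw <- ape::nj(as.dist(d))
  clamped <- nj_tree(d)
  expect_true(all(clamped$edge.length >= 0))
  expect_identical(clamped$edge, raw$edge)  # topology untouched
  expect_equal(sum(clamped$edge.length), sum(abs(raw$edge.length)),
               tolerance = 1e-12)
})

test_that("clade assignment respects the mixed-clade rule", {
  tree <- ape::read.tree(
    text = "((q1:1,eps1:1):1,((q2:1,(aob1:1,eps2:1):1):1,out1:1):1);")
  labels <- c(eps1 = "epsilonHao", eps2 = "epsilonHao", aob1 = "AOB-HAO",
              out1 = "nitrate-reductase-like")
  got <- assign_clade(tree, labels, queries = c("q1", "q2"))
  expect_equal(got$clade[got$id == "q1"], "epsilonHao")
  expect_equal(got$clade[got$id == "q2"], "unresolved")
  # reference leaves map to their own label
  self <- assign_clade(tree, labels, queries = "eps1")
  expect_equal(self$clade, "epsilonHao")
  expect_error(assign_clade(tree, c(zz = "AOB-HAO")), "no labeled")
})

test_that("end-to-end recovery: motif and clade match the ground truth", {
  cfg <- sim_config(seed = 64, n_oxidative_hao = 10, n_epsilon_hao = 10,
                    hao_mutation_rate = 0.05)
  pr <- generate_hao_proteins(cfg, ref)
  calls <- classify_hao_set(pr$sequences, ref)
  expect_equal(calls$call, pr$truth$class)  # 100% motif recovery
  # clade recovery across seeds
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfgs <- sim_config(seed = s, n_oxidative_hao = 5, n_epsilon_hao = 5,
                       hao_mutation_rate = 0.05)
    prs <- generate_hao_proteins(cfgs, ref)
    tr <- build_hao_tree(prs$sequences, ref)
    truth <- prs$truth$class[match(tr$clades$id, prs$truth$id)]
    hits <- hits + sum(clade_to_truth[tr$clades$clade] == truth, na.rm = TRUE)
    total <- total + nrow(tr$clades)
  }
  expect_gte(hits / total, 0.95)
})
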