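#' Configuration for a full pipeline run
#'
#' @param outdir Output directory (created if absent).
#' @param simulate If TRUE (default), all inputs come from the synthetic-data
#'   generators under `sim`; otherwise the `paths` list must name `qpcr`,
#'   `annotation`, `coverage`, `env` TSV files and a `proteins` FASTA.
#' @param sim A [sim_config()].
#' @param paths Named list of input paths (used when `simulate = FALSE`).
#' @param alpha Significance level used throughout.
#' @param basis qPCR normalization basis for ratios, `"per_g"` or
#'   `"per_ng"`.
#' @param simprof_perms Permutations per SIMPROF pool.
#' @param nmds_restarts NMDS random restarts.
#' @param seed Seed for the community-statistics randomness (SIMPROF, NMDS);
#'   generator seeds live in `sim`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            simulate = TRUE,
                            sim = sim_config(),
                            paths = list(),
                            alpha = 0.05,
                            basis = "per_g",
                            simprof_perms = 999,
                            nmds_restarts = 50,
                            seed = 7L) {
  if (!simulate) {
    need <- c("qpcr", "annotation", "coverage", "env", "proteins")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "))
    absent <- need[!vapply(paths[need], file.exists, logical(1))]
    if (length(absent))
      stop("input file(s) not found: ",
           paste(unlist(paths[absent]), collapse = ", "))
  }
  structure(
    list(outdir = outdir, simulate = simulate, sim = sim, paths = paths,
         alpha = alpha, basis = basis, simprof_perms = simprof_perms,
         nmds_restarts = nmds_restarts, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages in dependency order: input generation (or loading),
#' qPCR profiling (dual-basis normalization, cDNA/DNA ratios, layer tests
#' with letter displays), nitrogen coverage accounting (N-CPM, FDIC, pathway
#' summary), community statistics on both the qPCR ratio matrix and the
#' N-CPM layer matrix (Bray-Curtis, SIMPROF dendrogram, NMDS with
#' environmental vector overlay, Spearman matrix), and HAO protein
#' classification (motif calls, NJ tree, clades). Each stage writes its
#' artifacts before the next begins, and a stage failure is recorded in the
#' report without disturbing completed outputs. Reports carry no timestamps,
#' so rerunning an identical configuration reproduces every output file
#' byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return list of class `run_report`: per-stage status and summaries, the
#'   config echo (including every seed), and collected warnings. Also
#'   written to `report.json` in `outdir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    package_version = as.character(utils::packageVersion("nitromat")),
    config = list(
      simulate = config$simulate, alpha = config$alpha,
      basis = config$basis, simprof_perms = config$simprof_perms,
      nmds_restarts = config$nmds_restarts, seed = config$seed,
      sim_seed = if (config$simulate) config$sim$seed else NA
    ),
    stages = list(), warnings = character()
  )
  note <- function(w) report$warnings <<- c(report$warnings, conditionMessage(w))
  stage <- function(name, fun) {
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        structure(list(error = conditionMessage(e)), class = "stage_error")),
      warning = function(w) { note(w); invokeRestart("muffleWarning") }
    )
    if (inherits(res, "stage_error")) {
      report$stages[[name]] <<- list(status = "failed", cause = res$error)
      NULL
    } else {
      report$stages[[name]] <<- c(list(status = "ok"), res$summary)
      res$value
    }
  }

  inputs <- stage("inputs", function() {
    if (config$simulate) {
      panel <- simulate_qpcr_panel(config$sim)
      catalog <- simulate_gene_catalog(config$sim)
      prot <- generate_hao_proteins(config$sim)
      env <- make_env_fixture()
      write_tsv(panel, file.path(outdir, "qpcr_panel.tsv"))
      write_tsv(catalog$annotation, file.path(outdir, "annotation.tsv"))
      write_tsv(catalog$coverage, file.path(outdir, "coverage.tsv"))
      write_tsv(env, file.path(outdir, "environment.tsv"))
      write_fasta(prot$sequences, file.path(outdir, "hao_queries.faa"))
      write_tsv(prot$truth, file.path(outdir, "hao_truth.tsv"))
      list(value = list(qpcr = panel, annotation = catalog$annotation,
                        coverage = catalog$coverage, env = env,
                        proteins = prot$sequences),
           summary = list(n_qpcr_records = nrow(panel),
                          n_genes = nrow(catalog$annotation),
                          n_proteins = length(prot$sequences)))
    } else {
      p <- config$paths
      list(value = list(
        qpcr = read_table(p$qpcr, qpcr_schema()),
        annotation = read_table(p$annotation, annotation_schema()),
        coverage = read_table(p$coverage, coverage_schema()),
        env = read_table(p$env, env_schema()),
        proteins = read_fasta(p$proteins)),
        summary = list())
    }
  })
  if (is.null(inputs)) {
    report$stages$inputs$fatal <- TRUE
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(structure(report, class = "run_report"))
  }

  ratios_wide <- NULL
  stage("qpcr_profiles", function() {
    norm <- normalize_copies(inputs$qpcr)
    ratios <- expression_ratio(norm, basis = config$basis)
    col <- paste0("copies_", config$basis)
    vals <- data.frame(marker = norm$marker, layer = norm$layer,
                       value = norm[[col]], below_lod = norm$below_lod)
    vals <- vals[norm$template == "cDNA", ]
    tests <- test_layers(vals, alpha = config$alpha)
    write_tsv(ratios, file.path(outdir, "ratios.tsv"))
    letters_df <- do.call(rbind, lapply(names(tests), function(m)
      data.frame(marker = m, layer = names(tests[[m]]$letters),
                 letters = unname(tests[[m]]$letters),
                 stringsAsFactors = FALSE)))
    write_tsv(letters_df, file.path(outdir, "letters.tsv"))
    jsonlite::write_json(
      lapply(tests, function(t)
        list(H = t$H, df = t$df, p_global = t$p_global,
             letters = as.list(t$letters))),
      file.path(outdir, "qpcr_tests.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ratios_wide <<- stats::reshape(
      ratios[, c("marker", "layer", "ratio")],
      direction = "wide", idvar = "layer", timevar = "marker")
    list(value = tests,
         summary = list(n_markers_tested = length(tests)))
  })

  ncpm <- NULL
  stage("nitrogen_coverage", function() {
    nit <- filter_nitrogen_genes(inputs$annotation)
    ncpm <<- compute_ncpm(inputs$coverage, nit)
    fdic <- compute_fdic(ncpm)
    summ <- pathway_summary(nit)
    write_tsv(ncpm, file.path(outdir, "ncpm.tsv"))
    write_tsv(fdic, file.path(outdir, "fdic.tsv"))
    jsonlite::write_json(
      list(total = summ$total, per_category = summ$per_category,
           per_symbol = summ$per_symbol, footnote = summ$footnote),
      file.path(outdir, "pathway_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = summ,
         summary = list(n_nitrogen_genes = summ$total))
  })

  stage("community_stats", function() {
    # qPCR ratio matrix: layers x markers; undefined ratios treated as absent
    rw <- ratios_wide
    if (is.null(rw)) stop("qPCR stage did not produce ratios")
    rownames(rw) <- paste0("Layer", rw$layer)
    rmat <- as.matrix(rw[, -1, drop = FALSE])
    colnames(rmat) <- sub("^ratio\\.", "", colnames(rmat))
    na_n <- sum(is.na(rmat))
    if (na_n) warning(na_n, " undefined ratio(s) treated as 0")
    rmat[is.na(rmat)] <- 0
    std <- standardize_samples(rmat)
    res <- bray_curtis(std)
    fit <- nmds(res, n_restarts = config$nmds_restarts, seed = config$seed)
    env_vars <- inputs$env[match(rw$layer, inputs$env$layer),
                           c("o2_um", "nh4_um", "no3_um", "po4_um"),
                           drop = FALSE]
    overlay <- vector_overlay(fit, env_vars)
    cors <- spearman_matrix(rmat, env_vars)
    write_tsv(as.data.frame(unclass(res)), file.path(outdir, "resemblance_ratios.tsv"))
    write_tsv(data.frame(sample = rownames(fit$points), fit$points,
                         stringsAsFactors = FALSE),
              file.path(outdir, "nmds.tsv"))
    write_tsv(overlay, file.path(outdir, "nmds_vectors.tsv"))
    write_tsv(as.data.frame(cors$r), file.path(outdir, "spearman_r.tsv"))
    write_tsv(as.data.frame(cors$p), file.path(outdir, "spearman_p.tsv"))

    # metagenome layer structure: N-CPM matrix, layers x genes
    if (is.null(ncpm)) stop("nitrogen coverage stage did not produce N-CPM")
    nw <- stats::reshape(ncpm, direction = "wide", idvar = "layer",
                         timevar = "gene_id")
    rownames(nw) <- paste0("Layer", nw$layer)
    nmat <- as.matrix(nw[, -1, drop = FALSE])
    sp <- simprof(standardize_samples(nmat),
                  n_expected = config$simprof_perms,
                  n_null = config$simprof_perms,
                  alpha = config$alpha, seed = config$seed)
    write_tsv(sp$nodes, file.path(outdir, "simprof_nodes.tsv"))
    writeLines(ape::write.tree(ape::as.phylo(sp$hclust)),
               file.path(outdir, "dendrogram.nwk"))
    jsonlite::write_json(
      list(alpha = sp$alpha, seed = sp$seed,
           n_expected = sp$n_expected, n_null = sp$n_null,
           nodes = sp$nodes),
      file.path(outdir, "dendrogram.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(value = list(nmds = fit, simprof = sp),
         summary = list(nmds_stress = fit$stress,
                        n_significant_nodes = sum(sp$nodes$significant)))
  })

  stage("hao_classification", function() {
    refaln <- load_hao_reference()
    calls <- classify_hao_set(inputs$proteins, refaln)
    tree <- build_hao_tree(inputs$proteins, refaln)
    write_tsv(calls, file.path(outdir, "hao_calls.tsv"))
    writeLines(tree$newick, file.path(outdir, "hao_tree.nwk"))
    write_tsv(tree$clades, file.path(outdir, "hao_clades.tsv"))
    list(value = list(calls = calls, tree = tree),
         summary = list(
           n_oxidative = sum(calls$call == "oxidative-HAO-like"),
           n_epsilon = sum(calls$call == "epsilonHao-like"),
           n_ambiguous = sum(calls$call == "ambiguous")))
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("nitromat pipeline run\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-20s %s\n", nm, st$status))
    if (st$status == "failed") cat("    cause:", st$cause, "\n")
  }
  if (length(x$warnings))
    cat(length(x$warnings), "warning(s) recorded\n")
  invisible(x)
}
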