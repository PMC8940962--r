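#' Simulation configuration for the synthetic mat study
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generators. Defaults emulate the study design the pipeline targets:
#' seven 1-mm layers sampled with three replicate cores, nine qPCR/RT-qPCR
#' markers quantified on DNA and cDNA templates, a four-layer metagenome gene
#' catalog whose nitrogen categories follow depth trends of the expected sign,
#' and two labeled HAO protein families.
#'
#' Each generator draws from its own RNG stream, seeded from `seed` by a
#' stable per-table offset, so generating one table never perturbs another.
#'
#' @param seed Integer seed controlling all generators.
#' @param n_layers Number of 1-mm layers for the qPCR panel (default 7).
#' @param n_replicates Replicate cores per layer (default 3).
#' @param markers Marker names assayed by qPCR/RT-qPCR.
#' @param n_genes_per_category Named integer vector: unique genes simulated
#'   per pathway category (plus a `background` category of non-nitrogen
#'   genes, present so that nitrogen filtering is nontrivial).
#' @param n_coverage_layers Layers in the metagenome coverage table
#'   (default 4, the photic/chemocline zone pooled for sequencing).
#' @param depth_trend Named numeric vector of log10-abundance slopes per mm
#'   for the coverage categories. Defaults encode the depth behaviour the
#'   pipeline is designed to resolve: nif and assimilatory reduction genes
#'   decline with depth, DNRA/hao/hcp/denitrification genes increase,
#'   background genes are flat.
#' @param noise_sd_log10 Replicate/gene noise standard deviation on the
#'   log10 scale (lognormal noise model; copy numbers span orders of
#'   magnitude).
#' @param detection_limit qPCR detection limit in copies per reaction;
#'   records below it are flagged, not dropped.
#' @param mat_mass_g Mass of mat per slice extraction, grams.
#' @param na_mass_ng Nucleic acid input per reaction, nanograms.
#' @param n_oxidative_hao,n_epsilon_hao Number of synthetic HAO query
#'   proteins per family.
#' @param hao_mutation_rate Per-residue substitution probability applied to
#'   the family template when generating HAO queries (motif residues are
#'   preserved); must lie in \[0, 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_layers = 7L,
                       n_replicates = 3L,
                       markers = qpcr_markers(),
                       n_genes_per_category = default_gene_counts(),
                       n_coverage_layers = 4L,
                       depth_trend = default_depth_trends(),
                       noise_sd_log10 = 0.15,
                       detection_limit = 100,
                       mat_mass_g = 0.25,
                       na_mass_ng = 10,
                       n_oxidative_hao = 10L,
                       n_epsilon_hao = 10L,
                       hao_mutation_rate = 0.05) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_layers < 2L) stop("n_layers must be >= 2")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (noise_sd_log10 < 0) stop("noise_sd_log10 must be >= 0")
  if (detection_limit <= 0) stop("detection_limit must be positive")
  if (hao_mutation_rate < 0 || hao_mutation_rate >= 1)
    stop("hao_mutation_rate must be in [0, 1)")
  if (is.null(names(n_genes_per_category)) || any(names(n_genes_per_category) == ""))
    stop("n_genes_per_category must be a named vector")
  known <- c(nitrogen_categories(), "background")
  bad <- setdiff(names(n_genes_per_category), known)
  if (length(bad))
    stop("unknown category name(s): ", paste(bad, collapse = ", "))
  bad_trend <- setdiff(names(depth_trend), known)
  if (length(bad_trend))
    stop("unknown category in depth_trend: ", paste(bad_trend, collapse = ", "))
  structure(
    list(
      seed = as.integer(seed),
      n_layers = as.integer(n_layers),
      n_replicates = as.integer(n_replicates),
      markers = markers,
      n_genes_per_category = n_genes_per_category,
      n_coverage_layers = as.integer(n_coverage_layers),
      depth_trend = depth_trend,
      noise_sd_log10 = noise_sd_log10,
      detection_limit = detection_limit,
      mat_mass_g = mat_mass_g,
      na_mass_ng = na_mass_ng,
      n_oxidative_hao = as.integer(n_oxidative_hao),
      n_epsilon_hao = as.integer(n_epsilon_hao),
      hao_mutation_rate = hao_mutation_rate
    ),
    class = "sim_config"
  )
}

#' Marker names of the qPCR/RT-qPCR panel
#' @return Character vector of the nine assayed markers.
#' @export
qpcr_markers <- function() {
  c("Bacteria-16S", "Archaea-16S", "nifH", "Archaeal-amoA", "Bacterial-amoA",
    "Nitrospira-nxrB", "nosZ", "nirS", "Planctomycetes-16S")
}

#' @rdname sim_config
#' @export
default_gene_counts <- function() {
  c(
    "nitrogen fixation" = 60L,
    "assimilatory nitrate reduction" = 15L,
    "DNRA" = 38L,
    "hydroxylamine dehydrogenase" = 52L,
    "hydroxylamine reductase" = 121L,
    "denitrification" = 69L,
    "background" = 300L
  )
}

#' @rdname sim_config
#' @export
default_depth_trends <- function() {
  c(
    "nitrogen fixation" = -0.144,
    "assimilatory nitrate reduction" = -0.12,
    "DNRA" = 0.2,
    "hydroxylamine dehydrogenase" = 0.12,
    "hydroxylamine reductase" = 0.12,
    "denitrification" = 0.1,
    "background" = 0
  )
}

# Stable RNG stream offsets, one per output table.
.rng_offsets <- c(qpcr = 101L, catalog = 202L, proteins = 303L)

# True mean log10 copies-per-gram profiles for the default marker panel.
# Magnitudes and peak layers follow the depth behaviour of a hypersaline mat:
# low biomass in the diatom/EPS surface layer, most markers peaking near the
# oxic/anoxic chemocline (layers 2-4), archaeal amoA quantifiable in layer 3
# only. Expression (cDNA) peaks in layer 3 for the oxic markers (nifH, amoA)
# and layer 4 for nxrB, nosZ, nirS and the anammox 16S proxy.
.qpcr_truth <- function(markers, n_layers) {
  spec <- list(
    #                 lo    hi   peak width ratio_max ratio_peak
    "Bacteria-16S"       = c(5.0, 10.0, 2.5, 1.5, 2.0, 3.5),
    "Archaea-16S"        = c(6.0,  8.0, 4.0, 1.5, 2.0, 3.5),
    "nifH"               = c(8.0, 11.0, 2.0, 1.5, 3.0, 3.0),
    "Archaeal-amoA"      = c(0.5,  4.9, 3.0, 0.35, 1.8, 3.0),
    "Bacterial-amoA"     = c(4.0,  6.6, 3.0, 1.0, 3.3, 3.0),
    "Nitrospira-nxrB"    = c(5.0,  7.1, 3.0, 1.2, 1.5, 4.0),
    "nosZ"               = c(3.8,  5.4, 3.0, 1.2, 7.0, 4.0),
    "nirS"               = c(5.3,  7.6, 3.0, 1.2, 5.0, 4.0),
    "Planctomycetes-16S" = c(4.5,  6.3, 3.0, 1.2, 2.5, 4.0)
  )
  layers <- seq_len(n_layers)
  # map the canonical 7-layer profile onto n_layers via the depth coordinate
  depth <- if (n_layers == 7L) layers else 1 + (layers - 1) * 6 / (n_layers - 1)
  dna <- cdna <- matrix(NA_real_, length(markers), n_layers,
                        dimnames = list(markers, paste0("L", layers)))
  for (m in markers) {
    p <- spec[[m]]
    if (is.null(p)) p <- c(5.0, 7.0, 3.0, 1.5, 2.0, 3.5)  # generic marker
    bump <- exp(-((depth - p[3])^2) / (2 * p[4]^2))
    mu <- p[1] + (p[2] - p[1]) * bump
    ratio <- 1 + (p[5] - 1) * exp(-((depth - p[6])^2) / (2 * 0.8^2))
    dna[m, ] <- mu
    cdna[m, ] <- mu + log10(ratio)
  }
  list(dna = dna, cdna = cdna)
}

#' Simulate the qPCR/RT-qPCR panel
#'
#' Draws one record per marker x layer x replicate x template (DNA, cDNA).
#' True mean log10 copies-per-gram profiles are fixed per marker (see
#' [sim_config()]); replicate noise is Normal on the log10 scale
#' (i.e. lognormal copies). Raw copies per reaction are the per-gram value
#' times the extracted mat mass; records under the detection limit are
#' flagged `below_lod` but kept, so downstream code decides their treatment.
#'
#' @param config A [sim_config()].
#' @return data.frame of copy records with columns `marker`, `layer`,
#'   `replicate`, `template`, `raw_copies`, `mat_mass_g`, `na_mass_ng`,
#'   `below_lod`; the per-marker true mean log10 profiles are attached as
#'   attribute `"truth"`.
#' @examples
#' panel <- simulate_qpcr_panel(sim_config(seed = 1))
#' nrow(panel)  # 7 * 3 * 9 * 2
#' @export
simulate_qpcr_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- .qpcr_truth(config$markers, config$n_layers)
  grid <- expand.grid(
    replicate = seq_len(config$n_replicates),
    layer = seq_len(config$n_layers),
    template = c("DNA", "cDNA"),
    marker = config$markers,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("marker", "layer", "replicate", "template")]
  withr::with_seed(config$seed + .rng_offsets[["qpcr"]], {
    ij <- cbind(match(grid$marker, rownames(truth$dna)), grid$layer)
    mu <- ifelse(grid$template == "DNA", truth$dna[ij], truth$cdna[ij])
    log10_per_g <- mu + stats::rnorm(nrow(grid), 0, config$noise_sd_log10)
  })
  raw <- 10^log10_per_g * config$mat_mass_g
  out <- data.frame(
    grid,
    raw_copies = raw,
    mat_mass_g = config$mat_mass_g,
    na_mass_ng = config$na_mass_ng,
    below_lod = raw < config$detection_limit,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate a metagenome gene catalog with depth-structured coverage
#'
#' Generates an annotation table (nitrogen-pathway genes with category-
#' consistent KOs, plus non-nitrogen background genes) and a long-format
#' per-layer coverage table. Gene coverage follows the category depth trend
#' on the log10 scale with multiplicative lognormal noise; per-gene baseline
#' abundances are themselves lognormal.
#'
#' @param config A [sim_config()].
#' @return list with elements `annotation` (gene_id, ko, symbol, category,
#'   taxon), `coverage` (gene_id, layer, coverage) and `truth` (per-gene
#'   baseline and trend slope).
#' @export
simulate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$n_genes_per_category
  komap <- nitrogen_ko_map()
  sym_counts <- pathway_gene_counts()
  sym_counts$category <- komap$category[match(sym_counts$symbol, komap$symbol)]

  rows <- list()
  for (cat in names(counts)) {
    n <- counts[[cat]]
    if (n == 0L) next
    if (cat == "background") {
      rows[[cat]] <- data.frame(
        ko = sprintf("K9%04d", seq_len(n)),  # outside the nitrogen KO set
        symbol = "bg", category = "background", stringsAsFactors = FALSE
      )
    } else {
      syms <- sym_counts[sym_counts$category == cat, , drop = FALSE]
      # allocate genes to symbols proportionally to the worked-example counts
      alloc <- floor(n * syms$n_genes / sum(syms$n_genes))
      rem <- n - sum(alloc)
      if (rem > 0) {
        extra <- order(syms$n_genes, decreasing = TRUE)[seq_len(rem)]
        alloc[extra] <- alloc[extra] + 1L
      }
      rows[[cat]] <- data.frame(
        ko = rep(komap$ko[match(syms$symbol, komap$symbol)], alloc),
        symbol = rep(syms$symbol, alloc),
        category = cat, stringsAsFactors = FALSE
      )
    }
  }
  ann <- do.call(rbind, rows)
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(nrow(ann))), ann,
    taxon = "synthetic_taxon", stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL

  layers <- seq_len(config$n_coverage_layers)
  slope <- config$depth_trend[ann$category]
  slope[is.na(slope)] <- 0
  withr::with_seed(config$seed + .rng_offsets[["catalog"]], {
    base <- stats::rnorm(nrow(ann), mean = 1.5, sd = 0.5)
    noise <- matrix(stats::rnorm(nrow(ann) * length(layers), 0,
                                 config$noise_sd_log10),
                    nrow(ann), length(layers))
  })
  log10cov <- outer(base, rep(1, length(layers))) +
    outer(slope, layers - 1) + noise
  cov <- data.frame(
    gene_id = rep(ann$gene_id, times = length(layers)),
    layer = rep(layers, each = nrow(ann)),
    coverage = as.vector(10^log10cov),
    stringsAsFactors = FALSE
  )
  cov <- cov[order(cov$gene_id, cov$layer), ]
  rownames(cov) <- NULL
  truth <- data.frame(
    gene_id = ann$gene_id, category = ann$category,
    base_log10 = base, trend_log10_per_mm = unname(slope),
    stringsAsFactors = FALSE
  )
  list(annotation = ann, coverage = cov, truth = truth)
}

#' Generate labeled synthetic HAO query proteins
#'
#' Takes the packaged synthetic reference alignment, uses the ungapped
#' sequence of one oxidative-HAO reference row and one epsilonHao reference
#' row as family templates, and emits mutated copies. Substitutions hit each
#' residue independently at `hao_mutation_rate`, excluding the diagnostic
#' positions: the anchor-position residue (tyrosine for the oxidative family,
#' tryptophan for the epsilon family) and, for the epsilon family, the
#' conserved methionine eight residues before it.
#'
#' @param config A [sim_config()].
#' @param refaln Reference alignment, default [load_hao_reference()].
#' @return list with `sequences` (named character vector of protein
#'   sequences) and `truth` (data.frame id, class).
#' @export
generate_hao_proteins <- function(config, refaln = load_hao_reference()) {
  stopifnot(inherits(config, "sim_config"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  anchor_col <- map_anchor_column(refaln)
  pick_template <- function(class) {
    id <- names(refaln$class)[refaln$class == class][1]
    row <- strsplit(refaln$aln[[id]], "")[[1]]
    keep <- row != "-"
    ungapped <- row[keep]
    anchor_pos <- sum(keep[seq_len(anchor_col)])  # ungapped index of anchor
    list(seq = ungapped, anchor = anchor_pos)
  }
  oxi <- pick_template("AOB-HAO")
  eps <- pick_template("epsilonHao")
  mutate <- function(tmpl, protect) {
    s <- tmpl
    hit <- stats::runif(length(s)) < config$hao_mutation_rate
    hit[protect] <- FALSE
    for (i in which(hit)) s[i] <- sample(setdiff(aa, s[i]), 1)
    paste(s, collapse = "")
  }
  n_o <- config$n_oxidative_hao
  n_e <- config$n_epsilon_hao
  withr::with_seed(config$seed + .rng_offsets[["proteins"]], {
    seqs <- c(
      vapply(seq_len(n_o), function(i)
        mutate(oxi$seq, oxi$anchor), character(1)),
      vapply(seq_len(n_e), function(i)
        mutate(eps$seq, c(eps$anchor, eps$anchor - 8L)), character(1))
    )
  })
  ids <- c(sprintf("oxHAO_query_%02d", seq_len(n_o)),
           sprintf("epsHao_query_%02d", seq_len(n_e)))
  names(seqs) <- ids
  truth <- data.frame(
    id = ids,
    class = c(rep("oxidative-HAO-like", n_o), rep("epsilonHao-like", n_e)),
    stringsAsFactors = FALSE
  )
  list(sequences = seqs, truth = truth)
}

#' Environmental depth profile of the studied mat
#'
#' The seven-layer porewater/microsensor profile used as the abiotic fixture:
#' dissolved oxygen range over the diel cycle (not detectable below 4 mm,
#' encoded `NA`), and mean +/- sd porewater ammonium, nitrate and phosphate
#' per 1-mm layer. `o2_um` is a single representative oxygen value per layer
#' (range midpoint; 0 where oxygen is undetectable) for use in ordination
#' vector overlays and rank correlations.
#'
#' @return data.frame with one row per layer.
#' @examples
#' make_env_fixture()
#' @export
make_env_fixture <- function() {
  data.frame(
    layer = 1:7,
    o2_min = c(200, 0, 0, 0, NA, NA, NA),
    o2_max = c(800, 1200, 200, NA, NA, NA, NA),
    o2_um = c(500, 600, 100, 0, 0, 0, 0),
    nh4_um = c(34.1, 58.6, 110.8, 109.2, 116.5, 115.6, 124.0),
    nh4_sd = c(12.8, 27.5, 62.4, 52.7, 69.0, 38.4, 34.3),
    no3_um = c(33.2, 30.3, 30.5, 30.5, 30.6, 30.6, 26.05),
    no3_sd = c(10.9, 2.8, 3.7, 3.7, 10.9, 10.9, 5.2),
    po4_um = c(5.5, 2.6, 3.1, 3.1, 2.7, 2.7, 4.6),
    po4_sd = c(1.3, 0.3, 0.7, 0.7, 1.2, 1.2, 0.7),
    stringsAsFactors = FALSE
  )
}
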