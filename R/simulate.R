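# Synthetic single-cell data with known ground truth: negative-binomial
# counts with planted cell groups, marker genes, high-dispersion genes and
# a mitochondrial gene subset. Every page template and recovery property
# is testable against this generator's truth labels — no external data.

#' Specify a synthetic single-cell simulation
#'
#' Defaults describe a small but realistic filtered scRNA-seq panel:
#' gene means log-uniform between 1 and 20 counts per cell, gene-level
#' negative-binomial dispersion 0.8 (biological CV^2 near one, typical of
#' uncorrected single-cell counts), three cell groups with five planted
#' markers each at a log2 fold change of 2, fifty planted highly variable
#' genes with dispersion inflated fourfold, and 5% mitochondrial genes.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param k_groups Number of planted cell groups.
#' @param markers_per_group Planted marker genes per group (disjoint
#'   across groups).
#' @param marker_lfc Marker effect size: group mean multiplied by
#'   `2^marker_lfc`.
#' @param nb_mean_range Range of baseline gene means; means are drawn
#'   log-uniformly.
#' @param nb_dispersion Baseline negative-binomial dispersion (1/size).
#' @param hvg_inflation_factor Dispersion multiplier of planted highly
#'   variable genes.
#' @param n_hvg_planted Number of planted highly variable genes.
#' @param pct_mito_genes Fraction of genes flagged mitochondrial.
#' @param batch_levels Number of batch levels in `cell_meta`.
#' @param seed Mandatory random seed.
#' @return A `sim_spec` list, validated.
#' @export
sim_spec <- function(n_cells = 500L, n_genes = 2000L, k_groups = 3L,
                     markers_per_group = 5L, marker_lfc = 2,
                     nb_mean_range = c(1, 20), nb_dispersion = 0.8,
                     hvg_inflation_factor = 4, n_hvg_planted = 50L,
                     pct_mito_genes = 0.05, batch_levels = 2L, seed) {
  if (missing(seed) || is.null(seed)) dw_stop("sim_spec: 'seed' is mandatory", "validation")
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               k_groups = as.integer(k_groups),
               markers_per_group = as.integer(markers_per_group),
               marker_lfc = marker_lfc, nb_mean_range = nb_mean_range,
               nb_dispersion = nb_dispersion,
               hvg_inflation_factor = hvg_inflation_factor,
               n_hvg_planted = as.integer(n_hvg_planted),
               pct_mito_genes = pct_mito_genes,
               batch_levels = as.integer(batch_levels), seed = as.integer(seed))
  for (f in c("n_cells", "n_genes", "k_groups", "batch_levels")) {
    if (spec[[f]] < 1L) dw_stop(sprintf("sim_spec: '%s' must be positive", f), "validation")
  }
  if (spec$markers_per_group < 0L || spec$n_hvg_planted < 0L) {
    dw_stop("sim_spec: planted gene counts must be non-negative", "validation")
  }
  if (spec$k_groups * spec$markers_per_group + spec$n_hvg_planted > spec$n_genes) {
    dw_stop("sim_spec: planted marker and HVG sets exceed 'n_genes'", "validation")
  }
  if (length(spec$nb_mean_range) != 2L || any(spec$nb_mean_range <= 0) ||
      diff(spec$nb_mean_range) < 0) {
    dw_stop("sim_spec: 'nb_mean_range' must be an increasing positive pair", "validation")
  }
  if (spec$nb_dispersion <= 0 || spec$hvg_inflation_factor <= 0) {
    dw_stop("sim_spec: 'nb_dispersion' and 'hvg_inflation_factor' must be positive",
            "validation")
  }
  if (spec$pct_mito_genes < 0 || spec$pct_mito_genes > 1) {
    dw_stop("sim_spec: 'pct_mito_genes' must lie in [0, 1]", "validation")
  }
  structure(spec, class = "sim_spec")
}

#' Simulate a single-cell dataset with planted ground truth
#'
#' Counts are negative-binomial with gene means drawn log-uniformly over
#' `nb_mean_range`. Marker genes (disjoint across groups) have their mean
#' multiplied by `2^marker_lfc` within their group; planted highly
#' variable genes carry `hvg_inflation_factor` times the baseline
#' dispersion; a `pct_mito_genes` fraction of genes gets an `MT-` id
#' prefix and the mitochondrial flag. `cell_meta` carries `group`,
#' `batch` and `condition` covariates.
#'
#' @param spec A [sim_spec()].
#' @return List with elements `dataset` (an [sc_dataset()]) and `truth`
#'   (`group` assignment, `markers` as a per-group list of gene ids,
#'   `hvg` gene ids).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes; nc <- spec$n_cells; k <- spec$k_groups
  gene_id <- sprintf("gene%0*d", nchar(ng), seq_len(ng))
  n_mito <- round(spec$pct_mito_genes * ng)
  mito_idx <- if (n_mito) sample.int(ng, n_mito) else integer()
  gene_id[mito_idx] <- sub("^gene", "MT-gene", gene_id[mito_idx])

  mu <- exp(stats::runif(ng, log(spec$nb_mean_range[1]), log(spec$nb_mean_range[2])))
  disp <- rep(spec$nb_dispersion, ng)
  hvg_idx <- if (spec$n_hvg_planted) sample.int(ng, spec$n_hvg_planted) else integer()
  disp[hvg_idx] <- disp[hvg_idx] * spec$hvg_inflation_factor

  pool <- setdiff(seq_len(ng), hvg_idx)
  marker_idx <- if (spec$markers_per_group) {
    split(sample(pool, k * spec$markers_per_group),
          rep(seq_len(k), each = spec$markers_per_group))
  } else {
    stats::setNames(rep(list(integer()), k), seq_len(k))
  }

  group <- sprintf("group%d", rep_len(seq_len(k), nc))
  M <- matrix(0L, nc, ng)
  for (g in seq_len(k)) {
    cells <- which(group == sprintf("group%d", g))
    mug <- mu
    mug[marker_idx[[g]]] <- mug[marker_idx[[g]]] * 2^spec$marker_lfc
    M[cells, ] <- matrix(
      stats::rnbinom(length(cells) * ng,
                     mu = rep(mug, each = length(cells)),
                     size = rep(1 / disp, each = length(cells))),
      nrow = length(cells))
  }
  rownames(M) <- sprintf("cell%0*d", nchar(nc), seq_len(nc))
  colnames(M) <- gene_id

  cell_meta <- data.frame(
    group = group,
    batch = sprintf("batch%d", rep_len(seq_len(spec$batch_levels), nc)),
    condition = ifelse(seq_len(nc) %% 2 == 1, "treated", "control"),
    stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = gene_id,
                          mito = seq_len(ng) %in% mito_idx,
                          planted_hvg = seq_len(ng) %in% hvg_idx,
                          stringsAsFactors = FALSE)

  ds <- sc_dataset(M, cell_meta = cell_meta, gene_meta = gene_meta)
  truth <- list(
    group = group,
    markers = lapply(marker_idx, function(i) gene_id[i]),
    hvg = gene_id[hvg_idx])
  names(truth$markers) <- sprintf("group%d", seq_len(k))
  list(dataset = ds, truth = truth)
}

#' Simulate a 2D embedding with one blob per group
#'
#' Group centers sit on a circle whose adjacent-chord length equals
#' `separation` (so all pairwise center distances are at least
#' `separation`); cells scatter around their center with isotropic
#' Gaussian noise of standard deviation `spread`.
#'
#' @param groups Categorical vector, one entry per cell.
#' @param separation Minimum distance between blob centers.
#' @param spread Within-blob standard deviation.
#' @param seed Random seed.
#' @return Cells x 2 coordinate matrix (columns `x`, `y`).
#' @export
simulate_embedding <- function(groups, separation = 10, spread = 1, seed = 1L) {
  if (separation <= 0 || spread <= 0) {
    dw_stop("'separation' and 'spread' must be positive", "validation")
  }
  set.seed(seed)
  lv <- sort(unique(as.character(groups)))
  k <- length(lv)
  r <- if (k == 1L) 0 else separation / (2 * sin(pi / k))
  theta <- 2 * pi * (seq_len(k) - 1) / k
  centers <- cbind(r * cos(theta), r * sin(theta))
  idx <- match(as.character(groups), lv)
  coords <- centers[idx, , drop = FALSE] +
    matrix(stats::rnorm(2 * length(groups), sd = spread), ncol = 2)
  colnames(coords) <- c("x", "y")
  rownames(coords) <- names(groups)
  coords
}
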