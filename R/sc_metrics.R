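# Per-cell QC metrics, grouped aggregation, highly-variable-gene
# selection via a mean-variance trend, and group-vs-rest marker ranking.
# One documented normalization (counts-per-10k, log1p) backs both HVG
# selection and marker scores; the trend fit is isolated in
# fit_mean_variance_trend() so an alternative model is a drop-in.

#' Log-normalize a count matrix
#'
#' Counts are scaled per cell to 10,000 total (CP10K) and transformed with
#' `log1p`. Cells with zero total are left at zero.
#'
#' @param counts Cells x genes count matrix.
#' @return Matrix of log-normalized expression, same shape.
#' @export
normalize_log1p <- function(counts) {
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  log1p(counts / tot * 1e4)
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total count, the number of detected genes
#' (count > 0) and the percentage of counts in mitochondria-flagged genes.
#' All-zero cells get `pct_mito = 0` and are flagged.
#'
#' @param ds An [sc_dataset()].
#' @return Data frame with columns `cell_id`, `total_counts`,
#'   `detected_genes`, `pct_mito`, `zero_total`.
#' @export
qc_metrics <- function(ds) {
  stopifnot(inherits(ds, "sc_dataset"))
  M <- ds$counts
  total <- rowSums(M)
  mito_total <- rowSums(M[, ds$gene_meta$mito, drop = FALSE])
  data.frame(
    cell_id = rownames(M),
    total_counts = total,
    detected_genes = as.integer(rowSums(M > 0)),
    pct_mito = ifelse(total > 0, mito_total / total * 100, 0),
    zero_total = total == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Aggregate a per-cell value across levels of a grouping variable
#'
#' @param values Numeric vector, one value per cell.
#' @param groups Categorical vector of equal length.
#' @param fun Summary function name: `"mean"`, `"median"` or `"sum"`.
#' @return Data frame with columns `level` and `value`, one row per
#'   observed level in level order.
#' @export
aggregate_by_group <- function(values, groups, fun = c("mean", "median", "sum")) {
  if (length(values) != length(groups)) {
    dw_stop("'values' and 'groups' must have equal length", "validation")
  }
  if (!is.character(fun) || !fun[1] %in% c("mean", "median", "sum")) {
    dw_stop(sprintf("unknown aggregation '%s'; valid: mean, median, sum",
                    as.character(fun)[1]), "config")
  }
  fun <- fun[1]
  lv <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(as.character(groups)))
  fn <- match.fun(fun)
  data.frame(
    level = lv,
    value = vapply(lv, function(l) fn(values[as.character(groups) == l]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Rolling-median trend of log-variance against log-mean: genes are binned
# into equal-count bins by mean; the bin medians are linearly interpolated
# (constant beyond the outermost bins).
fit_mean_variance_trend <- function(log_mean, log_var, n_bins = 20L) {
  n <- length(log_mean)
  n_bins <- max(2L, min(n_bins, n %/% 5L))
  o <- order(log_mean)
  bin <- cut(seq_len(n), breaks = n_bins, labels = FALSE)
  bx <- tapply(log_mean[o], bin, stats::median)
  by <- tapply(log_var[o], bin, stats::median)
  stats::approx(bx, by, xout = log_mean, rule = 2, ties = "ordered")$y
}

#' Highly variable gene selection from the mean-variance relation
#'
#' Per-gene mean and variance are computed on log-normalized expression
#' ([normalize_log1p()]). A rolling-median trend of log-variance versus
#' log-mean (equal-count bins) captures the expected technical variance at
#' a given abundance; the residual (log-variance minus log-trend) ranks
#' genes, and the top `n_top` residuals are flagged as highly variable.
#' Ties break by gene id, lexicographically. Genes never observed (zero
#' mean/variance) get `-Inf` residuals and are flagged only when `n_top`
#' forces it.
#'
#' @param ds An [sc_dataset()].
#' @param n_top Number of genes to flag; at most the gene count.
#' @param n_bins Number of equal-count trend bins.
#' @return Data frame with one row per gene: `gene_id`, `mean`,
#'   `variance`, `trend`, `residual`, `hvg_flag`.
#' @export
mean_variance_hvg <- function(ds, n_top, n_bins = 20L) {
  stopifnot(inherits(ds, "sc_dataset"))
  n_genes <- ncol(ds$counts)
  if (n_top > n_genes) {
    dw_stop(sprintf("n_top (%d) exceeds the gene count (%d)", n_top, n_genes),
            "validation")
  }
  L <- normalize_log1p(ds$counts)
  mu <- colMeans(L)
  v <- apply(L, 2, stats::var)
  ok <- mu > 0 & v > 0
  residual <- rep(-Inf, n_genes)
  trend <- rep(NA_real_, n_genes)
  if (sum(ok) >= 2L) {
    tr <- fit_mean_variance_trend(log(mu[ok]), log(v[ok]), n_bins)
    trend[ok] <- exp(tr)
    residual[ok] <- log(v[ok]) - tr
  }
  gene_id <- colnames(ds$counts)
  ord <- order(-residual, gene_id)
  flag <- logical(n_genes)
  flag[ord[seq_len(n_top)]] <- TRUE
  data.frame(gene_id = gene_id, mean = mu, variance = v, trend = trend,
             residual = residual, hvg_flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank marker genes per group
#'
#' Scores every gene in every group by the difference of its mean
#' log-normalized expression inside the group versus all other cells, and
#' keeps the `n_top` highest-scoring genes per group (ties break by gene
#' id). A positive score means enrichment in the group.
#'
#' @param ds An [sc_dataset()].
#' @param group_var Name of a categorical `cell_meta` column with at least
#'   two levels.
#' @param n_top Markers kept per group (default 10).
#' @return Data frame with columns `group`, `gene_id`, `score`, `rank`;
#'   within each group ranks run 1..`n_top` with non-increasing scores.
#' @export
rank_markers <- function(ds, group_var, n_top = 10L) {
  stopifnot(inherits(ds, "sc_dataset"))
  if (!group_var %in% names(ds$cell_meta)) {
    dw_stop(sprintf("cell_meta has no column '%s'", group_var), "validation")
  }
  g <- as.character(ds$cell_meta[[group_var]])
  lv <- sort(unique(g))
  if (length(lv) < 2L) {
    dw_stop(sprintf("'%s' has a single level; marker ranking needs at least two",
                    group_var), "validation")
  }
  L <- normalize_log1p(ds$counts)
  gene_id <- colnames(ds$counts)
  out <- lapply(lv, function(l) {
    inside <- g == l
    score <- colMeans(L[inside, , drop = FALSE]) - colMeans(L[!inside, , drop = FALSE])
    keep <- order(-score, gene_id)[seq_len(min(n_top, length(score)))]
    data.frame(group = l, gene_id = gene_id[keep], score = unname(score[keep]),
               rank = seq_along(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deterministic 2D projection of a dataset
#'
#' Built-in embedding fallback for pipelines that bring no t-SNE/UMAP
#' coordinates: the top two principal directions of the log-normalized
#' matrix, with a fixed sign convention (the largest-magnitude loading of
#' each axis is positive) so repeated runs agree exactly.
#'
#' @param ds An [sc_dataset()].
#' @param n_genes Number of most-variable genes used (speed/stability).
#' @return Cells x 2 coordinate matrix.
#' @export
embed_pca <- function(ds, n_genes = 500L) {
  L <- normalize_log1p(ds$counts)
  v <- apply(L, 2, stats::var)
  keep <- order(-v)[seq_len(min(n_genes, ncol(L)))]
  pc <- stats::prcomp(L[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                      rank. = 2)
  for (j in 1:2) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$x[, j] <- -pc$x[, j]
    }
  }
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("x", "y")
  coords
}
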