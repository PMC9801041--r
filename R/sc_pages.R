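# Ready-made single-cell dashboard pages. Every page template here
# constructs its page exclusively through the public builder operations
# (add_page / add_component / add_link with fig_spec / link_spec /
# dispatch_content) — the extension mechanism the framework is designed
# around. No template touches dashboard internals.

.dw_sc_kinds <- c("qc", "feature_selection", "dimred_sample", "dimred_feature",
                  "feature_grid", "dimred_comparison", "marker_heatmap")

sc_opt <- function(options, name, default = NULL, required = FALSE) {
  if (!is.null(options[[name]])) return(options[[name]])
  if (required) dw_stop(sprintf("add_sc_page: required option '%s' is missing", name),
                        "config")
  default
}

# first categorical cell covariate, preferring an explicit 'group'
sc_default_group <- function(ds) {
  cats <- names(ds$cell_meta)[vapply(ds$cell_meta, function(v)
    is.character(v) || is.factor(v), logical(1))]
  if ("group" %in% cats) "group" else if (length(cats)) cats[1] else NULL
}

sc_embedding <- function(ds, options) {
  nm <- sc_opt(options, "embedding")
  if (!is.null(nm)) {
    if (!nm %in% names(ds$embeddings)) {
      dw_stop(sprintf("embedding '%s' not present in the dataset", nm), "config")
    }
    return(ds$embeddings[[nm]])
  }
  if (length(ds$embeddings)) return(ds$embeddings[[1]])
  embed_pca(ds) # deterministic built-in fallback
}

#' Add a ready-made single-cell page
#'
#' Page templates for a typical single-cell analysis: QC violins with an
#' aggregate table (`qc`), the mean-variance/HVG view
#' (`feature_selection`), linked embedding views on sample metadata
#' (`dimred_sample`) or feature expression (`dimred_feature`), a
#' multi-panel feature figure with downloadable data (`feature_grid`), an
#' embedding comparison tabset (`dimred_comparison`) and the top-marker
#' heatmap (`marker_heatmap`).
#'
#' Common options: `page_id`, `title`, `menu`, `colormap` (a registered
#' document colormap for the grouping variable), `group_var` (defaults to
#' the `group` covariate), `embedding` (name of a stored embedding; the
#' first stored embedding, or a deterministic PCA projection, is the
#' fallback), `n_top` (HVGs or markers per group), `stratify` (QC violins
#' split by a categorical covariate), `features` and `grid_cols` /
#' `panel_size` (feature grid), `aggregate` (`list(fun, var)` for the
#' linked aggregate panel of `dimred_sample`).
#'
#' @inheritParams add_page
#' @param ds An [sc_dataset()].
#' @param kind One of `"qc"`, `"feature_selection"`, `"dimred_sample"`,
#'   `"dimred_feature"`, `"feature_grid"`, `"dimred_comparison"`,
#'   `"marker_heatmap"`.
#' @param options Named list of template options (see Details).
#' @return The updated dashboard.
#' @examples
#' sim <- simulate_counts(sim_spec(n_cells = 60, n_genes = 100, seed = 1))
#' db <- create_dashboard("sc report")
#' db <- add_sc_page(db, sim$dataset, "qc")
#' @export
add_sc_page <- function(db, ds, kind, options = list()) {
  stopifnot(inherits(db, "dashboard"), inherits(ds, "sc_dataset"))
  if (!kind %in% .dw_sc_kinds) {
    dw_stop(sprintf("unknown sc page kind '%s'; valid kinds: %s",
                    kind, paste(.dw_sc_kinds, collapse = ", ")), "config")
  }
  builder <- switch(kind,
    qc = sc_page_qc, feature_selection = sc_page_feature_selection,
    dimred_sample = sc_page_dimred_sample, dimred_feature = sc_page_dimred_feature,
    feature_grid = sc_page_feature_grid, dimred_comparison = sc_page_dimred_comparison,
    marker_heatmap = sc_page_marker_heatmap)
  builder(db, ds, options)
}

sc_page_qc <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "qc")
  strat <- sc_opt(options, "stratify")
  cmap <- sc_opt(options, "colormap")
  qc <- qc_metrics(ds)
  if (!is.null(strat)) {
    if (!strat %in% names(ds$cell_meta)) {
      dw_stop(sprintf("stratify variable '%s' not in cell_meta", strat), "config")
    }
    qc[[strat]] <- as.character(ds$cell_meta[[strat]])
  } else {
    strat <- "all"
    qc[[strat]] <- "all cells"
  }
  db <- add_page(db, pid, sc_opt(options, "title", "Quality metrics"),
                 layout = "grid_2x2", menu = sc_opt(options, "menu"))
  for (metric in c("total_counts", "detected_genes", "pct_mito")) {
    db <- add_component(db, pid,
      fig_spec(qc, "violin", x = strat, y = metric, color = strat, colormap = cmap,
               ylab = metric),
      title = gsub("_", " ", metric))
  }
  agg <- do.call(rbind, lapply(c("total_counts", "detected_genes", "pct_mito"),
    function(metric) {
      a <- aggregate_by_group(qc[[metric]], qc[[strat]], "mean")
      data.frame(metric = metric, level = a$level, mean = a$value,
                 stringsAsFactors = FALSE)
    }))
  add_component(db, pid, agg, title = "Mean per level")
}

sc_page_feature_selection <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "feature_selection")
  n_top <- sc_opt(options, "n_top", 50L)
  hvg <- mean_variance_hvg(ds, n_top = n_top)
  shown <- hvg[hvg$mean > 0 & hvg$variance > 0, , drop = FALSE]
  shown$log10_mean <- log10(shown$mean)
  shown$log10_variance <- log10(shown$variance)
  shown$selection <- ifelse(shown$hvg_flag, "highly variable", "other")
  db <- add_page(db, pid, sc_opt(options, "title", "Feature selection"),
                 layout = "focal_left", menu = sc_opt(options, "menu"))
  db <- add_component(db, pid,
    fig_spec(shown, "scatter", x = "log10_mean", y = "log10_variance",
             color = "selection"),
    title = "Mean-variance relation")
  top <- hvg[hvg$hvg_flag, c("gene_id", "mean", "variance", "residual")]
  top <- top[order(-top$residual, top$gene_id), ]
  add_component(db, pid, top, title = sprintf("Top %d highly variable genes", n_top))
}

sc_page_dimred_sample <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "dimred_sample")
  gv <- sc_opt(options, "group_var", sc_default_group(ds), required = is.null(sc_default_group(ds)))
  agg <- sc_opt(options, "aggregate", list(fun = "mean", var = "pct_mito"))
  coords <- sc_embedding(ds, options)
  qc <- qc_metrics(ds)
  d <- data.frame(x = coords[, 1], y = coords[, 2],
                  group = as.character(ds$cell_meta[[gv]]),
                  stringsAsFactors = FALSE)
  names(d)[3] <- gv
  d[[agg$var]] <- if (agg$var %in% names(qc)) qc[[agg$var]] else ds$cell_meta[[agg$var]]
  db <- add_page(db, pid, sc_opt(options, "title", "Sample explorer"),
                 layout = "grid_2x2", menu = sc_opt(options, "menu"))
  db <- add_component(db, pid,
    fig_spec(d, "scatter", x = "x", y = "y", color = gv,
             colormap = sc_opt(options, "colormap"),
             xlab = "dim 1", ylab = "dim 2"),
    title = "2D embedding")
  db <- add_component(db, pid,
    fig_spec(d, "bar", x = gv, colormap = sc_opt(options, "colormap"),
             xlab = gv, ylab = "cells"),
    title = sprintf("Cells per %s", gv))
  db <- add_component(db, pid,
    fig_spec(d, "bar", x = gv, y = agg$var, colormap = sc_opt(options, "colormap"),
             xlab = gv, ylab = sprintf("%s %s", agg$fun, agg$var)),
    title = sprintf("%s %s per %s", agg$fun, agg$var, gv))
  db <- add_link(db, pid, link_spec(paste0(pid, "-c1"), paste0(pid, "-c2"),
    channel = "subset_recompute",
    aggregate = list(fun = "count", by = gv)))
  add_link(db, pid, link_spec(paste0(pid, "-c1"), paste0(pid, "-c3"),
    channel = "subset_recompute",
    aggregate = list(fun = agg$fun, by = gv, var = agg$var)))
}

sc_page_dimred_feature <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "dimred_feature")
  gv <- sc_opt(options, "group_var", sc_default_group(ds), required = is.null(sc_default_group(ds)))
  n_top <- sc_opt(options, "n_top", 10L)
  markers <- rank_markers(ds, gv, n_top = n_top)
  feature <- sc_opt(options, "feature", markers$gene_id[1])
  coords <- sc_embedding(ds, options)
  L <- normalize_log1p(ds$counts)
  d <- data.frame(x = coords[, 1], y = coords[, 2],
                  expression = L[, feature],
                  group = as.character(ds$cell_meta[[gv]]),
                  stringsAsFactors = FALSE)
  names(d)[4] <- gv
  db <- add_page(db, pid, sc_opt(options, "title", "Feature explorer"),
                 layout = "focal_left", menu = sc_opt(options, "menu"))
  db <- add_component(db, pid,
    fig_spec(d, "scatter", x = "x", y = "y", color = "expression",
             xlab = "dim 1", ylab = "dim 2"),
    title = sprintf("Expression of %s", feature))
  db <- add_component(db, pid, markers,
                      title = sprintf("Top %d markers per %s", n_top, gv))
  db <- add_component(db, pid,
    fig_spec(d, "violin", x = gv, y = "expression", color = gv,
             colormap = sc_opt(options, "colormap")),
    title = sprintf("%s by %s", feature, gv))
  # table selection re-colors the embedding and the violin panel
  db <- add_link(db, pid, link_spec(paste0(pid, "-c2"), paste0(pid, "-c1"),
                                    channel = "color_by_selection"))
  add_link(db, pid, link_spec(paste0(pid, "-c2"), paste0(pid, "-c3"),
                              channel = "color_by_selection"))
}

sc_page_feature_grid <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "feature_grid")
  features <- sc_opt(options, "features", required = TRUE)
  missing <- setdiff(features, colnames(ds$counts))
  if (length(missing)) {
    dw_stop(sprintf("feature_grid: unknown feature(s): %s",
                    paste(missing, collapse = ", ")), "config")
  }
  ncol_grid <- sc_opt(options, "grid_cols", 2L)
  panel <- sc_opt(options, "panel_size", 230L)
  coords <- sc_embedding(ds, options)
  L <- normalize_log1p(ds$counts)
  plotted <- data.frame(cell_id = rownames(ds$counts),
                        x = coords[, 1], y = coords[, 2],
                        L[, features, drop = FALSE], check.names = FALSE)
  # injected callable: panels are produced through the public dispatch and
  # stitched into one figure with its data downloadable as CSV
  make_body <- function() {
    panels <- vapply(features, function(f) {
      d <- data.frame(x = coords[, 1], y = coords[, 2], value = L[, f])
      fig <- fig_spec(d, "scatter", x = "x", y = "y", color = "value",
                      xlab = "dim 1", ylab = f, width = panel, height = panel)
      sprintf('<div style="display:inline-block">%s</div>',
              dispatch_content(fig)$body)
    }, character(1))
    csv <- utils::capture.output(utils::write.csv(plotted, row.names = FALSE))
    uri <- sprintf("data:text/csv;base64,%s",
                   jsonlite::base64_enc(charToRaw(paste0(paste(csv, collapse = "\n"), "\n"))))
    paste(c(sprintf('<div class="dw-grid" style="max-width:%dpx">', (panel + 10) * ncol_grid),
            panels, "</div>",
            sprintf('<p><a download="feature_grid.csv" href="%s">Download plotted values (CSV)</a></p>',
                    uri)),
          collapse = "\n")
  }
  db <- add_page(db, pid, sc_opt(options, "title", "Feature grid"),
                 layout = "storyboard", menu = sc_opt(options, "menu"))
  add_component(db, pid, make_body, title = "Embedding by feature")
}

sc_page_dimred_comparison <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "dimred_comparison")
  gv <- sc_opt(options, "group_var", sc_default_group(ds))
  runs <- sc_opt(options, "runs")
  if (is.null(runs)) {
    runs <- if (length(ds$embeddings)) {
      lapply(names(ds$embeddings), function(nm)
        list(label = nm, params = list(), coords = ds$embeddings[[nm]]))
    } else {
      list(list(label = "pca", params = list(components = "1-2"),
                coords = embed_pca(ds)))
    }
  }
  db <- add_page(db, pid, sc_opt(options, "title", "Embedding comparison"),
                 layout = "tabset", menu = sc_opt(options, "menu"))
  for (run in runs) {
    d <- data.frame(x = run$coords[, 1], y = run$coords[, 2],
                    stringsAsFactors = FALSE)
    if (!is.null(gv)) d[[gv]] <- as.character(ds$cell_meta[[gv]])
    lab <- if (length(run$params)) {
      sprintf("%s (%s)", run$label,
              paste(sprintf("%s=%s", names(run$params), unlist(run$params)),
                    collapse = ", "))
    } else run$label
    db <- add_component(db, pid,
      fig_spec(d, "scatter", x = "x", y = "y", color = gv,
               colormap = sc_opt(options, "colormap"),
               xlab = "dim 1", ylab = "dim 2"),
      title = lab)
  }
  db
}

sc_page_marker_heatmap <- function(db, ds, options) {
  pid <- sc_opt(options, "page_id", "marker_heatmap")
  gv <- sc_opt(options, "group_var", sc_default_group(ds), required = is.null(sc_default_group(ds)))
  n_top <- sc_opt(options, "n_top", 10L)
  markers <- rank_markers(ds, gv, n_top = n_top)
  genes <- unique(markers$gene_id)
  g <- as.character(ds$cell_meta[[gv]])
  lv <- sort(unique(g))
  L <- normalize_log1p(ds$counts)
  M <- vapply(lv, function(l) colMeans(L[g == l, genes, drop = FALSE]),
              numeric(length(genes)))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(genes), dimnames = list(genes, lv))
  rownames(M) <- genes
  db <- add_page(db, pid, sc_opt(options, "title", "Marker heatmap"),
                 layout = "storyboard", menu = sc_opt(options, "menu"))
  db <- add_component(db, pid,
    fig_spec(matrix = M, type = "heatmap",
             height = max(300L, 14L * length(genes) + 80L)),
    title = sprintf("Mean expression of top %d markers per %s", n_top, gv))
  add_component(db, pid, markers, title = "Marker ranking")
}
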