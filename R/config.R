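# YAML-driven builds and the high-level entry points behind the
# command-line interface (inst/cli/dashweave.R): config builds, the
# file-based single-cell report, and the fully synthetic demo dashboard.

#' Build a dashboard from a YAML configuration
#'
#' Recognized keys: `title`, `author`, `theme`, `interactive`,
#' `colormaps` (name -> level -> color), and `pages`, a list of entries
#' with `id`, `title`, `layout`, optional `menu` and `components`. Each
#' component is either a markdown string or a map with `kind`
#' (`text`/`image`/`table`), its `value` or `path`, and an optional
#' `title`.
#'
#' @param path Path to the YAML file.
#' @return A `dashboard`.
#' @export
dashboard_from_config <- function(path) {
  if (!file.exists(path)) dw_stop(sprintf("config file not found: %s", path), "io")
  cfg <- yaml::read_yaml(path)
  db <- create_dashboard(cfg$title %||% "Dashboard", cfg$author %||% "",
                         theme = cfg$theme %||% "default",
                         interactive = isTRUE(cfg$interactive))
  for (nm in names(cfg$colormaps %||% list())) {
    db <- add_colormap(db, nm, unlist(cfg$colormaps[[nm]]))
  }
  for (pg in cfg$pages %||% list()) {
    db <- add_page(db, pg$id, pg$title %||% pg$id,
                   layout = pg$layout %||% "storyboard", menu = pg$menu)
    for (cmp in pg$components %||% list()) {
      if (is.character(cmp)) {
        db <- add_component(db, pg$id, cmp)
      } else {
        content <- switch(cmp$kind %||% "text",
          text = cmp$value,
          image = , table = cmp$path,
          dw_stop(sprintf("config component kind '%s' not supported", cmp$kind),
                  "config"))
        db <- add_component(db, pg$id, content, title = cmp$title)
      }
    }
  }
  db
}

#' Assemble and render a dashboard to HTML
#'
#' @inheritParams add_page
#' @param out_path Output HTML path.
#' @param keep_intermediate If `TRUE`, the intermediate markdown-dialect
#'   document is written alongside the HTML (extension `.md`).
#' @return Invisibly, the [render_html()] summary.
#' @export
build_dashboard <- function(db, out_path, keep_intermediate = FALSE) {
  doc <- assemble(db)
  if (isTRUE(keep_intermediate)) {
    md_path <- sub("\\.html?$", ".md", out_path)
    if (identical(md_path, out_path)) md_path <- paste0(out_path, ".md")
    con <- file(md_path, open = "wb")
    writeChar(paste0(format(doc), "\n"), con, eos = NULL)
    close(con)
  }
  render_html(doc, out_path)
}

#' Build the fully synthetic demonstration dashboard
#'
#' Simulates a dataset from the default [sim_spec()] (at the given seed),
#' adds every single-cell page template plus an introduction page and a
#' document-wide group colormap, and renders the result.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param out_path Output HTML path (`NULL` to skip rendering).
#' @param keep_intermediate Also write the intermediate document.
#' @return List with `db`, `doc` (the intermediate document), `sim` (the
#'   simulation), and `summary` (render summary, when rendered).
#' @export
sc_demo <- function(seed = 1L, out_path = NULL, keep_intermediate = FALSE) {
  sim <- simulate_counts(sim_spec(seed = seed))
  ds <- sim$dataset
  ds$embeddings$blobs <- simulate_embedding(sim$truth$group, separation = 10,
                                            spread = 1, seed = seed + 1L)
  lv <- sort(unique(sim$truth$group))
  db <- create_dashboard("Synthetic single-cell report", "dashweave demo")
  db <- add_colormap(db, "Group",
                     stats::setNames(dw_palette(length(lv)), lv))
  db <- add_page(db, "about", "About", layout = "storyboard")
  db <- add_component(db, "about", paste(
    "## Synthetic single-cell demo",
    "",
    sprintf("Negative-binomial counts: %d cells x %d genes, %d planted groups,",
            nrow(ds$counts), ncol(ds$counts), length(lv)),
    "with planted marker genes, high-dispersion genes and a mitochondrial subset.",
    "All figures below are computed from this matrix at build time.",
    sep = "\n"), title = "Overview")
  common <- list(colormap = "Group", menu = "Single cell", embedding = "blobs")
  db <- add_sc_page(db, ds, "qc", c(list(stratify = "group"), common))
  db <- add_sc_page(db, ds, "feature_selection", list(menu = "Single cell"))
  db <- add_sc_page(db, ds, "dimred_sample", common)
  db <- add_sc_page(db, ds, "dimred_feature", common)
  db <- add_sc_page(db, ds, "feature_grid",
                    c(list(features = sim$truth$markers[[1]][1:2]), common))
  db <- add_sc_page(db, ds, "dimred_comparison", common)
  db <- add_sc_page(db, ds, "marker_heatmap", common[c("colormap", "menu")])
  doc <- assemble(db)
  summary <- NULL
  if (!is.null(out_path)) {
    summary <- build_dashboard(db, out_path, keep_intermediate = keep_intermediate)
  }
  list(db = db, doc = doc, sim = sim, summary = summary)
}

#' Build a single-cell report dashboard from files
#'
#' File-based counterpart of [sc_demo()]: reads counts, metadata and
#' embeddings with [read_sc_dataset()] and adds the requested page
#' templates.
#'
#' @inheritParams read_sc_dataset
#' @param pages Character vector of page kinds (see [add_sc_page()]).
#' @param out_path Output HTML path.
#' @param title Dashboard title.
#' @param options Extra options forwarded to every page template.
#' @return Invisibly, the render summary.
#' @export
sc_report <- function(counts, genes = NULL, barcodes = NULL, cell_meta = NULL,
                      gene_meta = NULL, embeddings = character(),
                      pages = c("qc", "feature_selection"), out_path,
                      title = "Single-cell report", options = list()) {
  ds <- read_sc_dataset(counts, genes = genes, barcodes = barcodes,
                        cell_meta = cell_meta, gene_meta = gene_meta,
                        embeddings = embeddings)
  db <- create_dashboard(title, "")
  for (kind in pages) db <- add_sc_page(db, ds, kind, options)
  build_dashboard(db, out_path)
}
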