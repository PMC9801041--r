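# Shared fixtures, all built in code at test time.

# small simulated dataset; sizes chosen so a full page build stays fast
small_sim <- function(seed = 42L, n_cells = 90L, n_genes = 120L, k = 3L) {
  simulate_counts(sim_spec(n_cells = n_cells, n_genes = n_genes, k_groups = k,
                           markers_per_group = 3L, n_hvg_planted = 10L,
                           seed = seed))
}

tiny_dataset <- function(counts, mito = NULL, meta = NULL) {
  gm <- if (!is.null(mito)) {
    data.frame(gene_id = colnames(counts) %||%
                 sprintf("g%d", seq_len(ncol(counts))), mito = mito)
  }
  sc_dataset(counts, cell_meta = meta, gene_meta = gm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1x1 transparent PNG, a valid minimal binary image
write_tiny_png <- function(path) {
  b64 <- paste0(
    "iVBORw0KGgoAAAANSUhEUgAAAAEAAAABCAYAAAAfFcSJAAAADUlEQVR42mNk",
    "YPhfDwAChwGA60e6kgAAAABJRU5ErkJggg==")
  writeBin(jsonlite::base64_dec(b64), path)
  path
}

write_tiny_svg <- function(path) {
  writeLines('<svg xmlns="http://www.w3.org/2000/svg" width="4" height="4"><rect width="4" height="4" fill="#ff0000"/></svg>', path)
  path
}

# a dashboard with one linkable page carrying records suited for linking
linked_page_db <- function(records, group_col = "g", value_col = "v") {
  db <- create_dashboard("link test")
  db <- add_page(db, "p", "P", layout = "grid_2x2")
  db <- add_component(db, "p",
    fig_spec(records, "scatter", x = "x", y = "y", color = group_col),
    title = "source")
  db <- add_component(db, "p",
    fig_spec(records, "bar", x = group_col), title = "counts")
  db <- add_component(db, "p",
    fig_spec(records, "bar", x = group_col, y = value_col), title = "agg")
  db
}
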