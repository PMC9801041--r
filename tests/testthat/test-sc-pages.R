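sim <- small_sim()
ds <- local({
  d <- sim$dataset
  d$embeddings$blobs <- simulate_embedding(sim$truth$group, seed = 8)
  d
})

test_that("unknown page kinds and missing options fail loudly", {
  db <- create_dashboard("d")
  expect_error(add_sc_page(db, ds, "volcano"), "valid kinds",
               class = "dw_config_error")
  expect_error(add_sc_page(db, ds, "feature_grid"), "features",
               class = "dw_config_error")
  expect_error(add_sc_page(db, ds, "qc", list(stratify = "nope")),
               class = "dw_config_error")
  expect_error(add_sc_page(db, ds, "dimred_sample", list(embedding = "umap")),
               "not present", class = "dw_config_error")
})

test_that("qc pages hold three stratified violins plus an aggregate table", {
  db <- add_sc_page(create_dashboard("d"), ds, "qc", list(stratify = "condition"))
  p <- db$pages$qc
  expect_identical(p$layout, "grid_2x2")
  expect_length(p$components, 4)
  kinds <- vapply(p$components, `[[`, character(1), "kind")
  expect_identical(kinds, c("figure", "figure", "figure", "table"))
  # violins are split by the stratification variable
  for (i in 1:3) {
    expect_identical(p$components[[i]]$figure$x, "condition")
    lv <- sort(unique(ds$cell_meta$condition))
    for (l in lv) expect_match(p$components[[i]]$body, l, fixed = TRUE)
  }
  agg <- p$components[[4]]$data_payload
  expect_setequal(unique(agg$metric),
                  c("total_counts", "detected_genes", "pct_mito"))
})

test_that("the feature-selection page shows the mean-variance scatter and table", {
  db <- add_sc_page(create_dashboard("d"), ds, "feature_selection",
                    list(n_top = 12))
  p <- db$pages$feature_selection
  expect_identical(p$layout, "focal_left")
  expect_length(p$components, 2)
  expect_identical(p$components[[1]]$figure$type, "scatter")
  expect_identical(nrow(p$components[[2]]$data_payload), 12L)
})

test_that("dimred_sample builds a grid page with 3 components and 2 links", {
  db <- add_sc_page(create_dashboard("d"), ds, "dimred_sample",
                    list(embedding = "blobs"))
  p <- db$pages$dimred_sample
  expect_identical(p$layout, "grid_2x2")
  expect_length(p$components, 3)
  expect_length(p$links, 2)
  w <- compile_wiring(p)
  expect_identical(w$update_fun, rep("subset_recompute", 2))
  expect_identical(w$agg_fun, c("count", "mean"))
  expect_identical(w$source, rep("dimred_sample-c1", 2))
})

test_that("dimred_feature wires table selection to embedding and violin", {
  db <- add_sc_page(create_dashboard("d"), ds, "dimred_feature",
                    list(embedding = "blobs"))
  p <- db$pages$dimred_feature
  expect_identical(p$layout, "focal_left")
  expect_length(p$components, 3)
  w <- compile_wiring(p)
  expect_identical(w$update_fun, rep("color_by_selection", 2))
  expect_identical(w$source, rep("dimred_feature-c2", 2))
  expect_setequal(w$target, c("dimred_feature-c1", "dimred_feature-c3"))
})

test_that("feature_grid injects a multi-panel figure with downloadable CSV", {
  feats <- sim$truth$markers$group1[1:2]
  db <- add_sc_page(create_dashboard("d"), ds, "feature_grid",
                    list(features = feats, embedding = "blobs"))
  fr <- db$pages$feature_grid$components[[1]]
  expect_identical(fr$kind, "injected")
  expect_identical(length(gregexpr("<svg ", fr$body)[[1]]), 2L)
  expect_match(fr$body, "data:text/csv;base64", fixed = TRUE)
  # the download payload decodes back to the plotted values
  b64 <- sub('.*href="data:text/csv;base64,([^"]+)".*', "\\1", fr$body)
  csv <- rawToChar(jsonlite::base64_dec(b64))
  got <- utils::read.csv(text = csv, check.names = FALSE)
  expect_identical(nrow(got), nrow(ds$counts))
  expect_true(all(feats %in% names(got)))
})

test_that("dimred_comparison makes one tab per embedding run", {
  db <- add_sc_page(create_dashboard("d"), ds, "dimred_comparison", list(
    runs = list(
      list(label = "umap", params = list(n_neighbors = 15),
           coords = ds$embeddings$blobs),
      list(label = "umap", params = list(n_neighbors = 50),
           coords = ds$embeddings$blobs[, 2:1]),
      list(label = "pca", params = list(), coords = embed_pca(ds)))))
  p <- db$pages$dimred_comparison
  expect_identical(p$layout, "tabset")
  expect_length(p$components, 3)
  expect_identical(p$components[[1]]$title, "umap (n_neighbors=15)")
  # no stored embeddings and no runs: deterministic PCA fallback, one tab
  ds2 <- sim$dataset
  db2 <- add_sc_page(create_dashboard("d"), ds2, "dimred_comparison")
  expect_length(db2$pages$dimred_comparison$components, 1)
})

test_that("marker heatmap rows cover the top markers of every group", {
  db <- add_sc_page(create_dashboard("d"), ds, "marker_heatmap",
                    list(n_top = 4))
  p <- db$pages$marker_heatmap
  M <- p$components[[1]]$figure$matrix
  mk <- rank_markers(ds, "group", n_top = 4)
  expect_identical(rownames(M), unique(mk$gene_id))
  expect_identical(colnames(M), sort(unique(ds$cell_meta$group)))
  expect_identical(as.integer(table(mk$group)), rep(4L, 3L))
})

test_that("sc pages are expressible through public operations alone", {
  # rebuild the feature-selection page calling only exported builders and
  # compare the assembled serialization with the template's output
  via_template <- add_sc_page(create_dashboard("d"), ds, "feature_selection",
                              list(n_top = 7))
  hvg <- mean_variance_hvg(ds, n_top = 7)
  shown <- hvg[hvg$mean > 0 & hvg$variance > 0, , drop = FALSE]
  shown$log10_mean <- log10(shown$mean)
  shown$log10_variance <- log10(shown$variance)
  shown$selection <- ifelse(shown$hvg_flag, "highly variable", "other")
  by_hand <- create_dashboard("d")
  by_hand <- add_page(by_hand, "feature_selection", "Feature selection",
                      layout = "focal_left")
  by_hand <- add_component(by_hand, "feature_selection",
    fig_spec(shown, "scatter", x = "log10_mean", y = "log10_variance",
             color = "selection"),
    title = "Mean-variance relation")
  top <- hvg[hvg$hvg_flag, c("gene_id", "mean", "variance", "residual")]
  top <- top[order(-top$residual, top$gene_id), ]
  by_hand <- add_component(by_hand, "feature_selection", top,
                           title = "Top 7 highly variable genes")
  expect_identical(format(assemble(via_template)), format(assemble(by_hand)))
})

test_that("page templates never touch dashboard internals", {
  src_file <- testthat::test_path("..", "..", "R", "sc_pages.R")
  expect_true(file.exists(src_file))
  src <- paste(readLines(src_file), collapse = "\n")
  # structure is only read/written through the public builder API
  expect_false(grepl("$pages", src, fixed = TRUE))
  expect_false(grepl("$components", src, fixed = TRUE))
  expect_false(grepl("$links", src, fixed = TRUE))
  expect_false(grepl("new_fragment", src, fixed = TRUE))
  expect_false(grepl(":::", src, fixed = TRUE))
})
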