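test_that("qc metrics match hand-computed values", {
  M <- rbind(c(1, 0, 3), c(0, 0, 0), c(2, 2, 0))
  ds <- tiny_dataset(M, mito = c(FALSE, FALSE, TRUE))
  qc <- qc_metrics(ds)
  expect_identical(qc$total_counts, c(4, 0, 4))
  expect_identical(qc$detected_genes, c(2L, 0L, 2L))
  expect_equal(qc$pct_mito, c(75, 0, 0))
  expect_identical(qc$zero_total, c(FALSE, TRUE, FALSE))
  # conservation: per-cell totals sum to the grand matrix total
  expect_identical(sum(qc$total_counts), sum(M))
  expect_true(all(qc$pct_mito >= 0 & qc$pct_mito <= 100))
  expect_true(all(qc$detected_genes <= ncol(M)))
  expect_error(qc_metrics(tiny_dataset(matrix(-1, 1, 1))),
               class = "dw_validation_error")
})

test_that("grouped aggregation covers mean/median/sum and rejects others", {
  a <- aggregate_by_group(c(1, 2, 3, 4), c("a", "a", "b", "b"), "mean")
  expect_identical(a$level, c("a", "b"))
  expect_identical(a$value, c(1.5, 3.5))
  s <- aggregate_by_group(c(1, 2, 3, 4), c("a", "a", "b", "b"), "sum")
  expect_identical(sum(s$value), 10)
  m <- aggregate_by_group(c(1, 5, 9), c("x", "x", "x"), "median")
  expect_identical(m$value, 5)
  expect_error(aggregate_by_group(1:2, c("a", "b"), "max"), "valid",
               class = "dw_config_error")
  expect_error(aggregate_by_group(1:3, c("a", "b")), "equal length",
               class = "dw_validation_error")
})

test_that("log-normalized moments match a two-cell hand computation", {
  # both cells total exactly 10^4 counts, so CP10K leaves counts unchanged
  M <- cbind(geneA = c(0, 2), filler = c(10000, 9998))
  ds <- tiny_dataset(M)
  hvg <- mean_variance_hvg(ds, n_top = 1)
  a <- hvg[hvg$gene_id == "geneA", ]
  expect_equal(a$mean, log1p(2) / 2)
  expect_equal(a$variance, stats::var(c(0, log1p(2))))
})

test_that("hvg selection flags exactly n_top genes with ordered residuals", {
  sim <- small_sim()
  hvg <- mean_variance_hvg(sim$dataset, n_top = 15)
  expect_identical(sum(hvg$hvg_flag), 15L)
  expect_true(all(is.finite(hvg$residual[hvg$mean > 0 & hvg$variance > 0])))
  expect_gte(min(hvg$residual[hvg$hvg_flag]),
             max(hvg$residual[!hvg$hvg_flag]) - 1e-12)
  # boundary: all genes flagged
  all_flag <- mean_variance_hvg(sim$dataset, n_top = ncol(sim$dataset$counts))
  expect_true(all(all_flag$hvg_flag))
  expect_error(mean_variance_hvg(sim$dataset, n_top = ncol(sim$dataset$counts) + 1),
               "exceeds", class = "dw_validation_error")
})

test_that("hvg ties break lexicographically by gene id", {
  # two identical genes: same counts, same residual
  M <- cbind(zz = c(0, 5, 1, 3), aa = c(0, 5, 1, 3), other = c(2, 2, 2, 3))
  ds <- tiny_dataset(M)
  hvg <- mean_variance_hvg(ds, n_top = 1)
  tied <- hvg[hvg$gene_id %in% c("aa", "zz"), ]
  expect_equal(tied$residual[1], tied$residual[2])
  expect_identical(hvg$gene_id[hvg$hvg_flag], "aa")
})

test_that("marker scores are group-vs-rest mean differences with sign", {
  M <- matrix(0, 6, 3, dimnames = list(NULL, c("mk", "flat", "noise")))
  M[1:3, "mk"] <- 5            # expressed only in group A
  M[, "flat"] <- 4
  M[, "noise"] <- c(1, 0, 2, 1, 0, 2)
  ds <- sc_dataset(M, cell_meta = data.frame(grp = rep(c("A", "B"), each = 3)))
  mk <- rank_markers(ds, "grp", n_top = 3)
  a <- mk[mk$group == "A", ]
  expect_identical(a$gene_id[1], "mk")
  expect_gt(a$score[1], 0)
  b <- mk[mk$group == "B", ]
  expect_lt(b$score[b$gene_id == "mk"], 0)
  # ranks are 1..n_top with non-increasing scores in every group
  for (g in unique(mk$group)) {
    sub <- mk[mk$group == g, ]
    expect_identical(sub$rank, seq_len(nrow(sub)))
    expect_true(all(diff(sub$score) <= 1e-12))
  }
  expect_error(rank_markers(sc_dataset(M,
    cell_meta = data.frame(grp = rep("A", 6))), "grp"), "single level",
    class = "dw_validation_error")
  expect_error(rank_markers(ds, "nope"), "no column",
               class = "dw_validation_error")
})

test_that("marker ranking defaults to ten genes per group", {
  expect_identical(eval(formals(rank_markers)$n_top), 10L)
  sim <- small_sim()
  mk <- rank_markers(sim$dataset, "group")
  expect_identical(as.integer(table(mk$group)), rep(10L, 3L))
})

test_that("the built-in PCA embedding is deterministic with fixed signs", {
  sim <- small_sim()
  e1 <- embed_pca(sim$dataset)
  e2 <- embed_pca(sim$dataset)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(nrow(sim$dataset$counts), 2L))
})
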