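records <- local({
  set.seed(3)
  data.frame(x = rnorm(10), y = rnorm(10),
             g = rep(c("tcell", "bcell"), each = 5),
             v = c(1:5, 11:15))
})

test_that("links attach only between distinct components on linkable pages", {
  db <- linked_page_db(records)
  spec <- link_spec("p-c1", "p-c2", "subset_recompute",
                    aggregate = list(fun = "count", by = "g"))
  db <- add_link(db, "p", spec)
  expect_length(db$pages$p$links, 1)

  sb <- create_dashboard("d")
  sb <- add_page(sb, "s", "S", "storyboard")
  sb <- add_component(sb, "s", "a")
  sb <- add_component(sb, "s", "b")
  expect_error(add_link(sb, "s", spec), "not linkable", class = "dw_config_error")
  expect_error(link_spec("p-c1", "p-c1"), "itself", class = "dw_config_error")
  expect_error(add_link(db, "p", link_spec("p-c1", "p-c9",
    aggregate = list(fun = "count", by = "g"))), "not a component",
    class = "dw_config_error")
  expect_error(link_spec("a", "b", "subset_recompute"), "aggregate",
               class = "dw_config_error")
  expect_error(link_spec("a", "b", aggregate = list(fun = "max", by = "g")),
               "valid", class = "dw_config_error")
})

test_that("wiring has one entry per link with matching fragment ids", {
  db <- linked_page_db(records)
  db <- add_link(db, "p", link_spec("p-c1", "p-c2",
    aggregate = list(fun = "count", by = "g")))
  db <- add_link(db, "p", link_spec("p-c1", "p-c3",
    aggregate = list(fun = "mean", by = "g", var = "v")))
  w <- compile_wiring(db$pages$p)
  expect_identical(nrow(w), 2L)
  expect_identical(w$source, c("p-c1", "p-c1"))
  expect_identical(w$target, c("p-c2", "p-c3"))
  expect_identical(w$agg_fun, c("count", "mean"))
})

test_that("wiring compilation requires data payloads", {
  db <- create_dashboard("d")
  db <- add_page(db, "p", "P", "grid_2x2")
  db <- add_component(db, "p", "just text")
  db <- add_component(db, "p", "more text")
  db <- add_link(db, "p", link_spec("p-c1", "p-c2",
    aggregate = list(fun = "count", by = "g")))
  expect_error(compile_wiring(db$pages$p), "no data payload",
               class = "dw_compile_error")
})

test_that("selection counts match a brute-force recount and sum to |S|", {
  db <- linked_page_db(records)
  db <- add_link(db, "p", link_spec("p-c1", "p-c2",
    aggregate = list(fun = "count", by = "g")))
  w <- compile_wiring(db$pages$p)
  sel <- c(1, 2, 7)
  upd <- link_update(w[1, ], records, sel)
  brute <- table(factor(records$g[sel], levels = sort(unique(records$g))))
  expect_identical(upd$value, as.numeric(brute))
  expect_identical(sum(upd$value), 3)

  # empty selection restores the full-data aggregation
  full <- link_update(w[1, ], records, integer(0))
  expect_identical(sum(full$value), as.numeric(nrow(records)))

  set.seed(99)
  for (i in 1:50) {
    s <- sample(nrow(records), sample(0:nrow(records), 1))
    u <- link_update(w[1, ], records, s)
    expected <- if (length(s)) length(s) else nrow(records)
    expect_identical(sum(u$value), as.numeric(expected))
  }
})

test_that("mean/median/sum aggregations recompute over the selected subset", {
  db <- linked_page_db(records)
  db <- add_link(db, "p", link_spec("p-c1", "p-c3",
    aggregate = list(fun = "mean", by = "g", var = "v")))
  w <- compile_wiring(db$pages$p)
  sel <- c(1, 2, 6)
  upd <- link_update(w[1, ], records, sel)
  expect_equal(upd$value[upd$level == "tcell"], mean(records$v[c(1, 2)]))
  expect_equal(upd$value[upd$level == "bcell"], records$v[6])
})

test_that("a page with k components may carry up to k(k-1) links", {
  db <- linked_page_db(records) # 3 components on grid_2x2
  ids <- sprintf("p-c%d", 1:3)
  n <- 0L
  for (s in ids) for (t in setdiff(ids, s)) {
    db <- add_link(db, "p", link_spec(s, t, "color_by_selection"))
    n <- n + 1L
  }
  expect_identical(length(db$pages$p$links), 6L)
  expect_identical(n, 6L)
  expect_identical(nrow(compile_wiring(db$pages$p)), 6L)
})
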