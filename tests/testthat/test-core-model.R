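test_that("a fresh dashboard is empty and validates its theme", {
  db <- create_dashboard("QC report", "A. Author", "default", FALSE)
  expect_s3_class(db, "dashboard")
  expect_identical(db$title, "QC report")
  expect_length(db$pages, 0)
  expect_length(db$colormaps, 0)
  expect_length(db$navbar, 0)
  expect_error(create_dashboard("x", theme = "neon-disco"), "valid themes",
               class = "dw_config_error")
})

test_that("assembling a fresh dashboard yields a front-matter-only document", {
  txt <- format(assemble(create_dashboard("Empty", "Me")))
  expect_match(txt, "^---\ntitle: Empty\nauthor: Me\n")
  expect_false(grepl("\n# ", txt))
})

test_that("pages are added, replaced with a warning, and removed cleanly", {
  db <- create_dashboard("d")
  db <- add_page(db, "overview", "Overview", "focal_left")
  expect_length(db$pages, 1)
  expect_warning(db <- add_page(db, "overview", "Overview v2", "focal_left"),
                 "replaced")
  expect_length(db$pages, 1)
  expect_identical(db$pages$overview$title, "Overview v2")

  db <- add_navbar_item(db, "Home", "overview")
  expect_warning(db <- remove_page(db, "overview"), "navbar")
  expect_length(db$pages, 0)
  expect_length(db$navbar, 0)
  expect_warning(db2 <- remove_page(db, "ghost"), "does not exist")
  expect_identical(db2$pages, db$pages)
})

test_that("page ids must be slugs and are lowercased", {
  db <- create_dashboard("d")
  db <- add_page(db, "MyPage", "T", "tabset")
  expect_named(db$pages, "mypage")
  expect_error(add_page(db, "bad id!", "T"), "slug", class = "dw_config_error")
})

test_that("components get ordinal element ids and respect capacity", {
  db <- create_dashboard("d")
  db <- add_page(db, "p1", "P1", "storyboard")
  for (i in 1:10) db <- add_component(db, "p1", sprintf("note %d", i))
  expect_length(db$pages$p1$components, 10)
  expect_identical(db$pages$p1$components[[1]]$element_id, "p1-c1")
  expect_identical(db$pages$p1$components[[10]]$element_id, "p1-c10")

  db <- add_page(db, "f", "F", "focal_left")
  for (i in 1:3) db <- add_component(db, "f", "x")
  expect_error(add_component(db, "f", "overflow"), "at most 3",
               class = "dw_capacity_error")
  db <- add_page(db, "g", "G", "grid_2x2")
  for (i in 1:4) db <- add_component(db, "g", "x")
  expect_error(add_component(db, "g", "overflow"), "at most 4",
               class = "dw_capacity_error")
  expect_error(add_component(db, "nope", "x"), "does not exist",
               class = "dw_config_error")
})

test_that("colormaps are unique, validated, and resolve identically everywhere", {
  db <- create_dashboard("d")
  db <- add_colormap(db, "Condition", c(A = "#ff0000", B = "#00ff00"))
  expect_identical(resolve_colormap(db, "Condition", "A"), "#ff0000")
  expect_identical(resolve_colormap(db, "Condition", "A"),
                   resolve_colormap(db, "Condition", "A"))
  expect_error(add_colormap(db, "Condition", c(A = "#ffffff")),
               "already registered", class = "dw_config_error")
  db <- remove_colormap(db, "Condition")
  db <- add_colormap(db, "Condition", c(A = "#0000ff"))
  expect_identical(resolve_colormap(db, "Condition", "A"), "#0000ff")
  expect_error(add_colormap(db, "Bad", c(A = "red-ish")), "red-ish",
               class = "dw_config_error")
  expect_error(add_colormap(db, "Dup", c(A = "#ffffff", A = "#000000")),
               "unique", class = "dw_config_error")
})

test_that("two figures sharing a colormap render identical colors", {
  d <- data.frame(x = 1:4, y = 1:4, cond = c("A", "B", "A", "B"))
  db <- create_dashboard("d")
  db <- add_colormap(db, "Condition", c(A = "#ff0000", B = "#00ff00"))
  for (pid in c("one", "two")) {
    db <- add_page(db, pid, pid, "storyboard")
    db <- add_component(db, pid,
      fig_spec(d, "scatter", x = "x", y = "y", color = "cond",
               colormap = "Condition"))
  }
  doc <- assemble(db)
  svg1 <- doc$pages$one$fragments[[1]]$body
  svg2 <- doc$pages$two$fragments[[1]]$body
  expect_true(grepl("#ff0000", svg1, fixed = TRUE))
  expect_identical(svg1, svg2)
})

test_that("invariants survive randomized operation sequences", {
  set.seed(11)
  db <- create_dashboard("fuzz")
  layouts <- c("storyboard", "tabset", "focal_left", "grid_2x2")
  for (step in 1:120) {
    op <- sample(c("add_page", "add_component", "remove_page"), 1,
                 prob = c(0.3, 0.5, 0.2))
    suppressWarnings(switch(op,
      add_page = {
        db <- add_page(db, sample(sprintf("p%d", 1:6), 1), "T",
                       sample(layouts, 1))
      },
      add_component = if (length(db$pages)) {
        pid <- sample(names(db$pages), 1)
        db <- tryCatch(add_component(db, pid, "txt"),
                       dw_capacity_error = function(e) db)
      },
      remove_page = {
        db <- remove_page(db, sample(sprintf("p%d", 1:6), 1))
      }))
    expect_false(anyDuplicated(names(db$pages)) > 0)
    for (p in db$pages) {
      expect_lte(length(p$components), layout_capacity(p$layout))
      ids <- vapply(p$components, `[[`, character(1), "element_id")
      expect_false(anyDuplicated(ids) > 0)
    }
  }
})
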