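test_that("assembly emits pages in insertion order with verbatim bodies", {
  db <- create_dashboard("doc", "me")
  db <- add_page(db, "first", "First", "storyboard", menu = "Main")
  db <- add_component(db, "first", "## Heading\nSome *prose* here.")
  db <- add_page(db, "second", "Second", "tabset")
  txt <- format(assemble(db))
  expect_match(txt, "## Heading\nSome \\*prose\\* here.")
  expect_lt(regexpr("{#first", txt, fixed = TRUE),
            regexpr("{#second", txt, fixed = TRUE))
  expect_match(txt, 'menu="Main"', fixed = TRUE)
})

test_that("assembly is byte-deterministic", {
  build <- function() {
    db <- create_dashboard("doc", "me")
    db <- add_page(db, "p", "P", "grid_2x2")
    db <- add_component(db, "p",
      fig_spec(data.frame(x = 1:5, y = 5:1, g = rep(c("a", "b"), c(2, 3))),
               "scatter", x = "x", y = "y", color = "g"))
    db <- add_component(db, "p", data.frame(k = 1:3))
    format(assemble(db))
  }
  expect_identical(build(), build())
})

test_that("validation flags broken structure without throwing", {
  db <- create_dashboard("d")
  db <- add_page(db, "empty", "E", "storyboard")
  db <- add_colormap(db, "Unused", c(A = "#123456"))
  issues <- validate_dashboard(db)
  expect_identical(unique(issues$level), "warning")
  expect_true(any(grepl("no components", issues$message)))
  expect_true(any(grepl("unused", issues$message)))

  # a link whose endpoint has vanished (page internals manipulated to
  # emulate corruption) must be reported as an error and block assembly
  db <- add_component(db, "empty", "a")
  db2 <- db
  db2$pages$empty$layout <- "grid_2x2"
  db2$pages$empty$links <- list(link_spec("empty-c1", "empty-c9",
    aggregate = list(fun = "count", by = "g")))
  issues2 <- validate_dashboard(db2)
  expect_true(any(issues2$level == "error" &
                  grepl("missing component", issues2$message)))
  expect_error(assemble(db2), "fails validation", class = "dw_validation_error")

  ok <- create_dashboard("d")
  ok <- add_page(ok, "a", "A", "storyboard")
  ok <- add_component(ok, "a", "x")
  ok <- add_page(ok, "b", "B", "storyboard")
  ok <- add_component(ok, "b", "y")
  expect_identical(nrow(validate_dashboard(ok)), 0L)
})

test_that("rendered HTML is a single self-contained file", {
  png <- write_tiny_png(withr::local_tempfile(fileext = ".png"))
  db <- create_dashboard("Render test", "me", theme = "dark")
  db <- add_page(db, "p", "Pics", "storyboard", menu = "Media")
  db <- add_component(db, "p", png, title = "tiny")
  db <- add_component(db, "p", "plain *markdown*")
  out <- withr::local_tempfile(fileext = ".html")
  s <- render_html(assemble(db), out)
  expect_identical(s$pages, 1L)
  expect_identical(s$assets, 1L)
  html <- paste(readLines(out), collapse = "\n")
  expect_match(html, "<title>Render test</title>", fixed = TRUE)
  expect_match(html, 'class="theme-dark"', fixed = TRUE)
  expect_identical(length(gregexpr("data:image/png;base64", html)[[1]]), 1L)
  expect_false(grepl("asset://", html, fixed = TRUE))
  expect_length(scan_external_refs(out), 0)
  expect_match(html, "<em>markdown</em>", fixed = TRUE)
  expect_error(render_html(assemble(db), file.path(out, "nope", "x.html")),
               class = "dw_io_error")
})

test_that("empty dashboards render valid HTML with no wiring islands", {
  out <- withr::local_tempfile(fileext = ".html")
  render_html(assemble(create_dashboard("Nothing here")), out)
  html <- paste(readLines(out), collapse = "\n")
  expect_match(html, "<title>Nothing here</title>", fixed = TRUE)
  expect_false(grepl('class="dw-wiring"', html, fixed = TRUE))
})

test_that("wiring islands appear for linkable pages with links", {
  d <- data.frame(x = 1:4, y = 4:1, g = c("a", "a", "b", "b"), v = c(2, 4, 6, 8))
  db <- linked_page_db(d)
  db <- add_link(db, "p", link_spec("p-c1", "p-c2",
    aggregate = list(fun = "count", by = "g")))
  out <- withr::local_tempfile(fileext = ".html")
  render_html(assemble(db), out)
  html <- paste(readLines(out), collapse = "\n")
  expect_identical(length(gregexpr('class="dw-wiring"', html)[[1]]), 1L)
  expect_match(html, '"update_fun":"subset_recompute"', fixed = TRUE)
})

test_that("sidebars render globally and locally", {
  db <- create_dashboard("d")
  db <- add_page(db, "p", "P", "storyboard")
  db <- add_component(db, "p", "body text")
  db <- add_sidebar(db, "global note", scope = "global")
  db <- add_sidebar(db, "local note", scope = "local", page_id = "p")
  txt <- format(assemble(db))
  expect_match(txt, "::: sidebar scope=global")
  expect_match(txt, "::: sidebar scope=local")
  out <- withr::local_tempfile(fileext = ".html")
  render_html(assemble(db), out)
  html <- paste(readLines(out), collapse = "\n")
  expect_identical(length(gregexpr('class="dw-sidebar"', html)[[1]]), 2L)
})
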