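# The dashboard document model: a value object mutated functionally from
# within an analysis pipeline (every operation returns the updated
# dashboard), then assembled and rendered once at the end.

.dw_themes <- c("default", "dark", "light")

#' Initialize an empty dashboard
#'
#' Entry point of the builder API: creates a dashboard with no pages,
#' colormaps or navigation items. Content is added iteratively with
#' [add_page()], [add_component()], [add_colormap()] and [add_link()],
#' then serialized with [assemble()] and [render_html()].
#'
#' @param title Dashboard title.
#' @param author Author line shown in the document header.
#' @param theme Visual theme, one of `"default"`, `"dark"`, `"light"`.
#'   Themes switch the emitted stylesheet token only, never structure.
#' @param interactive If `TRUE` the document is marked for served
#'   (reactive) use; v1 renders the identical static HTML either way and
#'   serving is a stub.
#' @return A `dashboard` object.
#' @examples
#' db <- create_dashboard("QC report", "A. Author")
#' @export
create_dashboard <- function(title, author = "", theme = "default",
                             interactive = FALSE) {
  if (!theme %in% .dw_themes) {
    dw_stop(sprintf("unknown theme '%s'; valid themes: %s",
                    theme, paste(.dw_themes, collapse = ", ")), "config")
  }
  dw_log("created dashboard '%s'", title)
  structure(list(
    title = as.character(title), author = as.character(author),
    theme = theme, interactive = isTRUE(interactive),
    pages = structure(list(), names = character()),
    colormaps = structure(list(), names = character()),
    navbar = list(),
    sidebar_global = NULL
  ), class = "dashboard")
}

#' @export
print.dashboard <- function(x, ...) {
  cat(sprintf("dashboard '%s' by %s (theme %s, %s)\n", x$title, x$author,
              x$theme, if (x$interactive) "interactive" else "static"))
  cat(sprintf("  %d page(s), %d colormap(s), %d navbar item(s)\n",
              length(x$pages), length(x$colormaps), length(x$navbar)))
  for (p in x$pages) {
    cat(sprintf("  - %s '%s' [%s] %d component(s), %d link(s)\n",
                p$id, p$title, p$layout, length(p$components), length(p$links)))
  }
  invisible(x)
}

#' Add (or replace) a dashboard page
#'
#' Re-adding an existing page id replaces the page and emits a warning —
#' the iterative-pipeline workflow where later stages refine earlier pages.
#' Ids are lowercased; characters outside `[a-z0-9_]` are an error.
#'
#' @param db A [create_dashboard()] object.
#' @param id Page id (slug).
#' @param title Page title.
#' @param layout One of `"storyboard"`, `"tabset"`, `"focal_left"`,
#'   `"grid_2x2"`; see [layout_capacity()].
#' @param menu Optional navigation-menu grouping label.
#' @return The updated dashboard.
#' @export
add_page <- function(db, id, title, layout = "storyboard", menu = NULL) {
  stopifnot(inherits(db, "dashboard"))
  id <- check_slug(id, "page id")
  layout_capacity(layout) # validates layout name
  if (id %in% names(db$pages)) {
    warning(sprintf("page '%s' already exists and is replaced", id), call. = FALSE)
  }
  db$pages[[id]] <- structure(list(
    id = id, title = as.character(title), layout = layout,
    menu = if (is.null(menu)) NULL else as.character(menu),
    sidebar = NULL, components = list(), links = list()
  ), class = "dw_page")
  dw_log("added page '%s' (%s)", id, layout)
  db
}

#' Remove a page
#'
#' Navigation-bar items pointing at the removed page are dropped with a
#' warning; removing a missing id is a no-op with a warning.
#'
#' @inheritParams add_page
#' @return The updated dashboard.
#' @export
remove_page <- function(db, id) {
  stopifnot(inherits(db, "dashboard"))
  if (!id %in% names(db$pages)) {
    warning(sprintf("page '%s' does not exist; nothing removed", id), call. = FALSE)
    return(db)
  }
  db$pages[[id]] <- NULL
  refs <- vapply(db$navbar, function(it) identical(it$target, id), logical(1))
  if (any(refs)) {
    warning(sprintf("dropped %d navbar item(s) referencing removed page '%s'",
                    sum(refs), id), call. = FALSE)
    db$navbar <- db$navbar[!refs]
  }
  dw_log("removed page '%s'", id)
  db
}

#' Add content to a page
#'
#' The content is passed through [dispatch_content()] and the resulting
#' fragment is appended to the page, receiving the deterministic element id
#' `<page_id>-c<ordinal>`. Adding beyond the layout's capacity is a hard
#' error — components are never silently dropped.
#'
#' @inheritParams add_page
#' @param page_id Id of an existing page.
#' @param content Any content supported by [dispatch_content()].
#' @param title Optional component title.
#' @return The updated dashboard.
#' @export
add_component <- function(db, page_id, content, title = NULL) {
  stopifnot(inherits(db, "dashboard"))
  page <- db$pages[[page_id]]
  if (is.null(page)) dw_stop(sprintf("page '%s' does not exist", page_id), "config")
  cap <- layout_capacity(page$layout)
  if (length(page$components) + 1L > cap) {
    dw_stop(sprintf("page '%s' uses layout '%s' which holds at most %d components",
                    page_id, page$layout, cap), "capacity")
  }
  frag <- dispatch_content(content, title)
  frag$element_id <- sprintf("%s-c%d", page_id, length(page$components) + 1L)
  page$components <- c(page$components, list(frag))
  db$pages[[page_id]] <- page
  dw_log("added %s component '%s' to page '%s'", frag$kind, frag$element_id, page_id)
  db
}

#' Attach sidebar content
#'
#' A sidebar holds static content next to a page (`scope = "local"`) or
#' next to every page (`scope = "global"`). Sidebar content goes through
#' the same dispatch as page components but occupies a fixed-width rail
#' outside the slot plan.
#'
#' @inheritParams add_component
#' @param scope `"global"` or `"local"`; local requires `page_id`.
#' @return The updated dashboard.
#' @export
add_sidebar <- function(db, content, scope = c("local", "global"),
                        page_id = NULL, title = NULL) {
  stopifnot(inherits(db, "dashboard"))
  scope <- match.arg(scope)
  frag <- dispatch_content(content, title)
  if (scope == "global") {
    sb <- db$sidebar_global %||% list(scope = "global", fragments = list())
    frag$element_id <- sprintf("sidebar-g%d", length(sb$fragments) + 1L)
    sb$fragments <- c(sb$fragments, list(frag))
    db$sidebar_global <- sb
  } else {
    if (is.null(page_id) || is.null(db$pages[[page_id]])) {
      dw_stop("local sidebar needs an existing page_id", "config")
    }
    page <- db$pages[[page_id]]
    sb <- page$sidebar %||% list(scope = "local", fragments = list())
    frag$element_id <- sprintf("%s-s%d", page_id, length(sb$fragments) + 1L)
    sb$fragments <- c(sb$fragments, list(frag))
    page$sidebar <- sb
    db$pages[[page_id]] <- page
  }
  dw_log("added %s sidebar fragment", scope)
  db
}

#' Register a document-wide colormap
#'
#' A colormap is a named mapping from category levels to 6-digit hex
#' colors. Every component declaring the colormap name resolves identical
#' level-to-color assignments at render time, so a category looks the same
#' on every page. Re-registering an existing name is an error; remove it
#' first with [remove_colormap()].
#'
#' @inheritParams add_page
#' @param name Colormap name.
#' @param mapping Named character vector, level -> `"#rrggbb"`.
#' @return The updated dashboard.
#' @examples
#' db <- create_dashboard("d")
#' db <- add_colormap(db, "Condition", c(A = "#ff0000", B = "#00ff00"))
#' @export
add_colormap <- function(db, name, mapping) {
  stopifnot(inherits(db, "dashboard"))
  if (name %in% names(db$colormaps)) {
    dw_stop(sprintf("colormap '%s' is already registered; remove it first", name),
            "config")
  }
  db$colormaps[[name]] <- check_colormap(mapping)
  dw_log("registered colormap '%s' (%d levels)", name, length(mapping))
  db
}

#' @rdname add_colormap
#' @export
remove_colormap <- function(db, name) {
  stopifnot(inherits(db, "dashboard"))
  if (!name %in% names(db$colormaps)) {
    warning(sprintf("colormap '%s' is not registered", name), call. = FALSE)
    return(db)
  }
  db$colormaps[[name]] <- NULL
  db
}

#' Resolve one colormap level to its color
#'
#' Pure lookup: the same (colormap, level) pair yields the same color
#' everywhere in one document.
#'
#' @inheritParams add_colormap
#' @param level Category level.
#' @return Hex color string.
#' @export
resolve_colormap <- function(db, name, level) {
  cols <- resolve_colors(level, name, db$colormaps)
  unname(cols[as.character(level)])
}

#' Add a navigation-bar item
#'
#' @inheritParams add_page
#' @param label Link label.
#' @param target A page id (validated against existing pages) or an
#'   anchor within the document.
#' @return The updated dashboard.
#' @export
add_navbar_item <- function(db, label, target) {
  stopifnot(inherits(db, "dashboard"))
  if (is_slug(tolower(target)) && !target %in% names(db$pages)) {
    dw_stop(sprintf("navbar target '%s' is not an existing page id", target), "config")
  }
  db$navbar <- c(db$navbar, list(list(label = as.character(label),
                                      target = as.character(target))))
  db
}
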