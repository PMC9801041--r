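# Assembly: validate the dashboard, re-render figures against the
# document colormaps, compute slot plans and wiring, and serialize
# everything into a deterministic markdown-dialect intermediate document.

#' Validate a dashboard
#'
#' Collects structural problems without throwing: errors (broken link
#' endpoints, unregistered colormap references, capacity overflow,
#' duplicate element ids, dangling navbar targets) and warnings (empty
#' pages, unused colormaps). [assemble()] refuses to run while errors are
#' present.
#'
#' @inheritParams add_page
#' @return Data frame with columns `level` (`"error"`/`"warning"`),
#'   `location` and `message`; zero rows for a well-formed dashboard.
#' @export
validate_dashboard <- function(db) {
  stopifnot(inherits(db, "dashboard"))
  issues <- list()
  note <- function(level, location, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      level = level, location = location, message = message,
      stringsAsFactors = FALSE)
  }
  used_maps <- character()
  all_ids <- character()
  for (p in db$pages) {
    ids <- vapply(p$components, `[[`, character(1), "element_id")
    all_ids <- c(all_ids, ids)
    if (!length(p$components)) note("warning", p$id, "page has no components")
    if (length(p$components) > layout_capacity(p$layout)) {
      note("error", p$id, sprintf("layout '%s' capacity exceeded", p$layout))
    }
    if (length(p$links) && !layout_linkable(p$layout)) {
      note("error", p$id, sprintf("links on non-linkable layout '%s'", p$layout))
    }
    for (l in p$links) {
      for (endpoint in c(l$source, l$target)) {
        if (!endpoint %in% ids) {
          note("error", p$id, sprintf("link references missing component '%s'", endpoint))
        }
      }
      if (identical(l$source, l$target)) {
        note("error", p$id, sprintf("self-link on component '%s'", l$source))
      }
    }
    for (fr in p$components) {
      if (!is.null(fr$figure) && !is.null(fr$figure$colormap)) {
        used_maps <- c(used_maps, fr$figure$colormap)
        if (!fr$figure$colormap %in% names(db$colormaps)) {
          note("error", fr$element_id,
               sprintf("figure declares unregistered colormap '%s'", fr$figure$colormap))
        }
      }
      refs <- regmatches(fr$body, gregexpr("asset://[a-z0-9_]+", fr$body))[[1]]
      have <- paste0("asset://", vapply(fr$assets, `[[`, character(1), "id"))
      for (r in setdiff(refs, have)) {
        note("error", fr$element_id, sprintf("body references missing %s", r))
      }
    }
  }
  if (anyDuplicated(all_ids)) {
    note("error", "document", sprintf("duplicate element id(s): %s",
                                      paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  for (it in db$navbar) {
    if (is_slug(tolower(it$target)) && !it$target %in% names(db$pages)) {
      note("error", "navbar", sprintf("navbar item '%s' references missing page '%s'",
                                      it$label, it$target))
    }
  }
  for (nm in setdiff(names(db$colormaps), unique(used_maps))) {
    note("warning", "colormaps", sprintf("colormap '%s' is registered but unused", nm))
  }
  if (!length(issues)) {
    return(data.frame(level = character(), location = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Assemble a dashboard into the intermediate document
#'
#' Produces the deterministic markdown-dialect document: an ordered
#' front-matter header followed by one section per page (insertion order),
#' each carrying its layout directive, slot plan, component bodies and
#' wiring island. Identical dashboards assemble to byte-identical
#' serializations; figures declaring document colormaps are re-rendered
#' here so colors resolve document-wide.
#'
#' @inheritParams add_page
#' @return A `dw_idoc` object; serialize with `format()` or pass to
#'   [render_html()].
#' @export
assemble <- function(db) {
  stopifnot(inherits(db, "dashboard"))
  issues <- validate_dashboard(db)
  errs <- issues[issues$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    dw_stop(paste0("dashboard fails validation:\n", paste(
      sprintf("- [%s] %s", errs$location, errs$message), collapse = "\n")),
      "validation")
  }
  pages <- lapply(db$pages, function(p) {
    ids <- vapply(p$components, `[[`, character(1), "element_id")
    frags <- lapply(p$components, function(fr) {
      if (!is.null(fr$figure)) {
        fr$body <- render_figure_svg(fr$figure, fr$element_id, db$colormaps)
      }
      fr
    })
    list(id = p$id, title = p$title, layout = p$layout, menu = p$menu,
         sidebar = p$sidebar, fragments = frags,
         slots = assign_slots(p$layout, ids),
         wiring = compile_wiring(p))
  })
  structure(list(
    front_matter = list(title = db$title, author = db$author,
                        theme = db$theme, interactive = db$interactive),
    colormaps = db$colormaps,
    sidebar_global = db$sidebar_global,
    pages = pages
  ), class = "dw_idoc")
}

fragment_block <- function(fr, slot_row) {
  head <- sprintf("## %s {#%s kind=%s slot=%s width=%s height=%s}",
                  fr$title %||% fr$element_id, fr$element_id, fr$kind,
                  slot_row$slot, num_fmt(slot_row$width, 3), num_fmt(slot_row$height, 3))
  c(head, "", fr$body, "")
}

#' @export
format.dw_idoc <- function(x, ...) {
  fm <- x$front_matter
  out <- c("---",
           sprintf("title: %s", fm$title),
           sprintf("author: %s", fm$author),
           sprintf("theme: %s", fm$theme),
           sprintf("interactive: %s", tolower(as.character(fm$interactive))),
           "---", "")
  if (!is.null(x$sidebar_global)) {
    out <- c(out, "::: sidebar scope=global")
    for (fr in x$sidebar_global$fragments) out <- c(out, "", fr$body)
    out <- c(out, ":::", "")
  }
  for (p in x$pages) {
    menu_attr <- if (is.null(p$menu)) "" else sprintf(' menu="%s"', p$menu)
    out <- c(out, sprintf("# %s {#%s layout=%s%s}", p$title, p$id, p$layout, menu_attr), "")
    if (!is.null(p$sidebar)) {
      out <- c(out, "::: sidebar scope=local")
      for (fr in p$sidebar$fragments) out <- c(out, "", fr$body)
      out <- c(out, ":::", "")
    }
    for (i in seq_along(p$fragments)) {
      out <- c(out, fragment_block(p$fragments[[i]], p$slots[i, ]))
    }
    if (nrow(p$wiring)) {
      out <- c(out, sprintf("```{=dw-wiring page=%s}", p$id),
               dw_json(p$wiring), "```", "")
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.dw_idoc <- function(x, ...) {
  cat(sprintf("<intermediate document: %d page(s), theme %s>\n",
              length(x$pages), x$front_matter$theme))
  invisible(x)
}
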