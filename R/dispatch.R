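# Generic content dispatch: heterogeneous inputs (markdown text, image
# paths, tables, figure specs, callables) become uniform, emit-ready
# component fragments. This is the extension mechanism: template packages
# add ready-made pages purely by passing content through here.

.dw_kinds <- c("text", "image", "table", "figure", "injected")
.dw_image_ext <- c(png = "image/png", jpg = "image/jpeg", jpeg = "image/jpeg",
                   svg = "image/svg+xml")
.dw_table_row_cap <- 20L

new_fragment <- function(kind, body, title = NULL, assets = list(),
                         data_payload = NULL, figure = NULL) {
  structure(list(
    kind = kind, title = title, element_id = "", body = body,
    assets = assets, data_payload = data_payload, figure = figure
  ), class = "dw_fragment")
}

#' @export
print.dw_fragment <- function(x, ...) {
  cat(sprintf("<component %s kind=%s%s, %d asset(s)>\n",
              if (nzchar(x$element_id)) x$element_id else "(unassigned)",
              x$kind, if (is.null(x$title)) "" else paste0(" '", x$title, "'"),
              length(x$assets)))
  invisible(x)
}

#' Convert arbitrary supported content into a component fragment
#'
#' Dispatch on the content's class decides how it is emitted:
#' \itemize{
#'   \item character markdown: kind `text`, body verbatim (a path ending in
#'     `.png/.jpg/.jpeg/.svg` is treated as an image, `.csv/.tsv` as a
#'     table file);
#'   \item image path: kind `image`, payload embedded base64;
#'   \item data frame / matrix: kind `table`, a rendered table (capped at
#'     20 rows in the static body) plus the full records as data payload;
#'   \item [fig_spec()] object: kind `figure`, rendered SVG plus records;
#'   \item function with no required arguments: invoked exactly once, its
#'     returned markdown becomes the body verbatim (kind `injected`).
#' }
#'
#' @param content The content object.
#' @param title Optional component title.
#' @return A `dw_fragment` (element id assigned later by
#'   [add_component()]).
#' @export
dispatch_content <- function(content, title = NULL) {
  if (is.function(content)) {
    return(dispatch_callable(content, title))
  }
  if (inherits(content, "dw_figure")) {
    return(dispatch_figure(content, title))
  }
  if (is.data.frame(content) || (is.matrix(content) && !is.raw(content))) {
    return(dispatch_table(as.data.frame(content, stringsAsFactors = FALSE), title))
  }
  if (is.character(content)) {
    txt <- paste(content, collapse = "\n")
    ext <- tolower(tools::file_ext(trimws(txt)))
    if (length(content) == 1L && ext %in% names(.dw_image_ext)) {
      return(dispatch_image(trimws(txt), title))
    }
    if (length(content) == 1L && ext %in% c("csv", "tsv")) {
      return(dispatch_table_file(trimws(txt), title))
    }
    if (!nzchar(txt)) dw_stop("text content must be non-empty", "dispatch")
    return(new_fragment("text", body = txt, title = title))
  }
  dw_stop(sprintf(
    "unsupported content of class '%s'; supported kinds: %s",
    paste(class(content), collapse = "/"), paste(.dw_kinds, collapse = ", ")
  ), "dispatch")
}

dispatch_callable <- function(fn, title) {
  fm <- formals(fn)
  required <- names(fm)[vapply(fm, function(d) is.symbol(d) && identical(as.character(d), ""),
                               logical(1))]
  required <- setdiff(required, "...")
  if (length(required)) {
    dw_stop(sprintf("injected function has required argument(s) without defaults: %s",
                    paste(required, collapse = ", ")), "dispatch")
  }
  res <- tryCatch(fn(), error = function(e) {
    dw_stop(sprintf("injected content function failed: %s", conditionMessage(e)),
            "dispatch")
  })
  if (!is.character(res) || !length(res) || !any(nzchar(res))) {
    dw_stop("injected content function must return non-empty markdown text", "dispatch")
  }
  new_fragment("injected", body = paste(res, collapse = "\n"), title = title)
}

dispatch_image <- function(path, title) {
  if (!file.exists(path)) {
    dw_stop(sprintf("image file not found: '%s'", path), "io")
  }
  media <- .dw_image_ext[[tolower(tools::file_ext(path))]]
  asset <- list(id = "a1", media_type = media, payload = base64_file(path))
  body <- sprintf("![%s](asset://a1)", title %||% basename(path))
  new_fragment("image", body = body, title = title, assets = list(asset))
}

dispatch_table_file <- function(path, title) {
  if (!file.exists(path)) {
    dw_stop(sprintf("table file not found: '%s'", path), "io")
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  dispatch_table(df, title)
}

dispatch_table <- function(df, title) {
  if (!nrow(df) || !ncol(df)) dw_stop("table content must have rows and columns", "dispatch")
  shown <- utils::head(df, .dw_table_row_cap)
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(v == round(v), format(v, trim = TRUE, scientific = FALSE),
                              formatC(v, format = "g", digits = 5))
    else as.character(v)
  }
  cells <- vapply(shown, fmt, character(nrow(shown)))
  cells <- matrix(html_escape(cells), nrow = nrow(shown))
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  rows <- apply(cells, 1, function(r) paste0("<tr>", paste0("<td>", r, "</td>",
                                                            collapse = ""), "</tr>"))
  note <- if (nrow(df) > .dw_table_row_cap) {
    sprintf('<p class="dw-tablenote">Showing %d of %d rows; full data embedded.</p>',
            .dw_table_row_cap, nrow(df))
  } else character()
  body <- paste(c('<table class="dw-table">', head_row, rows, "</table>", note),
                collapse = "\n")
  new_fragment("table", body = body, title = title, data_payload = df)
}

dispatch_figure <- function(fig, title) {
  # rendered with the default palette here; assembly re-renders with the
  # document colormaps so a declared colormap resolves document-wide
  preview <- fig
  preview$colormap <- NULL
  body <- render_figure_svg(preview, element_id = "")
  payload <- if (!is.null(fig$data)) fig$data else {
    as.data.frame(as.table(fig$matrix), stringsAsFactors = FALSE)
  }
  new_fragment("figure", body = body, title = title,
               data_payload = payload, figure = fig)
}
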