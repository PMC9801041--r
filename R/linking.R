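# Declarative one-way links between components on a page. A selection in
# the source component either re-aggregates the target from the selected
# record subset (subset_recompute) or re-colors the target by membership
# (color_by_selection). Links compile into a data-driven wiring table
# consumed by one small script embedded in the rendered HTML; the same
# semantics are available in R via link_update() for testing and
# server-side use.

.dw_channels <- c("subset_recompute", "color_by_selection")
.dw_agg_funs <- c("count", "mean", "median", "sum")

#' Declare a link between two components
#'
#' @param source,target Component element ids on the same page; must
#'   differ.
#' @param channel `"subset_recompute"` (target shows an aggregate of the
#'   selected source records) or `"color_by_selection"` (target is
#'   re-colored by selection membership).
#' @param event Triggering event; only `"selection"` in v1.
#' @param aggregate For `subset_recompute`: aggregation descriptor
#'   `list(fun, by, var)` with `fun` one of count/mean/median/sum, `by`
#'   the grouping variable in the source records and `var` the value
#'   variable (ignored for `fun = "count"`).
#' @return A `dw_link` specification for [add_link()].
#' @export
link_spec <- function(source, target, channel = c("subset_recompute", "color_by_selection"),
                      event = "selection", aggregate = NULL) {
  channel <- match.arg(channel)
  if (!identical(event, "selection")) {
    dw_stop("only the 'selection' event is supported in v1", "config")
  }
  if (identical(source, target)) dw_stop("a component cannot link to itself", "config")
  if (channel == "subset_recompute") {
    if (is.null(aggregate) || is.null(aggregate$fun) || is.null(aggregate$by)) {
      dw_stop("subset_recompute links need aggregate = list(fun, by[, var])", "config")
    }
    if (!aggregate$fun %in% .dw_agg_funs) {
      dw_stop(sprintf("unknown aggregation '%s'; valid: %s", aggregate$fun,
                      paste(.dw_agg_funs, collapse = ", ")), "config")
    }
    if (aggregate$fun != "count" && is.null(aggregate$var)) {
      dw_stop(sprintf("aggregation '%s' needs a value variable 'var'", aggregate$fun),
              "config")
    }
  }
  structure(list(source = source, target = target, event = event,
                 channel = channel, aggregate = aggregate),
            class = "dw_link")
}

#' Attach a link to a page
#'
#' Only the linkable layouts (`focal_left`, `grid_2x2`) accept links; both
#' endpoints must be existing, distinct components of the page.
#'
#' @inheritParams add_component
#' @param spec A [link_spec()].
#' @return The updated dashboard.
#' @export
add_link <- function(db, page_id, spec) {
  stopifnot(inherits(db, "dashboard"), inherits(spec, "dw_link"))
  page <- db$pages[[page_id]]
  if (is.null(page)) dw_stop(sprintf("page '%s' does not exist", page_id), "config")
  if (!layout_linkable(page$layout)) {
    dw_stop(sprintf("layout '%s' of page '%s' is not linkable; linkable layouts: %s",
                    page$layout, page_id, paste(.dw_linkable, collapse = ", ")),
            "config")
  }
  ids <- vapply(page$components, `[[`, character(1), "element_id")
  for (endpoint in c(spec$source, spec$target)) {
    if (!endpoint %in% ids) {
      dw_stop(sprintf("link endpoint '%s' is not a component of page '%s'",
                      endpoint, page_id), "config")
    }
  }
  page$links <- c(page$links, list(spec))
  db$pages[[page_id]] <- page
  dw_log("linked %s -> %s (%s) on page '%s'", spec$source, spec$target,
         spec$channel, page_id)
  db
}

#' Compile a page's links into a wiring table
#'
#' One row per link: source element, event, target element, update function
#' identifier and aggregation descriptor. The table is serialized as a JSON
#' island in the rendered HTML and drives the embedded linking script; no
#' per-link code is generated.
#'
#' @param page A page object from a dashboard (`db$pages[[id]]`).
#' @return Data frame with columns `source`, `event`, `target`,
#'   `update_fun`, `agg_fun`, `agg_by`, `agg_var`.
#' @export
compile_wiring <- function(page) {
  stopifnot(inherits(page, "dw_page"))
  ids <- vapply(page$components, `[[`, character(1), "element_id")
  payload_of <- function(id) page$components[[match(id, ids)]]$data_payload
  rows <- lapply(page$links, function(l) {
    if (is.null(payload_of(l$source))) {
      dw_stop(sprintf("link source '%s' carries no data payload", l$source), "compile")
    }
    if (l$channel == "color_by_selection" && is.null(payload_of(l$target))) {
      dw_stop(sprintf("link target '%s' carries no data payload", l$target), "compile")
    }
    if (l$channel == "subset_recompute") {
      ag <- l$aggregate
      if (!ag$by %in% names(payload_of(l$source))) {
        dw_stop(sprintf("aggregation variable '%s' not in source '%s' payload",
                        ag$by, l$source), "compile")
      }
      data.frame(source = l$source, event = l$event, target = l$target,
                 update_fun = "subset_recompute", agg_fun = ag$fun,
                 agg_by = ag$by, agg_var = ag$var %||% NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = l$source, event = l$event, target = l$target,
                 update_fun = "color_by_selection", agg_fun = NA_character_,
                 agg_by = NA_character_, agg_var = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(source = character(), event = character(), target = character(),
                      update_fun = character(), agg_fun = character(),
                      agg_by = character(), agg_var = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Recompute a link target for a selection
#'
#' Reference implementation of the linked-view update semantics: given the
#' source component's records and a selection (integer indices), return the
#' per-level aggregate the target displays. An empty selection restores the
#' full-data view. The embedded client-side script mirrors exactly these
#' semantics.
#'
#' @param wiring_row One row of [compile_wiring()] output (as a list or
#'   1-row data frame).
#' @param records The source component's data payload (data frame).
#' @param selection Integer indices of selected records; `integer(0)` or
#'   `NULL` means no selection (full data).
#' @return Data frame with columns `level` and `value`, one row per level
#'   of the grouping variable (levels fixed from the full data, so counts
#'   include zero levels).
#' @export
link_update <- function(wiring_row, records, selection = NULL) {
  if (is.data.frame(wiring_row)) wiring_row <- as.list(wiring_row[1, ])
  if (!identical(wiring_row$update_fun, "subset_recompute")) {
    dw_stop("link_update recomputes subset_recompute links only", "compile")
  }
  lv <- sort(unique(as.character(records[[wiring_row$agg_by]])))
  sel <- if (is.null(selection) || !length(selection)) seq_len(nrow(records)) else selection
  sub <- records[sel, , drop = FALSE]
  g <- factor(as.character(sub[[wiring_row$agg_by]]), levels = lv)
  value <- if (wiring_row$agg_fun == "count") {
    as.numeric(table(g))
  } else {
    fn <- match.fun(wiring_row$agg_fun)
    vapply(lv, function(l) {
      v <- sub[[wiring_row$agg_var]][g == l]
      if (length(v)) fn(v) else NA_real_
    }, numeric(1))
  }
  data.frame(level = lv, value = value, stringsAsFactors = FALSE)
}
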