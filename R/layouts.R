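# Layout grammar: the four slot-bearing page layouts plus the sidebar
# attachment. Capacities and slot geometry live here and nowhere else, so an
# alternate geometry is a one-line change.

.dw_layouts <- c("storyboard", "tabset", "focal_left", "grid_2x2")
.dw_linkable <- c("focal_left", "grid_2x2")
.dw_focal_fraction <- 2 / 3

#' Component capacity of a page layout
#'
#' Storyboard and tabset pages hold an unlimited number of components;
#' the focal-left layout holds up to three and the 2x2 grid up to four.
#'
#' @param layout Layout name: one of `"storyboard"`, `"tabset"`,
#'   `"focal_left"`, `"grid_2x2"`.
#' @return A positive integer, or `Inf` for the unbounded layouts.
#' @examples
#' layout_capacity("focal_left") # 3
#' layout_capacity("grid_2x2")   # 4
#' @export
layout_capacity <- function(layout) {
  switch(layout,
    storyboard = Inf,
    tabset     = Inf,
    focal_left = 3L,
    grid_2x2   = 4L,
    dw_stop(sprintf("unknown layout '%s'; valid layouts: %s",
                    layout, paste(.dw_layouts, collapse = ", ")), "config")
  )
}

#' Is a layout linkable?
#'
#' Only the fixed-capacity layouts (`focal_left`, `grid_2x2`) support
#' linked views between their components.
#'
#' @inheritParams layout_capacity
#' @return `TRUE` or `FALSE`.
#' @export
layout_linkable <- function(layout) {
  layout_capacity(layout) # validates the name
  layout %in% .dw_linkable
}

#' Assign components to layout slots
#'
#' Deterministic, order-preserving slot assignment. For `focal_left` the
#' first component fills a left column of 2/3 page width and the remaining
#' components (at most two) stack equally in the right column. For
#' `grid_2x2` components fill the grid row-major; missing cells stay empty.
#' Storyboard and tabset get one full-width slot per component in input
#' order.
#'
#' @inheritParams layout_capacity
#' @param component_ids Character vector of component element ids, in page
#'   order.
#' @return A `dw_slot_plan`: data frame with columns `slot`, `width`,
#'   `height` (fractions of the page), and `component` (element id, or `""`
#'   for an empty slot).
#' @export
assign_slots <- function(layout, component_ids) {
  cap <- layout_capacity(layout)
  n <- length(component_ids)
  if (n > cap) {
    dw_stop(sprintf("layout '%s' holds at most %d components, got %d",
                    layout, cap, n), "capacity")
  }
  plan <- switch(layout,
    storyboard = ,
    tabset = data.frame(
      slot = if (n) paste0("panel", seq_len(n)) else character(),
      width = rep(1, n), height = rep(1, n),
      component = as.character(component_ids),
      stringsAsFactors = FALSE
    ),
    focal_left = {
      slots <- data.frame(
        slot = c("focal", "side1", "side2"),
        width = c(.dw_focal_fraction, rep(1 - .dw_focal_fraction, 2)),
        height = c(1, 0.5, 0.5),
        component = c(component_ids, rep("", 3L - n)),
        stringsAsFactors = FALSE
      )
      slots[seq_len(if (n <= 1L) n else 3L), , drop = FALSE]
    },
    grid_2x2 = data.frame(
      slot = c("r1c1", "r1c2", "r2c1", "r2c2"),
      width = rep(0.5, 4), height = rep(0.5, 4),
      component = c(component_ids, rep("", 4L - n)),
      stringsAsFactors = FALSE
    )
  )
  rownames(plan) <- NULL
  class(plan) <- c("dw_slot_plan", "data.frame")
  attr(plan, "layout") <- layout
  plan
}
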