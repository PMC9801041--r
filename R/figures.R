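# Declarative figure specifications and their deterministic SVG renderer.
#
# Figures are described by one declarative form (a data frame plus
# encodings, or a matrix for heatmaps) and rendered by the package itself
# into inline SVG, so documents stay self-contained and byte-stable.

#' Declare a figure for a dashboard component
#'
#' @param data Data frame holding the plotted records (ignored for
#'   `type = "heatmap"`).
#' @param type Trace type: scatter, bar, violin, box or heatmap.
#' @param x,y Column names in `data` mapped to the axes. For `bar` with `y
#'   = NULL` the bar height is the per-level record count of `x`.
#' @param color Optional column name encoding a categorical color variable.
#' @param colormap Optional name of a document-wide colormap used to
#'   resolve colors of `color` levels at assembly time.
#' @param matrix Numeric matrix (with dimnames) for `type = "heatmap"`.
#' @param xlab,ylab Axis labels; default to the mapped column names.
#' @param width,height Figure size in pixels.
#' @return A `dw_figure` specification, accepted by [dispatch_content()]
#'   and [add_component()].
#' @examples
#' fig_spec(data.frame(x = 1:3, y = c(2, 1, 3)), "scatter", x = "x", y = "y")
#' @export
fig_spec <- function(data = NULL, type = c("scatter", "bar", "violin", "box", "heatmap"),
                     x = NULL, y = NULL, color = NULL, colormap = NULL,
                     matrix = NULL, xlab = NULL, ylab = NULL,
                     width = 460, height = 300) {
  type <- match.arg(type)
  if (type == "heatmap") {
    if (is.null(matrix) || !is.matrix(matrix) || !is.numeric(matrix)) {
      dw_stop("heatmap figures need a numeric 'matrix' with dimnames", "dispatch")
    }
  } else {
    if (!is.data.frame(data)) dw_stop("figure 'data' must be a data frame", "dispatch")
    for (col in c(x, y, color)) {
      if (!col %in% names(data)) {
        dw_stop(sprintf("figure column '%s' not found in data", col), "dispatch")
      }
    }
    if (is.null(x)) dw_stop("figure needs an 'x' column", "dispatch")
    if (is.null(y) && type != "bar") dw_stop("figure needs a 'y' column", "dispatch")
  }
  structure(list(
    type = type, data = data, x = x, y = y, color = color,
    colormap = colormap, matrix = matrix,
    xlab = xlab %||% x, ylab = ylab %||% y,
    width = width, height = height
  ), class = "dw_figure")
}

#' @export
print.dw_figure <- function(x, ...) {
  cat(sprintf("<dw_figure %s: %s vs %s, %d records>\n", x$type,
              x$ylab %||% "-", x$xlab %||% "-",
              if (is.null(x$data)) length(x$matrix) else nrow(x$data)))
  invisible(x)
}

# ---- color resolution -------------------------------------------------------

# Levels are ordered lexicographically so the same variable gets the same
# palette everywhere in a document even without a registered colormap.
resolve_colors <- function(levels, colormap = NULL, colormaps = list()) {
  levels <- as.character(levels)
  if (!is.null(colormap)) {
    if (!colormap %in% names(colormaps)) {
      dw_stop(sprintf("colormap '%s' is not registered on the dashboard", colormap),
              "config")
    }
    map <- colormaps[[colormap]]
    missing <- setdiff(levels, names(map))
    if (length(missing)) {
      dw_stop(sprintf("colormap '%s' lacks level(s): %s", colormap,
                      paste(missing, collapse = ", ")), "config")
    }
    return(map[levels])
  }
  stats::setNames(dw_palette(length(levels)), levels)
}

# ---- SVG helpers ------------------------------------------------------------

.f2 <- function(x) formatC(x, format = "f", digits = 2)

svg_open <- function(w, h) {
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %d %d" width="%d" height="%d" class="dw-fig">',
          w, h, w, h)
}

svg_scale <- function(r, lo, hi) {
  rng <- range(r[is.finite(r)])
  if (!length(rng) || !is.finite(rng[1])) rng <- c(0, 1)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  pad <- diff(rng) * 0.05
  rng <- rng + c(-pad, pad)
  function(v) lo + (v - rng[1]) / diff(rng) * (hi - lo)
}

svg_axes <- function(sx, sy, xr, yr, xlab, ylab, m, w, h) {
  xt <- pretty(xr, 5); xt <- xt[xt >= min(xr) & xt <= max(xr)]
  yt <- pretty(yr, 5); yt <- yt[yt >= min(yr) & yt <= max(yr)]
  c(
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" class="dw-axis"/>',
            .f2(m$l), .f2(h - m$b), .f2(w - m$r), .f2(h - m$b)),
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" class="dw-axis"/>',
            .f2(m$l), .f2(m$t), .f2(m$l), .f2(h - m$b)),
    sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="middle">%s</text>',
            .f2(sx(xt)), .f2(h - m$b + 14), format(xt, trim = TRUE)),
    sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="end">%s</text>',
            .f2(m$l - 4), .f2(sy(yt) + 3), format(yt, trim = TRUE)),
    sprintf('<text x="%s" y="%s" class="dw-axislab" text-anchor="middle">%s</text>',
            .f2((m$l + w - m$r) / 2), .f2(h - 4), html_escape(xlab %||% "")),
    sprintf('<text x="12" y="%s" class="dw-axislab" text-anchor="middle" transform="rotate(-90 12 %s)">%s</text>',
            .f2((m$t + h - m$b) / 2), .f2((m$t + h - m$b) / 2), html_escape(ylab %||% ""))
  )
}

# ---- per-type renderers -----------------------------------------------------

render_figure_svg <- function(fig, element_id, colormaps = list()) {
  w <- fig$width; h <- fig$height
  m <- list(l = 55, r = 12, t = 10, b = 38)
  body <- switch(fig$type,
    scatter = svg_scatter(fig, m, w, h, colormaps),
    bar     = svg_bar(fig, m, w, h, colormaps),
    violin  = svg_violin(fig, m, w, h, colormaps, box = FALSE),
    box     = svg_violin(fig, m, w, h, colormaps, box = TRUE),
    heatmap = svg_heatmap(fig, m, w, h)
  )
  paste(c(svg_open(w, h), body, "</svg>"), collapse = "\n")
}

svg_scatter <- function(fig, m, w, h, colormaps) {
  d <- fig$data
  xv <- d[[fig$x]]; yv <- d[[fig$y]]
  sx <- svg_scale(xv, m$l, w - m$r); sy <- svg_scale(yv, h - m$b, m$t)
  fill <- rep("#1f77b4", nrow(d))
  legend <- character()
  if (!is.null(fig$color)) {
    cv <- as.character(d[[fig$color]])
    if (is.numeric(d[[fig$color]])) {
      fill <- ramp_colors(d[[fig$color]])
    } else {
      lv <- sort(unique(cv))
      cols <- resolve_colors(lv, fig$colormap, colormaps)
      fill <- unname(cols[cv])
      legend <- sprintf(
        '<circle cx="%s" cy="%s" r="4" fill="%s"/><text x="%s" y="%s" class="dw-ticklab">%s</text>',
        .f2(w - m$r - 86), .f2(m$t + 8 + 14 * (seq_along(lv) - 1)), cols,
        .f2(w - m$r - 78), .f2(m$t + 11 + 14 * (seq_along(lv) - 1)), html_escape(lv))
    }
  }
  pts <- sprintf('<circle class="dw-pt" data-i="%d" cx="%s" cy="%s" r="3" fill="%s"/>',
                 seq_len(nrow(d)) - 1L, .f2(sx(xv)), .f2(sy(yv)), fill)
  c(svg_axes(sx, sy, range(xv, finite = TRUE), range(yv, finite = TRUE),
             fig$xlab, fig$ylab, m, w, h), pts, legend)
}

svg_bar <- function(fig, m, w, h, colormaps) {
  d <- fig$data
  lv <- sort(unique(as.character(d[[fig$x]])))
  val <- if (is.null(fig$y)) {
    as.numeric(table(factor(as.character(d[[fig$x]]), levels = lv)))
  } else {
    vapply(lv, function(l) mean(d[[fig$y]][d[[fig$x]] == l]), numeric(1))
  }
  cols <- resolve_colors(lv, fig$colormap, colormaps)
  sy <- svg_scale(c(0, val), h - m$b, m$t)
  n <- length(lv)
  bw <- (w - m$l - m$r) / max(n, 1)
  x0 <- m$l + bw * (seq_len(n) - 1) + bw * 0.1
  bars <- sprintf('<rect class="dw-bar" data-level="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                  html_escape(lv), .f2(x0), .f2(sy(val)), .f2(bw * 0.8),
                  .f2(sy(0) - sy(val)), cols)
  labs <- sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="middle">%s</text>',
                  .f2(x0 + bw * 0.4), .f2(h - m$b + 14), html_escape(lv))
  yr <- range(c(0, val))
  yt <- pretty(yr, 5); yt <- yt[yt >= yr[1] & yt <= yr[2]]
  c(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" class="dw-axis"/>',
            .f2(m$l), .f2(h - m$b), .f2(w - m$r), .f2(h - m$b)),
    sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="end">%s</text>',
            .f2(m$l - 4), .f2(sy(yt) + 3), format(yt, trim = TRUE)),
    bars, labs,
    sprintf('<text x="%s" y="%s" class="dw-axislab" text-anchor="middle">%s</text>',
            .f2((m$l + w - m$r) / 2), .f2(h - 4), html_escape(fig$xlab %||% "")))
}

svg_violin <- function(fig, m, w, h, colormaps, box = FALSE) {
  d <- fig$data
  grp <- if (!is.null(fig$color)) as.character(d[[fig$color]]) else as.character(d[[fig$x]])
  lv <- sort(unique(grp))
  cols <- resolve_colors(lv, fig$colormap, colormaps)
  yv <- d[[fig$y]]
  sy <- svg_scale(yv, h - m$b, m$t)
  n <- length(lv)
  bw <- (w - m$l - m$r) / max(n, 1)
  out <- character()
  for (i in seq_len(n)) {
    v <- yv[grp == lv[i]]
    cx <- m$l + bw * (i - 0.5)
    if (!box && length(unique(v)) >= 3) {
      den <- stats::density(v, n = 32)
      hw <- den$y / max(den$y) * bw * 0.38
      xs <- c(cx - hw, rev(cx + hw)); ys <- sy(c(den$x, rev(den$x)))
      out <- c(out, sprintf('<polygon points="%s" fill="%s" fill-opacity="0.6" stroke="%s"/>',
                            paste(paste(.f2(xs), .f2(ys), sep = ","), collapse = " "),
                            cols[i], cols[i]))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    out <- c(out,
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" fill-opacity="%s" stroke="#333333"/>',
              .f2(cx - bw * 0.12), .f2(sy(q[3])), .f2(bw * 0.24),
              .f2(max(sy(q[1]) - sy(q[3]), 0.5)), cols[i], if (box) "0.6" else "0.9"),
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#111111" stroke-width="1.5"/>',
              .f2(cx - bw * 0.12), .f2(sy(q[2])), .f2(cx + bw * 0.12), .f2(sy(q[2]))),
      sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="middle">%s</text>',
              .f2(cx), .f2(h - m$b + 14), html_escape(lv[i])))
  }
  yr <- range(yv, finite = TRUE)
  yt <- pretty(yr, 5); yt <- yt[yt >= yr[1] & yt <= yr[2]]
  c(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" class="dw-axis"/>',
            .f2(m$l), .f2(m$t), .f2(m$l), .f2(h - m$b)),
    sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="end">%s</text>',
            .f2(m$l - 4), .f2(sy(yt) + 3), format(yt, trim = TRUE)),
    out,
    sprintf('<text x="12" y="%s" class="dw-axislab" text-anchor="middle" transform="rotate(-90 12 %s)">%s</text>',
            .f2((m$t + h - m$b) / 2), .f2((m$t + h - m$b) / 2), html_escape(fig$ylab %||% "")))
}

# diverging blue-white-red ramp over the finite data range
ramp_colors <- function(v) {
  r <- range(v[is.finite(v)])
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  t <- pmin(pmax((v - r[1]) / diff(r), 0), 1)
  lo <- grDevices::col2rgb("#2166ac"); mid <- grDevices::col2rgb("#f7f7f7")
  hi <- grDevices::col2rgb("#b2182b")
  mix <- function(a, b, t) round(a + (b - a) * t)
  rgb_of <- function(t) {
    ifelse(t <= 0.5,
      grDevices::rgb(mix(lo[1], mid[1], t * 2), mix(lo[2], mid[2], t * 2),
                     mix(lo[3], mid[3], t * 2), maxColorValue = 255),
      grDevices::rgb(mix(mid[1], hi[1], (t - 0.5) * 2), mix(mid[2], hi[2], (t - 0.5) * 2),
                     mix(mid[3], hi[3], (t - 0.5) * 2), maxColorValue = 255))
  }
  vapply(t, rgb_of, character(1))
}

svg_heatmap <- function(fig, m, w, h) {
  M <- fig$matrix
  nr <- nrow(M); nc <- ncol(M)
  m$l <- 90; m$b <- 50
  cw <- (w - m$l - m$r) / nc; ch <- (h - m$t - m$b) / nr
  cols <- matrix(ramp_colors(as.vector(M)), nr, nc)
  cells <- character()
  for (i in seq_len(nr)) {
    cells <- c(cells, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s / %s: %s</title></rect>',
      .f2(m$l + cw * (seq_len(nc) - 1)), .f2(m$t + ch * (i - 1)),
      .f2(cw), .f2(ch), cols[i, ],
      html_escape(rownames(M)[i] %||% i), html_escape(colnames(M)), .f2(M[i, ])))
  }
  rlab <- sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="end">%s</text>',
                  .f2(m$l - 4), .f2(m$t + ch * (seq_len(nr) - 0.5) + 3),
                  html_escape(rownames(M) %||% as.character(seq_len(nr))))
  clab <- sprintf('<text x="%s" y="%s" class="dw-ticklab" text-anchor="middle">%s</text>',
                  .f2(m$l + cw * (seq_len(nc) - 0.5)), .f2(h - m$b + 14),
                  html_escape(colnames(M) %||% as.character(seq_len(nc))))
  c(cells, rlab, clab)
}
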