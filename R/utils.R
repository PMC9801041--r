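#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish configuration, capacity,
# dispatch and validation failures programmatically.
dw_stop <- function(msg, class = "generic", call. = FALSE) {
  stop(structure(
    class = c(paste0("dw_", class, "_error"), "dw_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

dw_log <- function(...) {
  if (isTRUE(getOption("dashweave.verbose", FALSE))) {
    message("[dashweave] ", sprintf(...))
  }
  invisible(NULL)
}

is_slug <- function(x) {
  is.character(x) && length(x) == 1L && nzchar(x) && grepl("^[a-z0-9_]+$", x)
}

check_slug <- function(id, what = "id") {
  id <- tolower(id)
  if (!is_slug(id)) {
    dw_stop(sprintf(
      "%s '%s' is not slug-safe: only lowercase alphanumerics and underscore are allowed",
      what, paste(id, collapse = ",")
    ), "config")
  }
  id
}

is_hex_color <- function(x) grepl("^#[0-9a-fA-F]{6}$", x)

check_colormap <- function(mapping) {
  if (length(mapping) == 0 || is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    dw_stop("a colormap must be a named character vector of level -> hex color", "config")
  }
  if (anyDuplicated(names(mapping))) {
    dw_stop("colormap levels must be unique", "config")
  }
  bad <- mapping[!is_hex_color(mapping)]
  if (length(bad)) {
    dw_stop(sprintf("invalid hex color(s): %s (expected '#rrggbb')",
                    paste(bad, collapse = ", ")), "config")
  }
  mapping
}

# Deterministic fallback palette used when no document colormap applies.
dw_palette <- function(n) {
  base <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
            "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
  rep_len(base, n)
}

base64_file <- function(path) {
  jsonlite::base64_enc(readBin(path, "raw", n = file.size(path)))
}

num_fmt <- function(x, digits = 4) {
  # fixed-notation formatting so serialized output is byte-stable
  ifelse(is.finite(x), formatC(x, format = "f", digits = digits), as.character(x))
}

dw_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
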