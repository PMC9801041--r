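# Minimal markdown-to-HTML conversion for component bodies: headings,
# paragraphs, lists, fenced code, inline emphasis/code/links/images. Raw
# HTML blocks (tables, inline SVG) pass through untouched.

md_inline <- function(x) {
  x <- gsub("!\\[([^]]*)\\]\\(([^)]+)\\)", '<img alt="\\1" src="\\2"/>', x)
  x <- gsub("\\[([^]]+)\\]\\(([^)]+)\\)", '<a href="\\2">\\1</a>', x)
  x <- gsub("`([^`]+)`", "<code>\\1</code>", x)
  x <- gsub("\\*\\*([^*]+)\\*\\*", "<strong>\\1</strong>", x)
  gsub("(?<![*\\w])\\*([^*]+)\\*(?![*\\w])", "<em>\\1</em>", x, perl = TRUE)
}

md_to_html <- function(text) {
  if (grepl("^\\s*<", text)) return(text) # raw HTML / SVG body
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- character(); para <- character(); in_code <- FALSE; in_list <- FALSE
  flush_para <- function() {
    if (length(para)) out <<- c(out, paste0("<p>", md_inline(paste(para, collapse = " ")), "</p>"))
    para <<- character()
  }
  close_list <- function() { if (in_list) { out <<- c(out, "</ul>"); in_list <<- FALSE } }
  for (ln in lines) {
    if (grepl("^```", ln)) {
      flush_para(); close_list()
      out <- c(out, if (in_code) "</code></pre>" else "<pre><code>")
      in_code <- !in_code
    } else if (in_code) {
      out <- c(out, html_escape(ln))
    } else if (grepl("^#{1,6} ", ln)) {
      flush_para(); close_list()
      lvl <- nchar(sub("^(#+) .*", "\\1", ln))
      out <- c(out, sprintf("<h%d>%s</h%d>", lvl, md_inline(sub("^#+ ", "", ln)), lvl))
    } else if (grepl("^[-*] ", ln)) {
      flush_para()
      if (!in_list) { out <- c(out, "<ul>"); in_list <- TRUE }
      out <- c(out, paste0("<li>", md_inline(sub("^[-*] ", "", ln)), "</li>"))
    } else if (!nzchar(trimws(ln))) {
      flush_para(); close_list()
    } else {
      close_list(); para <- c(para, ln)
    }
  }
  flush_para(); close_list()
  paste(out, collapse = "\n")
}
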