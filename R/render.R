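# HTML rendering: the intermediate document becomes one self-contained
# HTML file. All assets are embedded as data URIs, all styles and scripts
# are inline, and no timestamps are emitted, so repeated builds are
# byte-identical and the file needs no network access.

.dw_css <- '
body{font-family:system-ui,sans-serif;margin:0;line-height:1.45}
body.theme-default{background:#ffffff;color:#1a1a1a}
body.theme-light{background:#fafaf5;color:#222222}
body.theme-dark{background:#1e1e24;color:#e8e8e8}
body.theme-dark .dw-component{background:#2a2a32;border-color:#444}
nav.dw-nav{display:flex;gap:1em;align-items:center;padding:.5em 1em;
  background:#2c3e50;color:#fff;position:sticky;top:0;flex-wrap:wrap}
nav.dw-nav a{color:#fff;text-decoration:none}
nav.dw-nav .dw-menu{font-weight:bold}
nav.dw-nav .dw-title{font-size:1.15em;font-weight:bold;margin-right:1.5em}
section.dw-page{padding:1em 1.5em;border-bottom:2px solid #ddd}
.dw-pagebody{display:flex;flex-wrap:wrap;gap:.8em;align-items:stretch}
.dw-col{display:flex;flex-direction:column;gap:.8em}
.dw-component{border:1px solid #ccc;border-radius:6px;padding:.6em;
  background:#fdfdfd;box-sizing:border-box;overflow:auto}
.dw-component h3{margin:.1em 0 .4em 0;font-size:1em}
.dw-sidebar{float:left;width:220px;margin-right:1em;padding:.6em;
  background:#eef1f4;border-radius:6px}
table.dw-table{border-collapse:collapse;font-size:.85em}
table.dw-table th,table.dw-table td{border:1px solid #bbb;padding:2px 6px}
.dw-tablenote{font-size:.75em;color:#777}
.dw-ticklab{font-size:9px;fill:#555}
.dw-axislab{font-size:11px;fill:#333}
.dw-axis{stroke:#333;stroke-width:1}
.dw-pt{cursor:pointer}
.dw-pt.dw-selected{stroke:#000;stroke-width:2}
.dw-pt.dw-dim{opacity:.15}
.dw-tabbar{display:flex;gap:.4em;margin-bottom:.6em;flex-wrap:wrap}
.dw-tabbar button{padding:.3em .8em;border:1px solid #999;background:#eee;
  border-radius:4px;cursor:pointer}
.dw-tabbar button.dw-active{background:#2c3e50;color:#fff}
.dw-footer{padding:.6em 1.5em;font-size:.8em;color:#888}
tr.dw-rowsel{background:#ffe9a8}
'

# Data-driven client runtime: reads the wiring JSON islands and mirrors the
# link_update() semantics (subset_recompute aggregations, selection
# re-coloring). One script for the whole document; no per-link code.
.dw_js <- '
(function(){
"use strict";
function parseIsland(el){try{return JSON.parse(el.textContent);}catch(e){return null;}}
var data={};
document.querySelectorAll("script.dw-data").forEach(function(el){
  data[el.getAttribute("data-for")]=parseIsland(el);});
function agg(rows,fun,by,v){
  var lv=[]; rows.forEach(function(r){var k=String(r[by]);
    if(lv.indexOf(k)<0)lv.push(k);}); lv.sort();
  return {levels:lv,of:function(sub){
    return lv.map(function(l){
      var vals=sub.filter(function(r){return String(r[by])===l;});
      if(fun==="count")return vals.length;
      var xs=vals.map(function(r){return Number(r[v]);});
      if(!xs.length)return null;
      if(fun==="sum")return xs.reduce(function(a,b){return a+b;},0);
      if(fun==="mean")return xs.reduce(function(a,b){return a+b;},0)/xs.length;
      xs.sort(function(a,b){return a-b;});
      var m=Math.floor(xs.length/2);
      return xs.length%2?xs[m]:(xs[m-1]+xs[m])/2;});
  }};
}
function updateBars(target,levels,values){
  var svg=document.getElementById(target); if(!svg)return;
  var max=Math.max.apply(null,values.filter(function(x){return x!==null;}).concat([1e-9]));
  svg.querySelectorAll(".dw-bar").forEach(function(b){
    var i=levels.indexOf(b.getAttribute("data-level")); if(i<0)return;
    var v=values[i]===null?0:values[i];
    var y0=Number(b.getAttribute("y"))+Number(b.getAttribute("height"));
    var full=Number(b.getAttribute("data-full")||(y0-10));
    if(!b.hasAttribute("data-full"))b.setAttribute("data-full",String(full));
    var hgt=max>0?(v/max)*full:0;
    b.setAttribute("height",String(Math.max(hgt,0)));
    b.setAttribute("y",String(y0-Math.max(hgt,0)));
    b.querySelector("title")&&(b.querySelector("title").textContent=String(v));});
}
function recolor(target,sel){
  var svg=document.getElementById(target); if(!svg)return;
  svg.querySelectorAll(".dw-pt").forEach(function(p){
    var i=Number(p.getAttribute("data-i"));
    p.classList.toggle("dw-dim",sel.length>0&&sel.indexOf(i)<0);});
}
document.querySelectorAll("script.dw-wiring").forEach(function(el){
  var wiring=parseIsland(el)||[];
  wiring.forEach(function(w){
    var src=document.getElementById(w.source); if(!src)return;
    var rows=data[w.source]||[]; var sel=[];
    var run=function(){
      var sub=sel.length?sel.map(function(i){return rows[i];}):rows;
      if(w.update_fun==="subset_recompute"){
        var a=agg(rows,w.agg_fun,w.agg_by,w.agg_var);
        updateBars(w.target,a.levels,a.of(sub));
      }else{recolor(w.target,sel);}
    };
    src.querySelectorAll(".dw-pt,tr").forEach(function(p,ri){
      p.addEventListener("click",function(ev){
        var i=p.classList.contains("dw-pt")?Number(p.getAttribute("data-i")):ri-1;
        if(i<0)return;
        var at=sel.indexOf(i);
        if(!ev.shiftKey)sel=[];
        if(at<0)sel.push(i);
        p.classList.toggle("dw-selected");
        run();});});
  });
});
var tabsets=document.querySelectorAll("section.dw-page[data-layout=tabset]");
tabsets.forEach(function(sec){
  var panels=sec.querySelectorAll(".dw-component");
  var bar=sec.querySelector(".dw-tabbar"); if(!bar)return;
  bar.querySelectorAll("button").forEach(function(btn,i){
    btn.addEventListener("click",function(){
      panels.forEach(function(p,j){p.style.display=i===j?"":"none";});
      bar.querySelectorAll("button").forEach(function(b,j){
        b.classList.toggle("dw-active",i===j);});});
    if(i>0)panels[i].style.display="none"; else btn.classList.add("dw-active");});
});
})();
'

resolve_assets <- function(body, assets) {
  for (a in assets) {
    body <- gsub(paste0("asset://", a$id),
                 sprintf("data:%s;base64,%s", a$media_type, a$payload),
                 body, fixed = TRUE)
  }
  body
}

render_fragment_html <- function(fr) {
  body <- resolve_assets(fr$body, fr$assets)
  body <- switch(fr$kind,
    text = , injected = , image = md_to_html(body),
    body)
  title_html <- if (!is.null(fr$title)) sprintf("<h3>%s</h3>", html_escape(fr$title)) else ""
  payload <- if (!is.null(fr$data_payload)) {
    sprintf('<script type="application/json" class="dw-data" data-for="%s">%s</script>',
            fr$element_id, dw_json(fr$data_payload))
  } else ""
  paste0('<div class="dw-component" id="', fr$element_id, '" data-kind="',
         fr$kind, '">', title_html, "\n", body, "\n", payload, "</div>")
}

render_page_html <- function(p) {
  parts <- c(sprintf('<section class="dw-page" id="page-%s" data-layout="%s">', p$id, p$layout),
             sprintf("<h1>%s</h1>", html_escape(p$title)))
  if (!is.null(p$sidebar)) {
    parts <- c(parts, '<aside class="dw-sidebar">',
               vapply(p$sidebar$fragments,
                      function(fr) md_to_html(resolve_assets(fr$body, fr$assets)),
                      character(1)),
               "</aside>")
  }
  frag_html <- vapply(p$fragments, render_fragment_html, character(1))
  n <- length(p$fragments)
  if (p$layout == "tabset" && n) {
    labels <- vapply(p$fragments, function(fr) fr$title %||% fr$element_id, character(1))
    parts <- c(parts,
               '<div class="dw-tabbar">',
               sprintf("<button>%s</button>", html_escape(labels)),
               "</div>", '<div class="dw-pagebody dw-tabpanels">', frag_html, "</div>")
  } else if (p$layout == "focal_left" && n) {
    focal <- frag_html[1]
    side <- if (n > 1) frag_html[-1] else character()
    parts <- c(parts, '<div class="dw-pagebody">',
               sprintf('<div class="dw-col" style="flex:2 1 0">%s</div>', focal),
               if (length(side)) sprintf('<div class="dw-col" style="flex:1 1 0">%s</div>',
                                         paste(side, collapse = "\n")),
               "</div>")
  } else if (p$layout == "grid_2x2" && n) {
    cells <- sprintf('<div style="flex:0 0 48%%">%s</div>', frag_html)
    parts <- c(parts, '<div class="dw-pagebody">', cells, "</div>")
  } else if (n) {
    parts <- c(parts, '<div class="dw-pagebody" style="flex-direction:column">',
               frag_html, "</div>")
  }
  if (nrow(p$wiring)) {
    parts <- c(parts, sprintf(
      '<script type="application/json" class="dw-wiring" data-page="%s">%s</script>',
      p$id, dw_json(p$wiring)))
  }
  c(parts, "</section>")
}

render_nav_html <- function(doc) {
  fm <- doc$front_matter
  items <- c(sprintf('<span class="dw-title">%s</span>', html_escape(fm$title)))
  menus <- list()
  for (p in doc$pages) {
    link <- sprintf('<a href="#page-%s">%s</a>', p$id, html_escape(p$title))
    if (is.null(p$menu)) items <- c(items, link)
    else menus[[p$menu]] <- c(menus[[p$menu]] %||% character(), link)
  }
  for (m in names(menus)) {
    items <- c(items, sprintf('<span class="dw-menu">%s:</span>', html_escape(m)),
               menus[[m]])
  }
  c('<nav class="dw-nav">', items, "</nav>")
}

#' Render an intermediate document to self-contained HTML
#'
#' Emits one HTML5 file with every image, data record, style and script
#' embedded inline — zero external references — and a navigation bar
#' listing pages grouped by menu. Output is byte-identical across repeated
#' renders of the same document.
#'
#' @param doc A `dw_idoc` from [assemble()].
#' @param out_path Output file path.
#' @return Invisibly, a summary list: `bytes` written, `pages`, `assets`.
#' @export
render_html <- function(doc, out_path) {
  stopifnot(inherits(doc, "dw_idoc"))
  fm <- doc$front_matter
  n_assets <- sum(vapply(doc$pages, function(p) {
    sum(vapply(p$fragments, function(fr) length(fr$assets), integer(1)))
  }, integer(1)))
  html <- c(
    "<!DOCTYPE html>", '<html lang="en">', "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", html_escape(fm$title)),
    sprintf("<style>%s</style>", .dw_css),
    "</head>",
    sprintf('<body class="theme-%s">', fm$theme),
    render_nav_html(doc),
    if (!is.null(doc$sidebar_global)) {
      c('<aside class="dw-sidebar">',
        vapply(doc$sidebar_global$fragments,
               function(fr) md_to_html(resolve_assets(fr$body, fr$assets)), character(1)),
        "</aside>")
    },
    unlist(lapply(doc$pages, render_page_html)),
    sprintf('<footer class="dw-footer">%s%s</footer>',
            html_escape(fm$author),
            if (isTRUE(fm$interactive)) " &mdash; served mode is a stub in this build; the document is fully static" else ""),
    sprintf("<script>%s</script>", .dw_js),
    "</body>", "</html>"
  )
  txt <- paste(html, collapse = "\n")
  con <- withCallingHandlers(
    tryCatch(file(out_path, open = "wb"), # \n endings on every platform
             error = function(e) dw_stop(sprintf("cannot write '%s': %s", out_path,
                                                 conditionMessage(e)), "io")),
    warning = function(w) invokeRestart("muffleWarning"))
  on.exit(close(con))
  writeChar(paste0(txt, "\n"), con, eos = NULL)
  dw_log("rendered %s (%d bytes)", out_path, nchar(txt, type = "bytes"))
  invisible(list(bytes = nchar(txt, type = "bytes"),
                 pages = length(doc$pages), assets = n_assets))
}

#' Scan rendered HTML for external references
#'
#' Machine check of the self-containment contract: looks for `src`/`href`
#' attributes, CSS `url()` values and script/link tags pointing at
#' `http(s)://` locations. Anchors and visible text are not flagged.
#'
#' @param path Path to a rendered HTML file.
#' @return Character vector of offending references (empty when
#'   self-contained).
#' @export
scan_external_refs <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  pat <- c('src="https?://[^"]*', 'href="https?://[^"]*',
           "url\\(https?://[^)]*", '<link [^>]*href=[^>]*',
           '<script [^>]*src=[^>]*')
  unlist(lapply(pat, function(p) regmatches(txt, gregexpr(p, txt))[[1]]))
}
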