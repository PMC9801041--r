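# dashweave

Programmatic, iterative construction of multi-page dashboards from within
omics analysis pipelines, rendered to a single deterministic,
self-contained HTML file.

Analysis pipelines produce results in stages; the people who need to see
those results usually want a browsable report, not a pile of PNGs. With
dashweave a pipeline initializes an empty dashboard, adds pages and
components as results become available (markdown, images, tables,
declarative figures, or functions injecting arbitrary markup), optionally
links components into responsive views, and renders everything at the end.
The output is one HTML file with every asset, style and script embedded —
no server, no network, byte-identical across rebuilds.

The package ships a single-cell RNA-seq extension with ready-made page
templates and the statistics behind them, plus a negative-binomial
simulator with planted ground truth so every template is testable offline.

## The pieces

**Document model.** A `dashboard` holds title/author/theme, ordered pages,
document-wide colormaps and navigation items. Pages use one of four
layouts with fixed capacities:

| layout       | capacity  | linkable |
|--------------|-----------|----------|
| `storyboard` | unlimited | no       |
| `tabset`     | unlimited | no       |
| `focal_left` | 3         | yes      |
| `grid_2x2`   | 4         | yes      |

Sidebars attach globally or per page, outside the slot plan. Adding beyond
a layout's capacity is a hard error; re-adding a page id replaces the page
with a warning (the iterative-pipeline workflow).

**Content dispatch.** `add_component()` accepts heterogeneous content and
dispatches on its class: markdown strings, image paths (PNG/JPEG/SVG,
embedded base64), data frames or CSV/TSV paths (rendered table + full
records embedded), `fig_spec()` declarative figures (rendered to inline
SVG), and zero-argument functions whose returned markup is injected
verbatim — the extension mechanism templates build on.

**Linked views.** `link_spec()` declares one-way intra-page links: a
selection in the source either re-aggregates the target from the selected
records (`subset_recompute`, with count/mean/median/sum over a grouping
variable) or re-colors it (`color_by_selection`). Links compile to a JSON
wiring table consumed by one small embedded script; `link_update()` is the
reference implementation of the same semantics in R.

**Single-cell statistics.** One documented normalization (counts-per-10k,
`log1p`) backs all expression summaries. Per-cell QC metrics are total
counts, detected genes and percent mitochondrial counts. Highly variable
genes are ranked by the residual of log-variance about a rolling-median
trend of log-variance versus log-mean (equal-count bins): for gene *g*,

    residual_g = log var_g − log trend(mean_g)

and the top *n* residuals are flagged. Markers are ranked per group by the
group-vs-rest mean difference of log-normalized expression, top 10 per
group by default.

## Worked example

```r
library(dashweave)

sim <- simulate_counts(sim_spec(n_cells = 200, n_genes = 500,
                                n_hvg_planted = 20, seed = 1))
ds <- sim$dataset

head(qc_metrics(ds), 3)
#>   cell_id total_counts detected_genes pct_mito zero_total
#> 1 cell001         3238            404 3.705991      FALSE
#> 2 cell002         3381            404 4.406980      FALSE
#> 3 cell003         2918            391 1.919123      FALSE

hvg <- mean_variance_hvg(ds, n_top = 20)
length(intersect(hvg$gene_id[hvg$hvg_flag], sim$truth$hvg))
#> [1] 18        # 18 of the 20 planted high-dispersion genes recovered

head(rank_markers(ds, "group", n_top = 3), 4)
#>    group gene_id    score rank
#> 1 group1 gene006 1.511540    1
#> 2 group1 gene221 1.474509    2
#> 3 group1 gene422 1.258251    3
#> 4 group2 gene191 1.569554    1

db <- create_dashboard("My single-cell report", "J. Doe")
db <- add_sc_page(db, ds, "qc", list(stratify = "group"))
db <- add_sc_page(db, ds, "marker_heatmap")
print(db)
#> dashboard 'My single-cell report' by J. Doe (theme default, static)
#>   2 page(s), 0 colormap(s), 0 navbar item(s)
#>   - qc 'Quality metrics' [grid_2x2] 4 component(s), 0 link(s)
#>   - marker_heatmap 'Marker heatmap' [storyboard] 2 component(s), 0 link(s)

build_dashboard(db, "report.html")
#> $bytes 119944; $pages 2; $assets 0
```

The QC page holds three violins (total counts, detected genes, percent
mitochondrial, split by group) and a per-level mean table; the marker
heatmap shows mean log-normalized expression of the top 10 markers per
group. The marker scores above are in log1p-CP10K units: `gene006` is on
average ~1.5 log-units higher inside `group1` than outside.

A full multi-page demo (QC, feature selection, linked embedding pages,
feature grid, embedding comparison, marker heatmap) builds with
`sc_demo(seed = 1, out_path = "demo.html")`, or from the shell:

```sh
Rscript inst/cli/dashweave.R sc-demo --seed 1 -o demo.html
Rscript inst/cli/dashweave.R build config.yaml -o dashboard.html
Rscript inst/cli/dashweave.R sc-report --counts X.mtx --genes g.tsv \
    --barcodes b.tsv --pages qc,feature_selection -o report.html
```

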