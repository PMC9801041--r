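---
title: "dashweave: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dashweave: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dashweave)
```

dashweave separates data analysis from data presentation: a pipeline
mutates a dashboard value as results accrue, and one final call renders a
self-contained HTML document. This vignette explains the model behind
that workflow, the statistical methods of the single-cell extension, the
parameters that matter, and the choices made where the design was open.

## The document model and its guarantees

A `dashboard` is an ordinary R value; every mutation
(`add_page()`, `add_component()`, `add_link()`, `add_colormap()`)
returns an updated copy. This functional style makes builds trivially
reproducible and lets pipelines pass dashboards between stages like any
other result object.

Three invariants are enforced at mutation time and re-checked by
`validate_dashboard()`:

* a page never holds more components than its layout's capacity
  (storyboard and tabset are unbounded; focal-left holds 3, the 2x2 grid
  holds 4) — overflow is a hard error, never a silent drop;
* page ids are unique slugs (`[a-z0-9_]`; input is lowercased, anything
  else is rejected rather than auto-mangled, so ids used in links and
  anchors are predictable);
* links connect two distinct, existing components on one page, and only
  on the linkable layouts.

Element ids are ordinal (`<page>-c<k>`), never random, and front-matter
keys serialize in a fixed order, so assembling the same dashboard twice
yields byte-identical output. Timestamps are deliberately absent from the
output. Replacing an existing page id overwrites with a warning: in an
iterative pipeline, later stages legitimately refine earlier pages.

The theme set is fixed at `default`, `dark`, `light`; a theme switches
one stylesheet token in the rendered document and never affects
structure.

## Layout geometry

Capacities are the layout contract; geometry is a rendering convention,
held in one place (`R/layouts.R`) so alternates are one-line changes. The
focal-left layout gives its first component a 2/3-width left column with
the remaining components stacked vertically at equal heights on the
right (stacking was chosen over tabs for the secondary slots so all three
components stay simultaneously visible, which is what a highlight layout
is for). The grid fills row-major. Sidebars are content attached to a
page or the document, occupying a fixed-width rail outside the slot plan.

## Content dispatch and the extension mechanism

`dispatch_content()` maps heterogeneous inputs onto five fragment kinds
(text, image, table, figure, injected). Two choices deserve explanation:

* **Callables are evaluated eagerly at add-time**, not at render-time: a
  failure in content generation then surfaces at the pipeline step that
  caused it, with that step's context, instead of at the final render.
* **Figures are declarative** (`fig_spec()`: a data frame plus encodings,
  or a matrix for heatmaps) and rendered by the package itself to inline
  SVG. Coverage is by figure kind (scatter, bar, violin, box, heatmap),
  not by widget class; arbitrary third-party widget embedding is out of
  scope. This keeps rendered documents deterministic, auditable and free
  of external script dependencies.

Tables cap the static body at 20 rows but embed the full records as a
JSON island, so linked views and downloads always operate on complete
data.

The injected-callable pathway is the extension mechanism: the entire
single-cell extension builds its pages through public operations only
(verified by an architecture test that both scans the template source for
internal access and reproduces a template page with exported calls
alone).

## Linked views

Links are one-way and intra-page; bidirectional behavior is two links.
Only the `selection` event exists in v1. A `subset_recompute` link
carries an explicit aggregation — function (count/mean/median/sum),
grouping variable, and value variable — rather than a hidden default,
because a per-level update can legitimately be a count, a mean or a
median depending on the panel. Empty selections restore the full-data
view; per-level counts over any selection sum to the selection size.

Wiring compiles to a data-driven JSON table consumed by one small
embedded script — no per-link code generation — and `link_update()`
implements identical semantics in R, which is what the tests exercise
(the suite does not run a browser; the JS mirrors the R reference).

## Rendering and determinism

`assemble()` produces a markdown-dialect intermediate document (ordered
front matter, one section per page with layout directive, slot plan,
fragment bodies and wiring island); `render_html()` emits a single HTML5
file with every image as a data URI and every style/script inline.
Self-containment is machine-checked by `scan_external_refs()`, which
flags `src`/`href`/`url()` positions pointing at `http(s)`. Line endings
are normalized to `\n` on every platform. Numbers inside SVG are
formatted with fixed decimal places so serialization is byte-stable.

Interactive (served) mode is a stub in this release: `interactive = TRUE`
renders the same static HTML plus a footer note, and the CLI `serve`
command exits non-zero. Client-side linking covers the selection-driven
updates; a reactive server contract is deliberately deferred.

## Single-cell methods

All expression summaries use one normalization: counts scaled per cell
to 10,000 total (CP10K), then `log1p`. A single documented scheme
replaces the model menagerie of dedicated single-cell frameworks; the
trend fit is isolated in one function so a different model is a drop-in
substitution.

**QC metrics** are per-cell total counts, detected genes (count > 0) and
percent mitochondrial counts (0–100). Mitochondrial genes come from an
explicit `gene_meta` flag, with an `MT-` name-prefix convenience applied
at load time when no flag is supplied. All-zero cells are flagged rather
than dropped — filtering is the analyst's decision.

**Highly variable genes.** Per-gene mean and variance of log-normalized
expression; the expected log-variance at a given log-mean is a
rolling median over equal-count bins (default 20, reduced for small
panels), linearly interpolated and held constant beyond the outer bins.
The residual (log-variance minus log-trend) ranks genes; ties break
lexicographically by gene id so selection is total and reproducible.
Genes with zero variance get `-Inf` residuals and are only flagged when
`n_top` forces it. The rolling median was chosen over a parametric fit
because it is robust to the planted-outlier structure this statistic is
meant to find.

**Markers** score each (group, gene) by the difference in mean
log-normalized expression, group versus rest — a deliberately simple
effect-size ranking, not a test; no p-values are produced, and
differential-expression statistics are out of scope. The default of 10
markers per group matches the heatmap page default.

**Embeddings are consumed, not computed.** Pages take named precomputed
coordinate sets; the built-in fallback is the top two principal
directions of the log-normalized matrix with a fixed sign convention
(largest-magnitude loading positive), so even the fallback is exactly
reproducible. t-SNE/UMAP themselves are out of scope; the embedding
comparison page presents one tab per supplied (label, parameters,
coordinates) run instead of slider-driven recomputation, which would
require a server.

## The synthetic-data generator

`sim_spec()`/`simulate_counts()` generate negative-binomial counts with
planted structure, which defines the conditions under which the package's
statistical guarantees are stated:

* 500 cells x 2000 genes by default; gene means log-uniform over 1–20
  counts per cell — the regime of a filtered expression panel, where
  genes below ~1 count per cell have been removed;
* baseline dispersion 0.8 (squared biological CV near one, typical of
  uncorrected single-cell counts); planted highly variable genes carry 4x
  that dispersion;
* 3 groups with 5 disjoint markers each at log2 fold change 2; 5%
  mitochondrial genes; 2 batches; an explicit seed threads through every
  draw.

Under these defaults, HVG selection recovers >= 90% of the 50 planted
high-dispersion genes and per-group top-5 marker ranking recovers >= 90%
of planted markers across 20 seeds (both recomputed by the test suite
and `scripts/acceptance.R`). The mean floor matters: dispersion
inflation is nearly invisible below ~0.5 counts per cell, where Poisson
noise dominates the negative-binomial variance mu + phi mu^2 — a real
limitation of variance-residual HVG selection generally, not only of
this implementation.

What the generator does *not* emulate: library-size confounding,
zero-inflation beyond the negative binomial, doublets, ambient RNA, or
batch effects on expression (the batch covariate is a label only).
Passing recovery tests therefore demonstrate correctness of the
statistics on clean planted signal, not performance on real tissue data.

`simulate_embedding()` places one Gaussian blob per group, centers on a
circle with adjacent-chord distance equal to `separation`; at
`separation/spread = 10` nearest-centroid assignment recovers >= 99% of
labels, which makes the linked-view pages visually meaningful in the
demo.

## Problem sizes used in validation

The test suite exercises full default-size simulations (500 x 2000) for
the recovery guarantees, 20 seeds for marker recovery, 100 random
selections for link semantics, and 100-component pages for the unbounded
layouts; smaller panels (about 100-300 genes) back the structural tests
where the statistic itself is not under test. These sizes were chosen so
each claim is tested at the scale at which it is stated while the whole
suite stays fast enough to run on every change.

## Known limitations

* Violin panels fall back to a quartile box below three distinct values;
  densities use `stats::density` defaults, so violins are indicative,
  not publication-calibrated.
* The markdown subset covers headings, paragraphs, lists, fenced code
  and inline emphasis/links/images; raw HTML passes through untouched.
* The embedded linking script implements selection wiring only;
  hover/zoom channels and cross-page links are documented extension
  points, not features.
* YAML-driven builds cover text/image/table components; figures and
  links currently require the R API, where their data lives.
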