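---
title: "Curating MS1 ground truth with mzcurate: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating MS1 ground truth with mzcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzcurate)
```

## The problem

Quantitative evaluation of MS1 feature-detection algorithms needs
feature-level ground truth: raw (m/z, retention time, intensity) points
manually curated into isotopic traces (extracted ion chromatograms, the
signal of one isotope across retention time) and isotopic envelopes (the
group of traces belonging to one molecule at one charge state, spaced
about 1/z Thomson apart). Producing such annotations by hand requires an
engine that can (a) store millions of points and answer window queries
fast in either dimension, (b) return representative subsets when a full
window cannot be rendered, and (c) apply curation edits with semantics
strict enough that the resulting dataset is internally consistent.
`mzcurate` is that engine, headless: every interactive gesture of a
point-cloud annotation GUI (rectangle selection, click-near-a-trace,
line sweeps, mark-as-noise, the charge-state ruler) has an exact,
deterministic counterpart here, callable from R, from a JSON request
API, or from a shell tool.

## The annotation model

Each point carries two mutable integer fields. `trace_id` is 0
(unannotated), −1 (noise), or the positive id of the one trace owning
the point. `envelope_id` is 0 or the positive id of the envelope the
point's *trace* belongs to. Three invariants form the partition law that
every edit preserves and `validate_store()` audits by full scan:

* trace member sets are disjoint — a point belongs to at most one trace;
* envelope membership is mediated by traces: `envelope_id > 0` requires
  `trace_id > 0`, and every point of a trace carries the trace's
  envelope id;
* noise is terminal for grouping: `trace_id == −1` forces
  `envelope_id == 0`.

Edit semantics follow from treating curation as a sequence of local,
reversible gestures:

* **Rectangle add never steals.** Adding points to a trace claims only
  unannotated points inside the rectangle; points owned by another trace
  and points marked as noise are untouched. Overlapping rectangles are
  therefore order-dependent only in who gets a contested point first,
  never destructive. Points added to a trace already in an envelope
  inherit that envelope id immediately (the partition law demands it).
* **Envelope add re-parents silently.** Moving a trace into an envelope
  removes it from its previous envelope first, matching fluid
  interactive regrouping rather than erroring.
* **Mark-as-noise is guarded.** The edit is refused — with no partial
  mutation — unless the window's true point count is within the render
  budget *and* equals the count the client actually displayed. This
  encodes "the user is viewing every point" as an explicit API contract,
  so no unseen point can be condemned as noise.
* **Id allocation** uses the smallest unused positive integer per
  namespace (traces and envelopes separately); deleted ids become
  reusable. This keeps replayed edit logs deterministic.

In exported CSV, noise points appear with annotation id −1 and
unannotated points with 0.

## Spatial index and budgeted queries

Points are bulk-loaded into a balanced binary partition tree whose split
dimension alternates by depth: m/z at even depths, retention time at odd
depths. Each level splits its points at the median of the split
dimension (ties broken by ascending point id), so the build is
deterministic and the tree balanced regardless of input order; leaves
hold at most `leaf_capacity` points (default 512). Queries descend only
into nodes whose bounding rectangle overlaps the window and filter at
the leaves, which makes narrow-in-m/z and narrow-in-RT requests equally
cheap. Window membership is closed on all four bounds, because boundary
points must be selectable by a rectangle drawn onto them.

When a query carries a point budget smaller than the in-window count,
the engine applies **weighted striding**: order the in-window points
along the traversal axis (ascending m/z, ties by RT then point id),
partition them into `limit` contiguous strides of near-equal point
count (the i-th point lands in stride `floor((i−1)·limit/n)+1`), and
return each stride's maximum-intensity point, ties to the smaller point
id. The choice of equal *point-count* strides over equal *m/z-width*
strides is deliberate: it guarantees every stride is non-empty whenever
`n ≥ limit`, so the subset always has exactly `limit` points spread
across the data's actual density, and the global intensity maximum is
always retained (it is the maximum of its own stride). The selection is
deterministic, so repeated identical requests return identical
sequences. A separate intensity registry — all point ids ordered by
non-increasing intensity, ties ascending — backs
`next_unannotated_max()`, the jump-to-next-unannotated-peak operation;
because the registry is a static order and annotation state is read at
call time, the sequence of visited intensities under
annotate-then-jump iteration is non-increasing until exhaustion.

The store is single-writer and synchronous: an edit completes before
any later query is answered, so reads are never stale.

## Proximity selection without pixels

In a browser the "closest trace to the click" is a pixel distance. The
headless equivalent normalizes each axis by the caller's current view
span: the distance between a probe and a point is
`sqrt(((Δmz)/mz_span)² + ((Δrt)/rt_span)²)`. The default threshold of
0.02 corresponds to about 2% of the view diagonal, a comfortable click
tolerance; callers pass their own spans, so zooming in tightens the
absolute tolerance exactly as it would on screen. Segment sweeps use
the same normalized metric against the point-to-segment distance; a
zero-length segment degenerates to nearest-trace semantics.

## Ruler and guard rails

For a charge state z, isotope peaks sit 1/z Thomson apart, so the ruler
anchored at `a` marks `a + k/z` for k = 0, 1, …, truncated at the
window's upper m/z bound. Positions are constructed directly as
`anchor + k/z` (not by repeated addition), so consecutive differences
equal the constructed increments bit-for-bit and the bound check is a
simple filter. Guard rails are the pair `center ± width/2` clipped to
the window — a straightness aid, since traces run along near-constant
m/z.

## The synthetic generator

Tests and the acceptance script run exclusively on generated data with
known truth. One envelope is parameterized by monoisotopic m/z, charge
z, isotope count, Gaussian elution (apex `rt_center`, width `rt_sigma`
in seconds), apex intensity, and a geometric per-isotope decay
`isotope_ratio`; points are emitted on the scan grid (integer multiples
of `scan_interval`) within ±4σ of the apex, at
`mono_mz + k/z + jitter`, with intensity
`base_height · ratio^k · exp(−(t−rt_center)²/(2σ²))`. Dataset-level
defaults are chosen to resemble a small LC-MS map: charges drawn
uniformly from 1–4, 3–6 isotopes, elution widths 3–8 s on a 1 s scan
cycle (a typical MS1 cycle time), log-normal apex heights around 10⁵,
per-point m/z jitter with SD 0.002 Th (a few ppm at m/z 500), and
uniform background noise as a Poisson point process over the (m/z, RT)
area with exponentially distributed intensities at 2% of the nominal
apex height, snapped to the scan grid as real noise is. The generator
is fully deterministic given a seed and restores the caller's RNG
state.

What it does *not* emulate — and therefore what passing tests do not
show about real data: averagine-accurate isotope abundances, chimeric
co-eluting features sharing m/z windows, RT peak asymmetry (tailing),
detector saturation, and centroiding artifacts. The generator's role is
to give the *engine* a known answer key, not to benchmark feature
detectors.

Ground-truth recovery is verified by replaying the truth table through
the public editing API: each true trace is created and claimed with one
degenerate rectangle per member point, then traces are grouped with
`set_envelope()`. Per-point rectangles (rather than one bounding box
per trace) make recovery exact even when two traces' m/z ranges happen
to overlap, since a bounding box could otherwise capture a neighbour's
still-unannotated points.

## File formats

* **mzML** is read with Bioconductor's `mzR`; only MS level-1 spectra
  are ingested, one point per (m/z, intensity) pair, profile or
  centroid alike, with scan start times converted to seconds on ingest
  whatever unit the file declares. `write_fixture_mzml()` emits a
  minimal valid mzML (uncompressed 64-bit float arrays) and lets the
  caller choose the declared scan-time unit, which is how the
  minutes→seconds conversion is exercised without external data; it is
  a synthetic-fixture writer, not a general exporter.
* **Annotated CSV** is the persistence format:
  `point_id,mz,rt,intensity,trace_id,envelope_id`, rows in ascending
  point id. Doubles are rendered in the shortest decimal form that
  parses back to the identical IEEE value, which makes
  export → import → re-export byte-identical while keeping files
  readable. Import re-validates every invariant and reports the first
  offending row.
* **Bookmark TSV** is `label<TAB>mz<TAB>rt` with an optional header
  (detected by a non-numeric second field on the first line); it backs
  the jump list used to iterate regions of interest.

## The request API

`api_app()` + `api_request()` implement the JSON contract —
`/api/getpoints`, `/api/edit`, `/api/jump`, `/api/export`,
`/api/status` — as pure in-process handlers returning
`(status, body)`. `getpoints` always reports `total_in_window`
alongside the (possibly budgeted) records so clients can enforce the
noise-marking guard; engine errors map to 400 (malformed request), 404
(unknown id, exhausted jump), and 409 (guard violation, no data
loaded). `serve_api()` binds the same dispatcher to a socket via
`httpuv` when that package is available; every behaviour of the API is
testable without it. The server is single-session by design — one
loaded dataset, one curator.

## Problem sizes and numerical choices

The test suite and the acceptance script use fixtures of 10,000 points
for query-oracle comparisons (100 random windows on each of three
clouds), 1,000–2,000 points for edit-sequence and jump properties, and
five ~800-point envelope datasets for end-to-end recovery — sizes at
which a linear-scan oracle is still cheap to compute while the tree
takes several levels, so both sides of each comparison are exercised
honestly. Tie-breaks are by ascending id everywhere; query output is
ordered by (m/z, RT, point id); all retention times are seconds
internally. Degenerate inputs are defined, not special-cased: empty
stores build (only `global_bounds()` refuses them), zero-point windows
and zero budgets return empty results, and a zero-length sweep segment
selects at most one trace.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(n_envelopes = 3, seed = 42)
store <- build_index(sim$points, leaf_capacity = 256)

w <- global_bounds(store)
head(query_window(store, w, limit = 5))

tid <- create_trace(store)
assign_rectangle(store, mz_window(500, 500.01, 100, 160), tid)
eid <- create_envelope(store)
set_envelope(store, tid, eid)

export_annotations_csv(store, "annotations.csv")
```

## Known limitations

The store is in-memory (no out-of-core paging) and single-writer;
MS2/MSn spectra are ignored on ingest; CSV is the only persistence
format; trace/envelope *detection* is out of scope — the engine curates
and serves annotations, it does not compute them.
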