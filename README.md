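# mzcurate

A headless engine for creating, editing, storing, and serving **MS1
feature ground truth** — the manually curated point→trace→envelope
annotations needed to evaluate mass-spectrometry feature-detection
algorithms quantitatively.

MS1 data is a cloud of millions of 3-D points (mass-to-charge *m/z* in
Thomson, retention time RT in seconds, intensity). Curation groups them
twice: points into **isotopic traces** (extracted ion chromatograms, the
signal of one isotope across RT) and traces into **isotopic envelopes**
(the isotope pattern of one molecule at charge state *z*, whose traces
sit 1/*z* Th apart). `mzcurate` provides the storage, query, and editing
semantics behind that workflow, with no GUI attached: every interactive
gesture of a point-cloud annotation viewer has an exact, deterministic
counterpart callable from R, over a JSON request API, or from a shell
tool.

## What's inside

* **Spatial index** — a balanced partition tree that alternates its
  split dimension by level (*m/z* at even depths, RT at odd), answering
  closed-bound window queries fast whether the request is narrow in
  *m/z*, RT, or both; plus an intensity-ordered registry backing
  jump-to-next-unannotated-maximum.
* **Budgeted queries with weighted striding** — when a window holds more
  points than the requested limit, the in-window points are ordered
  along the traversal axis, cut into `limit` contiguous equal-count
  strides, and each stride contributes its intensity maximum. The subset
  is deterministic, spans the window, and always contains the window's
  intensity maximum.
* **Annotation engine** — trace creation and rectangle-based point
  assignment (never stealing from other traces, never reclaiming noise),
  proximity and line-sweep trace selection under a view-span-normalized
  distance, envelope grouping with silent re-parenting, and
  mark-as-noise behind a visibility guard: the edit is refused unless
  the window's true point count is within the render budget and equals
  what the client displayed. Noise points export with annotation id −1.
* **Ruler / guard rails** — expected isotope positions `anchor + k/z`
  truncated at the plot bound; parallel rails `center ± width/2`.
* **I/O** — mzML ingest (MS1 only, scan times converted to seconds via
  Bioconductor `mzR`), a round-trip-safe annotated CSV dialect, and a
  bookmark TSV dialect for jump lists.
* **JSON API** — `/api/getpoints`, `/api/edit`, `/api/jump`,
  `/api/export`, `/api/status` as in-process handlers
  (`api_app()`/`api_request()`); `serve_api()` puts them on a socket
  when `httpuv` is installed.
* **Synthetic LC-MS generator** — envelopes with exact 1/*z* trace
  spacing, Gaussian elution, geometric isotope decay, and Poisson
  background noise, with a ground-truth table; plus a minimal mzML
  fixture writer. All tests run on generated data only.

## Worked example

```r
library(mzcurate)

sim <- simulate_dataset(n_envelopes = 3, seed = 42)
store <- build_index(sim$points, leaf_capacity = 256)
store
#> <mz_store> 2014 points, 0 trace(s), 0 envelope(s), leaf capacity 256
#>   m/z [400.048, 599.876] Th, RT [0, 600] s
#>   annotated: 0 in traces, 0 noise, 2014 unannotated

w <- global_bounds(store)
head(query_window(store, w, limit = 5))
#>    point_id       mz    rt intensity trace_id envelope_id
#> 1:     1057 450.5775   280 217414.16        0           0
#> 2:     1058 450.9082   280 138111.52        0           0
#> 3:      986 507.8721   270  13049.85        0           0
#> 4:     1504 563.5980   380 102421.74        0           0
#> 5:      319 587.7547    76 101797.52        0           0
```

The budget of 5 came back as 5 representative points spread across the
full 400–600 Th extent — stride maxima, including the global intensity
maximum (217,414 at 450.58 Th). Annotate and jump:

```r
tid <- create_trace(store)                          # allocates id 1
assign_rectangle(store, mz_window(450, 550, 0, 600), tid)
#> [1] 960                                           # points claimed
next_unannotated_max(store)
#>    point_id      mz    rt intensity trace_id envelope_id
#> 1:     1504 563.598   380  102421.7        0           0
```

960 points inside the rectangle joined trace 1; the jump target is now
the brightest point *outside* any annotation (the 450.58 Th maximum is
annotated, so 102,422 at 563.60 Th is next). The charge-2 ruler from
500 Th, truncated at a 501.6 Th plot edge:

```r
ruler_positions(500, 2, mz_window(499, 501.6, 0, 600))
#> [1] 500.0 500.5 501.0 501.5                       # spacing 1/z = 0.5 Th
```

Export writes the CSV dialect
`point_id,mz,rt,intensity,trace_id,envelope_id`, with −1 marking noise:

```r
export_annotations_csv(store, "annotations.csv")
```

The same workflows are available from the shell via the installed
`exec/mzcurate` script (`ingest`, `serve`, `export`, `bookmarks`,
`simulate`).

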