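#' Parameters of one synthetic isotopic envelope
#'
#' Describes an LC-MS feature as the generator realizes it: `n_isotopes`
#' isotopic traces spaced exactly `1/charge` Thomson apart starting at
#' the monoisotopic m/z, each eluting as a Gaussian profile in retention
#' time and decaying geometrically across isotopes.
#'
#' @param mono_mz Monoisotopic m/z, Thomson.
#' @param charge Charge state z, integer >= 1 (trace spacing is 1/z).
#' @param n_isotopes Number of isotopic traces, >= 1.
#' @param rt_center Elution apex, seconds.
#' @param rt_sigma Gaussian elution width, seconds, > 0.
#' @param base_height Apex intensity of the monoisotopic trace.
#' @param isotope_ratio Multiplicative intensity decay per isotope,
#'   in (0, 1].
#' @param scan_interval MS1 scan period, seconds (default 1 s, a typical
#'   MS1 cycle time).
#' @param mz_jitter_sd Gaussian m/z measurement jitter, Thomson, >= 0
#'   (default 0.002 Th, a few ppm at m/z 500).
#' @return An object of class `envelope_spec`.
#' @export
envelope_spec <- function(mono_mz, charge, n_isotopes = 3L,
                          rt_center = 60, rt_sigma = 5,
                          base_height = 1e5, isotope_ratio = 0.7,
                          scan_interval = 1, mz_jitter_sd = 0.002) {
  stopifnot(is_num1(mono_mz), mono_mz > 0,
            is_count(charge, 1L), is_count(n_isotopes, 1L),
            is_num1(rt_center), rt_center >= 0,
            is_num1(rt_sigma), rt_sigma > 0,
            is_num1(base_height), base_height >= 0,
            is_num1(isotope_ratio), isotope_ratio > 0, isotope_ratio <= 1,
            is_num1(scan_interval), scan_interval > 0,
            is_num1(mz_jitter_sd), mz_jitter_sd >= 0)
  structure(list(mono_mz = mono_mz, charge = as.integer(charge),
                 n_isotopes = as.integer(n_isotopes), rt_center = rt_center,
                 rt_sigma = rt_sigma, base_height = base_height,
                 isotope_ratio = isotope_ratio, scan_interval = scan_interval,
                 mz_jitter_sd = mz_jitter_sd),
            class = "envelope_spec")
}

# scan grid = integer multiples of scan_interval within [lo, hi]
scan_grid <- function(lo, hi, interval) {
  ks <- seq.int(ceiling(lo / interval), floor(hi / interval))
  ks <- ks[ks >= 0]
  ks * interval
}

#' Simulate the point cloud of one isotopic envelope
#'
#' For every scan time on the interval grid within +/- 4 elution sigmas
#' of the apex, and every isotope k = 0..n_isotopes-1, emits one point at
#' `mono_mz + k/charge` (plus m/z jitter) with intensity
#' `base_height * isotope_ratio^k * exp(-(t - rt_center)^2 / (2 rt_sigma^2))`.
#' All points of isotope k share one true trace id and all traces share
#' one true envelope id. Deterministic given `seed`.
#'
#' @param spec An [envelope_spec()].
#' @param seed Integer RNG seed for the m/z jitter.
#' @return A list with `points` (peak-point `data.table`, annotations 0)
#'   and `truth` (`data.table` with `point_id`, `true_trace_id`,
#'   `true_envelope_id`).
#' @export
simulate_envelope <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "envelope_spec"))
  ts <- scan_grid(spec$rt_center - 4 * spec$rt_sigma,
                  spec$rt_center + 4 * spec$rt_sigma, spec$scan_interval)
  ks <- seq_len(spec$n_isotopes) - 1L
  grid <- data.table::CJ(k = ks, rt = ts)
  with_local_seed(seed, {
    grid[, "mz" := spec$mono_mz + k / spec$charge +
           rnorm(nrow(grid), sd = spec$mz_jitter_sd)]
  })
  grid[, "intensity" := spec$base_height * spec$isotope_ratio^k *
         exp(-(rt - spec$rt_center)^2 / (2 * spec$rt_sigma^2))]
  data.table::setorderv(grid, c("rt", "mz"))
  grid[, "point_id" := seq_len(nrow(grid))]
  list(points = as_peak_points(grid[, c("point_id", "mz", "rt", "intensity")]),
       truth = data.table::data.table(point_id = grid$point_id,
                                      true_trace_id = grid$k + 1L,
                                      true_envelope_id = 1L))
}

#' Simulate a full MS1 map with known trace/envelope ground truth
#'
#' Draws `n_envelopes` envelope specs uniformly inside the given ranges
#' (charges 1-4, 3-6 isotopes, log-normal apex heights, elution widths
#' 3-8 s) and scatters Poisson noise points uniformly over the
#' (m/z, RT) area with exponentially distributed intensities (scale 2\%
#' of the mean apex height). Noise retention times sit on the same scan
#' grid as the signal, as real noise does. True ids: trace and envelope
#' ids number the envelopes' traces consecutively; noise points carry 0.
#'
#' @param n_envelopes Number of envelopes, >= 0.
#' @param mz_range,rt_range Length-2 numeric ranges (Thomson, seconds).
#' @param noise_density Expected noise points per (Thomson x second) of
#'   area, >= 0.
#' @param seed Integer RNG seed; the result is fully deterministic given
#'   it.
#' @param scan_interval MS1 scan period, seconds.
#' @param mz_jitter_sd Per-point m/z jitter SD, Thomson.
#' @return A list with `points`, `truth` (as in [simulate_envelope()]),
#'   and `specs` (list of the drawn [envelope_spec()]s).
#' @export
simulate_dataset <- function(n_envelopes, mz_range = c(400, 600),
                             rt_range = c(0, 600), noise_density = 0.01,
                             seed = 1L, scan_interval = 1,
                             mz_jitter_sd = 0.002) {
  stopifnot(is_count(n_envelopes), length(mz_range) == 2L,
            length(rt_range) == 2L, mz_range[1L] < mz_range[2L],
            rt_range[1L] <= rt_range[2L],
            is_num1(noise_density), noise_density >= 0)
  with_local_seed(seed, {
    specs <- vector("list", n_envelopes)
    parts <- list()
    truth_parts <- list()
    next_trace <- 1L
    for (e in seq_len(n_envelopes)) {
      charge <- sample(1:4, 1L)
      n_iso <- sample(3:6, 1L)
      sigma <- runif(1L, 3, 8)
      sp <- envelope_spec(
        mono_mz = runif(1L, mz_range[1L], mz_range[2L] - n_iso / charge),
        charge = charge, n_isotopes = n_iso,
        rt_center = runif(1L, rt_range[1L] + 4 * sigma,
                          max(rt_range[1L] + 4 * sigma, rt_range[2L] - 4 * sigma)),
        rt_sigma = sigma,
        base_height = exp(rnorm(1L, log(1e5), 0.5)),
        isotope_ratio = runif(1L, 0.6, 0.9),
        scan_interval = scan_interval, mz_jitter_sd = mz_jitter_sd)
      specs[[e]] <- sp
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      sim <- simulate_envelope(sp, seed = sub_seed)
      sim$points <- sim$points[sim$points$rt >= rt_range[1L] &
                                 sim$points$rt <= rt_range[2L] &
                                 sim$points$mz > 0]
      keep <- sim$truth$point_id %in% sim$points$point_id
      parts[[e]] <- sim$points
      truth_parts[[e]] <- data.table::data.table(
        true_trace_id = sim$truth$true_trace_id[keep] + (next_trace - 1L),
        true_envelope_id = e)
      next_trace <- next_trace + sp$n_isotopes
    }
    area <- diff(mz_range) * diff(rt_range)
    n_noise <- rpois(1L, noise_density * area)
    if (n_noise > 0L) {
      grid <- scan_grid(rt_range[1L], rt_range[2L], scan_interval)
      noise <- data.table::data.table(
        mz = runif(n_noise, mz_range[1L], mz_range[2L]),
        rt = grid[sample.int(length(grid), n_noise, replace = TRUE)],
        intensity = rexp(n_noise, rate = 1 / (0.02 * 1e5)))
      parts[[length(parts) + 1L]] <- noise
      truth_parts[[length(truth_parts) + 1L]] <- data.table::data.table(
        true_trace_id = rep(0L, n_noise), true_envelope_id = rep(0L, n_noise))
    }
    if (!length(parts))
      return(list(points = peak_points(numeric(0), numeric(0), numeric(0)),
                  truth = data.table::data.table(point_id = integer(0),
                                                 true_trace_id = integer(0),
                                                 true_envelope_id = integer(0)),
                  specs = specs))
    pts <- data.table::rbindlist(parts, fill = TRUE)
    truth <- data.table::rbindlist(truth_parts)
    ord <- order(pts$rt, pts$mz)
    pts <- pts[ord]
    truth <- truth[ord]
    pts[, "point_id" := seq_len(nrow(pts))]
    truth[, "point_id" := pts$point_id]
    data.table::setcolorder(truth, c("point_id", "true_trace_id",
                                     "true_envelope_id"))
    list(points = as_peak_points(
           pts[, c("point_id", "mz", "rt", "intensity")]),
         truth = truth, specs = specs)
  })
}

#' Replay a ground-truth table as annotation edits
#'
#' Drives the editing engine with the generator's truth: for every true
#' trace, a trace is created and each of its points claimed with a
#' degenerate selection rectangle; traces of each true envelope are then
#' grouped with [set_envelope()]. Used to verify end-to-end that edits,
#' export and import reproduce a known annotation exactly.
#'
#' @param store An `mz_store` holding the generated points, unannotated.
#' @param truth A truth `data.table` (see [simulate_dataset()]).
#' @return Invisibly, a named integer map from true trace id to allocated
#'   trace id.
#' @export
replay_truth <- function(store, truth) {
  stopifnot(inherits(store, "mz_store"))
  pts <- store$points
  id_map <- integer(0)
  for (tt in sort(unique(truth$true_trace_id[truth$true_trace_id > 0L]))) {
    tid <- create_trace(store)
    id_map[[as.character(tt)]] <- tid
    members <- pts[list(truth$point_id[truth$true_trace_id == tt])]
    for (i in seq_len(nrow(members)))
      assign_rectangle(store,
                       mz_window(members$mz[i], members$mz[i],
                                 members$rt[i], members$rt[i]),
                       tid, mode = "add")
  }
  env_of_trace <- unique(truth[truth$true_envelope_id > 0L,
                               c("true_trace_id", "true_envelope_id")])
  for (ee in sort(unique(env_of_trace$true_envelope_id))) {
    eid <- create_envelope(store)
    tts <- env_of_trace$true_trace_id[env_of_trace$true_envelope_id == ee]
    set_envelope(store, id_map[as.character(tts)], eid, mode = "add")
  }
  invisible(id_map)
}

#' Write peak points as a minimal synthetic mzML file
#'
#' Groups points by retention time into MS1 spectra (one spectrum per
#' distinct RT, ascending; peaks sorted by m/z) and writes a minimal
#' valid mzML document with uncompressed 64-bit float binary arrays. Scan
#' start times are declared in the chosen unit — the default `"minute"`
#' exercises the minutes-to-seconds conversion a reader must perform.
#' Intended for generating test inputs; this is a synthetic-data writer,
#' not a general mzML exporter.
#'
#' @param points A data frame of peak points.
#' @param path Output path.
#' @param rt_unit Unit to declare on scan start times: `"minute"` or
#'   `"second"`.
#' @return The number of spectra written.
#' @export
write_fixture_mzml <- function(points, path, rt_unit = c("minute", "second")) {
  rt_unit <- match.arg(rt_unit)
  pts <- as_peak_points(points)
  rts <- sort(unique(pts$rt))
  spectra <- character(length(rts))
  for (i in seq_along(rts)) {
    scan <- pts[pts$rt == rts[i]]
    data.table::setorderv(scan, c("mz", "point_id"))
    spectra[i] <- mzml_spectrum_xml(i, rts[i], rt_unit, scan$mz, scan$intensity)
  }
  doc <- mzml_document(spectra)
  ok <- tryCatch({ writeLines(doc, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) mz_stop("io", "cannot write %s", path)
  length(rts)
}

encode_f64 <- function(x)
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8L,
                                               endian = "little")),
       fixed = TRUE)

mzml_spectrum_xml <- function(i, rt_seconds, rt_unit, mz, intensity) {
  mz_b64 <- encode_f64(mz)
  in_b64 <- encode_f64(intensity)
  unit_acc <- if (rt_unit == "minute") "UO:0000031" else "UO:0000010"
  rt_val <- if (rt_unit == "minute") rt_seconds / 60 else rt_seconds
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
            i - 1L, i, length(mz)),
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '<scanList count="1">',
    '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    sprintf('<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%s" unitCvRef="UO" unitAccession="%s" unitName="%s"/></scan>',
            sprintf("%.17g", rt_val), unit_acc, rt_unit),
    '</scanList>\n',
    '<binaryDataArrayList count="2">\n',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(mz_b64)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    sprintf('<binary>%s</binary></binaryDataArray>\n', mz_b64),
    sprintf('<binaryDataArray encodedLength="%d">', nchar(in_b64)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    sprintf('<binary>%s</binary></binaryDataArray>\n', in_b64),
    '</binaryDataArrayList>\n</spectrum>')
}

mzml_document <- function(spectra) {
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="syn" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="synthetic fixture writer"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="syn">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="%d" defaultDataProcessingRef="DP1">\n',
            length(spectra)),
    paste(spectra, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>')
}
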