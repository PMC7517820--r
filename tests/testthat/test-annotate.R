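fresh_store <- function(n = 60, seed = 5) build_index(random_cloud(n, seed))

test_that("trace and envelope ids are the smallest unused positive integers", {
  st <- fresh_store()
  expect_equal(create_trace(st), 1L)
  for (i in 2:5) expect_equal(create_trace(st), i)
  delete_trace(st, 3L)
  expect_equal(create_trace(st), 3L)  # freed id is reused
  expect_equal(create_trace(st), 6L)

  expect_equal(create_envelope(st), 1L)
  expect_equal(create_envelope(st), 2L)
  expect_equal(create_envelope(st), 3L)
  delete_envelope(st, 2L)
  expect_equal(create_envelope(st), 2L)
  expect_error(delete_trace(st, 99L), class = "mzcurate_missing_trace")
  expect_error(delete_envelope(st, 99L), class = "mzcurate_missing_id")
})

test_that("rectangle add claims unannotated points, is idempotent, and remove inverts", {
  pts <- peak_points(mz = 500 + (1:10) / 100, rt = rep(60, 10),
                     intensity = 1:10)
  st <- build_index(pts)
  tid <- create_trace(st)
  rect <- mz_window(500.01, 500.07, 0, 120)  # 7 points
  expect_equal(assign_rectangle(st, rect, tid, "add"), 7)
  expect_equal(sum(st$points$trace_id == tid), 7)
  expect_equal(assign_rectangle(st, rect, tid, "add"), 0)  # idempotent
  expect_equal(assign_rectangle(st, rect, tid, "remove"), 7)
  expect_true(all(st$points$trace_id == 0))
  expect_error(assign_rectangle(st, rect, 42L), class = "mzcurate_missing_trace")
})

test_that("rectangle add never steals from other traces nor reclaims noise", {
  pts <- peak_points(mz = c(500.1, 500.2, 500.3), rt = c(60, 60, 60),
                     intensity = c(1, 2, 3))
  st <- build_index(pts)
  t1 <- create_trace(st); t2 <- create_trace(st)
  assign_rectangle(st, mz_window(500.1, 500.1, 60, 60), t1)
  mark_noise(st, mz_window(500.3, 500.3, 60, 60), rendered_count = 1,
             point_threshold = 10)
  # t2's rectangle covers all three points; only the free one changes
  expect_equal(assign_rectangle(st, mz_window(500, 501, 0, 120), t2), 1)
  expect_equal(st$points$trace_id, c(t1, t2, -1L))
})

test_that("points added to an enveloped trace inherit its envelope id", {
  pts <- peak_points(mz = c(500.1, 500.2), rt = c(60, 61), intensity = c(1, 2))
  st <- build_index(pts)
  tid <- create_trace(st)
  assign_rectangle(st, mz_window(500.1, 500.1, 0, 120), tid)
  eid <- create_envelope(st)
  set_envelope(st, tid, eid)
  assign_rectangle(st, mz_window(500.2, 500.2, 0, 120), tid)
  expect_equal(st$points$envelope_id, c(eid, eid))
  validate_store(st)
})

test_that("nearest trace minimizes the span-normalized distance", {
  pts <- peak_points(mz = c(500.0, 500.5, 502.0), rt = c(100, 100, 100),
                     intensity = c(1, 1, 1))
  st <- build_index(pts)
  for (i in 1:3) {
    tid <- create_trace(st)
    assign_rectangle(st, mz_window(pts$mz[i], pts$mz[i], 100, 100), tid)
  }
  span <- list(mz = 10, rt = 1000)
  # probe exactly on a member point: distance zero
  expect_equal(nearest_trace(st, probe(500.5, 100, span$mz, span$rt)), 2L)
  # brute-force comparison over a grid of probes
  withr::with_seed(31, {
    for (r in 1:25) {
      pr <- probe(runif(1, 499, 503), runif(1, 0, 200), span$mz, span$rt)
      d <- sqrt(((pts$mz - pr$mz) / span$mz)^2 + ((pts$rt - pr$rt) / span$rt)^2)
      expected <- if (min(d) > 0.05) NA_integer_ else which.min(d)
      expect_identical(nearest_trace(st, pr, threshold = 0.05), expected)
    }
  })
  # probe farther than threshold from every trace
  expect_identical(nearest_trace(st, probe(600, 100, span$mz, span$rt),
                                 threshold = 0.02), NA_integer_)
})

test_that("a dragged segment sweeps up every trace within the threshold", {
  # three traces at one RT, plus a distant one
  pts <- peak_points(mz = c(500.0, 500.5, 501.0, 520.0),
                     rt = c(100, 100, 100, 100), intensity = rep(1, 4))
  st <- build_index(pts)
  for (i in 1:4) {
    tid <- create_trace(st)
    assign_rectangle(st, mz_window(pts$mz[i], pts$mz[i], 100, 100), tid)
  }
  mk <- function(mz, rt) probe(mz, rt, 10, 1000)
  seg <- probe_segment(mk(499.9, 100), mk(501.1, 100))
  expect_equal(traces_on_segment(st, seg, threshold = 0.02), c(1L, 2L, 3L))
  # brute-force point-to-segment oracle on a slanted segment
  seg2 <- probe_segment(mk(499.8, 90), mk(501.2, 110))
  d <- vapply(seq_len(4), function(i) {
    px <- pts$mz[i] / 10; py <- pts$rt[i] / 1000
    ax <- 499.8 / 10; ay <- 90 / 1000; bx <- 501.2 / 10; by <- 110 / 1000
    t <- max(0, min(1, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
                      ((bx - ax)^2 + (by - ay)^2)))
    sqrt((px - (ax + t * (bx - ax)))^2 + (py - (ay + t * (by - ay)))^2)
  }, 0)
  expect_equal(traces_on_segment(st, seg2, threshold = 0.02),
               sort(which(d <= 0.02)))
  # zero-length segment behaves like nearest_trace (0 or 1 ids)
  seg0 <- probe_segment(mk(500.5, 100), mk(500.5, 100))
  expect_equal(traces_on_segment(st, seg0, threshold = 0.02), 2L)
  far <- probe_segment(mk(900, 100), mk(901, 100))
  expect_equal(traces_on_segment(st, far, threshold = 0.02), integer(0))
})

test_that("envelope membership add/remove stamps points and re-parents silently", {
  pts <- peak_points(mz = 500 + (1:6) / 10, rt = rep(60, 6), intensity = 1:6)
  st <- build_index(pts)
  for (i in 1:3) {
    tid <- create_trace(st)
    rect <- mz_window(500 + (2 * i - 1) / 10, 500 + (2 * i) / 10, 0, 120)
    assign_rectangle(st, rect, tid)
  }
  e1 <- create_envelope(st)
  expect_equal(set_envelope(st, c(1L, 2L, 3L), e1), 3)
  expect_true(all(st$points$envelope_id == e1))
  expect_equal(set_envelope(st, c(1L, 2L, 3L), e1), 0)  # idempotent
  expect_equal(set_envelope(st, 2L, e1, "remove"), 1)
  expect_equal(st$points$envelope_id[st$points$trace_id == 2L], c(0L, 0L))
  expect_equal(st$points$envelope_id[st$points$trace_id != 2L], rep(e1, 4))
  # silent re-parenting
  e2 <- create_envelope(st)
  expect_equal(set_envelope(st, 1L, e2), 1)
  expect_equal(unique(st$points$envelope_id[st$points$trace_id == 1L]), e2)
  expect_error(set_envelope(st, 1L, 99L), class = "mzcurate_missing_id")
  expect_error(set_envelope(st, 99L, e1), class = "mzcurate_missing_id")
  validate_store(st)
})

test_that("mark_noise marks only unannotated visible points behind its guard", {
  pts <- peak_points(mz = 500 + (1:50) / 100, rt = rep(60, 50),
                     intensity = rep(1, 50))
  st <- build_index(pts)
  tid <- create_trace(st)
  assign_rectangle(st, mz_window(500.01, 500.10, 0, 120), tid)  # 10 in trace
  w <- mz_window(500, 501, 0, 120)
  expect_equal(mark_noise(st, w, rendered_count = 50, point_threshold = 100), 40)
  expect_equal(sum(st$points$trace_id == -1L), 40)
  expect_equal(sum(st$points$trace_id == tid), 10)
  # idempotent
  expect_equal(mark_noise(st, w, rendered_count = 50, point_threshold = 100), 0)
})

test_that("a violated visibility guard is a strict no-op", {
  pts <- random_cloud(200, seed = 37)
  st <- build_index(pts)
  w <- global_bounds(st)
  before <- annotation_state(st)
  # threshold below the true count
  expect_error(mark_noise(st, w, rendered_count = 200, point_threshold = 100),
               class = "mzcurate_visibility_guard")
  # rendered count disagrees with the true count (hidden points)
  expect_error(mark_noise(st, w, rendered_count = 150, point_threshold = 500),
               class = "mzcurate_visibility_guard")
  expect_identical(annotation_state(st), before)
})

test_that("randomized edit sequences preserve the partition law", {
  pts <- random_cloud(400, seed = 41)
  st <- build_index(pts)
  withr::with_seed(42, {
    for (i in 1:400) {
      op <- sample(6, 1)
      if (op == 1) create_trace(st)
      else if (op == 2 && nrow(st$traces) > 0) {
        tid <- resample(st$traces$trace_id)
        assign_rectangle(st, random_window(pts), tid,
                         mode = resample(c("add", "remove")))
      } else if (op == 3) create_envelope(st)
      else if (op == 4 && nrow(st$traces) > 0 && nrow(st$envelopes) > 0) {
        set_envelope(st, resample(st$traces$trace_id,
                                  min(2, nrow(st$traces))),
                     resample(st$envelopes$envelope_id),
                     mode = resample(c("add", "remove")))
      } else if (op == 5) {
        w <- random_window(pts)
        n <- count_in_window(st, w)
        try(mark_noise(st, w, rendered_count = n, point_threshold = 50),
            silent = TRUE)
      } else if (op == 6 && nrow(st$traces) > 1) {
        delete_trace(st, resample(st$traces$trace_id))
      }
    }
  })
  expect_true(validate_store(st))
  # full partition: each point is exactly one of unannotated/noise/one-trace
  expect_true(all(st$points$trace_id >= -1L))
  expect_true(all(st$points$envelope_id[st$points$trace_id <= 0L] == 0L))
})

test_that("add edits are reversible by the corresponding remove", {
  pts <- random_cloud(150, seed = 43)
  st <- build_index(pts)
  tid <- create_trace(st)
  withr::with_seed(44, {
    for (i in 1:20) {
      w <- random_window(pts)
      before <- annotation_state(st)
      changed <- assign_rectangle(st, w, tid, "add")
      assign_rectangle(st, w, tid, "remove")
      after <- annotation_state(st)
      expect_identical(after, before)
    }
  })
  # envelope add/remove round trip
  assign_rectangle(st, global_bounds(st), tid, "add")
  eid <- create_envelope(st)
  before <- annotation_state(st)
  set_envelope(st, tid, eid, "add")
  set_envelope(st, tid, eid, "remove")
  expect_identical(annotation_state(st), before)
})

test_that("trace summaries derive centroid and extent from current membership", {
  pts <- peak_points(mz = c(500.00, 500.01, 500.02), rt = c(10, 20, 30),
                     intensity = c(1, 2, 1))
  st <- build_index(pts)
  tid <- create_trace(st)
  assign_rectangle(st, mz_window(499, 501, 0, 100), tid)
  s <- trace_summary(st)
  expect_equal(s$n_points, 3L)
  expect_equal(s$centroid_mz, sum(pts$mz * pts$intensity) / sum(pts$intensity))
  expect_equal(c(s$rt_min, s$rt_max), c(10, 30))
  # membership change recomputes the derived fields
  assign_rectangle(st, mz_window(500.02, 500.02, 30, 30), tid, "remove")
  s2 <- trace_summary(st)
  expect_equal(s2$n_points, 2L)
  expect_equal(c(s2$rt_min, s2$rt_max), c(10, 20))
})
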