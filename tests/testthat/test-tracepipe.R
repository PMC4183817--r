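# Trace analysis pipeline: event detection, WLC fits, selection,
# model-free statistics, alignment and density maps.

test_that("event detection recovers the simulated ground truth", {
  con <- study_construct("i27_5")
  tr <- simulate_pull(con, pull_protocol(seed = 33, noise_sd = 0))
  ev <- detect_events(tr)
  expect_equal(sum(ev$kind == "unfold"), 5)
  expect_equal(sum(ev$kind == "detach"), 1)
  truth_idx <- round(tr$events_truth$time / (tr$time[2] - tr$time[1]))
  expect_true(all(abs(ev$peak_index - truth_idx) <= 2))

  flat <- structure(list(time = seq_len(500) * 2e-4, piezo = seq_len(500),
                         extension = seq_len(500), force = numeric(500),
                         events_truth = NULL, metadata = list()),
                    class = "fx_trace")
  expect_equal(nrow(detect_events(flat)), 0)
  empty <- flat
  empty$force <- numeric(0)
  expect_error(detect_events(empty), "empty")

  c4 <- corrupt_trace(cached_trace("i27_5", seed = 5), "four_peaks")
  expect_equal(sum(detect_events(c4)$kind == "unfold"), 4)
})

test_that("single-segment WLC fit recovers exact and noisy parameters", {
  th <- thermo()
  wp <- wlc_params(0.4, 47)
  x <- seq(5, wlc_extension(100, wp, th), length.out = 120)
  f <- wlc_force(x, wp, th)
  mk <- function(force) structure(
    list(time = seq_along(x) * 2e-4, piezo = x, extension = x, force = force,
         events_truth = NULL, metadata = list()),
    class = "fx_trace")
  fit <- fit_wlc_segment(mk(f), seq_along(x))
  expect_equal(fit$contour_length, 47, tolerance = 1e-3)
  expect_equal(fit$persistence_length, 0.4, tolerance = 1e-3)

  # Monte Carlo recovery under 6 pN force noise
  set.seed(42)
  lcs <- replicate(30, {
    fit_wlc_segment(mk(f + rnorm(length(f), sd = 6)),
                    seq_along(x))$contour_length
  })
  expect_equal(mean(lcs), 47, tolerance = 0.02)

  # every point above the cap is a validation error
  expect_error(fit_wlc_segment(mk(f + 200), seq_along(x)), "points")
})

test_that("global five-peak fit recovers the contour increment and p", {
  con <- study_construct("i27_5")
  tr <- simulate_pull(con, pull_protocol(seed = 33, noise_sd = 0))
  ev <- detect_events(tr)
  g <- global_i27_fit(tr, ev)
  expect_equal(g$delta_lc, 28, tolerance = 1e-4)
  expect_equal(g$p, 0.4, tolerance = 1e-4)
  expect_equal(g$lc1, predicted_contour_length(con), tolerance = 1e-3)
  expect_error(global_i27_fit(tr, ev[1:3, ]), "exactly 5")
})

test_that("unequal contour spacing is detectable as gross misfit", {
  mk_con <- function(dlcs) {
    segs <- c(list(segment_spec("unfolded_polypeptide", 30)),
              lapply(dlcs, function(d)
                segment_spec("folded_i27", 89, delta_lc_unfold = d)))
    construct("test", segs, detach_rate0 = 3e-8, detach_distance = 0.4)
  }
  rss_for <- function(con, seed) {
    tr <- simulate_pull(con, pull_protocol(seed = seed, noise_sd = 0))
    ev <- detect_events(tr)
    if (sum(ev$kind == "unfold") != 5) return(NA_real_)
    g <- global_i27_fit(tr, ev)
    g$rss / g$n_points
  }
  rss_eq <- rss_for(mk_con(rep(28, 5)), 2)
  rss_uneq <- rss_for(mk_con(c(20, 36, 20, 36, 20)), 2)
  expect_gt(rss_uneq, 100 * rss_eq)
})

test_that("selection accepts clean traces and rejects each corruption mode", {
  con <- study_construct("i27_5")
  full <- predicted_full_unfolded_length(con)
  tr <- cached_trace("i27_5", seed = 5)
  ev <- detect_events(tr)
  v <- select_trace(tr, ev, selection_criteria(), full)
  expect_true(v$accepted)
  expect_equal(v$reason, "")

  verdict <- function(mode) {
    ct <- corrupt_trace(tr, mode, seed = 3)
    select_trace(ct, detect_events(ct), selection_criteria(), full)
  }
  v4 <- verdict("four_peaks")
  expect_false(v4$accepted)
  expect_match(v4$reason, "event count")
  vd <- verdict("double_detachment")
  expect_false(vd$accepted)
  expect_match(vd$reason, "multiple detachment")
  vl <- verdict("long_tether")
  expect_false(vl$accepted)
  expect_match(vl$reason, "unphysical contour length")
  vr <- verdict("drift")
  expect_false(vr$accepted)

  # determinism of the verdicts
  expect_identical(verdict("four_peaks")$reason, v4$reason)

  # clean SAH trace passes end to end
  tr_s <- cached_trace("i27_5_sah1", seed = 6)
  con_s <- study_construct("i27_5_sah1")
  vs <- select_trace(tr_s, detect_events(tr_s), selection_criteria(),
                     predicted_full_unfolded_length(con_s))
  expect_true(vs$accepted)
})

test_that("peak-to-peak follows the lower-peak reference rule", {
  # two noiseless peaks with identical rising edges exactly 24 nm apart:
  # P2P must be 24.0 at whatever reference force is used
  th <- thermo()
  wp <- wlc_params(0.4, 40)
  mk <- function(drop2 = 0) {
    x1 <- seq(wlc_extension(1, wp, th), wlc_extension(180, wp, th), by = 0.2)
    f1 <- wlc_force(x1, wp, th)
    keep2 <- f1 <= 180 - drop2
    x <- c(x1, x1[keep2] + 24, max(x1) + 24 + 0.2 * seq_len(400))
    f <- c(f1, f1[keep2], numeric(400))
    peaks <- c(length(x1), length(x1) + sum(keep2))
    trace <- structure(
      list(time = seq_along(x) * 2e-4, piezo = x, extension = x, force = f,
           events_truth = NULL, metadata = list(noise_sd = 0)),
      class = "fx_trace")
    events <- data.frame(peak_index = peaks, peak_force = f[peaks],
                         peak_extension = x[peaks], drop = f[peaks],
                         kind = c("unfold", "unfold"),
                         stringsAsFactors = FALSE)
    list(trace = trace, events = events)
  }
  s <- mk()
  p2p <- peak_to_peak(s$trace, s$events)
  expect_equal(length(p2p), 1)
  expect_equal(p2p, 24, tolerance = 1e-3)

  # second peak 20 pN lower: the measurement is taken at the second
  # peak's height, so the identical-edge separation is still recovered
  s2 <- mk(drop2 = 20)
  expect_equal(peak_to_peak(s2$trace, s2$events), 24, tolerance = 1e-3)

  expect_error(peak_to_peak(s$trace, s$events[1, ]), "two unfolding")
})

test_that("unfolding forces exclude the detachment peak", {
  tr <- cached_trace("i27_5", seed = 5)
  ev <- detect_events(tr)
  fu <- unfolding_forces(ev)
  expect_equal(length(fu), 5)
  expect_false(max(ev$peak_extension) %in%
                 ev$peak_extension[ev$kind == "unfold"])
  expect_equal(unfolding_forces(ev[0, ]), numeric(0))
})

test_that("alignment places the 100 pN pre-detachment crossing at zero", {
  b <- cached_batch("i27_5", 6, seed = 101)
  evs <- lapply(b$traces, detect_events)
  al <- align_traces(b$traces, evs)
  expect_equal(length(al), length(b$traces))
  for (i in seq_along(al)) {
    ev <- evs[[i]]
    det <- which(ev$kind == "detach")
    xc <- sahspring:::rising_crossing(al[[i]], ev, det, 100)
    expect_equal(xc, 0, tolerance = 1e-9)
  }
  # aligning two copies of one trace gives identical extensions
  al2 <- align_traces(list(b$traces[[1]], b$traces[[1]]),
                      list(evs[[1]], evs[[1]]))
  expect_identical(al2[[1]]$extension, al2[[2]]$extension)
})

test_that("density map conserves counts and shifts with the data", {
  tr1 <- structure(list(time = 1, piezo = 10, extension = 10.5, force = 21,
                        events_truth = NULL, metadata = list()),
                   class = "fx_trace")
  dm <- density_map(list(tr1), xlim = c(0, 20), flim = c(0, 40))
  expect_equal(sum(dm$counts), 1)
  expect_equal(dm$counts[11, 11], 1L)  # bin [10, 11) x [20, 22)

  b <- cached_batch("i27_5", 6, seed = 101)
  dm2 <- density_map(b$traces[1:3])
  npts <- sum(vapply(b$traces[1:3], function(t) length(t$force), numeric(1)))
  expect_equal(sum(dm2$counts), npts)  # default grid spans all points

  # translating by exactly one pixel shifts the occupied bins by one
  shift <- function(tr) {
    tr$extension <- tr$extension + 1
    tr$force <- tr$force + 2
    tr
  }
  lim <- list(x = c(-10, 300), f = c(-60, 400))
  d0 <- density_map(b$traces[1:2], xlim = lim$x, flim = lim$f)
  d1 <- density_map(lapply(b$traces[1:2], shift), xlim = lim$x, flim = lim$f)
  n <- dim(d0$counts)
  expect_equal(d1$counts[2:n[1], 2:n[2]], d0$counts[1:(n[1] - 1), 1:(n[2] - 1)])
})

test_that("batch summary aggregates accepted traces only", {
  con <- study_construct("i27_5")
  b <- cached_batch("i27_5", 6, seed = 101)
  # three copies of one trace: zero spread in the per-trace statistics
  sm_same <- summarize_batch(b$traces[c(1, 1, 1)], selection_criteria(), con)
  expect_equal(sm_same$table$lc_sd, 0, tolerance = 1e-12)
  expect_equal(sm_same$table$p_sd, 0, tolerance = 1e-12)
  expect_equal(sm_same$table$delta_lc_sd, 0, tolerance = 1e-12)
  expect_equal(sm_same$table$n_traces, 3)

  sm <- summarize_batch(b$traces, selection_criteria(), con)
  expect_equal(sm$table$predicted_lc, 34)
  expect_true(sm$accepted_fraction > 0)
  expect_equal(sm$table$n_total, 6)
  # a corrupted trace lowers the acceptance count, not the statistics
  bad <- corrupt_trace(b$traces[[1]], "four_peaks")
  sm_bad <- summarize_batch(c(b$traces, list(bad)), selection_criteria(), con)
  expect_equal(sm_bad$table$n_total, 7)
  expect_equal(sm_bad$table$n_traces, sm$table$n_traces)
})

test_that("pre-I27 event force helper reports 0 for clean SAH traces", {
  tr <- cached_trace("i27_5_sah1", seed = 6)
  ev <- detect_events(tr)
  expect_equal(max_pre_i27_event_force(ev), 0)
  # a fabricated low-force event before the first I27 peak is reported
  fake <- rbind(data.frame(peak_index = 1, peak_force = 25,
                           peak_extension = 1, drop = 25, kind = "unfold"),
                ev)
  expect_equal(max_pre_i27_event_force(fake), 25)
  expect_equal(max_pre_i27_event_force(ev[0, ]), 0)
})
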