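# Constant-velocity pulling simulator and construct bookkeeping.

test_that("predicted contour lengths of the shipped constructs", {
  expect_equal(round(predicted_contour_length(study_construct("i27_5"))), 34)
  expect_equal(round(predicted_contour_length(study_construct("i27_5_sah1"))),
               73)
  expect_equal(round(predicted_contour_length(study_construct("i27_5_sah2"))),
               111)
  # exact arithmetic underneath: residues x 0.38 + folded domains x 4.5
  expect_equal(predicted_contour_length(study_construct("i27_5")),
               30 * 0.38 + 5 * 4.5)
  # fully unfolded length adds delta_lc per domain
  expect_equal(predicted_full_unfolded_length(study_construct("i27_5")),
               30 * 0.38 + 5 * (4.5 + 28))
})

test_that("with kinetics disabled the loading curve is the series inversion", {
  con <- study_construct("i27_5",
                         unfold_rate0 = 0, unfold_distance = 0.33)
  con$detach_rate0 <- 0
  pr <- pull_protocol(seed = 3, noise_sd = 0, max_travel = 60)
  tr <- simulate_pull(con, pr)
  expect_equal(nrow(tr$events_truth), 0)
  expect_true(all(diff(tr$force) > -1e-9))
  # force-balance residual: F = k_c (z - x) and F = WLC(x) at every step
  taut <- tr$force > 1
  wp <- wlc_params(0.4, predicted_contour_length(con))
  resid <- tr$force[taut] - wlc_force(tr$extension[taut], wp, thermo())
  expect_lt(max(abs(resid)), 1e-6)
  resid_bal <- tr$force - pr$cantilever_k * (tr$piezo - tr$extension)
  expect_lt(max(abs(resid_bal)), 1e-6)
})

test_that("a trace is bitwise reproducible under its seed", {
  con <- study_construct("i27_5")
  pr <- pull_protocol(seed = 17)
  t1 <- simulate_pull(con, pr)
  t2 <- simulate_pull(con, pr)
  expect_identical(t1$force, t2$force)
  expect_identical(t1$events_truth, t2$events_truth)
})

test_that("I27 pentamer traces unfold all five domains before detaching", {
  b <- cached_batch("i27_5", 6, seed = 101)
  for (tr in b$traces) {
    ev <- tr$events_truth
    expect_equal(sum(ev$kind == "unfold"), 5)
    expect_equal(sum(ev$kind == "detach"), 1)
    # detachment comes last
    expect_equal(ev$kind[nrow(ev)], "detach")
    expect_true(all(diff(tr$time) > 0))
    expect_true(all(diff(tr$piezo) >= 0))
  }
})

test_that("mean unfolding force increases with pulling velocity", {
  con <- study_construct("i27_5")
  mean_truth_fu <- function(v, seed) {
    pr <- pull_protocol(velocity = v, seed = seed, noise_sd = 0)
    b <- simulate_batch(con, pr, 4)
    mean(unlist(lapply(b$traces, function(tr) {
      ev <- tr$events_truth
      ev$force[ev$kind == "unfold"]
    })))
  }
  f_slow <- mean_truth_fu(100, 5)
  f_mid <- mean_truth_fu(1000, 6)
  f_fast <- mean_truth_fu(10000, 7)
  expect_lt(f_slow, f_mid)
  expect_lt(f_mid, f_fast)
})

test_that("corruption modes build the intended bad-trace fixtures", {
  tr <- cached_trace("i27_5", seed = 5)
  c4 <- corrupt_trace(tr, "four_peaks", seed = 3)
  expect_equal(sum(c4$events_truth$kind == "unfold"), 4)
  expect_true(all(diff(c4$time) > 0))

  dd <- corrupt_trace(tr, "double_detachment", seed = 3)
  expect_equal(sum(dd$events_truth$kind == "detach"), 2)
  expect_gt(length(dd$time), length(tr$time))

  lt <- corrupt_trace(tr, "long_tether", seed = 3)
  expect_gt(max(lt$extension),
            predicted_full_unfolded_length(study_construct("i27_5")) + 40)

  d1 <- corrupt_trace(tr, "drift", seed = 3)
  d2 <- corrupt_trace(tr, "drift", seed = 3)
  expect_identical(d1$force, d2$force)
  expect_error(corrupt_trace(tr, "nonsense"))
})

test_that("batch simulation writes a reproducible manifest and traces", {
  con <- study_construct("i27_5")
  pr <- pull_protocol(seed = 9)
  b0 <- simulate_batch(con, pr, 0)
  expect_equal(nrow(b0$manifest), 0)

  dir <- withr::local_tempdir()
  b1 <- simulate_batch(con, pr, 3, out_dir = dir)
  expect_equal(nrow(b1$manifest), 3)
  expect_true(all(file.exists(file.path(dir, b1$manifest$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  b2 <- simulate_batch(con, pr, 3)
  expect_identical(b1$manifest$seed, b2$manifest$seed)
  expect_identical(b1$traces[[2]]$force, b2$traces[[2]]$force)

  # trace file round trip
  rt <- read_trace(file.path(dir, b1$manifest$file[1]))
  expect_equal(rt$force, b1$traces[[1]]$force, tolerance = 1e-9)
  expect_equal(rt$extension, b1$traces[[1]]$extension, tolerance = 1e-9)
  expect_equal(rt$metadata$construct, "I27_5")
})

test_that("construct YAML round trips", {
  con <- study_construct("i27_5_sah1")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_construct(con, path)
  con2 <- read_construct(path)
  expect_equal(con2$name, con$name)
  expect_equal(length(con2$segments), length(con$segments))
  expect_equal(predicted_contour_length(con2), predicted_contour_length(con))
})

test_that("SAH element never produces a force drop before the first I27 peak", {
  b <- cached_batch("i27_5_sah1", 4, seed = 55)
  for (tr in b$traces) {
    t_first <- min(tr$events_truth$time[tr$events_truth$kind == "unfold"])
    pre <- tr$force[tr$time < t_first]
    noise_sd <- tr$metadata$noise_sd
    # smoothed drops only; raw noise excursions are not force drops
    sm <- stats::filter(pre, rep(0.2, 5), sides = 2)
    sm <- sm[!is.na(sm)]
    expect_gt(min(diff(sm)), -2 * noise_sd)
  }
})
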