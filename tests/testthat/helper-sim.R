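# Shared fixtures for the test suite.  Simulated batches are cached per
# session so that several test files can reuse the same traces without
# re-running the simulator.

.sim_cache <- new.env(parent = emptyenv())

cached_batch <- function(name, n, seed, noise_sd = 6) {
  key <- paste(name, n, seed, noise_sd, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    con <- study_construct(name)
    pr <- pull_protocol(seed = seed, noise_sd = noise_sd)
    .sim_cache[[key]] <- simulate_batch(con, pr, n)
  }
  .sim_cache[[key]]
}

cached_trace <- function(name, seed, noise_sd = 6) {
  key <- paste("tr", name, seed, noise_sd, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    con <- study_construct(name)
    .sim_cache[[key]] <-
      simulate_pull(con, pull_protocol(seed = seed, noise_sd = noise_sd))
  }
  .sim_cache[[key]]
}

# Synthetic sawtooth built directly from the WLC formula (independent of
# the simulator): `lcs` gives the contour length of each rising segment;
# each segment rises from `f_lo` to its peak force and then drops.
synthetic_sawtooth <- function(lcs, peak_forces, f_lo = 1,
                               p = 0.4, th = thermo(), dx = 0.2) {
  x_all <- numeric(0)
  f_all <- numeric(0)
  peak_idx <- integer(0)
  for (k in seq_along(lcs)) {
    wp <- wlc_params(p, lcs[k])
    x0 <- wlc_extension(f_lo, wp, th)
    x1 <- wlc_extension(peak_forces[k], wp, th)
    xs <- seq(x0, x1, by = dx)
    x_all <- c(x_all, xs)
    f_all <- c(f_all, wlc_force(xs, wp, th))
    peak_idx <- c(peak_idx, length(x_all))
  }
  # final baseline so the last event classifies as a detachment
  x_all <- c(x_all, max(x_all) + dx * seq_len(400))
  f_all <- c(f_all, numeric(400))
  trace <- structure(
    list(time = seq_along(x_all) * 2e-4, piezo = x_all, extension = x_all,
         force = f_all,
         events_truth = data.frame(time = numeric(), segment = integer(),
                                   force = numeric(), kind = character()),
         metadata = list(construct = "synthetic", noise_sd = 0)),
    class = "fx_trace")
  events <- data.frame(
    peak_index = peak_idx, peak_force = f_all[peak_idx],
    peak_extension = x_all[peak_idx],
    drop = f_all[peak_idx],
    kind = c(rep("unfold", length(lcs) - 1), "detach"),
    stringsAsFactors = FALSE)
  list(trace = trace, events = events)
}
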