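# AFM sawtooth-trace analysis: peak detection, trace selection, wormlike-
# chain fitting (first peak and global five-peak), model-free statistics
# (unfolding forces, peak-to-peak distances), trace alignment and
# force-extension density maps.

#' Trace selection criteria
#'
#' The filter that admits only single-molecule, end-picked traces: the
#' expected number of unfolding events followed by exactly one
#' detachment peak, no unphysical contour length at detachment (more
#' than `max_excess_length` beyond the fully unfolded construct length,
#' allowing for origin-placement error), and a global five-peak fit
#' whose contour-length increment and persistence length fall in the
#' expected windows (28 +/- 1 nm and 0.4 +/- 0.1 nm for I27).
#'
#' @param required_unfold_events Unfolding events required (default 5).
#' @param max_detach_events Maximum detachment peaks (default 1).
#' @param delta_lc_center,delta_lc_halfwidth Window for the global-fit
#'   contour-length increment, nm.
#' @param p_center,p_halfwidth Window for the global-fit persistence
#'   length, nm.
#' @param max_excess_length Allowed excess of detachment contour length
#'   over the fully unfolded construct length, nm (default 40).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(required_unfold_events = 5,
                               max_detach_events = 1,
                               delta_lc_center = 28, delta_lc_halfwidth = 1,
                               p_center = 0.4, p_halfwidth = 0.1,
                               max_excess_length = 40) {
  stopifnot(delta_lc_halfwidth > 0, p_halfwidth > 0, max_excess_length > 0)
  structure(
    list(required_unfold_events = as.integer(required_unfold_events),
         max_detach_events = as.integer(max_detach_events),
         delta_lc_center = delta_lc_center,
         delta_lc_halfwidth = delta_lc_halfwidth,
         p_center = p_center, p_halfwidth = p_halfwidth,
         max_excess_length = max_excess_length),
    class = "selection_criteria"
  )
}

# Centered running mean with shrinking windows at the edges (length
# preserved); used to suppress sampling noise before peak picking.
smooth_force <- function(f, window = 5) {
  if (window <= 1) return(f)
  stats::filter(f, rep(1 / window, window), sides = 2) ->
    sm
  sm <- as.numeric(sm)
  # shrink the window at the edges instead of returning NA
  half <- window %/% 2
  n <- length(f)
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    sm[i] <- mean(f[lo:hi])
  }
  sm
}

# Robust per-trace noise estimate from first differences.
estimate_noise_sd <- function(f) {
  stats::mad(diff(f)) / sqrt(2)
}

#' Detect unfolding and detachment events in a force-extension trace
#'
#' Hysteresis peak picking on a lightly smoothed force signal: a peak is
#' reported where the force exceeds `min_peak_force` and subsequently
#' drops by at least `min_drop` within `drop_window` samples of the
#' local maximum.  An event after which the force stays at baseline
#' (within `3 * noise_sd` of zero for at least `baseline_window` samples
#' or to the end of the trace) is classified as a detachment.
#'
#' @param trace An `fx_trace`.
#' @param min_peak_force Minimum peak force, pN (default 50).
#' @param min_drop Minimum force drop that qualifies as an event, pN
#'   (default 30).
#' @param drop_window Samples after the peak within which the drop must
#'   occur (default 50).
#' @param smooth_window Running-mean window for detection (samples).
#' @param baseline_window Samples of near-zero force that mark a
#'   detachment (default 250).
#' @return A data.frame of events: `peak_index`, `peak_force` (pN, from
#'   the raw signal at the peak), `peak_extension` (nm), `drop` (pN),
#'   `kind` (`"unfold"` or `"detach"`), time-ordered.
#' @export
detect_events <- function(trace, min_peak_force = 50, min_drop = 30,
                          drop_window = 50, smooth_window = 5,
                          baseline_window = 250) {
  stopifnot(inherits(trace, "fx_trace"))
  if (length(trace$force) == 0) stop("empty trace")
  raw <- trace$force
  f <- smooth_force(raw, smooth_window)
  n <- length(f)
  noise_sd <- max(estimate_noise_sd(raw), 1e-9)

  # candidate local maxima of the smoothed force above the peak threshold
  cand <- which(f >= min_peak_force)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[f[cand] >= f[cand - 1] & f[cand] > f[cand + 1]]

  peaks <- integer(0)
  for (i in cand) {
    after <- f[(i + 1):min(n, i + drop_window)]
    if (f[i] - min(after) < min_drop) next
    if (length(peaks) > 0) {
      last <- peaks[length(peaks)]
      valley <- min(f[last:i])
      # no qualifying valley between this candidate and the previous
      # accepted peak: the two belong to the same peak; keep the higher
      if (valley > min(f[last], f[i]) - min_drop) {
        if (f[i] > f[last]) peaks[length(peaks)] <- i
        next
      }
    }
    peaks <- c(peaks, i)
  }

  # refine each peak on the raw signal (smoothing shifts and lowers the
  # apex) and measure the drop from the raw values
  drops <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    win <- max(1, i - smooth_window):min(n, i + smooth_window)
    iraw <- win[which.max(raw[win])]
    peaks[k] <- iraw
    after <- raw[(iraw + 1):min(n, iraw + drop_window)]
    drops[k] <- raw[iraw] - min(after)
  }

  if (length(peaks) == 0) {
    return(data.frame(peak_index = integer(), peak_force = numeric(),
                      peak_extension = numeric(), drop = numeric(),
                      kind = character(), stringsAsFactors = FALSE))
  }

  # an event is a detachment if the force settles at baseline after the
  # drop (most of the following baseline_window samples within 3 sd of 0)
  kind <- rep("unfold", length(peaks))
  for (k in seq_along(peaks)) {
    j0 <- peaks[k]
    # the force must reach baseline within the drop window of the peak...
    j1 <- min(n, j0 + drop_window)
    seg <- f[j0:j1]
    low <- which(seg < 3 * noise_sd)
    if (length(low) > 0) {
      # ... and stay there for most of the following baseline window
      start <- j0 + low[1] - 1
      stop_ <- min(n, start + baseline_window - 1)
      if (mean(f[start:stop_] < 3 * noise_sd) > 0.8) kind[k] <- "detach"
    }
  }
  data.frame(peak_index = peaks, peak_force = raw[peaks],
             peak_extension = trace$extension[peaks], drop = drops,
             kind = kind, stringsAsFactors = FALSE)
}

# Sample range of the rising edge leading to event k: from just after the
# previous event's force minimum (or trace start) to the event peak.
rising_segment <- function(trace, events, k, smooth_window = 5) {
  f <- smooth_force(trace$force, smooth_window)
  i_peak <- events$peak_index[k]
  i_start <- if (k == 1) 1 else {
    prev <- events$peak_index[k - 1]
    prev + which.min(f[prev:i_peak]) - 1
  }
  i_start:i_peak
}

#' Fit a wormlike chain to one rising segment of a trace
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of the WLC
#' force-extension relation to the points of a rising edge with forces
#' inside `[floor, cap]`.  The fit is capped at 100 pN to stay below the
#' I27 unfolding-intermediate regime.
#'
#' @param trace An `fx_trace`.
#' @param segment Integer sample indices of the rising segment.
#' @param cap Upper force bound for fitted points, pN (default 100).
#' @param floor Lower force bound for fitted points, pN (default 5).
#' @param predicted_lc_bound Upper bound on the contour length, nm.
#' @param min_points Minimum number of fitted points (default 20).
#' @param thermo A [thermo()] object.
#' @return An object of class `wlc_fit`: `contour_length`,
#'   `persistence_length`, `fit_cap`, `rss` (pN^2), `n_points`.
#' @export
fit_wlc_segment <- function(trace, segment, cap = 100, floor = 5,
                            predicted_lc_bound = 500, min_points = 20,
                            thermo = default_thermo()) {
  stopifnot(inherits(trace, "fx_trace"))
  x <- trace$extension[segment]
  f <- trace$force[segment]
  use <- f <= cap & f >= floor
  if (sum(use) < min_points) {
    stop("fewer than ", min_points, " points under the ", cap, " pN cap")
  }
  x <- x[use]
  f <- f[use]
  kBT <- thermo$kBT
  max_ext <- max(x)
  start <- list(lc = 1.2 * max_ext, p = 0.4)
  fit <- minpack.lm::nlsLM(
    f ~ (kBT / p) * (1 / (4 * (1 - x / lc)^2) - 0.25 + x / lc),
    start = start,
    lower = c(lc = max_ext * 1.001, p = 0.05),
    upper = c(lc = predicted_lc_bound, p = 2),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  structure(
    list(contour_length = unname(cf["lc"]),
         persistence_length = unname(cf["p"]),
         fit_cap = cap, rss = sum(stats::resid(fit)^2),
         n_points = length(x)),
    class = "wlc_fit"
  )
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> lc = %.2f nm, p = %.3f nm (%d points, rss %.1f pN^2)\n",
              x$contour_length, x$persistence_length, x$n_points, x$rss))
  invisible(x)
}

#' Global wormlike-chain fit to the five I27 unfolding events
#'
#' Simultaneous fit of the five rising edges preceding the I27
#' unfolding peaks, sharing one persistence length and with the contour
#' lengths constrained to an arithmetic progression
#' `lc_k = lc_1 + (k - 1) * delta_lc`.  Returns the shared
#' contour-length increment `delta_lc` and persistence length `p`, the
#' two quantities on which the trace selection windows operate.
#'
#' @param trace An `fx_trace`.
#' @param events Event table from [detect_events()]; must contain
#'   exactly `n_events` unfolding events.
#' @param cap,floor Force window of fitted points, pN.  The lower bound
#'   (default 10) keeps the fit clear of the contact region while
#'   retaining enough of the low-force shape to pin the persistence
#'   length; narrower windows leave the fit on the (p, lc) ridge where
#'   force noise biases both parameters.
#' @param n_events Number of unfolding events expected (default 5).
#' @param thermo A [thermo()] object.
#' @return List with `delta_lc` (nm), `p` (nm), `lc1` (nm), `rss`
#'   (pN^2), `n_points`.
#' @export
global_i27_fit <- function(trace, events, cap = 100, floor = 10,
                           n_events = 5, thermo = default_thermo()) {
  unf <- which(events$kind == "unfold")
  if (length(unf) != n_events) {
    stop("global fit requires exactly ", n_events, " unfolding events")
  }
  xs <- list(); fs <- list(); ks <- list()
  for (k in seq_along(unf)) {
    seg <- rising_segment(trace, events, unf[k])
    x <- trace$extension[seg]
    f <- trace$force[seg]
    use <- f >= floor & f <= cap
    xs[[k]] <- x[use]
    fs[[k]] <- f[use]
    ks[[k]] <- rep(k - 1, sum(use))
  }
  x <- unlist(xs); f <- unlist(fs); k <- unlist(ks)
  if (length(x) < 40) stop("too few points for the global fit")
  kBT <- thermo$kBT
  max1 <- max(xs[[1]])
  fit <- minpack.lm::nlsLM(
    f ~ (kBT / p) *
      (1 / (4 * (1 - x / (lc1 + k * dlc))^2) - 0.25 + x / (lc1 + k * dlc)),
    start = list(lc1 = 1.2 * max1, p = 0.4, dlc = 28),
    lower = c(lc1 = max1 * 1.001, p = 0.05, dlc = 5),
    upper = c(lc1 = 500, p = 2, dlc = 80),
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  cf <- stats::coef(fit)
  list(delta_lc = unname(cf["dlc"]), p = unname(cf["p"]),
       lc1 = unname(cf["lc1"]), rss = sum(stats::resid(fit)^2),
       n_points = length(x))
}

# Apparent contour length at the detachment peak: WLC fit to the final
# rising edge, used by the unphysical-length selection rule.
detachment_contour_length <- function(trace, events,
                                      thermo = default_thermo()) {
  det <- which(events$kind == "detach")
  if (length(det) == 0) return(NA_real_)
  k <- det[length(det)]
  seg <- rising_segment(trace, events, k)
  cap <- min(100, 0.9 * events$peak_force[k])
  fit <- try(fit_wlc_segment(trace, seg, cap = cap, floor = 10,
                             thermo = thermo), silent = TRUE)
  if (inherits(fit, "try-error")) return(max(trace$extension[seg]))
  fit$contour_length
}

#' Apply the trace selection filter
#'
#' Applies, in order: the unfolding-event-count rule, the
#' single-detachment rule, the unphysical-contour-length rule (apparent
#' contour length at detachment more than `max_excess_length` beyond the
#' fully unfolded construct length), and the global-fit window rules on
#' the contour-length increment and persistence length.  The first
#' failing rule is named in the rejection reason.
#'
#' @param trace An `fx_trace`.
#' @param events Event table from [detect_events()].
#' @param criteria A [selection_criteria()] object.
#' @param predicted_full_length Fully unfolded construct length, nm
#'   (see [predicted_full_unfolded_length()]).
#' @param global_fit Optional precomputed result of [global_i27_fit()];
#'   computed on demand when `NULL`.
#' @param thermo A [thermo()] object.
#' @return List with `accepted` (flag), `reason` (empty if accepted)
#'   and `global_fit` (the fit, or NULL if rejected before fitting).
#' @export
select_trace <- function(trace, events, criteria = selection_criteria(),
                         predicted_full_length, global_fit = NULL,
                         thermo = default_thermo()) {
  n_unf <- sum(events$kind == "unfold")
  n_det <- sum(events$kind == "detach")
  verdict <- function(accepted, reason = "", fit = NULL) {
    list(accepted = accepted, reason = reason, global_fit = fit)
  }
  if (n_unf != criteria$required_unfold_events) {
    return(verdict(FALSE, sprintf(
      "unfolding event count %d != required %d", n_unf,
      criteria$required_unfold_events)))
  }
  if (n_det > criteria$max_detach_events) {
    return(verdict(FALSE, "multiple detachment peaks"))
  }
  if (n_det == 0) {
    return(verdict(FALSE, "no detachment peak"))
  }
  lc_det <- detachment_contour_length(trace, events, thermo)
  if (is.finite(lc_det) &&
      lc_det > predicted_full_length + criteria$max_excess_length) {
    return(verdict(FALSE, "unphysical contour length"))
  }
  if (is.null(global_fit)) {
    global_fit <- try(global_i27_fit(trace, events,
                                     n_events = criteria$required_unfold_events,
                                     thermo = thermo), silent = TRUE)
    if (inherits(global_fit, "try-error")) {
      return(verdict(FALSE, "global WLC fit failed"))
    }
  }
  if (abs(global_fit$delta_lc - criteria$delta_lc_center) >
      criteria$delta_lc_halfwidth) {
    return(verdict(FALSE, "contour length increment outside window", global_fit))
  }
  if (abs(global_fit$p - criteria$p_center) > criteria$p_halfwidth) {
    return(verdict(FALSE, "persistence length outside window", global_fit))
  }
  verdict(TRUE, "", global_fit)
}

#' Unfolding forces of a trace
#'
#' Peak force of each unfolding event (detachment excluded).
#'
#' @param events Event table from [detect_events()].
#' @return Numeric vector of unfolding forces, pN.
#' @export
unfolding_forces <- function(events) {
  events$peak_force[events$kind == "unfold"]
}

# Extension at which the rising edge to event k crosses `force`
# (last upward crossing before the peak, linearly interpolated).
rising_crossing <- function(trace, events, k, force, smooth_window = 5) {
  f <- smooth_force(trace$force, smooth_window)
  seg <- rising_segment(trace, events, k, smooth_window)
  fs <- f[seg]
  xs <- trace$extension[seg]
  below <- which(fs[-length(fs)] < force & fs[-1] >= force)
  if (length(below) == 0) return(NA_real_)
  i <- below[length(below)]
  x0 <- xs[i]; x1 <- xs[i + 1]
  f0 <- fs[i]; f1 <- fs[i + 1]
  x0 + (force - f0) / (f1 - f0) * (x1 - x0)
}

#' Peak-to-peak distances of a trace
#'
#' Distance from one unfolding peak to the same force value on the
#' following unfolding event: the reference force is the lower of the
#' two peak forces, and the distance is measured between the points
#' where the two rising edges cross that reference force (linear
#' interpolation).  Five unfolding peaks yield four distances.
#'
#' @param trace An `fx_trace`.
#' @param events Event table from [detect_events()].
#' @return Numeric vector of peak-to-peak distances, nm.
#' @export
peak_to_peak <- function(trace, events) {
  unf <- which(events$kind == "unfold")
  if (length(unf) < 2) stop("need at least two unfolding events")
  # peak heights re-read from the smoothed signal so the reference force
  # is guaranteed to be crossed by the smoothed rising edges
  f_sm <- smooth_force(trace$force, 5)
  out <- numeric(0)
  for (k in seq_len(length(unf) - 1)) {
    i <- unf[k]; j <- unf[k + 1]
    ref <- min(f_sm[events$peak_index[i]], f_sm[events$peak_index[j]])
    xa <- rising_crossing(trace, events, i, ref)
    xb <- rising_crossing(trace, events, j, ref)
    if (is.na(xa) || is.na(xb)) {
      warning("no rising-edge crossing for event pair ", k, "; skipped")
      next
    }
    out <- c(out, xb - xa)
  }
  out
}

#' Largest detected event force before the first I27 unfolding peak
#'
#' A SAH domain lengthens at nearly constant low force and should leave
#' no sawtooth peak of its own before the first I27 unfolding event.
#' This helper reports the maximum peak force of any detected event
#' preceding the first I27-scale peak (the first event at or above
#' `i27_threshold`), or 0 when there is none.
#'
#' @param events Event table from [detect_events()].
#' @param i27_threshold Force above which a peak is unambiguously an
#'   I27 unfolding (or detachment) event, pN (default 100).
#' @return Largest pre-I27 event force in pN (0 if none).
#' @export
max_pre_i27_event_force <- function(events, i27_threshold = 100) {
  if (nrow(events) == 0) return(0)
  first <- which(events$peak_force >= i27_threshold)[1]
  pre <- if (is.na(first)) events$peak_force else
    events$peak_force[seq_len(first - 1)]
  if (length(pre) == 0) 0 else max(pre)
}

#' Align traces at the 100 pN crossing before the detachment peak
#'
#' Shifts each trace's extension axis so that the last upward 100 pN
#' crossing on the rising edge to the detachment peak sits at a common
#' reference extension (0 by default).  Traces without a detachment
#' event or without such a crossing are dropped with a warning.
#'
#' @param traces List of `fx_trace` objects.
#' @param events_list List of event tables, parallel to `traces`.
#' @param reference_force Alignment force, pN (default 100).
#' @param reference_extension Extension assigned to the crossing, nm.
#' @return List of aligned `fx_trace` objects (possibly shorter).
#' @export
align_traces <- function(traces, events_list, reference_force = 100,
                         reference_extension = 0) {
  out <- list()
  for (i in seq_along(traces)) {
    ev <- events_list[[i]]
    det <- which(ev$kind == "detach")
    if (length(det) == 0) {
      warning("trace ", i, " has no detachment event; dropped")
      next
    }
    xc <- rising_crossing(traces[[i]], ev, det[length(det)], reference_force)
    if (is.na(xc)) {
      warning("trace ", i, " has no ", reference_force,
              " pN crossing before detachment; dropped")
      next
    }
    tr <- traces[[i]]
    tr$extension <- tr$extension - xc + reference_extension
    out[[length(out) + 1]] <- tr
  }
  out
}

#' Force-extension density map
#'
#' Bins all points of a set of (aligned) traces on a grid of
#' `pixel_nm` x `pixel_pN` pixels with half-open bins `[lo, hi)`.
#'
#' @param traces List of `fx_trace` objects (typically aligned).
#' @param pixel_nm Extension pixel size, nm (default 1).
#' @param pixel_pN Force pixel size, pN (default 2).
#' @param xlim,flim Optional grid limits `c(lo, hi)`; default spans the
#'   data.
#' @return A list of class `density_map`: `counts` (matrix, extension
#'   rows x force columns), `x_edges`, `f_edges`.
#' @export
density_map <- function(traces, pixel_nm = 1, pixel_pN = 2,
                        xlim = NULL, flim = NULL) {
  x <- unlist(lapply(traces, `[[`, "extension"))
  f <- unlist(lapply(traces, `[[`, "force"))
  if (is.null(xlim)) xlim <- range(x)
  if (is.null(flim)) flim <- range(f)
  x_edges <- seq(floor(xlim[1] / pixel_nm) * pixel_nm,
                 ceiling(xlim[2] / pixel_nm) * pixel_nm + pixel_nm,
                 by = pixel_nm)
  f_edges <- seq(floor(flim[1] / pixel_pN) * pixel_pN,
                 ceiling(flim[2] / pixel_pN) * pixel_pN + pixel_pN,
                 by = pixel_pN)
  ix <- findInterval(x, x_edges, rightmost.closed = FALSE)
  jf <- findInterval(f, f_edges, rightmost.closed = FALSE)
  ok <- ix >= 1 & ix < length(x_edges) & jf >= 1 & jf < length(f_edges)
  counts <- matrix(0L, nrow = length(x_edges) - 1, ncol = length(f_edges) - 1)
  tab <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
               factor(jf[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, x_edges = x_edges, f_edges = f_edges),
            class = "density_map")
}

#' Analyse a single trace end-to-end
#'
#' Runs event detection, selection, the first-peak WLC fit and the
#' model-free statistics for one trace, producing the machine-readable
#' summary row behind a construct-level table.
#'
#' @param trace An `fx_trace`.
#' @param criteria A [selection_criteria()] object.
#' @param predicted_full_length Fully unfolded construct length, nm.
#' @param thermo A [thermo()] object.
#' @param ... Passed to [detect_events()].
#' @return An object of class `trace_summary`: `accepted`,
#'   `rejection_reason`, `fu_list`, `p2p_list`, `first_peak_fit`
#'   (a `wlc_fit` or NULL), `global_delta_lc`, `global_p`, `events`.
#' @export
analyze_trace <- function(trace, criteria = selection_criteria(),
                          predicted_full_length,
                          thermo = default_thermo(), ...) {
  events <- detect_events(trace, ...)
  sel <- select_trace(trace, events, criteria, predicted_full_length,
                      thermo = thermo)
  fu <- unfolding_forces(events)
  p2p <- if (sum(events$kind == "unfold") >= 2)
    suppressWarnings(peak_to_peak(trace, events)) else numeric(0)
  first_fit <- NULL
  unf <- which(events$kind == "unfold")
  if (length(unf) >= 1) {
    seg <- rising_segment(trace, events, unf[1])
    first_fit <- try(fit_wlc_segment(trace, seg, thermo = thermo),
                     silent = TRUE)
    if (inherits(first_fit, "try-error")) first_fit <- NULL
  }
  structure(
    list(accepted = sel$accepted, rejection_reason = sel$reason,
         fu_list = fu, p2p_list = p2p, first_peak_fit = first_fit,
         global_delta_lc = if (!is.null(sel$global_fit))
           sel$global_fit$delta_lc else NA_real_,
         global_p = if (!is.null(sel$global_fit))
           sel$global_fit$p else NA_real_,
         events = events),
    class = "trace_summary"
  )
}

#' Summarise a batch of traces for one construct
#'
#' Computes the per-construct summary statistics (mean +/- sd over
#' accepted traces) of the unfolding force, peak-to-peak distance,
#' first-peak contour and persistence lengths, and global contour-length
#' increment, alongside the predicted contour length of the construct.
#'
#' @param traces List of `fx_trace` objects.
#' @param criteria A [selection_criteria()] object.
#' @param con The [construct()] the traces belong to.
#' @param thermo A [thermo()] object.
#' @param ... Passed to [detect_events()] via [analyze_trace()].
#' @return A list of class `batch_summary`: `table` (one-row
#'   data.frame), `summaries` (per-trace `trace_summary` list),
#'   `accepted_fraction`.
#' @export
summarize_batch <- function(traces, criteria = selection_criteria(), con,
                            thermo = default_thermo(), ...) {
  full_len <- predicted_full_unfolded_length(con)
  sums <- lapply(traces, analyze_trace, criteria = criteria,
                 predicted_full_length = full_len, thermo = thermo, ...)
  acc <- vapply(sums, `[[`, logical(1), "accepted")
  a <- sums[acc]
  stat <- function(v) c(mean = mean(v), sd = stats::sd(v))
  if (length(a) > 0) {
    fu <- stat(unlist(lapply(a, `[[`, "fu_list")))
    p2p <- stat(unlist(lapply(a, `[[`, "p2p_list")))
    lc1 <- stat(vapply(a, function(s) s$first_peak_fit$contour_length,
                       numeric(1)))
    p1 <- stat(vapply(a, function(s) s$first_peak_fit$persistence_length,
                      numeric(1)))
    dlc <- stat(vapply(a, `[[`, numeric(1), "global_delta_lc"))
    gp <- stat(vapply(a, `[[`, numeric(1), "global_p"))
  } else {
    fu <- p2p <- lc1 <- p1 <- dlc <- gp <- c(mean = NA_real_, sd = NA_real_)
  }
  tab <- data.frame(
    construct = con$name, n_traces = length(a), n_total = length(traces),
    fu_mean = fu["mean"], fu_sd = fu["sd"],
    p2p_mean = p2p["mean"], p2p_sd = p2p["sd"],
    lc_mean = lc1["mean"], lc_sd = lc1["sd"],
    p_mean = p1["mean"], p_sd = p1["sd"],
    delta_lc_mean = dlc["mean"], delta_lc_sd = dlc["sd"],
    global_p_mean = gp["mean"], global_p_sd = gp["sd"],
    predicted_lc = round(predicted_contour_length(con)),
    row.names = NULL)
  structure(list(table = tab, summaries = sums,
                 accepted_fraction = mean(acc)),
            class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  t <- x$table
  cat(sprintf(
    "<batch_summary> %s: %d/%d traces accepted\n  Fu %.0f +/- %.0f pN; P2P %.1f +/- %.1f nm; lc %.0f +/- %.0f nm; p %.2f +/- %.2f nm; dlc %.1f nm; predicted lc %d nm\n",
    t$construct, t$n_traces, t$n_total, t$fu_mean, t$fu_sd, t$p2p_mean,
    t$p2p_sd, t$lc_mean, t$lc_sd, t$p_mean, t$p_sd, t$delta_lc_mean,
    t$predicted_lc))
  invisible(x)
}
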