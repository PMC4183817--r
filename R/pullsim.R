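# Constant-velocity pulling simulator: cantilever + construct in series,
# Bell-model unfolding kinetics for folded I27 domains, equilibrium
# helix-coil mechanics for SAH domains.  Produces sawtooth force-extension
# traces with the acquisition characteristics of an AFM experiment.

# Per-residue contour length of an unfolded polypeptide, nm.
RESIDUE_CONTOUR_NM <- 0.38
# Length of a folded I27 domain, nm.
I27_FOLDED_NM <- 4.5
# Contour-length gain on unfolding one I27 domain, nm.
I27_DELTA_LC_NM <- 28

#' Mechanical segment of a construct
#'
#' @param kind One of `"folded_i27"`, `"unfolded_polypeptide"`,
#'   `"sah_helix"`.
#' @param n_residues Residue count of the segment.
#' @param folded_length Folded length in nm (`folded_i27` only;
#'   default 4.5).
#' @param unfold_rate0 Zero-force unfolding rate k0 in 1/s
#'   (`folded_i27` only; Bell model).
#' @param unfold_distance Distance to the unfolding transition state in
#'   nm (`folded_i27` only; Bell model).
#' @param delta_lc_unfold Contour-length gain on unfolding, nm
#'   (`folded_i27` only; default 28): the construct's wormlike-chain
#'   contour length grows by this amount when the domain unfolds.
#' @param delta_g_per_residue,cooperativity_block Helix-coil parameters
#'   (`sah_helix` only); see [helix_coil_params()].
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(kind,
                         n_residues,
                         folded_length = I27_FOLDED_NM,
                         unfold_rate0 = 3.3e-4,
                         unfold_distance = 0.33,
                         delta_lc_unfold = I27_DELTA_LC_NM,
                         delta_g_per_residue = -0.4,
                         cooperativity_block = 4) {
  kind <- match.arg(kind, c("folded_i27", "unfolded_polypeptide", "sah_helix"))
  if (!is.numeric(n_residues) || n_residues < 1) {
    stop("n_residues must be >= 1")
  }
  structure(
    list(kind = kind,
         n_residues = as.integer(n_residues),
         folded_length = folded_length,
         unfold_rate0 = unfold_rate0,
         unfold_distance = unfold_distance,
         delta_lc_unfold = delta_lc_unfold,
         delta_g_per_residue = delta_g_per_residue,
         cooperativity_block = as.integer(cooperativity_block)),
    class = "segment_spec"
  )
}

#' Polyprotein construct
#'
#' Ordered series of mechanical segments plus the Bell parameters of the
#' final tip/surface detachment process.  The shipped detachment
#' defaults give detachment forces of roughly 150-300 pN after the last
#' I27 unfolding while making detachment before the last unfolding
#' negligibly rare.
#'
#' @param name Construct name.
#' @param segments List of [segment_spec()] objects.
#' @param detach_rate0 Zero-force detachment rate, 1/s.
#' @param detach_distance Bell distance of the detachment process, nm.
#' @return An object of class `construct`.
#' @export
construct <- function(name, segments, detach_rate0 = 3e-8,
                      detach_distance = 0.4) {
  if (length(segments) < 1) stop("a construct needs at least one segment")
  stopifnot(all(vapply(segments, inherits, logical(1), "segment_spec")))
  structure(
    list(name = name, segments = segments,
         detach_rate0 = detach_rate0, detach_distance = detach_distance),
    class = "construct"
  )
}

#' Pulling protocol
#'
#' Acquisition parameters of a constant-velocity pulling experiment.
#' Defaults follow standard polyprotein AFM practice: 1000 nm/s pulling
#' speed, 5 kHz sampling, a 40 pN/nm cantilever and 6 pN white force
#' noise.
#'
#' @param velocity Pulling speed, nm/s.
#' @param cantilever_k Cantilever spring constant, pN/nm.
#' @param sample_rate Sampling rate, Hz.
#' @param max_travel Maximum piezo travel, nm.
#' @param max_force Abort force, pN.
#' @param noise_sd Gaussian noise added to the reported force, pN.
#' @param seed Integer seed for the trace's stochastic events and noise.
#' @return An object of class `pull_protocol`.
#' @export
pull_protocol <- function(velocity = 1000, cantilever_k = 40,
                          sample_rate = 5000, max_travel = 800,
                          max_force = 2000, noise_sd = 6, seed = 1L) {
  if (velocity <= 0 || cantilever_k <= 0 || sample_rate <= 0) {
    stop("velocity, cantilever_k and sample_rate must all be positive")
  }
  structure(
    list(velocity = velocity, cantilever_k = cantilever_k,
         sample_rate = sample_rate, max_travel = max_travel,
         max_force = max_force, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "pull_protocol"
  )
}

# Mechanical state of a construct part-way through a pull.  The chain of
# folded domains plus unfolded polypeptide behaves as one wormlike chain
# whose contour length is the unfolded residue contour plus the folded
# length of each still-folded domain (the standard polyprotein picture:
# the fitted contour grows by delta_lc_unfold at each unfolding); SAH
# domains are separate helix-coil elements in series.
construct_state <- function(con, wlc_p = 0.4) {
  lc_chain <- 0
  hc <- list()
  folded <- logical(length(con$segments))
  for (i in seq_along(con$segments)) {
    seg <- con$segments[[i]]
    if (seg$kind == "folded_i27") {
      lc_chain <- lc_chain + seg$folded_length
      folded[i] <- TRUE
    } else if (seg$kind == "unfolded_polypeptide") {
      lc_chain <- lc_chain + seg$n_residues * RESIDUE_CONTOUR_NM
    } else {
      hc[[length(hc) + 1]] <- helix_coil_params(
        n_residues = seg$n_residues,
        coil_persistence_length = wlc_p,
        delta_g_per_residue = seg$delta_g_per_residue,
        cooperativity_block = seg$cooperativity_block
      )
    }
  }
  list(lc_chain = lc_chain, hc = hc, folded = folded, wlc_p = wlc_p)
}

# Molecular extension at force F for a given state (scalar F).
state_extension <- function(F, st, th) {
  x <- st$lc_chain * wlc_inv_scaled(F * st$wlc_p / th$kBT)
  for (h in st$hc) x <- x + helix_coil_extension(F, h, th)$extension
  x
}

# Solve the force balance F = k_c (z - x(F)) for F >= 0.  g(F) is strictly
# decreasing, so the root is unique; bracketed from a warm start.
solve_force <- function(z, st, k_c, th, f_prev = 0) {
  if (state_extension(0, st, th) >= z) return(0)
  g <- function(F) k_c * (z - state_extension(F, st, th)) - F
  lo <- max(0, f_prev - 5)
  hi <- f_prev + 15
  while (g(lo) < 0 && lo > 0) lo <- max(0, lo - 50)
  while (g(hi) > 0) hi <- hi + 50
  if (g(lo) < 0) return(0)  # taut only marginally; force ~ 0
  stats::uniroot(g, lower = lo, upper = hi, tol = 1e-9)$root
}

#' Simulate one constant-velocity pulling trace
#'
#' At each sampling step the piezo advances by `velocity / sample_rate`,
#' the force balance between the cantilever and the construct is solved,
#' and each still-folded I27 domain unfolds with Bell-model probability
#' `1 - exp(-k0 exp(F dx / kBT) dt)`.  On unfolding the domain's rigid
#' folded length is replaced by an unfolded wormlike chain; detachment is
#' sampled from an analogous Bell process and ends the pull (a short
#' zero-force tail is appended so the detachment peak is identifiable).
#' Gaussian noise is added to the reported force only; the dynamics and
#' kinetics use the noise-free force.
#'
#' @param con A [construct()].
#' @param protocol A [pull_protocol()].
#' @param thermo A [thermo()] object.
#' @param wlc_p Persistence length used for all unfolded polypeptide, nm.
#' @return An object of class `fx_trace`: time-ordered `time` (s),
#'   `piezo` (nm), `extension` (nm, noise-free molecular extension),
#'   `force` (pN, with noise), ground-truth event table `events_truth`
#'   (time, segment, force, kind) and `metadata`.
#' @export
simulate_pull <- function(con, protocol, thermo = default_thermo(),
                          wlc_p = 0.4) {
  stopifnot(inherits(con, "construct"), inherits(protocol, "pull_protocol"))
  set.seed(protocol$seed)
  th <- thermo
  dt <- 1 / protocol$sample_rate
  dz <- protocol$velocity * dt
  n_max <- ceiling(protocol$max_travel / dz)
  st <- construct_state(con, wlc_p)
  segs <- con$segments

  time <- piezo <- ext <- force <- numeric(n_max)
  ev_time <- ev_force <- numeric(0)
  ev_seg <- integer(0)
  ev_kind <- character(0)

  f_prev <- 0
  n <- 0
  detached <- FALSE
  for (i in seq_len(n_max)) {
    z <- i * dz
    F <- solve_force(z, st, protocol$cantilever_k, th, f_prev)
    n <- n + 1
    time[n] <- i * dt
    piezo[n] <- z
    force[n] <- F
    ext[n] <- z - F / protocol$cantilever_k
    f_prev <- F
    if (F > protocol$max_force) break

    # Bell kinetics as competing risks: at most one event per step (the
    # first unfolding within a step collapses the force, so the chance of
    # a second barrier crossing in the same step is negligible).
    if (F > 0) {
      idx_folded <- which(st$folded)
      rates <- vapply(idx_folded, function(j) {
        segs[[j]]$unfold_rate0 * exp(F * segs[[j]]$unfold_distance / th$kBT)
      }, numeric(1))
      r_det <- con$detach_rate0 * exp(F * con$detach_distance / th$kBT)
      r_tot <- sum(rates) + r_det
      if (stats::runif(1) < -expm1(-r_tot * dt)) {
        pick <- sample.int(length(rates) + 1, 1,
                           prob = c(rates, r_det) / r_tot)
        if (pick <= length(rates)) {
          j <- idx_folded[pick]
          st$folded[j] <- FALSE
          st$lc_chain <- st$lc_chain + segs[[j]]$delta_lc_unfold
          ev_time <- c(ev_time, i * dt)
          ev_seg <- c(ev_seg, j)
          ev_force <- c(ev_force, F)
          ev_kind <- c(ev_kind, "unfold")
        } else {
          ev_time <- c(ev_time, i * dt)
          ev_seg <- c(ev_seg, NA_integer_)
          ev_force <- c(ev_force, F)
          ev_kind <- c(ev_kind, "detach")
          detached <- TRUE
        }
      }
    }
    if (detached) break
  }

  # Post-detachment tail: cantilever relaxed, force at baseline.
  if (detached) {
    n_tail <- round(0.08 * protocol$sample_rate)
    i0 <- length(time[seq_len(n)])
    t0 <- time[n]
    z0 <- piezo[n]
    time <- c(time[seq_len(n)], t0 + dt * seq_len(n_tail))
    piezo <- c(piezo[seq_len(n)], z0 + dz * seq_len(n_tail))
    ext <- c(ext[seq_len(n)], z0 + dz * seq_len(n_tail))
    force <- c(force[seq_len(n)], numeric(n_tail))
    n <- i0 + n_tail
  } else {
    time <- time[seq_len(n)]
    piezo <- piezo[seq_len(n)]
    ext <- ext[seq_len(n)]
    force <- force[seq_len(n)]
  }

  if (protocol$noise_sd > 0) {
    force <- force + stats::rnorm(n, sd = protocol$noise_sd)
  }

  events <- data.frame(time = ev_time, segment = ev_seg,
                       force = ev_force, kind = ev_kind,
                       stringsAsFactors = FALSE)
  structure(
    list(time = time, piezo = piezo, extension = ext, force = force,
         events_truth = events,
         metadata = list(construct = con$name, velocity = protocol$velocity,
                         cantilever_k = protocol$cantilever_k,
                         sample_rate = protocol$sample_rate,
                         noise_sd = protocol$noise_sd,
                         seed = protocol$seed, detached = detached)),
    class = "fx_trace"
  )
}

#' @export
print.fx_trace <- function(x, ...) {
  ev <- x$events_truth
  cat("<fx_trace>", x$metadata$construct, "-", length(x$time), "samples,",
      sum(ev$kind == "unfold"), "unfolding event(s),",
      sum(ev$kind == "detach"), "detachment(s)\n")
  invisible(x)
}

#' Predicted contour length of a construct before I27 unfolding
#'
#' Expected fully-stretched length of a construct before any I27 domain
#' has unfolded, assuming SAH domains and linkers are unfolded:
#' 0.38 nm per unfolded (linker or SAH) residue plus 4.5 nm per folded
#' I27 domain.
#'
#' @param con A [construct()].
#' @return Predicted contour length in nm (exact; round for display).
#' @export
predicted_contour_length <- function(con) {
  if (length(con$segments) == 0) return(0)
  sum(vapply(con$segments, function(seg) {
    if (seg$kind == "folded_i27") seg$folded_length
    else seg$n_residues * RESIDUE_CONTOUR_NM
  }, numeric(1)))
}

#' Predicted fully unfolded length of a construct
#'
#' As [predicted_contour_length()] but with every I27 domain unfolded
#' (each contributing `folded_length + delta_lc_unfold`).  Used by the
#' unphysical-contour-length selection rule.
#'
#' @inheritParams predicted_contour_length
#' @return Length in nm.
#' @export
predicted_full_unfolded_length <- function(con) {
  if (length(con$segments) == 0) return(0)
  sum(vapply(con$segments, function(seg) {
    if (seg$kind == "folded_i27") seg$folded_length + seg$delta_lc_unfold
    else seg$n_residues * RESIDUE_CONTOUR_NM
  }, numeric(1)))
}

#' Corrupt a simulated trace to emulate a known bad-trace failure mode
#'
#' Produces deterministic fixtures for testing the trace selection
#' filter: `four_peaks` splices out one unfolding cycle so only four
#' I27 unfoldings remain; `double_detachment` appends a second tether
#' pick-up and detachment peak after the true detachment; `long_tether`
#' stretches the extension axis so the apparent contour length at
#' detachment is unphysically long; `drift` adds a strong linear
#' baseline drift to the force.
#'
#' @param trace An `fx_trace` from [simulate_pull()].
#' @param mode One of `"four_peaks"`, `"double_detachment"`,
#'   `"long_tether"`, `"drift"`.
#' @param seed Seed for the corruption's own randomness.
#' @return A corrupted `fx_trace` with updated ground-truth metadata.
#' @export
corrupt_trace <- function(trace, mode, seed = 1L) {
  stopifnot(inherits(trace, "fx_trace"))
  mode <- match.arg(mode,
                    c("four_peaks", "double_detachment", "long_tether", "drift"))
  set.seed(seed)
  tr <- trace
  ev <- tr$events_truth
  unf <- which(ev$kind == "unfold")
  if (mode == "four_peaks") {
    if (length(unf) < 2) stop("need at least two unfolding events to splice")
    # remove the samples of one full unfolding cycle (between the last two
    # unfolding events) and close the gap in time/piezo/extension
    t_a <- ev$time[unf[length(unf) - 1]]
    t_b <- ev$time[unf[length(unf)]]
    keep <- tr$time <= t_a | tr$time > t_b
    drop_n <- sum(!keep)
    dt <- tr$time[2] - tr$time[1]
    dz <- tr$piezo[2] - tr$piezo[1]
    shift <- tr$time > t_b
    tr$time[shift] <- tr$time[shift] - drop_n * dt
    tr$piezo[shift] <- tr$piezo[shift] - drop_n * dz
    tr$extension[shift] <- tr$extension[shift] - drop_n * dz
    for (f in c("time", "piezo", "extension", "force")) tr[[f]] <- tr[[f]][keep]
    keep_ev <- ev$time <= t_a | ev$time > t_b
    ev <- ev[keep_ev, , drop = FALSE]
    ev$time[ev$time > t_b] <- ev$time[ev$time > t_b] - drop_n * dt
    tr$events_truth <- ev
  } else if (mode == "double_detachment") {
    det <- which(ev$kind == "detach")
    if (length(det) != 1) stop("trace must contain exactly one detachment")
    dt <- tr$time[2] - tr$time[1]
    dz <- tr$piezo[2] - tr$piezo[1]
    n0 <- length(tr$time)
    z0 <- tr$piezo[n0]
    # second pick-up: a fresh wormlike-chain tether loaded to ~180 pN
    th <- thermo()
    lc2 <- z0 + 60
    p2 <- wlc_params(0.4, lc2)
    k_c <- tr$metadata$cantilever_k
    z <- z0
    f2 <- z2 <- numeric(0)
    F <- 0
    repeat {
      z <- z + dz
      g <- function(Fv) k_c * (z - wlc_extension(Fv, p2, th)) - Fv
      F <- if (g(0) <= 0) 0 else
        stats::uniroot(g, lower = 0, upper = 1000, tol = 1e-9)$root
      f2 <- c(f2, F)
      z2 <- c(z2, z)
      if (F >= 180) break
    }
    n_tail <- round(0.08 / dt)
    f2 <- c(f2, numeric(n_tail))
    z2 <- c(z2, z + dz * seq_len(n_tail))
    f2[seq_along(f2) > (length(f2) - n_tail)] <- 0
    noise <- tr$metadata$noise_sd
    if (noise > 0) f2 <- f2 + stats::rnorm(length(f2), sd = noise)
    t2 <- tr$time[n0] + dt * seq_along(f2)
    x2 <- z2 - pmax(f2, 0) / k_c
    tr$time <- c(tr$time, t2)
    tr$piezo <- c(tr$piezo, z2)
    tr$extension <- c(tr$extension, x2)
    tr$force <- c(tr$force, f2)
    tr$events_truth <- rbind(ev, data.frame(
      time = t2[which.max(f2)], segment = NA_integer_,
      force = max(f2), kind = "detach"))
  } else if (mode == "long_tether") {
    stretch <- 1.5
    tr$piezo <- tr$piezo * stretch
    tr$extension <- tr$extension * stretch
  } else if (mode == "drift") {
    slope <- 400  # pN/s; strong baseline drift
    tr$force <- tr$force + slope * (tr$time - tr$time[1])
  }
  tr$metadata$corruption <- mode
  tr
}

#' Simulate a batch of traces
#'
#' Per-trace seeds are drawn reproducibly from the protocol seed, so a
#' fixed protocol seed yields an identical batch (and manifest) on rerun.
#'
#' @param constructs List of [construct()] objects (or a single one).
#' @param protocol A [pull_protocol()]; its `seed` is the master seed.
#' @param n_per_construct Number of traces per construct.
#' @param out_dir Optional directory; when given, traces are written as
#'   tab-separated files and the manifest as `manifest.csv`.
#' @return A list with `traces` (list of `fx_trace`) and `manifest`
#'   (data.frame: file, construct, seed, n_unfold_truth, detached).
#' @export
simulate_batch <- function(constructs, protocol, n_per_construct,
                           out_dir = NULL) {
  if (inherits(constructs, "construct")) constructs <- list(constructs)
  set.seed(protocol$seed)
  total <- length(constructs) * n_per_construct
  seeds <- if (total > 0) sample.int(.Machine$integer.max - 1L, total) else
    integer(0)
  traces <- vector("list", total)
  rows <- vector("list", total)
  k <- 0
  for (con in constructs) {
    for (i in seq_len(n_per_construct)) {
      k <- k + 1
      pr <- protocol
      pr$seed <- seeds[k]
      tr <- simulate_pull(con, pr)
      traces[[k]] <- tr
      file <- if (is.null(out_dir)) NA_character_ else
        sprintf("%s_%03d.tsv", gsub("[^A-Za-z0-9_]+", "_", con$name), i)
      rows[[k]] <- data.frame(
        file = file, construct = con$name, seed = seeds[k],
        n_unfold_truth = sum(tr$events_truth$kind == "unfold"),
        detached = tr$metadata$detached, stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_trace(tr, file.path(out_dir, file))
      }
    }
  }
  manifest <- if (total > 0) do.call(rbind, rows) else
    data.frame(file = character(), construct = character(),
               seed = integer(), n_unfold_truth = integer(),
               detached = logical())
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(traces = traces, manifest = manifest)
}

# --- trace and construct I/O ------------------------------------------------

#' Read and write force-extension traces
#'
#' Traces are stored as tab-separated text with columns `time_s`,
#' `piezo_nm`, `extension_nm`, `force_pN` and a `#`-prefixed YAML
#' metadata header.
#'
#' @param trace An `fx_trace`.
#' @param path File path.
#' @return `read_trace` returns an `fx_trace` (without ground-truth
#'   events unless they were stored); `write_trace` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fx_trace"))
  meta <- trace$metadata
  hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  df <- data.frame(time_s = trace$time, piezo_nm = trace$piezo,
                   extension_nm = trace$extension, force_pN = trace$force)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- if (any(is_hdr)) {
    yaml::yaml.load(paste(sub("^# ?", "", lines[is_hdr]), collapse = "\n"))
  } else list()
  df <- utils::read.table(text = lines[!is_hdr], header = TRUE, sep = "\t")
  structure(
    list(time = df$time_s, piezo = df$piezo_nm, extension = df$extension_nm,
         force = df$force_pN,
         events_truth = data.frame(time = numeric(), segment = integer(),
                                   force = numeric(), kind = character()),
         metadata = meta),
    class = "fx_trace"
  )
}

#' Read and write construct definitions as YAML
#'
#' @param con A [construct()].
#' @param path YAML file path.
#' @return `read_construct` returns a [construct()].
#' @export
write_construct <- function(con, path) {
  stopifnot(inherits(con, "construct"))
  obj <- list(
    name = con$name,
    detach_rate0 = con$detach_rate0,
    detach_distance = con$detach_distance,
    segments = lapply(con$segments, function(s) s[!vapply(s, is.null, TRUE)])
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_construct
#' @export
read_construct <- function(path) {
  obj <- yaml::yaml.load_file(path)
  segs <- lapply(obj$segments, function(s) do.call(segment_spec, s))
  construct(name = obj$name, segments = segs,
            detach_rate0 = obj$detach_rate0,
            detach_distance = obj$detach_distance)
}

#' Shipped construct definitions
#'
#' Returns one of the three study constructs: an I27 pentamer
#' (`i27_5`), the pentamer with one 97-residue SAH domain inserted
#' (`i27_5_sah1`), or with two (`i27_5_sah2`).  Linker and tag residue
#' counts (30 unfolded residues for the bare pentamer; 6 and 3 extra
#' linker residues accompanying the first and second SAH cassette) are
#' chosen so the predicted contour lengths are 34, 73 and 111 nm.
#'
#' @param name One of `"i27_5"`, `"i27_5_sah1"`, `"i27_5_sah2"`.
#' @param unfold_rate0,unfold_distance Bell parameters applied to every
#'   I27 domain; defaults are the shipped calibration (see
#'   [default_i27_bell()]).
#' @return A [construct()].
#' @export
study_construct <- function(name = c("i27_5", "i27_5_sah1", "i27_5_sah2"),
                            unfold_rate0 = default_i27_bell()$unfold_rate0,
                            unfold_distance = default_i27_bell()$unfold_distance) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "sahspring", mustWork = TRUE)
  con <- read_construct(path)
  con$segments <- lapply(con$segments, function(s) {
    if (s$kind == "folded_i27") {
      s$unfold_rate0 <- unfold_rate0
      s$unfold_distance <- unfold_distance
    }
    s
  })
  con
}

#' Default Bell-model calibration for I27 unfolding
#'
#' Zero-force unfolding rate and transition-state distance used for the
#' I27 domains in the shipped constructs.  Starting from the commonly
#' used literature values (k0 = 3.3e-4 1/s, dx = 0.25 nm) the distance
#' was fine-tuned (see `scripts/tune_bell.R`) so that the mean unfolding
#' force measured by the analysis pipeline on traces simulated at
#' 1000 nm/s with a 40 pN/nm cantilever is ~174 pN.
#'
#' @return List with `unfold_rate0` (1/s) and `unfold_distance` (nm).
#' @export
default_i27_bell <- function() {
  list(unfold_rate0 = 3.3e-4, unfold_distance = 0.33)
}
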