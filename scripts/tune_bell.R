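#!/usr/bin/env Rscript
# Calibrate the I27 Bell-model unfolding parameters so that the mean
# unfolding force measured by the analysis pipeline on simulated I27
# pentamer traces (1000 nm/s, 5 kHz, 40 pN/nm cantilever, 6 pN noise)
# matches the 174 pN reference value.  k0 is held at the literature
# 3.3e-4 1/s and the transition-state distance is scanned; the chosen
# value is recorded as the default in default_i27_bell().
#
# Usage: Rscript scripts/tune_bell.R [n_traces_per_point]

suppressMessages({
  if (!requireNamespace("sahspring", quietly = TRUE)) {
    # allow running from a source checkout during development
    invisible(lapply(list.files("R", full.names = TRUE), source))
  } else {
    library(sahspring)
  }
})

args <- commandArgs(trailingOnly = TRUE)
n_per <- if (length(args) >= 1) as.integer(args[1]) else 20L
target_fu <- 174

mean_fu <- function(dx, n, seed = 1234) {
  con <- read_construct(file.path("inst", "extdata", "i27_5.yaml"))
  con$segments <- lapply(con$segments, function(s) {
    if (s$kind == "folded_i27") {
      s$unfold_rate0 <- 3.3e-4
      s$unfold_distance <- dx
    }
    s
  })
  pr <- pull_protocol(seed = seed)
  b <- simulate_batch(con, pr, n)
  fu <- unlist(lapply(b$traces, function(tr) {
    ev <- detect_events(tr)
    if (sum(ev$kind == "unfold") == 5 && sum(ev$kind == "detach") == 1) {
      unfolding_forces(ev)
    } else numeric(0)
  }))
  c(mean = mean(fu), sd = stats::sd(fu), n_events = length(fu))
}

grid <- seq(0.28, 0.40, by = 0.02)
res <- t(vapply(grid, mean_fu, numeric(3), n = n_per))
tab <- data.frame(unfold_distance = grid, res)
print(tab, row.names = FALSE)

# linear interpolation of the scan to the target
fit <- stats::lm(mean ~ unfold_distance, data = tab)
dx_star <- (target_fu - stats::coef(fit)[1]) / stats::coef(fit)[2]
cat(sprintf("\ninterpolated unfold_distance for %g pN: %.3f nm\n",
            target_fu, dx_star))
cat("check at that value:\n")
print(mean_fu(round(dx_star, 3), n_per))
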