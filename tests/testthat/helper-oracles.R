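# Independent oracles used across tests. These deliberately use naive
# algorithms (double loops, pairwise counts) so they cannot share a bug
# with the vectorized implementations they check.

# exhaustive sample-aligned window search for HIC, incremental trapezoid
# sums, O(n * w) double loop
hic_oracle <- function(times, accel, max_window = 0.036) {
  n <- length(times)
  dt <- times[2L] - times[1L]
  w_max <- min(n - 1L, floor(max_window / dt + 1e-9))
  best <- -Inf
  best_t <- c(NA, NA)
  for (i in seq_len(n - 1L)) {
    integ <- 0
    for (j in (i + 1L):min(i + w_max, n)) {
      integ <- integ + (accel[j - 1L] + accel[j]) / 2 * dt
      tw <- times[j] - times[i]
      val <- (integ / tw)^2.5 * tw
      if (val > best) {
        best <- val
        best_t <- c(times[i], times[j])
      }
    }
  }
  list(hic = best, t1 = best_t[1L], t2 = best_t[2L])
}

# Mann-Whitney pairwise AUC with ties credited one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# simulate one condition end to end and return its criteria + bands
surrogate_chain <- function(delta_v, belted, deploy_time,
                            params = default_surrogate_params(),
                            duration = 0.1) {
  pulse <- generate_vehicle_pulse(delta_v, duration = duration)
  resp <- simulate_occupant(pulse, belted, deploy_time, params = params)
  crit <- compute_injury_criteria(resp)
  crit$head_ais <- ais_code(band_for_hic(crit$hic36))
  crit$chest_ais <- ais_code(band_for_cti(crit$cti))
  crit
}

# random uniformly-sampled head acceleration trace
random_trace <- function(n, dt = 1e-3, peak = 80) {
  times <- seq(0, by = dt, length.out = n)
  base <- abs(stats::rnorm(n, 0, peak / 4)) +
    peak * sin(pi * seq(0, 1, length.out = n))^2 * stats::runif(1)
  list(times = times, accel = base)
}
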