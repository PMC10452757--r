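#' Generate an idealized frontal-crash deceleration pulse
#'
#' Builds a haversine-shaped vehicle deceleration pulse
#' \eqn{a(t) = A \sin^2(\pi t / T)} whose time integral over the pulse
#' duration equals the specified velocity change (delta-v). The haversine
#' is the standard idealization of a full-frontal rigid-wall crash pulse;
#' its closed-form integral \eqn{A T / 2} fixes the amplitude at
#' \eqn{A = 2\,\Delta v / T}.
#'
#' @param delta_v Vehicle velocity change in km/h. Must be positive.
#' @param duration Pulse duration in seconds. Default 0.1 s, typical of a
#'   full-frontal rigid-wall impact.
#' @param n_samples Number of uniformly spaced samples, including both
#'   endpoints. Must be at least 16. The default gives a 0.1 ms step.
#'
#' @return An object of class `vehicle_pulse`: a list with elements
#'   `times` (s), `decel` (m/s^2, non-negative), `duration` (s) and
#'   `delta_v` (km/h, as supplied).
#'
#' @examples
#' p <- generate_vehicle_pulse(50)
#' max(p$decel) / 9.80665  # peak deceleration in g, about 28.3 g
#' @export
generate_vehicle_pulse <- function(delta_v, duration = 0.1,
                                   n_samples = round(duration / 1e-4) + 1L) {
  if (!is.numeric(delta_v) || length(delta_v) != 1L || !is.finite(delta_v) ||
      delta_v <= 0) {
    stop("`delta_v` must be a single positive number (km/h)")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number (s)")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 16L) {
    stop("`n_samples` must be at least 16")
  }
  dv_ms <- delta_v / 3.6
  amplitude <- 2 * dv_ms / duration
  times <- seq(0, duration, length.out = n_samples)
  decel <- amplitude * sin(pi * times / duration)^2
  structure(
    list(times = times, decel = decel, duration = duration, delta_v = delta_v),
    class = "vehicle_pulse"
  )
}

#' @export
print.vehicle_pulse <- function(x, ...) {
  cat(sprintf(
    "<vehicle_pulse> delta-v %.1f km/h, duration %.0f ms, %d samples, peak %.1f g\n",
    x$delta_v, x$duration * 1000, length(x$times), max(x$decel) / 9.80665
  ))
  invisible(x)
}

# trapezoidal integral of a uniformly sampled trace
trapz_uniform <- function(times, values) {
  dt <- times[2L] - times[1L]
  dt * (sum(values) - (values[1L] + values[length(values)]) / 2)
}
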