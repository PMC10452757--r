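#' Head Injury Criterion (HIC36)
#'
#' Computes
#' \deqn{HIC = \max_{t_1 < t_2} \left[\frac{1}{t_2 - t_1}
#'   \int_{t_1}^{t_2} a(t)\,dt\right]^{2.5} (t_2 - t_1)}
#' over all sample-aligned window pairs with \eqn{t_2 - t_1 \le}
#' `max_window`, the standard 36 ms cap. The window-average acceleration
#' is the trapezoidal integral divided by the window length. Candidate
#' windows are restricted to sample-aligned endpoints so the optimum is
#' exactly reproducible; ties are broken by the smallest window start,
#' then the smallest window.
#'
#' @param times Uniformly spaced sample times in seconds.
#' @param accel Resultant head acceleration in g, same length as `times`.
#' @param max_window Maximum window length in seconds (default 0.036,
#'   i.e. HIC36).
#'
#' @return An object of class `hic_result`: list with `hic`
#'   (dimensionless), `t1` and `t2` (s, the maximizing window).
#'
#' @examples
#' t <- seq(0, 0.01, by = 1e-4)
#' compute_hic(t, rep(50, length(t)))$hic  # 50^2.5 * 0.010 = 176.78
#' @export
compute_hic <- function(times, accel, max_window = 0.036) {
  n <- length(times)
  if (n == 0L || length(accel) == 0L) stop("empty trace")
  if (n < 2L) stop("trace must have at least 2 samples")
  if (length(accel) != n) stop("`times` and `accel` lengths differ")
  if (!is.numeric(max_window) || max_window < 0) {
    stop("`max_window` must be non-negative")
  }
  dt <- diff(times)
  if (any(abs(dt - dt[1L]) > 1e-9 * max(dt[1L], 1e-12))) {
    stop("trace must be uniformly sampled")
  }
  dt <- dt[1L]

  # cumulative trapezoidal integral of a(t)
  ctrap <- c(0, cumsum((accel[-n] + accel[-1L]) / 2 * dt))
  w_max <- min(n - 1L, floor(max_window / dt + 1e-9))
  if (w_max < 1L) {
    stop("`max_window` is shorter than the sampling step")
  }

  best <- -Inf
  best_i <- 1L
  best_k <- 1L
  for (k in seq_len(w_max)) {
    tw <- k * dt
    i <- seq_len(n - k)
    vals <- ((ctrap[i + k] - ctrap[i]) / tw)^2.5 * tw
    j <- which.max(vals)
    v <- vals[j]
    if (v > best ||
        (v == best && (j < best_i || (j == best_i && k < best_k)))) {
      best <- v
      best_i <- j
      best_k <- k
    }
  }
  structure(
    list(hic = best, t1 = times[best_i], t2 = times[best_i + best_k]),
    class = "hic_result"
  )
}

#' @export
print.hic_result <- function(x, ...) {
  cat(sprintf(
    "HIC = %.2f over [%.1f, %.1f] ms\n", x$hic, x$t1 * 1000, x$t2 * 1000
  ))
  invisible(x)
}

#' Combined Thoracic Index (CTI)
#'
#' \deqn{CTI = A_{max}/A_{int} + D_{max}/D_{int}} where \eqn{A_{max}} and
#' \eqn{D_{max}} are the peak chest acceleration and deflection and the
#' intercepts are the maximum allowable values. The defaults (85 g,
#' 102 mm) are the NHTSA intercepts for the 50th-percentile male.
#'
#' @param a_max Peak chest acceleration, g (non-negative).
#' @param d_max Peak chest deflection, mm (non-negative).
#' @param a_int Acceleration intercept, g (positive, default 85).
#' @param d_int Deflection intercept, mm (positive, default 102).
#'
#' @return An object of class `cti_result`: list with `cti`, `a_max`,
#'   `d_max`, `a_int`, `d_int`.
#'
#' @examples
#' compute_cti(42.5, 51)$cti  # 0.5 + 0.5 = 1
#' @export
compute_cti <- function(a_max, d_max, a_int = 85, d_int = 102) {
  if (a_int <= 0 || d_int <= 0) stop("intercepts must be positive")
  if (a_max < 0 || d_max < 0) stop("peaks must be non-negative")
  structure(
    list(
      cti = a_max / a_int + d_max / d_int,
      a_max = a_max, d_max = d_max, a_int = a_int, d_int = d_int
    ),
    class = "cti_result"
  )
}

#' @export
print.cti_result <- function(x, ...) {
  cat(sprintf(
    "CTI = %.3f (Amax %.1f g / %.0f g + Dmax %.1f mm / %.0f mm)\n",
    x$cti, x$a_max, x$a_int, x$d_max, x$d_int
  ))
  invisible(x)
}

#' Peak chest acceleration and deflection of an occupant response
#'
#' @param response An `occupant_response` from [simulate_occupant()].
#' @return List with `a_max` (g) and `d_max` (mm).
#' @export
extract_peaks <- function(response) {
  stopifnot(inherits(response, "occupant_response"))
  if (length(response$chest_accel) == 0L || length(response$chest_defl) == 0L) {
    stop("empty trace")
  }
  list(a_max = max(response$chest_accel), d_max = max(response$chest_defl))
}

#' Injury criteria for one occupant response
#'
#' Convenience wrapper: HIC36 from the head acceleration trace, peak
#' chest acceleration/deflection, and CTI.
#'
#' @param response An `occupant_response`.
#' @param max_window HIC window cap, s.
#' @param a_int,d_int CTI intercepts (g, mm).
#' @return A one-row data frame with columns `hic36`, `t1_s`, `t2_s`,
#'   `cti`, `a_max_g`, `d_max_mm`.
#' @export
compute_injury_criteria <- function(response, max_window = 0.036,
                                    a_int = 85, d_int = 102) {
  stopifnot(inherits(response, "occupant_response"))
  h <- compute_hic(response$times, response$head_accel, max_window)
  pk <- extract_peaks(response)
  cti <- compute_cti(pk$a_max, pk$d_max, a_int, d_int)
  data.frame(
    hic36 = h$hic, t1_s = h$t1, t2_s = h$t2,
    cti = cti$cti, a_max_g = pk$a_max, d_max_mm = pk$d_max
  )
}
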