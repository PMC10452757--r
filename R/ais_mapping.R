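AIS_LABELS <- c("0-1", "2", "3", "4", "5-6")

#' AIS severity band constructor
#'
#' Bands follow the five-row severity classification used for HIC/CTI
#' thresholds: none-or-minor (0-1), moderate (2), major (3), acute (4)
#' and critical-death (5-6). Bands are represented as ordered factors so
#' ordinal comparisons work; `ais_code()` recovers the integer code 1..5
#' for arithmetic (e.g. MAIS).
#'
#' @param code Integer vector of ordinal codes in 1..5.
#' @return An ordered factor with levels `0-1 < 2 < 3 < 4 < 5-6`.
#' @export
ais_band <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 1L | code > 5L)) {
    stop("AIS ordinal codes must be integers in 1..5")
  }
  factor(AIS_LABELS[code], levels = AIS_LABELS, ordered = TRUE)
}

#' @rdname ais_band
#' @param band An ordered factor produced by `ais_band()` or the banding
#'   functions, or an integer code vector (returned unchanged).
#' @export
ais_code <- function(band) {
  if (is.factor(band)) {
    if (!identical(levels(band), AIS_LABELS)) stop("not an AIS band factor")
    return(as.integer(band))
  }
  code <- as.integer(band)
  if (any(is.na(code)) || any(code < 1L | code > 5L)) {
    stop("AIS ordinal codes must be integers in 1..5")
  }
  code
}

new_band_table <- function(metric, bounds) {
  if (length(bounds) != 4L) stop("a band table needs 4 upper bounds")
  if (any(diff(bounds) <= 0)) stop("band bounds must be strictly increasing")
  structure(
    list(metric = metric, bounds = bounds, labels = AIS_LABELS),
    class = "band_table"
  )
}

#' Default HIC and CTI severity band tables
#'
#' The operative thresholds relating HIC36 and CTI to AIS bands:
#' HIC upper bounds 250 / 750 / 1250 / 1750 and CTI upper bounds
#' 0.80 / 1.15 / 1.39 / 2.16, with anything at or above the top bound in
#' the critical 5-6 band. Intervals are half-open `[lower, upper)`: a
#' value exactly on a bound belongs to the band above it.
#'
#' @return A `band_table`: list with `metric`, ascending `bounds`, and
#'   band `labels`.
#' @examples
#' band_for_hic(800)  # major injury, AIS 3
#' @export
hic_band_table <- function() new_band_table("HIC", c(250, 750, 1250, 1750))

#' @rdname hic_band_table
#' @export
cti_band_table <- function() new_band_table("CTI", c(0.80, 1.15, 1.39, 2.16))

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("<band_table> %s\n", x$metric))
  lo <- c(0, x$bounds)
  hi <- c(x$bounds, Inf)
  for (i in seq_along(x$labels)) {
    cat(sprintf("  AIS %-4s [%g, %g)\n", x$labels[i], lo[i], hi[i]))
  }
  invisible(x)
}

band_for_metric <- function(x, table) {
  stopifnot(inherits(table, "band_table"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s values must be finite and non-negative", table$metric))
  }
  # counts bounds <= x, so a value on a bound lands in the band above
  ais_band(findInterval(x, table$bounds) + 1L)
}

#' Map injury-criterion values to AIS severity bands
#'
#' Looks the value up in the half-open intervals of a [hic_band_table()]
#' or [cti_band_table()]; vectorized.
#'
#' @param hic,cti Non-negative criterion values.
#' @param table A `band_table`; defaults to the matching metric's table.
#' @return AIS band(s), an ordered factor (see [ais_band()]).
#' @examples
#' band_for_cti(1.0)   # moderate injury, AIS 2
#' band_for_hic(1750)  # boundary value rolls up to 5-6
#' @export
band_for_hic <- function(hic, table = hic_band_table()) {
  band_for_metric(hic, table)
}

#' @rdname band_for_hic
#' @export
band_for_cti <- function(cti, table = cti_band_table()) {
  band_for_metric(cti, table)
}

#' Logistic injury risk curves
#'
#' Builds a list of monotone risk functions P(AIS >= k | metric), one per
#' severity level 2..5, as logistics
#' \eqn{P(x) = 1 / (1 + e^{-s_k (x - m_k)})}. The midpoints are then the
#' 50%-risk metric values. Provided so that band thresholds can be
#' derived from risk curves under the equal-severity-ratio 50%-risk
#' construction; coefficients are configuration, not hard-coded.
#'
#' @param midpoints Ascending 50%-risk metric values, one per level 2..5.
#' @param slopes Positive slopes, recycled to length 4.
#' @return Named list of functions (`"2"`, `"3"`, `"4"`, `"5"`).
#' @export
make_logistic_risk_curves <- function(midpoints, slopes = 1) {
  if (length(midpoints) != 4L) stop("need one midpoint per AIS level 2..5")
  slopes <- rep_len(slopes, 4L)
  if (any(slopes <= 0)) stop("slopes must be positive")
  curves <- Map(function(m, s) {
    force(m); force(s)
    function(x) 1 / (1 + exp(-s * (x - m)))
  }, midpoints, slopes)
  names(curves) <- as.character(2:5)
  curves
}

#' Derive band thresholds from injury risk curves
#'
#' For each severity level k in 2..5 solves P(AIS >= k | metric) = 0.5 by
#' bisection (to `tol` in metric units) and assembles the ascending
#' solutions into a `band_table`. This mirrors the construction that
#' assumes equal severity ratios between the metric and AIS risk curves
#' at 50% risk. Curves must be monotone non-decreasing, and higher
#' severity levels must cross 0.5 at larger metric values.
#'
#' @param curves Named list (`"2"`..`"5"`) of vectorized risk functions
#'   mapping metric values to probabilities.
#' @param metric Name for the resulting table ("HIC", "CTI", ...).
#' @param interval Search interval for the bisection.
#' @param tol Bisection tolerance in metric units.
#' @return A `band_table` whose bounds are the 50%-risk metric values.
#' @examples
#' curves <- make_logistic_risk_curves(c(250, 750, 1250, 1750), 0.01)
#' thresholds_from_risk_curves(curves, "HIC", c(0, 4000))$bounds
#' @export
thresholds_from_risk_curves <- function(curves, metric = "metric",
                                        interval = c(0, 1e4), tol = 1e-6) {
  if (length(curves) != 4L) stop("need one risk curve per AIS level 2..5")
  bounds <- vapply(seq_along(curves), function(i) {
    f <- curves[[i]]
    lvl <- names(curves)[i]
    xs <- seq(interval[1L], interval[2L], length.out = 201L)
    ps <- f(xs)
    if (any(diff(ps) < -1e-9)) {
      stop(sprintf("risk curve for AIS >= %s is not monotone", lvl))
    }
    lo <- interval[1L]
    hi <- interval[2L]
    if (f(lo) >= 0.5 || f(hi) < 0.5) {
      stop(sprintf(
        "risk curve for AIS >= %s has no 0.5 crossing on the interval", lvl
      ))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0.5) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  if (any(diff(bounds) <= 0)) {
    stop("risk curves are mis-ordered: 50%-risk values must increase with severity")
  }
  new_band_table(metric, bounds)
}
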