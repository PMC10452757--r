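test_that("the default band tables carry the published bounds", {
  expect_equal(hic_band_table()$bounds, c(250, 750, 1250, 1750))
  expect_equal(cti_band_table()$bounds, c(0.80, 1.15, 1.39, 2.16))
  expect_equal(hic_band_table()$labels, c("0-1", "2", "3", "4", "5-6"))
})

test_that("HIC and CTI banding follows the half-open interval convention", {
  expect_equal(as.character(band_for_hic(800)), "3")
  expect_equal(as.character(band_for_hic(0)), "0-1")
  expect_equal(as.character(band_for_hic(750)), "3")  # bound rolls upward
  expect_equal(as.character(band_for_hic(2500)), "5-6")
  expect_equal(as.character(band_for_cti(1.0)), "2")
  expect_equal(as.character(band_for_cti(3.0)), "5-6")
  expect_equal(as.character(band_for_cti(0)), "0-1")
  expect_equal(as.character(band_for_cti(2.16)), "5-6")
  expect_error(band_for_hic(-1), "non-negative")
})

test_that("banding is monotone in the metric", {
  set.seed(11)
  x <- sort(runif(200, 0, 3000))
  expect_true(all(diff(ais_code(band_for_hic(x))) >= 0))
  y <- sort(runif(200, 0, 4))
  expect_true(all(diff(ais_code(band_for_cti(y))) >= 0))
})

test_that("AIS band and ordinal code are a consistent bijection", {
  b <- ais_band(1:5)
  expect_equal(as.character(b), c("0-1", "2", "3", "4", "5-6"))
  expect_equal(ais_code(b), 1:5)
  expect_true(is.ordered(b))
  expect_error(ais_band(0), "1..5")
  expect_error(ais_band(6), "1..5")
})

test_that("logistic risk curves recover their midpoints as 50% thresholds", {
  mids <- c(250, 750, 1250, 1750)
  curves <- make_logistic_risk_curves(mids, slopes = 0.01)
  tab <- thresholds_from_risk_curves(curves, "HIC", interval = c(0, 4000))
  expect_equal(tab$bounds, mids, tolerance = 1e-5)
})

test_that("a step risk curve is thresholded at its jump", {
  step_at <- function(x0) function(x) as.numeric(x >= x0)
  curves <- list(
    `2` = step_at(100), `3` = step_at(200),
    `4` = step_at(300), `5` = step_at(400)
  )
  tab <- thresholds_from_risk_curves(curves, "toy", interval = c(0, 1000))
  expect_equal(tab$bounds, c(100, 200, 300, 400), tolerance = 1e-4)
})

test_that("mis-ordered or crossing risk curves are rejected", {
  crossed <- make_logistic_risk_curves(c(250, 750, 1250, 1750), 0.01)
  crossed[[2]] <- crossed[[4]]  # AIS>=3 curve now sits above AIS>=4
  expect_error(
    thresholds_from_risk_curves(crossed, interval = c(0, 4000)),
    "mis-ordered"
  )
  flat <- make_logistic_risk_curves(c(250, 750, 1250, 1750), 0.01)
  flat[[1]] <- function(x) rep(0.2, length(x))
  expect_error(
    thresholds_from_risk_curves(flat, interval = c(0, 4000)),
    "no 0.5 crossing"
  )
})

test_that("curve-derived thresholds classify like thresholding the curves", {
  curves <- make_logistic_risk_curves(c(0.8, 1.15, 1.39, 2.16), slopes = 8)
  tab <- thresholds_from_risk_curves(curves, "CTI", interval = c(0, 10))
  set.seed(5)
  x <- runif(200, 0, 4)
  via_table <- ais_code(band_for_cti(x, tab))
  via_curves <- 1L + vapply(
    x, function(v) sum(vapply(curves, function(f) f(v) >= 0.5, logical(1))),
    integer(1)
  )
  expect_equal(via_table, via_curves)
})
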