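test_that("constant-pulse HIC matches the closed form a^2.5 * T", {
  t <- seq(0, 0.010, by = 1e-4)
  h <- compute_hic(t, rep(50, length(t)))
  expect_equal(h$hic, 50^2.5 * 0.010, tolerance = 1e-10)
  expect_equal(h$hic, 176.78, tolerance = 1e-4)
  # constant trace: the best window is the whole (sub-cap) pulse
  expect_equal(h$t1, 0)
  expect_equal(h$t2, 0.010)
})

test_that("an all-zero trace has HIC 0", {
  t <- seq(0, 0.05, by = 1e-3)
  expect_equal(compute_hic(t, rep(0, length(t)))$hic, 0)
})

test_that("compute_hic equals the exhaustive-window oracle on random traces", {
  set.seed(421)
  for (rep in 1:40) {
    n <- sample(30:300, 1)
    tr <- random_trace(n, dt = sample(c(5e-4, 1e-3, 2e-3), 1))
    got <- compute_hic(tr$times, tr$accel)
    want <- hic_oracle(tr$times, tr$accel)
    expect_equal(got$hic, want$hic, tolerance = 1e-12)
    expect_identical(c(got$t1, got$t2), c(want$t1, want$t2))
  }
  # a couple of long traces near the size bound
  for (n in c(1500, 2000)) {
    tr <- random_trace(n, dt = 1e-4)
    got <- compute_hic(tr$times, tr$accel)
    want <- hic_oracle(tr$times, tr$accel)
    expect_equal(got$hic, want$hic, tolerance = 1e-12)
  }
})

test_that("scaling acceleration by k scales HIC by k^2.5 with the same window", {
  set.seed(77)
  for (rep in 1:20) {
    tr <- random_trace(200, dt = 1e-3)
    k <- runif(1, 0.3, 4)
    base <- compute_hic(tr$times, tr$accel)
    scaled <- compute_hic(tr$times, k * tr$accel)
    expect_equal(scaled$hic, k^2.5 * base$hic, tolerance = 1e-12)
    expect_identical(c(scaled$t1, scaled$t2), c(base$t1, base$t2))
  }
})

test_that("a wider window cap can only increase HIC", {
  set.seed(9)
  for (rep in 1:20) {
    tr <- random_trace(150, dt = 1e-3)
    expect_gte(
      compute_hic(tr$times, tr$accel, max_window = 0.036)$hic,
      compute_hic(tr$times, tr$accel, max_window = 0.015)$hic
    )
  }
})

test_that("compute_hic rejects malformed traces", {
  expect_error(compute_hic(numeric(0), numeric(0)), "empty")
  expect_error(compute_hic(0.1, 5), "at least 2")
  expect_error(compute_hic(c(0, 0.001, 0.003), c(1, 2, 3)), "uniform")
})

test_that("CTI is the two-term normalized sum", {
  expect_equal(compute_cti(42.5, 51)$cti, 1.0)
  expect_equal(compute_cti(85, 102)$cti, 2.0)
  expect_equal(compute_cti(0, 0)$cti, 0)
  expect_error(compute_cti(10, 10, a_int = 0), "positive")
  expect_error(compute_cti(-1, 10), "non-negative")
})

test_that("CTI is additive in its two load paths", {
  set.seed(3)
  for (rep in 1:25) {
    a <- runif(1, 0, 120)
    d <- runif(1, 0, 150)
    expect_equal(
      compute_cti(a, d)$cti,
      compute_cti(a, 0)$cti + compute_cti(0, d)$cti,
      tolerance = 1e-12
    )
  }
})

test_that("extract_peaks matches a naive linear scan of the traces", {
  pulse <- generate_vehicle_pulse(56)
  resp <- simulate_occupant(pulse, belted = TRUE, deploy_time = 20)
  pk <- extract_peaks(resp)
  naive_a <- -Inf
  naive_d <- -Inf
  for (i in seq_along(resp$times)) {
    if (resp$chest_accel[i] > naive_a) naive_a <- resp$chest_accel[i]
    if (resp$chest_defl[i] > naive_d) naive_d <- resp$chest_defl[i]
  }
  expect_identical(pk$a_max, naive_a)
  expect_identical(pk$d_max, naive_d)

  toy <- structure(
    list(times = c(0, 1, 2) * 1e-3, head_accel = c(0, 0, 0),
         chest_accel = c(0, 10, 5), chest_defl = c(0, 20, 40)),
    class = "occupant_response"
  )
  expect_equal(extract_peaks(toy), list(a_max = 10, d_max = 40))
})
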