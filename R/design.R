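#' Full-factorial crash simulation design
#'
#' Crosses collision speed, airbag deployment time and belt state into
#' the simulation experiment design. The defaults are the study levels —
#' six speeds (30, 40, 50, 56, 70, 80 km/h), seven deployment times
#' (2, 5, 10, 20, 30, 40, 50 ms) and belted/unbelted — whose full cross
#' gives the 84 simulated conditions.
#'
#' @param speeds Collision speeds (= delta-v for a full-frontal
#'   rigid-wall impact), km/h. No duplicates.
#' @param deploy_times Airbag deployment delays, ms. No duplicates.
#' @param belt_states Logical belt states. No duplicates.
#' @return A data frame of class `experiment_design` with columns
#'   `delta_v` (km/h), `belted` (logical), `deploy_time` (ms), in
#'   deterministic lexicographic order (speed slowest-varying).
#' @examples
#' nrow(build_design())  # 84
#' @export
build_design <- function(speeds = c(30, 40, 50, 56, 70, 80),
                         deploy_times = c(2, 5, 10, 20, 30, 40, 50),
                         belt_states = c(TRUE, FALSE)) {
  if (length(speeds) == 0L || length(deploy_times) == 0L ||
      length(belt_states) == 0L) {
    stop("all factor level lists must be non-empty")
  }
  if (anyDuplicated(speeds) || anyDuplicated(deploy_times) ||
      anyDuplicated(belt_states)) {
    stop("duplicate levels within a factor")
  }
  if (any(speeds <= 0) || any(deploy_times < 0)) {
    stop("speeds must be positive and deployment times non-negative")
  }
  grid <- expand.grid(
    belted = belt_states,
    deploy_time = sort(deploy_times),
    delta_v = sort(speeds),
    KEEP.OUT.ATTRS = FALSE
  )[, c("delta_v", "belted", "deploy_time")]
  grid <- grid[order(grid$delta_v, grid$deploy_time, -grid$belted), ]
  rownames(grid) <- NULL
  class(grid) <- c("experiment_design", "data.frame")
  grid
}

#' Simulate the design and label it with injury criteria and AIS bands
#'
#' Runs the occupant surrogate for every design condition, computes
#' HIC36 and CTI, and assigns head and chest AIS bands from the default
#' (or supplied) band tables. This is the labeled dataset the injury
#' prediction network is trained on. The computation is deterministic;
#' `seed` is consumed so that any stochastic extension (e.g. trace
#' noise) stays reproducible under the same contract.
#'
#' @param design An `experiment_design` (or data frame with columns
#'   `delta_v`, `belted`, `deploy_time`).
#' @param params Surrogate parameters, see [default_surrogate_params()].
#' @param seed Integer seed.
#' @param duration Pulse duration, s.
#' @param dt Pulse sampling step, s. The 0.1 ms default keeps HIC
#'   grid-insensitive to within about 1%.
#' @param max_window HIC window cap, s.
#' @param a_int,d_int CTI intercepts.
#' @param hic_table,cti_table Band tables for head and chest.
#' @return A data frame with one row per condition: the condition
#'   columns, `hic36`, `cti`, `a_max_g`, `d_max_mm`, and the ordinal
#'   codes `head_ais`, `chest_ais` (1..5).
#' @export
generate_training_set <- function(design = build_design(),
                                  params = default_surrogate_params(),
                                  seed = 1L,
                                  duration = 0.1,
                                  dt = 1e-4,
                                  max_window = 0.036,
                                  a_int = 85, d_int = 102,
                                  hic_table = hic_band_table(),
                                  cti_table = cti_band_table()) {
  stopifnot(is.data.frame(design))
  required <- c("delta_v", "belted", "deploy_time")
  if (!all(required %in% names(design))) {
    stop("design must have columns delta_v, belted, deploy_time")
  }
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    cond <- design[i, ]
    res <- tryCatch(
      {
        pulse <- generate_vehicle_pulse(
          cond$delta_v, duration = duration,
          n_samples = round(duration / dt) + 1L
        )
        resp <- simulate_occupant(
          pulse, belted = cond$belted, deploy_time = cond$deploy_time,
          params = params
        )
        compute_injury_criteria(resp, max_window, a_int, d_int)
      },
      error = function(e) {
        stop(sprintf(
          "surrogate failed at condition %d (delta-v %.1f, %s, %s ms): %s",
          i, cond$delta_v, if (cond$belted) "belted" else "unbelted",
          format(cond$deploy_time), conditionMessage(e)
        ), call. = FALSE)
      }
    )
    cbind(cond, res)
  })
  out <- do.call(rbind, rows)
  out$head_ais <- ais_code(band_for_hic(out$hic36, hic_table))
  out$chest_ais <- ais_code(band_for_cti(out$cti, cti_table))
  rownames(out) <- NULL
  out
}

#' Generate synthetic EDR validation cases
#'
#' Draws crash conditions from distributions representative of real
#' frontal-crash event-data-recorder records: delta-v lognormal over
#' roughly 10-80 km/h, deployment time with a 1 ms minimum and a 22 ms
#' mean, and a Bernoulli belt state. The "observed" head and chest AIS
#' come from the surrogate chain (simulate, criteria, banding) and are
#' then perturbed: with probability `noise`, independently per body
#' region, the band is shifted by one level (direction random, forced
#' inward at the scale ends so a perturbation always changes the label).
#'
#' @param n Number of cases (>= 1).
#' @param noise Per-region label perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param params Surrogate parameters.
#' @param belt_rate Probability a case is belted.
#' @param duration Pulse duration, s.
#' @param dt Pulse sampling step, s.
#' @return A data frame with columns `case_id`, `delta_v`, `belted`,
#'   `deploy_time`, `head_ais`, `chest_ais` (observed, possibly
#'   perturbed), plus `true_head_ais` and `true_chest_ais` from the
#'   unperturbed surrogate chain.
#' @export
generate_edr_cases <- function(n, noise = 0.25, seed = 1L,
                               params = default_surrogate_params(),
                               belt_rate = 0.75,
                               duration = 0.1, dt = 1e-4) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    stop("`noise` must be in [0, 1]")
  }
  set.seed(as.integer(seed))
  delta_v <- pmin(pmax(rlnorm(n, meanlog = log(35), sdlog = 0.4), 10), 80)
  deploy_time <- pmin(1 + rgamma(n, shape = 2, scale = 10.5), 60)
  belted <- runif(n) < belt_rate

  conds <- data.frame(
    delta_v = delta_v, belted = belted, deploy_time = deploy_time
  )
  labeled <- generate_training_set(
    conds, params = params, seed = as.integer(seed) + 1L,
    duration = duration, dt = dt
  )
  # restore the RNG stream for the perturbation draws
  set.seed(as.integer(seed))
  invisible(runif(3L * n))

  perturb <- function(code) {
    hit <- runif(length(code)) < noise
    dir <- ifelse(runif(length(code)) < 0.5, -1L, 1L)
    dir[code == 1L] <- 1L   # forced inward at the scale ends
    dir[code == 5L] <- -1L
    ifelse(hit, code + dir, code)
  }
  head_obs <- perturb(labeled$head_ais)
  chest_obs <- perturb(labeled$chest_ais)

  data.frame(
    case_id = sprintf("case_%03d", seq_len(n)),
    delta_v = delta_v,
    belted = belted,
    deploy_time = deploy_time,
    head_ais = head_obs,
    chest_ais = chest_obs,
    true_head_ais = labeled$head_ais,
    true_chest_ais = labeled$chest_ais
  )
}
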