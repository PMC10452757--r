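#' Default lumped-parameter occupant restraint model
#'
#' Parameters of the single-mass occupant surrogate used by
#' [simulate_occupant()]. The occupant is a point mass coupled to the
#' decelerating cabin through up to three one-sided spring-damper
#' elements: the seatbelt (engages from t = 0 when worn, after a small
#' film slack), the airbag (engages only once deployed *and* once the
#' occupant has closed the bag standoff gap), and hard interior contact
#' (steering wheel / dashboard, reached only after a long forward
#' excursion, typically by unrestrained occupants).
#'
#' Head and chest accelerations are weighted combinations of the three
#' restraint forces: the belt loads the torso more than the head, while
#' the airbag and interior contact load the head more — which is why a
#' late-deploying airbag penalizes the Head Injury Criterion more than
#' the Combined Thoracic Index. Chest deflection is the chest-borne
#' restraint force divided by a linear thoracic stiffness.
#'
#' @return A named list of surrogate parameters:
#' \describe{
#'   \item{mass}{occupant effective mass, kg}
#'   \item{k_belt, c_belt, belt_slack}{belt stiffness (N/m), damping
#'     (N s/m) and film slack (m)}
#'   \item{k_airbag, c_airbag, airbag_gap}{airbag stiffness, damping and
#'     standoff gap (m)}
#'   \item{k_contact, c_contact, contact_dist}{interior-contact stiffness,
#'     damping and free-flight distance to the interior (m)}
#'   \item{w_head, w_chest}{length-3 weights (belt, airbag, contact)
#'     distributing each restraint force to head and chest acceleration}
#'   \item{chest_stiffness}{thoracic stiffness, N/mm, mapping chest force
#'     to deflection}
#'   \item{tail}{extra integration time after pulse end, s, so that
#'     occupant loading completing after the vehicle has stopped is
#'     captured}
#' }
#' @export
default_surrogate_params <- function() {
  list(
    mass = 75,
    k_belt = 110e3, c_belt = 1.5e3, belt_slack = 0.02,
    k_airbag = 40e3, c_airbag = 1.5e3, airbag_gap = 0.04,
    k_contact = 900e3, c_contact = 4.0e3, contact_dist = 0.22,
    w_head = c(belt = 1.00, airbag = 1.80, contact = 2.20),
    w_chest = c(belt = 1.00, airbag = 1.00, contact = 1.30),
    chest_stiffness = 500,
    tail = 0.10
  )
}

# one-sided spring-damper restraint forces at state (x, v) and time t;
# forces only resist forward excursion (never pull the occupant forward)
restraint_forces <- function(x, v, t, belted, t_deploy, p) {
  fb <- 0
  if (belted && x > p$belt_slack) {
    fb <- max(0, p$k_belt * (x - p$belt_slack) + p$c_belt * v)
  }
  fa <- 0
  if (t >= t_deploy && x > p$airbag_gap) {
    fa <- max(0, p$k_airbag * (x - p$airbag_gap) + p$c_airbag * v)
  }
  fc <- 0
  if (x > p$contact_dist) {
    fc <- max(0, p$k_contact * (x - p$contact_dist) + p$c_contact * v)
  }
  c(fb, fa, fc)
}

#' Simulate the occupant response to a crash pulse
#'
#' Integrates a single-mass occupant coupled to the decelerating vehicle
#' of a [generate_vehicle_pulse()] pulse, in the cabin frame, with
#' fixed-step fourth-order Runge-Kutta at the pulse sampling step. Before
#' any restraint engages the occupant is in free flight relative to the
#' cabin and accumulates forward velocity; the belt (when worn) couples
#' from t = 0, the airbag only from the deployment time onward, and hard
#' interior contact catches occupants that travel far enough forward.
#' Integration continues for a short tail beyond the pulse so that
#' occupant loading that completes after the vehicle has stopped is
#' captured.
#'
#' @param pulse A `vehicle_pulse` object.
#' @param belted Logical: is the occupant belted?
#' @param deploy_time Airbag deployment delay in milliseconds (from first
#'   impact). A value beyond the pulse duration raises a warning and the
#'   airbag never engages (the undeployed worst case).
#' @param params Surrogate parameter list, see [default_surrogate_params()].
#'
#' @return An object of class `occupant_response`: a list with the shared
#'   time grid `times` (s) and traces `head_accel` (g), `chest_accel` (g)
#'   and `chest_defl` (mm), all non-negative, plus the `condition` fields
#'   used.
#'
#' @examples
#' pulse <- generate_vehicle_pulse(56, duration = 0.1)
#' resp <- simulate_occupant(pulse, belted = TRUE, deploy_time = 20)
#' max(resp$head_accel)
#' @export
simulate_occupant <- function(pulse, belted, deploy_time,
                              params = default_surrogate_params()) {
  stopifnot(inherits(pulse, "vehicle_pulse"))
  if (!is.logical(belted) || length(belted) != 1L || is.na(belted)) {
    stop("`belted` must be TRUE or FALSE")
  }
  if (!is.numeric(deploy_time) || length(deploy_time) != 1L || deploy_time < 0) {
    stop("`deploy_time` must be a single non-negative number (ms)")
  }
  if (any(unlist(params[c(
    "mass", "k_belt", "k_airbag", "k_contact", "chest_stiffness"
  )]) <= 0)) {
    stop("surrogate stiffness and mass parameters must be positive")
  }
  t_deploy <- deploy_time / 1000
  if (t_deploy > pulse$duration) {
    warning(
      "deploy_time exceeds the pulse duration; airbag never engages",
      call. = FALSE
    )
    t_deploy <- Inf
  }

  dt <- pulse$times[2L] - pulse$times[1L]
  n_tail <- ceiling(params$tail / dt)
  times <- seq(0, by = dt, length.out = length(pulse$times) + n_tail)
  # cabin deceleration, zero after the pulse ends
  av <- c(pulse$decel, rep(0, n_tail))
  av_at <- function(t) {
    # linear interpolation on the uniform grid
    if (t >= times[length(times)]) return(0)
    i <- floor(t / dt)
    w <- t / dt - i
    (1 - w) * av[i + 1L] + w * av[min(i + 2L, length(av))]
  }

  p <- params
  m <- p$mass
  deriv <- function(t, x, v) {
    f <- restraint_forces(x, v, t, belted, t_deploy, p)
    c(v, av_at(t) - sum(f) / m)
  }

  n <- length(times)
  xs <- numeric(n)
  vs <- numeric(n)
  x <- 0
  v <- 0
  for (i in seq_len(n - 1L)) {
    t <- times[i]
    k1 <- deriv(t, x, v)
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1[1L], v + dt / 2 * k1[2L])
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2[1L], v + dt / 2 * k2[2L])
    k4 <- deriv(t + dt, x + dt * k3[1L], v + dt * k3[2L])
    x <- x + dt / 6 * (k1[1L] + 2 * k2[1L] + 2 * k3[1L] + k4[1L])
    v <- v + dt / 6 * (k1[2L] + 2 * k2[2L] + 2 * k3[2L] + k4[2L])
    xs[i + 1L] <- x
    vs[i + 1L] <- v
  }

  g0 <- 9.80665
  head <- numeric(n)
  chest <- numeric(n)
  defl <- numeric(n)
  for (i in seq_len(n)) {
    f <- restraint_forces(xs[i], vs[i], times[i], belted, t_deploy, p)
    head[i] <- sum(p$w_head * f) / (m * g0)
    chest_force <- sum(p$w_chest * f)
    chest[i] <- chest_force / (m * g0)
    defl[i] <- chest_force / p$chest_stiffness  # N / (N/mm) -> mm
  }

  structure(
    list(
      times = times,
      head_accel = pmax(head, 0),
      chest_accel = pmax(chest, 0),
      chest_defl = pmax(defl, 0),
      condition = list(
        delta_v = pulse$delta_v, belted = belted, deploy_time = deploy_time
      )
    ),
    class = "occupant_response"
  )
}

#' @export
print.occupant_response <- function(x, ...) {
  cat(sprintf(
    "<occupant_response> delta-v %.1f km/h, %s, airbag %s ms: peak head %.1f g, peak chest defl %.1f mm\n",
    x$condition$delta_v,
    if (x$condition$belted) "belted" else "unbelted",
    format(x$condition$deploy_time),
    max(x$head_accel), max(x$chest_defl)
  ))
  invisible(x)
}
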