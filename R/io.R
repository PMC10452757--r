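# File-format plumbing: CSV traces/conditions/EDR tables, YAML
# configuration, JSON model and report serialization. CSV dialect:
# comma-separated, UTF-8, '.' decimal, mandatory header, belt encoded 0/1.

#' Read and write occupant response traces
#'
#' Trace CSV columns: `time_s`, `head_accel_g`, `chest_accel_g`,
#' `chest_defl_mm`, header mandatory. Units are enforced here:
#' acceleration in g, time in seconds — the convention the Head Injury
#' Criterion expects. No frequency-class filtering is applied; `filter`
#' is a hook taking and returning the trace data frame.
#'
#' @param path File path.
#' @param filter Optional function applied to the trace data frame after
#'   reading (e.g. a CFC filter); default identity.
#' @return `read_trace_csv()`: an `occupant_response`.
#' @export
read_trace_csv <- function(path, filter = identity) {
  df <- utils::read.csv(path)
  required <- c("time_s", "head_accel_g", "chest_accel_g", "chest_defl_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("trace CSV missing column(s): %s", paste(missing, collapse = ", ")))
  }
  df <- filter(df)
  structure(
    list(
      times = df$time_s,
      head_accel = df$head_accel_g,
      chest_accel = df$chest_accel_g,
      chest_defl = df$chest_defl_mm,
      condition = NULL
    ),
    class = "occupant_response"
  )
}

#' @rdname read_trace_csv
#' @param response An `occupant_response` to write.
#' @export
write_trace_csv <- function(response, path) {
  stopifnot(inherits(response, "occupant_response"))
  utils::write.csv(
    data.frame(
      time_s = response$times,
      head_accel_g = response$head_accel,
      chest_accel_g = response$chest_accel,
      chest_defl_mm = response$chest_defl
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read and write crash-condition tables
#'
#' Condition CSV columns: `delta_v_kmh`, `belted` (0/1),
#' `deploy_time_ms`. EDR CSV adds `case_id`, `head_ais`, `chest_ais`.
#'
#' @param path File path.
#' @return A data frame with columns `delta_v`, `belted` (logical),
#'   `deploy_time` (and, for EDR files, `case_id`, `head_ais`,
#'   `chest_ais`).
#' @export
read_conditions_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("delta_v_kmh", "belted", "deploy_time_ms")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("condition CSV missing column(s): %s", paste(missing, collapse = ", ")))
  }
  data.frame(
    delta_v = df$delta_v_kmh,
    belted = df$belted != 0,
    deploy_time = df$deploy_time_ms
  )
}

#' @rdname read_conditions_csv
#' @param conditions Data frame with `delta_v`, `belted`, `deploy_time`.
#' @export
write_conditions_csv <- function(conditions, path) {
  utils::write.csv(
    data.frame(
      delta_v_kmh = conditions$delta_v,
      belted = as.integer(conditions$belted),
      deploy_time_ms = conditions$deploy_time
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname read_conditions_csv
#' @export
read_edr_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("case_id", "delta_v_kmh", "belted", "deploy_time_ms",
                "head_ais", "chest_ais")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("EDR CSV missing column(s): %s", paste(missing, collapse = ", ")))
  }
  data.frame(
    case_id = df$case_id,
    delta_v = df$delta_v_kmh,
    belted = df$belted != 0,
    deploy_time = df$deploy_time_ms,
    head_ais = as.integer(df$head_ais),
    chest_ais = as.integer(df$chest_ais)
  )
}

#' @rdname read_conditions_csv
#' @param edr Data frame of EDR records.
#' @export
write_edr_csv <- function(edr, path) {
  utils::write.csv(
    data.frame(
      case_id = edr$case_id,
      delta_v_kmh = edr$delta_v,
      belted = as.integer(edr$belted),
      deploy_time_ms = edr$deploy_time,
      head_ais = edr$head_ais,
      chest_ais = edr$chest_ais
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Serialize and restore a trained network
#'
#' The model is stored as JSON: scaler parameters, weight matrices,
#' biases, config, and the tail of the training log. A JSON round trip
#' restores a model that predicts identically.
#'
#' @param model A trained `ais_net`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ais_net"))
  obj <- list(
    scaler = list(lo = model$scaler$lo, rng = model$scaler$rng),
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    config = unclass(model$config),
    training_log = utils::tail(model$training_log, 20L)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json()`: an `ais_net`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  structure(
    list(
      scaler = list(
        lo = unlist(obj$scaler$lo), rng = unlist(obj$scaler$rng)
      ),
      W1 = matrix(unlist(obj$W1), nrow = 3L),
      b1 = unlist(obj$b1),
      W2 = matrix(unlist(obj$W2), ncol = 2L),
      b2 = unlist(obj$b2),
      config = net_config(
        cfg$n_hidden, cfg$learning_rate, cfg$max_epochs,
        cfg$target_error, cfg$seed
      ),
      training_log = as.data.frame(obj$training_log)
    ),
    class = "ais_net"
  )
}

#' Read and write surrogate parameters as YAML
#'
#' @param path File path.
#' @return `read_surrogate_yaml()`: a surrogate parameter list (see
#'   [default_surrogate_params()]).
#' @export
read_surrogate_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  defaults <- default_surrogate_params()
  missing <- setdiff(names(defaults), names(p))
  if (length(missing)) {
    stop(sprintf("surrogate YAML missing entries: %s", paste(missing, collapse = ", ")))
  }
  p$w_head <- unlist(p$w_head)[c("belt", "airbag", "contact")]
  p$w_chest <- unlist(p$w_chest)[c("belt", "airbag", "contact")]
  p[names(defaults)]
}

#' @rdname read_surrogate_yaml
#' @param params Surrogate parameter list.
#' @export
write_surrogate_yaml <- function(params, path) {
  params$w_head <- as.list(params$w_head)
  params$w_chest <- as.list(params$w_chest)
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Read and write AIS band tables as YAML
#'
#' YAML fields: `metric`, `bounds` (4 ascending upper bounds), `labels`.
#'
#' @param path File path.
#' @return `read_band_table_yaml()`: a `band_table`.
#' @export
read_band_table_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  tab <- new_band_table(obj$metric, as.numeric(unlist(obj$bounds)))
  if (!is.null(obj$labels) &&
      !identical(as.character(unlist(obj$labels)), tab$labels)) {
    stop("band table labels must be 0-1, 2, 3, 4, 5-6")
  }
  tab
}

#' @rdname read_band_table_yaml
#' @param table A `band_table`.
#' @export
write_band_table_yaml <- function(table, path) {
  stopifnot(inherits(table, "band_table"))
  yaml::write_yaml(
    list(metric = table$metric, bounds = table$bounds, labels = table$labels),
    path
  )
  invisible(path)
}
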