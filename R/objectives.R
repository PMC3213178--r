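#' Min-max scaling of an intensity series
#'
#' Rescales a vector so its lowest value equals zero and its highest
#' equals one, mimicking relative immunoblot band intensities. A constant
#' series maps to all zeros (a flat basal control carries no shape
#' information). The scaling is invariant to positive affine transforms of
#' the input, which is what lets raw blot intensities from different
#' sources be compared.
#'
#' @param v numeric vector (nonempty)
#' @return scaled vector in `[0, 1]`
#' @export
minmax_scale <- function(v) {
  if (!length(v)) abort("cannot scale an empty series")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Define a training objective
#'
#' One objective is one experimental data set: a readout (one or more model
#' species whose sum stands for a blot band), a condition (protocol name,
#' or several protocol names for a condition-comparison bar set), and the
#' measured series. Raw intensities are in arbitrary units; scoring scales
#' them (and the simulation) to `[0, 1]` before comparison.
#'
#' @param objective_id short id, e.g. `"O3"`
#' @param readout character vector of species ids; the simulated readout is
#'   their sum
#' @param protocol protocol name (time-course objective) or vector of
#'   protocol names (bar-set objective comparing conditions at one time)
#' @param times measurement times (minutes); a single time for bar sets
#' @param values raw measured intensities, one per time (time course) or
#'   one per protocol (bar set)
#' @param kind `"timecourse"` or `"bars"`
#' @return an `objective_series`
#' @export
objective_series <- function(objective_id, readout, protocol, times, values,
                             kind = c("timecourse", "bars")) {
  kind <- match.arg(kind)
  if (kind == "timecourse") {
    stopifnot(length(protocol) == 1, length(times) == length(values),
              length(times) >= 2)
  } else {
    stopifnot(length(times) == 1, length(values) == length(protocol),
              length(protocol) >= 2)
  }
  structure(list(objective_id = objective_id, readout = readout,
                 protocol = protocol, times = times, values = values,
                 kind = kind),
            class = "objective_series")
}

readout_values <- function(traj, readout, times) {
  missing_sp <- setdiff(readout, colnames(traj$states))
  if (length(missing_sp)) {
    abort(paste0("readout species absent from model: ",
                 paste(missing_sp, collapse = ", ")))
  }
  y <- rowSums(traj$states[, readout, drop = FALSE])
  if (any(times < min(traj$times) | times > max(traj$times))) {
    abort("objective times outside the simulated horizon")
  }
  approx(traj$times, y, xout = times)$y
}

#' Scaled squared error of one objective
#'
#' Measurement and simulated readout are min-max scaled independently,
#' then compared by the sum of squared differences over the objective's
#' time points (or condition bars). The score is therefore sensitive to the
#' shape of the response, not its absolute scale.
#'
#' @param series an [objective_series()]
#' @param trajectories a single `trajectory` (time-course objective) or a
#'   named list of trajectories keyed by protocol name (bar set)
#' @return list with `objective_id`, `squared_error`, `scaled_sim`,
#'   `scaled_data`
#' @export
scaled_error <- function(series, trajectories) {
  if (series$kind == "timecourse") {
    traj <- if (inherits(trajectories, "trajectory")) trajectories
            else trajectories[[series$protocol]]
    sim <- readout_values(traj, series$readout, series$times)
  } else {
    if (inherits(trajectories, "trajectory")) {
      abort("bar-set objective needs one trajectory per protocol")
    }
    sim <- vapply(series$protocol, function(p) {
      readout_values(trajectories[[p]], series$readout, series$times)
    }, numeric(1))
  }
  sd_ <- minmax_scale(series$values)
  ss_ <- minmax_scale(sim)
  list(objective_id = series$objective_id,
       squared_error = sum((sd_ - ss_)^2),
       scaled_sim = ss_, scaled_data = sd_)
}

#' Evaluate all objectives for one parameter set
#'
#' Simulates each unique protocol once (shared conditions are cached) and
#' scores every objective. A protocol whose simulation fails flags the
#' dependent objectives with `Inf` instead of aborting the run.
#'
#' @param net an irreversible `rxn_network`
#' @param params a `param_vec`
#' @param objectives list of [objective_series()]
#' @param protocols named list of [stim_protocol()] covering every protocol
#'   name used by the objectives
#' @param t_step simulation output grid spacing (minutes)
#' @param ... passed to [simulate_protocol()]
#' @return named numeric vector of squared errors, one per objective
#' @export
evaluate_objectives <- function(net, params, objectives, protocols,
                                t_step = 1, ...) {
  needed <- unique(unlist(lapply(objectives, `[[`, "protocol")))
  missing_p <- setdiff(needed, names(protocols))
  if (length(missing_p)) {
    abort(paste0("objectives reference undefined protocols: ",
                 paste(missing_p, collapse = ", ")))
  }
  cache <- new.env(parent = emptyenv())
  sims <- lapply(setNames(needed, needed), function(p) {
    tryCatch(simulate_protocol(net, params, protocols[[p]],
                               t_step = t_step, ss_cache = cache, ...),
             error = function(e) e)
  })
  errs <- vapply(objectives, function(ob) {
    used <- sims[ob$protocol]
    if (any(vapply(used, inherits, logical(1), "error"))) return(Inf)
    tryCatch(scaled_error(ob, used)$squared_error,
             error = function(e) {
               if (grepl("absent from model", conditionMessage(e))) stop(e)
               Inf
             })
  }, numeric(1))
  setNames(errs, vapply(objectives, `[[`, character(1), "objective_id"))
}
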