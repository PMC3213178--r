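#' Stimulus protocols
#'
#' A protocol describes one simulated experiment: optional structural
#' perturbations (species knockdowns, zeroed reaction rates emulating
#' small-molecule inhibitors), a pre-equilibration to steady state, and a
#' stimulus issued at time 0 by *adding* an amount of the stimulus species
#' to its steady-state level (the ligand is then consumed by mass action,
#' not clamped). Time is in minutes; the default observation horizon is
#' 100 min.
#'
#' @param stimulus_species character vector of species ids receiving the
#'   stimulus (may be empty for an unstimulated control)
#' @param stimulus_amount amount added to each stimulus species at time 0
#' @param horizon simulation length after the stimulus (minutes)
#' @param knockdowns species ids to knock down (see [knockdown()])
#' @param zero_rates reaction ids whose rate constants are set to 0
#'   (inhibitor analogue)
#' @param equilibrate run to steady state before the stimulus (the default
#'   experimental design); `FALSE` starts directly from the initial
#'   conditions
#' @param label protocol label carried into trajectories
#' @return a `stim_protocol` object
#' @export
stim_protocol <- function(stimulus_species = character(0),
                          stimulus_amount = 1,
                          horizon = 100,
                          knockdowns = character(0),
                          zero_rates = character(0),
                          equilibrate = TRUE,
                          label = "protocol") {
  stopifnot(horizon > 0, stimulus_amount >= 0)
  structure(list(stimulus_species = stimulus_species,
                 stimulus_amount = stimulus_amount,
                 horizon = horizon,
                 knockdowns = knockdowns,
                 zero_rates = zero_rates,
                 equilibrate = equilibrate,
                 label = label),
            class = "stim_protocol")
}

new_trajectory <- function(times, states, label) {
  stopifnot(all(diff(times) > 0))
  structure(list(times = times, states = states, protocol_label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> '", x$protocol_label, "': ", length(x$times),
      " time points x ", ncol(x$states), " species, t in [",
      min(x$times), ", ", max(x$times), "] min\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into long form
#'
#' @param x a `trajectory`
#' @param ... unused
#' @return a tibble with columns `time`, `species`, `value`, `protocol`
#' @export
tidy.trajectory <- function(x, ...) {
  tibble(time = rep(x$times, times = ncol(x$states)),
         species = rep(colnames(x$states), each = length(x$times)),
         value = as.vector(x$states),
         protocol = x$protocol_label)
}

# Low-level stiff integration with the analytical Jacobian. Returns the
# deSolve matrix (time column + species columns). States are guarded with
# pmax(., 0) inside the right-hand side so solver probe points fractionally
# below zero cannot poison the mass-action monomials.
integrate_raw <- function(net, k, x0, times, rtol = 1e-6, atol = 1e-9) {
  cp <- net$compiled
  k <- as.numeric(k)
  func <- function(t, y, p) {
    list(.ma_rhs(pmax(y, 0), k, cp$S, cp$ri, cp$rj, cp$re))
  }
  jacfunc <- function(t, y, p) {
    .ma_jac_dfdk(pmax(y, 0), k, cp$S, cp$ri, cp$rj, cp$re, TRUE, FALSE)[["J"]]
  }
  out <- deSolve::lsoda(y = as.numeric(x0), times = times, func = func,
                        parms = NULL, jacfunc = jacfunc, jactype = "fullusr",
                        rtol = rtol, atol = atol)
  if (nrow(out) < length(times)) {
    abort(paste0("integration failed at t = ", max(out[, 1]),
                 " (of ", max(times), ")"))
  }
  out
}

#' Integrate the network ODEs on a time grid
#'
#' Solves `dx/dt = S r(x, k)` with a stiff solver (lsoda) using the
#' analytical Jacobian. Tiny negative excursions (within solver tolerance)
#' are clipped to 0 in the returned trajectory.
#'
#' @param net an irreversible `rxn_network`
#' @param params a `param_vec` (rates + initial conditions); initial
#'   conditions may be overridden with `x0`
#' @param t_grid strictly increasing times (minutes), starting at 0
#' @param x0 optional starting state (defaults to `params$x0`)
#' @param rtol,atol relative/absolute integration tolerances
#' @param label protocol label for the trajectory
#' @return a `trajectory`
#' @export
integrate_network <- function(net, params, t_grid, x0 = NULL,
                              rtol = 1e-6, atol = 1e-9, label = "free") {
  check_irreversible(net)
  validate_params(params, net)
  if (is.null(x0)) x0 <- params$x0
  out <- integrate_raw(net, params$k, x0, t_grid, rtol, atol)
  states <- out[, -1, drop = FALSE]
  colnames(states) <- net$species$id
  if (min(states) < -1e-5) {
    warn(paste0("trajectory dipped to ", signif(min(states), 3),
                "; clipped to 0"))
  }
  tr <- new_trajectory(out[, 1], pmax(states, 0), label)
  attr(tr, "min_raw") <- min(states)
  tr
}

#' Find the pre-stimulus steady state
#'
#' Integrates the model over successive windows of length `dt` and returns
#' the first state at which the norm of the difference between successive
#' window endpoints drops below `eps` (default 0.001, the tolerance used
#' for all simulations). The comparison norm is Euclidean by default.
#'
#' @inheritParams integrate_network
#' @param eps steady-state tolerance on the between-window state difference
#' @param dt window length (minutes)
#' @param max_windows give up after this many windows
#' @param norm `"l2"` (Euclidean) or `"max"`
#' @return the steady state (named vector) with attributes `windows`
#'   (windows used) and `residual` (the final between-window norm)
#' @export
find_steady_state <- function(net, params, x0 = NULL, eps = 1e-3, dt = 1,
                              max_windows = 1000, norm = c("l2", "max"),
                              rtol = 1e-6, atol = 1e-9) {
  check_irreversible(net)
  validate_params(params, net)
  norm <- match.arg(norm)
  nf <- if (norm == "l2") function(v) sqrt(sum(v^2)) else function(v) max(abs(v))
  x <- as.numeric(if (is.null(x0)) params$x0 else x0)
  windows_done <- 0L
  chunk <- 10L
  last_diff <- NA_real_
  while (windows_done < max_windows) {
    n_win <- min(chunk, max_windows - windows_done)
    chunk <- min(chunk * 2L, 200L)
    out <- integrate_raw(net, params$k, x, seq(0, n_win * dt, by = dt),
                         rtol, atol)
    states <- out[, -1, drop = FALSE]
    for (w in seq_len(n_win)) {
      d <- nf(states[w + 1, ] - states[w, ])
      if (d < eps) {
        ss <- setNames(pmax(states[w + 1, ], 0), net$species$id)
        attr(ss, "windows") <- windows_done + w
        attr(ss, "residual") <- d
        return(ss)
      }
      last_diff <- d
    }
    x <- pmax(states[n_win + 1, ], 0)
    windows_done <- windows_done + n_win
  }
  resid <- abs(network_rhs(net, x, params$k))
  abort(paste0("no steady state within ", max_windows, " windows; largest ",
               "residual species: ", names(which.max(resid)),
               " (|dx/dt| = ", signif(max(resid), 3),
               ", last state change ", signif(last_diff, 3), ")"))
}

#' Simulate a stimulus protocol
#'
#' Applies the protocol's structural perturbations, runs the network to
#' steady state with the stimulus species at basal level, adds the stimulus
#' amount, and records the response over the protocol horizon.
#'
#' @inheritParams integrate_network
#' @param protocol a [stim_protocol()]
#' @param t_step output grid spacing (minutes)
#' @param ss_control list of [find_steady_state()] settings
#'   (`eps`, `dt`, `max_windows`, `norm`)
#' @param ss_cache optional environment caching pre-stimulus steady states
#'   across protocols that share the same structural perturbations (valid
#'   only within one parameter set)
#' @return a `trajectory` over `[0, horizon]`; time 0 is the stimulated
#'   state
#' @export
simulate_protocol <- function(net, params, protocol, t_step = 1,
                              rtol = 1e-6, atol = 1e-9,
                              ss_control = list(), ss_cache = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  validate_params(params, net)
  if (length(protocol$knockdowns)) {
    kd <- knockdown(net, params, protocol$knockdowns)
    net <- kd$net
    params <- kd$params
  }
  if (length(protocol$zero_rates)) {
    missing_r <- setdiff(protocol$zero_rates, names(params$k))
    keep <- intersect(protocol$zero_rates, names(params$k))
    if (length(missing_r) && !length(keep)) {
      abort(paste0("zero_rates reactions not in network: ",
                   paste(missing_r, collapse = ", ")))
    }
    params$k[keep] <- 0
  }
  if (isFALSE(protocol$equilibrate)) {
    ss <- setNames(as.numeric(params$x0), net$species$id)
  } else {
    cache_key <- paste(c(sort(protocol$knockdowns), "|",
                         sort(protocol$zero_rates)), collapse = ",")
    if (!is.null(ss_cache) && !is.null(ss_cache[[cache_key]])) {
      ss <- ss_cache[[cache_key]]
    } else {
      sc <- modifyList(list(eps = 1e-3, dt = 1, max_windows = 1000,
                            norm = "l2"), ss_control)
      ss <- find_steady_state(net, params, eps = sc$eps, dt = sc$dt,
                              max_windows = sc$max_windows, norm = sc$norm,
                              rtol = rtol, atol = atol)
      if (!is.null(ss_cache)) ss_cache[[cache_key]] <- ss
    }
  }
  x_start <- as.numeric(ss)
  stim <- intersect(protocol$stimulus_species, net$species$id)
  if (length(protocol$stimulus_species) && !length(stim) &&
      protocol$stimulus_amount > 0) {
    abort(paste0("stimulus species not in network: ",
                 paste(protocol$stimulus_species, collapse = ", ")))
  }
  if (length(stim)) {
    idx <- match(stim, net$species$id)
    x_start[idx] <- x_start[idx] + protocol$stimulus_amount
  }
  tr <- integrate_network(net, params, seq(0, protocol$horizon, by = t_step),
                          x0 = x_start, rtol = rtol, atol = atol,
                          label = protocol$label)
  attr(tr, "steady_state") <- ss
  attr(tr, "net") <- net
  attr(tr, "params") <- params
  tr
}

#' In-silico knockdown of a species
#'
#' Removes the target node from the stoichiometric matrix: every reaction
#' in which the target participates (as reactant or product) is deleted and
#' the target's initial condition is set to zero. Remaining species and
#' their order are unchanged, so trajectories stay comparable. Removing
#' the reactions (rather than only zeroing the species) prevents the target
#' from being regenerated by synthesis reactions. Idempotent.
#'
#' @param net an irreversible `rxn_network`
#' @param params a matching `param_vec`
#' @param target species id(s) to remove
#' @return list with the perturbed `net` and `params` (rate constants
#'   subset to the surviving reactions)
#' @export
knockdown <- function(net, params, target) {
  check_irreversible(net)
  validate_params(params, net)
  unknown <- setdiff(target, net$species$id)
  if (length(unknown)) {
    abort(paste0("unknown knockdown target: ", paste(unknown, collapse = ", ")))
  }
  touches <- vapply(seq_len(nrow(net$reactions)), function(j) {
    any(target %in% names(net$reactions$reactants[[j]])) ||
      any(target %in% names(net$reactions$products[[j]]))
  }, logical(1))
  species <- net$species
  species$initial_amount[species$id %in% target] <- 0
  net2 <- rxn_network(species, net$reactions[!touches, ])
  params$k <- params$k[net2$reactions$id]
  params$x0[target] <- 0
  list(net = net2, params = params)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj a `trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(tidy(traj)), path, row.names = FALSE)
  invisible(path)
}

#' Plot a trajectory
#'
#' @param object a `trajectory`
#' @param species optional subset of species ids to draw
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.trajectory <- function(object, species = NULL, ...) {
  d <- tidy(object)
  if (!is.null(species)) d <- dplyr::filter(d, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (a.u.)",
                  title = object$protocol_label) +
    ggplot2::theme_minimal()
}
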