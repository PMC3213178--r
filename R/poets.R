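#' Pareto dominance of error vectors
#'
#' `e1` dominates `e2` when it is no worse in every objective and strictly
#' better in at least one.
#'
#' @param e1,e2 numeric error vectors of equal length
#' @return logical
#' @export
dominates <- function(e1, e2) {
  if (length(e1) != length(e2)) abort("error vectors differ in length")
  all(e1 <= e2) && any(e1 < e2)
}

#' Fonseca–Fleming Pareto rank against an archive
#'
#' The rank of a candidate is the number of archived error vectors that
#' dominate it; rank 0 means nondominated. Rank is the fitness driving the
#' annealing acceptance rule.
#'
#' @param e candidate error vector
#' @param archive_errors matrix of archived error vectors (rows = members)
#'   or `NULL`/empty for an empty archive
#' @return integer rank
#' @export
pareto_rank <- function(e, archive_errors) {
  if (is.null(archive_errors) || NROW(archive_errors) == 0) return(0L)
  E <- matrix(archive_errors, ncol = length(e))
  le <- E <= rep(e, each = nrow(E))
  lt <- E < rep(e, each = nrow(E))
  sum(rowSums(le) == ncol(E) & rowSums(lt) > 0L)
}

#' Annealing acceptance probability
#'
#' A candidate with Pareto rank `rank` is accepted with probability
#' `exp(-rank / T)`: nondominated candidates are always accepted, and the
#' tolerance for dominated candidates shrinks as the temperature falls.
#'
#' @param rank nonnegative Pareto rank
#' @param temperature annealing temperature (> 0)
#' @return probability in `(0, 1]`
#' @export
acceptance_probability <- function(rank, temperature) {
  if (temperature <= 0) abort("temperature must be > 0")
  if (rank < 0) abort("rank must be >= 0")
  exp(-rank / temperature)
}

#' Multiplicative random perturbation of a parameter set
#'
#' Each parameter is multiplied by an independent factor drawn uniformly
#' from `[1 - magnitude, 1 + magnitude]`, preserving nonnegativity (and
#' leaving exact zeros at zero). Uses the current R random stream.
#'
#' @param params a `param_vec`
#' @param magnitude perturbation magnitude in `(0, 1)`
#' @param perturb_ics also perturb initial conditions (default `TRUE`)?
#' @return perturbed `param_vec`
#' @export
perturb_params <- function(params, magnitude = 0.25, perturb_ics = TRUE) {
  stopifnot(magnitude >= 0, magnitude < 1)
  params$k <- params$k * runif(length(params$k), 1 - magnitude, 1 + magnitude)
  if (perturb_ics) {
    params$x0 <- params$x0 * runif(length(params$x0), 1 - magnitude,
                                   1 + magnitude)
  }
  params
}

evaluate_single_objective <- function(net, params, objective, protocols,
                                      t_step = 1) {
  sims <- lapply(setNames(objective$protocol, objective$protocol), function(p) {
    tryCatch(simulate_protocol(net, params, protocols[[p]], t_step = t_step),
             error = function(e) e)
  })
  if (any(vapply(sims, inherits, logical(1), "error"))) return(Inf)
  tryCatch(scaled_error(objective, sims)$squared_error,
           error = function(e) Inf)
}

#' Local pattern search on a single objective
#'
#' Coordinate-wise polling: each selected parameter is tried multiplied and
#' divided by `1 + step_frac`; a move is kept only if it lowers the
#' objective's scaled squared error, and the step fraction is halved after
#' a sweep with no improvement. The returned error never exceeds the input
#' error.
#'
#' @param net,protocols model context (see [evaluate_objectives()])
#' @param params starting `param_vec`
#' @param objective the single [objective_series()] to minimize
#' @param steps number of polling sweeps (0 returns the input unchanged)
#' @param step_frac initial multiplicative step
#' @param param_subset indices into the rate-constant vector to poll
#'   (default: all rate constants)
#' @param t_step simulation grid spacing
#' @return list with `params` and achieved `error`
#' @export
pattern_search <- function(net, params, objective, protocols, steps = 1,
                           step_frac = 0.5, param_subset = NULL, t_step = 1) {
  f_cur <- evaluate_single_objective(net, params, objective, protocols, t_step)
  if (steps <= 0) return(list(params = params, error = f_cur))
  if (is.null(param_subset)) param_subset <- seq_along(params$k)
  frac <- step_frac
  for (s in seq_len(steps)) {
    improved <- FALSE
    for (i in param_subset) {
      for (mult in c(1 + frac, 1 / (1 + frac))) {
        trial <- params
        trial$k[i] <- trial$k[i] * mult
        f_t <- evaluate_single_objective(net, trial, objective, protocols,
                                         t_step)
        if (is.finite(f_t) && f_t < f_cur) {
          params <- trial
          f_cur <- f_t
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) frac <- frac / 2
  }
  list(params = params, error = f_cur)
}

#' POETs run configuration
#'
#' Collects the tunable constants of the annealing schedule and search.
#' The schedule's structure is fixed — 10 temperature quanta walked from
#' `t_initial` down to `t_final`, an epoch counter advancing per
#' `epoch_size` accepted members — while the free constants are explicit
#' here and logged with every archive.
#'
#' @param iterations annealing iterations
#' @param perturb_magnitude multiplicative perturbation magnitude
#' @param perturb_ics perturb initial conditions alongside rate constants?
#' @param pattern_search_every run a local pattern search after this many
#'   accepted members (0 disables)
#' @param pattern_search_steps polling sweeps per pattern search
#' @param pattern_search_params number of randomly chosen rate constants
#'   polled per pattern search (`NULL` = all)
#' @param t_initial,t_final first and last of the 10 temperature quanta
#' @param n_quanta number of temperature quanta
#' @param epoch_size accepted members per epoch
#' @param t_step simulation output grid spacing (minutes)
#' @return a list of class `poets_config`
#' @export
poets_config <- function(iterations = 500,
                         perturb_magnitude = 0.25,
                         perturb_ics = TRUE,
                         pattern_search_every = 10,
                         pattern_search_steps = 1,
                         pattern_search_params = 8,
                         t_initial = 10,
                         t_final = 0.1,
                         n_quanta = 10,
                         epoch_size = 100,
                         t_step = 2) {
  structure(as.list(environment()), class = "poets_config")
}

#' Estimate a model ensemble with POETs
#'
#' Multiobjective simulated annealing with Pareto-rank fitness. Per
#' iteration the current parameter set is multiplicatively perturbed, the
#' training objectives are evaluated, the candidate is Pareto-ranked
#' against the archive (Fonseca–Fleming), and it is accepted with
#' probability `exp(-rank / T)`. Accepted candidates enter the archive and
#' all archive ranks are updated, so stored ranks always equal a
#' from-scratch dominance count. The temperature is discretized into
#' `n_quanta` quanta spaced geometrically between `t_initial` and
#' `t_final`; the quantum advances with the iteration count and with the
#' epoch counter (incremented per `epoch_size` accepted members), so late
#' acceptance of high-rank candidates becomes unlikely. A local pattern
#' search on one randomly selected objective is interleaved every
#' `pattern_search_every` acceptances.
#'
#' @param net an irreversible `rxn_network`
#' @param objectives list of [objective_series()] (the training set)
#' @param protocols named list of [stim_protocol()]
#' @param initial_params starting `param_vec` (must simulate cleanly)
#' @param config a [poets_config()]
#' @param seed integer seed; the run is exactly reproducible given
#'   (config, seed)
#' @param fold_id integer tag carried into the archive (cross-validation)
#' @return a `poets_archive`: entries (tibble with list-columns `params`,
#'   `errors` and columns `member`, `iteration`, `rank`, `fold_id`), the
#'   acceptance `trace`, `config` and `seed`
#' @export
run_poets <- function(net, objectives, protocols, initial_params,
                      config = poets_config(), seed = 1L, fold_id = 0L) {
  stopifnot(inherits(config, "poets_config"))
  set.seed(seed)
  obj_ids <- vapply(objectives, `[[`, character(1), "objective_id")

  e0 <- evaluate_objectives(net, initial_params, objectives, protocols,
                            t_step = config$t_step)
  if (any(!is.finite(e0))) {
    abort("initial parameter set fails to simulate some objectives")
  }

  n_obj <- length(objectives)
  cap <- config$iterations + 2L + config$iterations %/%
    max(1L, config$pattern_search_every)
  E <- matrix(NA_real_, cap, n_obj)
  P <- vector("list", cap)
  ranks <- integer(cap)
  iters <- integer(cap)
  n_mem <- 0L

  add_member <- function(params, errs, iteration) {
    r <- pareto_rank(errs, E[seq_len(n_mem), , drop = FALSE])
    if (n_mem > 0L) {
      Ecur <- E[seq_len(n_mem), , drop = FALSE]
      le <- rep(errs, each = n_mem) <= Ecur
      lt <- rep(errs, each = n_mem) < Ecur
      dominated <- rowSums(le) == n_obj & rowSums(lt) > 0L
      ranks[seq_len(n_mem)][dominated] <<- ranks[seq_len(n_mem)][dominated] + 1L
    }
    n_mem <<- n_mem + 1L
    E[n_mem, ] <<- errs
    P[[n_mem]] <<- params
    ranks[n_mem] <<- r
    iters[n_mem] <<- iteration
    r
  }
  add_member(initial_params, e0, 0L)

  t_ratio <- (config$t_final / config$t_initial)^(1 / (config$n_quanta - 1))
  cur <- initial_params
  accepted <- 0L
  trace <- vector("list", config$iterations)

  for (iter in seq_len(config$iterations)) {
    epoch <- accepted %/% config$epoch_size
    quantum <- min(config$n_quanta - 1L,
                   max(epoch, (config$n_quanta * (iter - 1L)) %/%
                         config$iterations))
    temp <- config$t_initial * t_ratio^quantum

    cand <- perturb_params(cur, config$perturb_magnitude, config$perturb_ics)
    e_cand <- evaluate_objectives(net, cand, objectives, protocols,
                                  t_step = config$t_step)
    ok <- all(is.finite(e_cand))
    r_cand <- if (ok) {
      pareto_rank(e_cand, E[seq_len(n_mem), , drop = FALSE])
    } else NA_integer_
    accept <- ok && runif(1) < acceptance_probability(r_cand, temp)

    if (accept) {
      add_member(cand, e_cand, iter)
      cur <- cand
      accepted <- accepted + 1L
      if (config$pattern_search_every > 0 &&
          accepted %% config$pattern_search_every == 0L) {
        ob <- objectives[[sample.int(n_obj, 1)]]
        subset <- if (is.null(config$pattern_search_params)) NULL else {
          sample.int(length(cur$k),
                     min(config$pattern_search_params, length(cur$k)))
        }
        ps <- pattern_search(net, cur, ob, protocols,
                             steps = config$pattern_search_steps,
                             param_subset = subset, t_step = config$t_step)
        e_ps <- evaluate_objectives(net, ps$params, objectives, protocols,
                                    t_step = config$t_step)
        if (all(is.finite(e_ps))) {
          add_member(ps$params, e_ps, iter)
          cur <- ps$params
        }
      }
    }
    trace[[iter]] <- c(iteration = iter, rank = as.numeric(r_cand),
                       temperature = temp, quantum = quantum,
                       accepted = as.numeric(accept))
  }

  idx <- seq_len(n_mem)
  entries <- tibble(
    member = idx,
    iteration = iters[idx],
    fold_id = fold_id,
    rank = ranks[idx],
    errors = lapply(idx, function(i) setNames(E[i, ], obj_ids)),
    params = P[idx]
  )
  structure(list(entries = entries,
                 trace = as_tibble(do.call(rbind, trace)),
                 objective_ids = obj_ids,
                 config = config, seed = seed),
            class = "poets_archive")
}

#' @export
print.poets_archive <- function(x, ...) {
  cat("<poets_archive> ", nrow(x$entries), " members (",
      sum(x$entries$rank == 0), " rank-0), ", length(x$objective_ids),
      " objectives, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Tidy an archive into one row per member
#'
#' @param x a `poets_archive`
#' @param ... unused
#' @return tibble with member, iteration, fold, rank and total error
#' @export
tidy.poets_archive <- function(x, ...) {
  dplyr::mutate(
    x$entries[, c("member", "iteration", "fold_id", "rank")],
    total_error = vapply(x$entries$errors, sum, numeric(1)),
    error_norm = vapply(x$entries$errors,
                        function(e) sqrt(sum(e^2)), numeric(1)))
}

#' @export
glance.poets_archive <- function(x, ...) {
  tibble(n_members = nrow(x$entries),
         n_rank0 = sum(x$entries$rank == 0),
         n_objectives = length(x$objective_ids),
         acceptance_rate = mean(x$trace$accepted),
         seed = x$seed)
}

archive_error_matrix <- function(archive) {
  do.call(rbind, archive$entries$errors)
}

archive_param_matrix <- function(archive) {
  do.call(cbind, lapply(archive$entries$params, as.numeric))
}

#' Leave-`holdout`-out cross-validation folds
#'
#' Partitions the objective ids into disjoint validation sets of size
#' `holdout` (default 3: 24 objectives give eight folds of 21 training and
#' 3 validation objectives); each fold trains on the remainder.
#'
#' @param objective_ids character vector of objective ids
#' @param holdout validation objectives per fold
#' @return list of folds, each a list with `fold_id`, `train_ids`,
#'   `validation_ids`
#' @export
make_cv_folds <- function(objective_ids, holdout = 3) {
  n <- length(objective_ids)
  if (n %% holdout != 0) {
    abort(paste0("number of objectives (", n,
                 ") is not divisible by the holdout size (", holdout, ")"))
  }
  shuffled <- sample(objective_ids)
  lapply(seq_len(n %/% holdout), function(f) {
    val <- shuffled[(f - 1L) * holdout + seq_len(holdout)]
    list(fold_id = f, train_ids = setdiff(objective_ids, val),
         validation_ids = val)
  })
}

log_param_profile <- function(params) {
  log10(pmax(params$k, 1e-12))
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(1)
  cor(a, b)
}

#' Select a low-correlation sub-ensemble
#'
#' From each fold's rank-0 archive entries, iteratively selects
#' `n_per_fold` members favoring a short Euclidean distance to the origin
#' in error space and low pairwise Pearson correlation of log-transformed
#' rate-constant profiles with the members already chosen. Candidates are
#' first restricted to the low-error fraction of the rank-0 set
#' (`error_quantile`), then selection is greedy-random: at each step a
#' random candidate pool is scored and the best is kept.
#'
#' @param archives a `poets_archive` or list of them (one per fold)
#' @param n_per_fold members to draw per archive
#' @param pool random candidates scored per selection step
#' @param lambda weight of the (normalized) error-norm term against the
#'   mean-correlation term
#' @param error_quantile rank-0 members above this error-norm quantile are
#'   not eligible (1 disables the restriction)
#' @return a `poets_archive`-like object with the selected entries; the
#'   achieved mean pairwise correlation is in attribute
#'   `mean_pairwise_correlation` and in `glance()`
#' @export
select_subensemble <- function(archives, n_per_fold = 50, pool = 10,
                               lambda = 1, error_quantile = 0.15) {
  if (inherits(archives, "poets_archive")) archives <- list(archives)
  picked <- list()
  for (arch in archives) {
    ent <- arch$entries[arch$entries$rank == 0, ]
    if (nrow(ent) > n_per_fold && error_quantile < 1) {
      norms <- vapply(ent$errors, function(e) sqrt(sum(e^2)), numeric(1))
      cut <- quantile(norms, error_quantile)
      keep <- norms <= cut
      if (sum(keep) >= n_per_fold) ent <- ent[keep, ]
    }
    if (nrow(ent) == 0) next
    if (nrow(ent) <= n_per_fold) {
      if (nrow(ent) < n_per_fold) {
        warn(paste0("fold ", ent$fold_id[1], ": only ", nrow(ent),
                    " rank-0 members available; selecting all"))
      }
      picked[[length(picked) + 1L]] <- ent
      next
    }
    enorm <- vapply(ent$errors, function(e) sqrt(sum(e^2)), numeric(1))
    maxnorm <- max(enorm, 1e-300)
    profiles <- lapply(ent$params, log_param_profile)
    chosen <- which.min(enorm)
    remaining <- setdiff(seq_len(nrow(ent)), chosen)
    while (length(chosen) < n_per_fold) {
      cand <- if (length(remaining) > pool) sample(remaining, pool) else remaining
      score <- vapply(cand, function(i) {
        mc <- mean(vapply(chosen, function(j) {
          abs(safe_cor(profiles[[i]], profiles[[j]]))
        }, numeric(1)))
        mc + lambda * enorm[i] / maxnorm
      }, numeric(1))
      best <- cand[which.min(score)]
      chosen <- c(chosen, best)
      remaining <- setdiff(remaining, best)
    }
    picked[[length(picked) + 1L]] <- ent[chosen, ]
  }
  if (!length(picked)) abort("no rank-0 members in any archive")
  entries <- dplyr::bind_rows(picked)
  entries$member <- seq_len(nrow(entries))
  profiles <- lapply(entries$params, log_param_profile)
  n <- length(profiles)
  mean_cor <- if (n < 2) NA_real_ else {
    pairs <- utils::combn(n, 2)
    mean(vapply(seq_len(ncol(pairs)), function(p) {
      abs(safe_cor(profiles[[pairs[1, p]]], profiles[[pairs[2, p]]]))
    }, numeric(1)))
  }
  out <- structure(list(entries = entries,
                        trace = NULL,
                        objective_ids = archives[[1]]$objective_ids,
                        config = archives[[1]]$config,
                        seed = archives[[1]]$seed),
                   class = "poets_archive")
  attr(out, "mean_pairwise_correlation") <- mean_cor
  out
}

#' Per-parameter coefficient of variation across an ensemble
#'
#' The CV (sample standard deviation over mean) of each rate constant
#' across ensemble members measures how tightly the training data
#' constrain that parameter.
#'
#' @param ensemble a `poets_archive` (>= 2 members)
#' @return tibble with `parameter`, `mean`, `sd`, `cv`
#' @export
parameter_cv <- function(ensemble) {
  if (nrow(ensemble$entries) < 2) abort("need at least 2 ensemble members")
  K <- do.call(cbind, lapply(ensemble$entries$params, `[[`, "k"))
  mu <- rowMeans(K)
  sdev <- apply(K, 1, sd)
  tibble(parameter = rownames(K), mean = mu, sd = sdev,
         cv = ifelse(mu > 0, sdev / mu, NA_real_))
}

#' Random-parameter control sets
#'
#' Draws control parameter sets with each rate constant scattered
#' log-uniformly within +/- `decades` decades of its nominal value
#' (initial conditions untouched); used as the baseline against which
#' trained ensemble errors are compared.
#'
#' @param params nominal `param_vec`
#' @param n number of control sets
#' @param decades half-width of the log-uniform scatter
#' @return list of `param_vec`
#' @export
random_control_params <- function(params, n = 10, decades = 1) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$k <- p$k * 10^runif(length(p$k), -decades, decades)
    p
  })
}
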