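#' Solve the forward kinetic-sensitivity equations
#'
#' Integrates, alongside the states, the first-order sensitivities
#' `s_j(t) = dx/dk_j` for the selected rate constants via
#' `ds_j/dt = J(x, k) s_j + B_j(x, k)` with `s_j(0) = 0`, where `J` and
#' `B_j` are the analytical Jacobian and parameter-derivative column. The
#' trajectory starts from the protocol's stimulated state (steady state
#' plus stimulus), matching how responses are simulated.
#'
#' @param net an irreversible `rxn_network`
#' @param params a `param_vec`
#' @param protocol a [stim_protocol()]
#' @param param_subset reaction ids (names) or indices of the rate
#'   constants to differentiate against (default: all)
#' @param t_grid output times (default 0..horizon, 1 min spacing)
#' @param rtol,atol integration tolerances
#' @return a `sensitivity_field`: `times`, `states` (time x species), and
#'   `s` (time x species x parameter array), plus the rate constants used
#' @export
solve_sensitivities <- function(net, params, protocol,
                                param_subset = NULL, t_grid = NULL,
                                rtol = 1e-6, atol = 1e-8) {
  base <- simulate_protocol(net, params, protocol, t_step = protocol$horizon)
  net_p <- attr(base, "net")
  params_p <- attr(base, "params")
  x_start <- base$states[1, ]
  if (is.null(t_grid)) t_grid <- seq(0, protocol$horizon, by = 1)

  rxn_ids <- net_p$reactions$id
  if (is.null(param_subset)) param_subset <- rxn_ids
  if (is.numeric(param_subset)) param_subset <- rxn_ids[param_subset]
  param_subset <- intersect(param_subset, rxn_ids)
  if (!length(param_subset)) abort("param_subset selects no surviving reactions")
  sub_idx <- match(param_subset, rxn_ids)

  cp <- net_p$compiled
  k <- as.numeric(params_p$k)
  n_sp <- nrow(net_p$species)
  n_par <- length(sub_idx)

  func <- function(t, y, p) {
    x <- pmax(y[seq_len(n_sp)], 0)
    ev <- .ma_jac_dfdk(x, k, cp$S, cp$ri, cp$rj, cp$re, TRUE, TRUE)
    f <- cp$S %*% ev$rates
    Smat <- matrix(y[-seq_len(n_sp)], n_sp, n_par)
    dS <- ev$J %*% Smat + ev$B[, sub_idx, drop = FALSE]
    list(c(f, as.vector(dS)))
  }
  y0 <- c(as.numeric(x_start), rep(0, n_sp * n_par))
  out <- deSolve::ode(y = y0, times = t_grid, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(t_grid)) {
    abort(paste0("sensitivity integration failed at t = ", max(out[, 1]),
                 " (parameters ", paste(head(param_subset, 3), collapse = ", "),
                 " ...)"))
  }
  states <- out[, 1 + seq_len(n_sp), drop = FALSE]
  colnames(states) <- net_p$species$id
  s <- array(out[, -(1:(1 + n_sp))],
             dim = c(length(t_grid), n_sp, n_par),
             dimnames = list(NULL, net_p$species$id, param_subset))
  structure(list(times = t_grid, states = states, s = s,
                 k = params_p$k[param_subset],
                 species = net_p$species$id,
                 param_ids = param_subset,
                 protocol_label = protocol$label),
            class = "sensitivity_field")
}

trapz_mean <- function(t, y) {
  # trapezoid-rule time average over [t_1, t_end]
  if (length(t) < 2) abort("window needs at least two grid points")
  w <- diff(t)
  sum(w * (head(y, -1) + y[-1]) / 2) / (max(t) - min(t))
}

#' Scale and time-average a sensitivity field
#'
#' Converts raw sensitivities to dimensionless log-sensitivities
#' `(k_j / x_i) dx_i/dk_j` (the concentration guarded by
#' `max(x_i, delta)`) and averages them over the window with the trapezoid
#' rule, divided by the window length.
#'
#' @param field a `sensitivity_field`
#' @param window `c(t_start, t_end)` within the simulated span (default:
#'   the full span)
#' @param delta concentration guard for species at or near zero
#' @return matrix (species x parameters) of time-averaged scaled
#'   sensitivities
#' @export
scale_and_time_average <- function(field, window = NULL, delta = 1e-6) {
  stopifnot(inherits(field, "sensitivity_field"))
  if (is.null(window)) window <- range(field$times)
  if (diff(window) <= 0) abort("window must have positive width")
  keep <- field$times >= window[1] - 1e-9 & field$times <= window[2] + 1e-9
  if (sum(keep) < 2) abort("window contains fewer than two grid points")
  t <- field$times[keep]
  xg <- pmax(field$states[keep, , drop = FALSE], delta)
  n_sp <- length(field$species)
  n_par <- length(field$param_ids)
  M <- matrix(0, n_sp, n_par, dimnames = list(field$species, field$param_ids))
  for (j in seq_len(n_par)) {
    scaled <- field$s[keep, , j, drop = FALSE][, , 1] * field$k[j] / xg
    M[, j] <- apply(scaled, 2, function(col) trapz_mean(t, col))
  }
  M
}

#' Assemble per-member sensitivity matrices into one array
#'
#' Stacks the (species x parameters) matrices of the ensemble members into
#' the parameters x (members * species) array that is decomposed by SVD.
#'
#' @param member_mats list of matrices from [scale_and_time_average()],
#'   one per ensemble member (identical dimnames)
#' @return a `sensitivity_array`: the matrix `A` with `member_index` and
#'   `species_index` maps for its columns
#' @export
assemble_sensitivity_array <- function(member_mats) {
  stopifnot(length(member_mats) >= 1)
  n_sp <- nrow(member_mats[[1]])
  A <- do.call(cbind, lapply(member_mats, t))
  structure(list(A = A,
                 member_index = rep(seq_along(member_mats), each = n_sp),
                 species_index = rep(rownames(member_mats[[1]]),
                                     times = length(member_mats)),
                 param_ids = colnames(member_mats[[1]]),
                 species = rownames(member_mats[[1]])),
            class = "sensitivity_array")
}

#' SVD fragility ranking
#'
#' Decomposes the sensitivity array `A` (parameters x members*species) by
#' singular value decomposition, keeps the singular vectors of the largest
#' `k_vectors` singular values, marks within each vector the indices whose
#' coefficient magnitude exceeds `threshold`, and scores each index by the
#' fraction of the kept vectors in which it is marked. Left singular
#' vectors rank the parameter (reaction) axis; right singular vectors rank
#' the member-species axis, which is collapsed to species (a species is
#' marked in a vector if any of its member columns is marked). Reaction
#' scores are also attributed to species by taking, per species, the
#' maximum score over the reactions it participates in.
#'
#' @param arr a `sensitivity_array` (or a bare matrix, in which case
#'   columns are treated as one member's species)
#' @param k_vectors number of singular vectors kept; `NULL` keeps the
#'   vectors capturing 95% of the spectral energy
#' @param threshold coefficient magnitude cutoff (default 0.001)
#' @param threshold_mode `"absolute"` applies `threshold` to the raw
#'   coefficient magnitudes; `"relative"` marks coefficients within
#'   `threshold` of the vector's dominant loading
#'   (`|c| > threshold * max|c|`), which keeps the score discriminating on
#'   small (tens-of-species) networks where unit-norm vectors push every
#'   involved coefficient above a small absolute cutoff
#' @param net optional `rxn_network` for the reaction-to-species mapping
#' @return a `fragility_ranking`: tibbles `species_scores` (species,
#'   score), `parameter_scores` (reaction, score) and, with `net`,
#'   `species_from_reactions`; plus `k_vectors` and `threshold`
#' @export
svd_rank <- function(arr, k_vectors = NULL, threshold = 1e-3,
                     threshold_mode = c("absolute", "relative"), net = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.matrix(arr)) {
    arr <- structure(list(A = t(arr),
                          member_index = rep(1L, nrow(arr)),
                          species_index = rownames(arr),
                          param_ids = colnames(arr),
                          species = rownames(arr)),
                     class = "sensitivity_array")
  }
  A <- arr$A
  if (any(!is.finite(A))) abort("sensitivity array has non-finite entries")
  dec <- svd(A)
  energy <- cumsum(dec$d^2) / sum(dec$d^2)
  k_default <- which(energy >= 0.95)[1]
  if (is.null(k_vectors)) k_vectors <- k_default
  r <- sum(dec$d > max(dec$d) * 1e-12)
  if (k_vectors > r) {
    warn(paste0("k_vectors = ", k_vectors, " exceeds matrix rank ", r,
                "; clamping"))
    k_vectors <- r
  }
  kv <- seq_len(k_vectors)
  mark <- function(M) {
    cut <- if (threshold_mode == "absolute") rep(threshold, ncol(M)) else {
      threshold * apply(abs(M), 2, max)
    }
    sweep(abs(M), 2, cut, `>`)
  }
  u_marked <- mark(dec$u[, kv, drop = FALSE])
  param_score <- rowMeans(u_marked)
  v_marked <- mark(dec$v[, kv, drop = FALSE])
  sp_levels <- unique(arr$species_index)
  sp_marked <- vapply(sp_levels, function(sp) {
    rows <- arr$species_index == sp
    colSums(v_marked[rows, , drop = FALSE]) > 0
  }, logical(k_vectors))
  sp_score <- if (k_vectors == 1) as.numeric(sp_marked) else colMeans(sp_marked)
  out <- list(
    species_scores = tibble(species = sp_levels, score = unname(sp_score)),
    parameter_scores = tibble(reaction = arr$param_ids, score = param_score),
    k_vectors = k_vectors, threshold = threshold
  )
  if (!is.null(net)) {
    rx_score <- setNames(param_score, arr$param_ids)
    sfr <- vapply(net$species$id, function(sp) {
      touch <- vapply(seq_len(nrow(net$reactions)), function(j) {
        sp %in% names(net$reactions$reactants[[j]]) ||
          sp %in% names(net$reactions$products[[j]])
      }, logical(1))
      ids <- intersect(net$reactions$id[touch], arr$param_ids)
      if (!length(ids)) 0 else max(rx_score[ids])
    }, numeric(1))
    out$species_from_reactions <- tibble(species = net$species$id,
                                         score = unname(sfr))
  }
  structure(out, class = "fragility_ranking")
}

#' @export
print.fragility_ranking <- function(x, ...) {
  cat("<fragility_ranking> ", nrow(x$species_scores), " species, ",
      nrow(x$parameter_scores), " reactions; k = ", x$k_vectors,
      ", threshold = ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Ensemble sensitivity ranking for one condition
#'
#' Runs the full fragility pipeline for every selected ensemble member —
#' forward sensitivities under the protocol, log-scaling, trapezoid
#' time-averaging over the window — assembles the member matrices into one
#' array and ranks species and reactions by SVD. Per-member rankings are
#' also computed so each species score carries a standard error across the
#' member family.
#'
#' @param net an irreversible `rxn_network`
#' @param ensemble a `poets_archive` (the sub-ensemble to analyze)
#' @param protocol a [stim_protocol()] defining the condition
#' @param window time-averaging window (default: full horizon)
#' @param n_members members to use (default all; subsampling is the
#'   caller's choice, e.g. 10% of a large sub-ensemble)
#' @param param_subset,k_vectors,threshold,threshold_mode,t_grid see
#'   [svd_rank()] and [solve_sensitivities()]
#' @return a `sensitivity_ranking`: tibble `species` with pooled `score`,
#'   per-member `mean_score` and `se`, plus the pooled `fragility_ranking`
#' @export
sensitivity_ranking <- function(net, ensemble, protocol, window = NULL,
                                n_members = NULL, param_subset = NULL,
                                k_vectors = NULL, threshold = 1e-3,
                                threshold_mode = "absolute",
                                t_grid = NULL) {
  entries <- ensemble$entries
  if (!is.null(n_members) && n_members < nrow(entries)) {
    entries <- entries[sample.int(nrow(entries), n_members), ]
  }
  mats <- lapply(entries$params, function(p) {
    fld <- solve_sensitivities(net, p, protocol, param_subset = param_subset,
                               t_grid = t_grid)
    scale_and_time_average(fld, window = window)
  })
  arr <- assemble_sensitivity_array(mats)
  pooled <- svd_rank(arr, k_vectors = k_vectors, threshold = threshold,
                     threshold_mode = threshold_mode, net = net)
  per_member <- lapply(mats, function(M) {
    svd_rank(M, k_vectors = k_vectors, threshold = threshold,
             threshold_mode = threshold_mode)
  })
  sp <- pooled$species_scores$species
  member_scores <- vapply(per_member, function(r) {
    setNames(r$species_scores$score,
             r$species_scores$species)[sp]
  }, numeric(length(sp)))
  member_scores <- matrix(member_scores, nrow = length(sp))
  species <- tibble(
    species = sp,
    score = pooled$species_scores$score,
    mean_score = rowMeans(member_scores),
    se = apply(member_scores, 1, sd) / sqrt(ncol(member_scores))
  )
  structure(list(species = species, pooled = pooled,
                 window = window %||% "full horizon",
                 condition = protocol$label,
                 n_members = nrow(entries)),
            class = "sensitivity_ranking")
}

#' @export
print.sensitivity_ranking <- function(x, ...) {
  cat("<sensitivity_ranking> condition '", x$condition, "', ",
      x$n_members, " members\n", sep = "")
  print(head(dplyr::arrange(x$species, dplyr::desc(.data$score)), 10))
  invisible(x)
}

#' @export
tidy.sensitivity_ranking <- function(x, ...) {
  dplyr::mutate(x$species, condition = x$condition)
}

#' Pair two fragility rankings for comparison
#'
#' Produces per-species `(score_a, score_b)` pairs — the data behind
#' with/without-stimulus, with/without-feedback or early/late-window
#' scatter plots.
#'
#' @param rank_a,rank_b `sensitivity_ranking` objects over the same species
#' @param score_col `"score"` (pooled) or `"mean_score"` (member mean)
#' @return tibble with `species`, `score_a`, `score_b`
#' @export
ranking_comparison <- function(rank_a, rank_b, score_col = "score") {
  a <- rank_a$species
  b <- rank_b$species
  if (!setequal(a$species, b$species)) {
    abort("rankings cover different species universes")
  }
  b <- b[match(a$species, b$species), ]
  tibble(species = a$species,
         score_a = a[[score_col]],
         score_b = b[[score_col]])
}

#' Scatter plot of two sensitivity rankings
#'
#' @param object a `sensitivity_ranking`
#' @param other a second `sensitivity_ranking` to compare against; omitted,
#'   plots the ranked scores of `object`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.sensitivity_ranking <- function(object, other = NULL, ...) {
  if (is.null(other)) {
    d <- dplyr::arrange(object$species, .data$score)
    d$species <- factor(d$species, levels = d$species)
    return(ggplot2::ggplot(d, ggplot2::aes(.data$score, .data$species)) +
             ggplot2::geom_col() +
             ggplot2::geom_errorbarh(ggplot2::aes(
               xmin = pmax(.data$mean_score - .data$se, 0),
               xmax = pmin(.data$mean_score + .data$se, 1)), height = 0.3) +
             ggplot2::labs(x = "fragility score", y = NULL,
                           title = object$condition) +
             ggplot2::theme_minimal())
  }
  d <- ranking_comparison(object, other)
  ggplot2::ggplot(d, ggplot2::aes(.data$score_a, .data$score_b)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$condition, y = other$condition) +
    ggplot2::theme_minimal()
}

#' Export a sensitivity ranking as CSV
#'
#' @param ranking a `sensitivity_ranking`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ranking <- function(ranking, path) {
  d <- tidy(ranking)
  d$window <- paste(ranking$window, collapse = "-")
  write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}
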