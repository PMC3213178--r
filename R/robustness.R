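#' Robustness coefficient of a marker species
#'
#' The ratio of the time-integrated (trapezoid rule) concentration of a
#' network marker in the perturbed simulation (numerator) over the nominal
#' simulation (denominator). Values above 1 mean the perturbation
#' increased the integrated marker, below 1 decreased it, and exactly 1
#' means no influence.
#'
#' @param traj_perturbed,traj_nominal `trajectory` objects covering
#'   `[t0, tf]`
#' @param marker marker species id (e.g. the assembled 80S complex)
#' @param t0,tf integration window (defaults: the nominal trajectory span)
#' @return positive real ratio
#' @export
robustness_coefficient <- function(traj_perturbed, traj_nominal, marker,
                                   t0 = NULL, tf = NULL) {
  if (is.null(t0)) t0 <- min(traj_nominal$times)
  if (is.null(tf)) tf <- max(traj_nominal$times)
  integrate_marker <- function(traj) {
    if (!marker %in% colnames(traj$states)) {
      abort(paste0("marker species '", marker, "' not in trajectory"))
    }
    if (t0 < min(traj$times) - 1e-9 || tf > max(traj$times) + 1e-9) {
      abort("integration window outside the trajectory span")
    }
    keep <- traj$times >= t0 - 1e-9 & traj$times <= tf + 1e-9
    t <- traj$times[keep]
    y <- traj$states[keep, marker]
    sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  }
  num <- integrate_marker(traj_perturbed)
  den <- integrate_marker(traj_nominal)
  if (den <= 0) abort("marker never produced in the nominal simulation")
  num / den
}

#' Knockdown screen over an ensemble
#'
#' For every (ensemble member, knockdown target, condition) cell the
#' nominal and knocked-down protocols are simulated and the marker's
#' robustness coefficient computed. Nominal simulations are shared across
#' targets within a member/condition. Cells whose simulation fails are
#' flagged and excluded from aggregates, with the failure count reported.
#'
#' @param net an irreversible `rxn_network`
#' @param ensemble a `poets_archive` (or list of `param_vec`)
#' @param targets species ids to knock down; an element may be a vector of
#'   ids knocked down together (named list entries name the target)
#' @param conditions named list of [stim_protocol()]
#' @param marker marker species id (default `"R80S"`, the assembled
#'   ribosome proxy)
#' @param t0,tf integration window (default: full horizon)
#' @param t_step simulation grid spacing
#' @param delta,c_sev classification thresholds (see [classify_effect()])
#' @return a `knockdown_screen`: tibble `cells` (member, target,
#'   condition, coefficient, failed) plus a category summary per
#'   target/condition (see [classify_effect()])
#' @export
knockdown_screen <- function(net, ensemble, targets, conditions,
                             marker = "R80S", t0 = NULL, tf = NULL,
                             t_step = 2, delta = 0.1, c_sev = 0.25) {
  params_list <- if (inherits(ensemble, "poets_archive")) {
    ensemble$entries$params
  } else ensemble
  if (!length(params_list)) abort("ensemble is empty")
  if (is.null(names(targets))) {
    names(targets) <- vapply(targets, function(t) paste(t, collapse = "+"),
                             character(1))
  }
  unknown <- setdiff(unlist(targets), net$species$id)
  if (length(unknown)) {
    abort(paste0("unknown knockdown target: ", paste(unknown, collapse = ", ")))
  }
  rows <- list()
  for (m in seq_along(params_list)) {
    p <- params_list[[m]]
    for (cn in names(conditions)) {
      nominal <- tryCatch(
        simulate_protocol(net, p, conditions[[cn]], t_step = t_step),
        error = function(e) e)
      for (tn in names(targets)) {
        coefficient <- NA_real_
        failed <- TRUE
        if (!inherits(nominal, "error")) {
          proto_kd <- conditions[[cn]]
          proto_kd$knockdowns <- union(proto_kd$knockdowns, targets[[tn]])
          pert <- tryCatch(
            simulate_protocol(net, p, proto_kd, t_step = t_step),
            error = function(e) e)
          if (!inherits(pert, "error")) {
            coefficient <- tryCatch(
              robustness_coefficient(pert, nominal, marker, t0, tf),
              error = function(e) NA_real_)
            failed <- !is.finite(coefficient)
          }
        }
        rows[[length(rows) + 1L]] <- tibble(
          member = m, target = tn, condition = cn,
          coefficient = coefficient, failed = failed)
      }
    }
  }
  cells <- dplyr::bind_rows(rows)
  summary <- cells |>
    dplyr::group_by(.data$target, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_failed = sum(.data$failed),
      median = median(.data$coefficient[!.data$failed]),
      category = classify_effect(.data$coefficient[!.data$failed],
                                 delta = delta, c_sev = c_sev),
      .groups = "drop")
  structure(list(cells = cells, summary = summary, marker = marker,
                 delta = delta, c_sev = c_sev,
                 window = c(t0 %||% 0, tf %||% NA)),
            class = "knockdown_screen")
}

#' @export
print.knockdown_screen <- function(x, ...) {
  cat("<knockdown_screen> marker '", x$marker, "', ",
      dplyr::n_distinct(x$cells$member), " members x ",
      dplyr::n_distinct(x$cells$target), " targets x ",
      dplyr::n_distinct(x$cells$condition), " conditions ",
      "(delta = ", x$delta, ", c_sev = ", x$c_sev, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.knockdown_screen <- function(x, ...) x$cells

#' @export
glance.knockdown_screen <- function(x, ...) {
  tibble(n_cells = nrow(x$cells), n_failed = sum(x$cells$failed),
         n_targets = dplyr::n_distinct(x$cells$target),
         n_conditions = dplyr::n_distinct(x$cells$condition))
}

#' Classify a knockdown's effect on the marker
#'
#' The member-median coefficient `m` is mapped to one of four categories:
#' `increase` (`m > 1 + delta`), `none` (`|m - 1| <= delta`),
#' `moderate_decrease` (`c_sev < m < 1 - delta`) and `severe_decrease`
#' (`m <= c_sev`; the boundary itself is severe). With no finite
#' coefficients the category is `undetermined`. Defaults: `delta = 0.1`,
#' `c_sev = 0.25` (severe = marker reduced by at least 75%).
#'
#' @param member_coefficients robustness coefficients across members
#' @param delta half-width of the "no effect" band around 1
#' @param c_sev severe-decrease cutoff
#' @return category string
#' @export
classify_effect <- function(member_coefficients, delta = 0.1, c_sev = 0.25) {
  cf <- member_coefficients[is.finite(member_coefficients)]
  if (!length(cf)) return("undetermined")
  m <- median(cf)
  if (m <= c_sev) return("severe_decrease")
  if (m > 1 + delta) return("increase")
  if (abs(m - 1) <= delta) return("none")
  "moderate_decrease"
}

#' Subpopulation report for one knockdown target
#'
#' Tallies qualitatively different ensemble members: how many increased
#' the marker, decreased it, showed at least a two-fold increase, or at
#' least a two-fold decrease — with member ids, so claims like "80% of the
#' sampled models increased initiation" can be read off directly.
#'
#' @param screen a `knockdown_screen`
#' @param target target name present in the screen
#' @return tibble per condition with counts `n_increase`, `n_decrease`,
#'   `n_twofold_up`, `n_twofold_down`, `n_members` and list-columns of the
#'   member ids
#' @export
subpopulation_report <- function(screen, target) {
  d <- screen$cells[screen$cells$target == target & !screen$cells$failed, ]
  if (!nrow(d)) abort(paste0("target '", target, "' not in screen"))
  d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_increase = sum(.data$coefficient > 1),
      n_decrease = sum(.data$coefficient < 1),
      n_twofold_up = sum(.data$coefficient >= 2),
      n_twofold_down = sum(.data$coefficient <= 0.5),
      members_increase = list(.data$member[.data$coefficient > 1]),
      members_twofold_up = list(.data$member[.data$coefficient >= 2]),
      .groups = "drop")
}

#' Category stability across nested subsample sizes
#'
#' Re-derives each target/condition category from nested member subsets
#' (e.g. the first 50, 100, 200 and all members) and flags targets whose
#' category flips — a convergence diagnostic for the ensemble size.
#'
#' @param screen a `knockdown_screen`
#' @param sizes subsample sizes (clamped to the member count)
#' @return tibble (target, condition, size, category, stable)
#' @export
screen_convergence <- function(screen, sizes = c(50, 100, 200)) {
  n_mem <- dplyr::n_distinct(screen$cells$member)
  sizes <- sort(unique(pmin(c(sizes, n_mem), n_mem)))
  out <- list()
  for (sz in sizes) {
    sub <- screen$cells[screen$cells$member <= sz & !screen$cells$failed, ]
    agg <- sub |>
      dplyr::group_by(.data$target, .data$condition) |>
      dplyr::summarise(category = classify_effect(
        .data$coefficient, delta = screen$delta, c_sev = screen$c_sev),
        .groups = "drop")
    agg$size <- sz
    out[[length(out) + 1L]] <- agg
  }
  res <- dplyr::bind_rows(out)
  res |>
    dplyr::group_by(.data$target, .data$condition) |>
    dplyr::mutate(stable = dplyr::n_distinct(.data$category) == 1) |>
    dplyr::ungroup()
}

#' Histogram of knockdown fold changes
#'
#' @param object a `knockdown_screen`
#' @param target optional single target to show
#' @param ... unused
#' @return a ggplot of the per-member coefficient distribution
#' @export
autoplot.knockdown_screen <- function(object, target = NULL, ...) {
  d <- object$cells[!object$cells$failed, ]
  if (!is.null(target)) d <- d[d$target == target, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$coefficient)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_grid(condition ~ target, scales = "free_y") +
    ggplot2::labs(x = "robustness coefficient (perturbed / nominal)",
                  y = "members") +
    ggplot2::theme_minimal()
}

#' Export a knockdown screen as CSVs
#'
#' Writes the long-form cell table and the category summary; the summary
#' header records the classification thresholds.
#'
#' @param screen a `knockdown_screen`
#' @param dir output directory
#' @return the file paths, invisibly
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells_path <- file.path(dir, "screen_cells.csv")
  summary_path <- file.path(dir, "screen_summary.csv")
  write.csv(as.data.frame(screen$cells), cells_path, row.names = FALSE)
  con <- file(summary_path, "w")
  writeLines(sprintf("# marker=%s delta=%g c_sev=%g", screen$marker,
                     screen$delta, screen$c_sev), con)
  write.csv(as.data.frame(screen$summary[, c("target", "condition", "n",
                                             "n_failed", "median",
                                             "category")]),
            con, row.names = FALSE)
  close(con)
  invisible(c(cells_path, summary_path))
}
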