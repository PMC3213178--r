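test_that("dominance is strict, irreflexive and length-checked", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1), c(1, 2)), "length")
})

test_that("Pareto ranks equal all-pairs brute-force dominance counts", {
  expect_equal(pareto_rank(c(1, 1), NULL), 0L)
  set.seed(42)
  E <- matrix(runif(100 * 4), ncol = 4)
  for (i in sample(100, 20)) {
    brute <- 0L
    for (j in seq_len(100)) {
      if (j != i && dominates(E[j, ], E[i, ])) brute <- brute + 1L
    }
    expect_identical(pareto_rank(E[i, ], E[-i, , drop = FALSE]), brute)
  }
  # candidate dominated by exactly 3 of 5 archive members
  arch <- rbind(c(1, 1), c(2, 2), c(0.5, 2.5), c(1, 4), c(4, 2.9))
  expect_identical(pareto_rank(c(3, 3), arch), 3L)
})

test_that("acceptance probability is exp(-rank/T) with the right limits", {
  expect_identical(acceptance_probability(0, 5), 1)
  expect_equal(acceptance_probability(2, 2), exp(-1))
  expect_error(acceptance_probability(1, 0), "temperature")
  # decreasing in rank, decreasing as T falls for fixed positive rank
  ranks <- 0:6
  p_seq <- vapply(ranks, acceptance_probability, numeric(1), temperature = 1)
  expect_true(all(diff(p_seq) < 0))
  temps <- c(5, 2, 1, 0.5, 0.1)
  p_t <- vapply(temps, function(t) acceptance_probability(3, t), numeric(1))
  expect_true(all(diff(p_t) < 0))
})

test_that("multiplicative perturbation is unbiased, bounded and seeded", {
  p <- network_params(chain_net())
  set.seed(1)
  tiny <- perturb_params(p, magnitude = 1e-9)
  expect_equal(as.numeric(tiny), as.numeric(p), tolerance = 1e-6)

  set.seed(5); a <- perturb_params(p, 0.25)
  set.seed(5); b <- perturb_params(p, 0.25)
  expect_identical(a, b)

  set.seed(9)
  base <- setNames(rep(1, 1e4), paste0("k", 1:1e4))
  pv <- structure(list(k = base, x0 = numeric(0)), class = "param_vec")
  drawn <- perturb_params(pv, 0.25, perturb_ics = FALSE)$k
  expect_lt(abs(mean(drawn) - 1), 0.01)
  expect_true(all(drawn >= 0.75 & drawn <= 1.25))
})

test_that("pattern search only improves the selected objective", {
  net <- decay_net(k = 0.4, x0 = 1)
  proto <- stim_protocol(stimulus_amount = 0, horizon = 5,
                         equilibrate = FALSE, label = "free")
  protos <- list(free = proto)
  k_star <- 1.3
  truth <- network_params(net); truth$k[] <- k_star
  target <- exp(-k_star * seq(0, 5, 1))
  ob <- objective_series("O1", "A", "free", seq(0, 5, 1), target)

  start <- network_params(net)  # k = 0.4, well off
  e0 <- poetsim:::evaluate_single_objective(net, start, ob, protos)
  ps <- pattern_search(net, start, ob, protos, steps = 25, t_step = 1)
  expect_lte(ps$error, e0)
  expect_equal(unname(ps$params$k[["dec"]]), k_star, tolerance = 1e-2)

  ps0 <- pattern_search(net, start, ob, protos, steps = 0)
  expect_identical(ps0$params, start)
})

test_that("a seeded POETs run is reproducible and its ranks re-derive exactly", {
  net <- decay_net(k = 1, x0 = 1)
  proto <- stim_protocol(stimulus_amount = 0, horizon = 4,
                         equilibrate = FALSE, label = "free")
  protos <- list(free = proto)
  grid <- seq(0, 4, 0.5)
  mk_ob <- function(id, k_true) {
    objective_series(id, "A", "free", grid, exp(-k_true * grid))
  }
  objectives <- list(mk_ob("Oa", 0.5), mk_ob("Ob", 2))
  cfg <- poets_config(iterations = 120, t_step = 0.5,
                      pattern_search_every = 0, perturb_ics = FALSE)
  arch1 <- run_poets(net, objectives, protos, network_params(net),
                     config = cfg, seed = 31)
  arch2 <- run_poets(net, objectives, protos, network_params(net),
                     config = cfg, seed = 31)
  expect_identical(arch1$entries, arch2$entries)
  expect_identical(arch1$trace, arch2$trace)

  # stored ranks match a from-scratch dominance count over the final archive
  E <- do.call(rbind, arch1$entries$errors)
  for (i in seq_len(nrow(E))) {
    expect_identical(arch1$entries$rank[i],
                     pareto_rank(E[i, ], E[-i, , drop = FALSE]))
  }

  # the bi-objective trade-off: rank-0 decay constants span [0.5, 2]
  k0 <- vapply(arch1$entries$params[arch1$entries$rank == 0],
               function(p) p$k[["dec"]], numeric(1))
  expect_gt(sum(k0 > 0.4 & k0 < 2.2), 0.8 * length(k0))
  expect_gt(max(k0), 1)
  expect_lt(min(k0), 1)
})

test_that("leave-three-out folds partition the objectives", {
  ids <- sprintf("O%02d", 1:24)
  set.seed(3)
  folds <- make_cv_folds(ids)
  expect_length(folds, 8)
  for (f in folds) {
    expect_length(f$train_ids, 21)
    expect_length(f$validation_ids, 3)
    expect_length(intersect(f$train_ids, f$validation_ids), 0)
    expect_setequal(c(f$train_ids, f$validation_ids), ids)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "validation_ids")), ids)
  expect_length(make_cv_folds(ids[1:6]), 2)
  expect_error(make_cv_folds(ids[1:7]), "divisible")
})

make_archive <- function(params_list, errors_list, ranks = NULL) {
  n <- length(params_list)
  if (is.null(ranks)) ranks <- rep(0L, n)
  structure(list(
    entries = tibble::tibble(member = seq_len(n), iteration = seq_len(n),
                             fold_id = 1L, rank = ranks,
                             errors = errors_list, params = params_list),
    trace = NULL, objective_ids = names(errors_list[[1]]),
    config = poets_config(), seed = 1L), class = "poets_archive")
}

test_that("sub-ensemble selection favors the origin and decorrelated members", {
  p <- network_params(chain_net())
  # two candidates, one strictly closer to the origin -> it is preferred
  arch <- make_archive(list(p, p),
                       list(c(a = 1, b = 1), c(a = 0.1, b = 0.1)))
  sel <- select_subensemble(arch, n_per_fold = 1)
  expect_equal(sel$entries$errors[[1]], c(a = 0.1, b = 0.1))

  # identical members report mean pairwise correlation 1
  arch_same <- make_archive(rep(list(p), 4),
                            rep(list(c(a = 0.2, b = 0.2)), 4))
  sel_same <- select_subensemble(arch_same, n_per_fold = 3)
  expect_equal(attr(sel_same, "mean_pairwise_correlation"), 1)

  # two decorrelated parameter clusters: both get sampled and the mean
  # correlation drops below the single-cluster baseline
  set.seed(11)
  mk_p <- function(base) {
    q <- p
    q$k <- setNames(base * exp(rnorm(3, 0, 0.05)), names(q$k))
    q
  }
  cluster1 <- lapply(1:10, function(i) mk_p(c(0.01, 1, 100)))
  cluster2 <- lapply(1:10, function(i) mk_p(c(100, 0.01, 1)))
  errs <- lapply(1:20, function(i) c(a = runif(1), b = runif(1)))
  arch_two <- make_archive(c(cluster1, cluster2), errs)
  sel2 <- select_subensemble(arch_two, n_per_fold = 10)
  picked_c2 <- sum(vapply(sel2$entries$params,
                          function(q) q$k[[1]] > 1, logical(1)))
  expect_gt(picked_c2, 0)
  expect_lt(picked_c2, 10)
  sel_one <- select_subensemble(make_archive(cluster1, errs[1:10]),
                                n_per_fold = 10)
  expect_lt(attr(sel2, "mean_pairwise_correlation"),
            attr(sel_one, "mean_pairwise_correlation"))

  # insufficient rank-0 members: selects all with a warning
  arch_short <- make_archive(rep(list(p), 2),
                             rep(list(c(a = 1, b = 1)), 2))
  expect_warning(sel3 <- select_subensemble(arch_short, n_per_fold = 5),
                 "only")
  expect_equal(nrow(sel3$entries), 2)
})

test_that("parameter CV uses the sample standard deviation over the mean", {
  p1 <- network_params(chain_net(1, 1, 1))
  p2 <- network_params(chain_net(3, 1, 1))
  ens <- make_archive(list(p1, p2),
                      rep(list(c(a = 0, b = 0)), 2))
  cv <- parameter_cv(ens)
  expect_equal(unname(cv$cv[cv$parameter == "src"]), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(unname(cv$cv[cv$parameter == "conv"]), 0)
  ens_same <- make_archive(list(p1, p1), rep(list(c(a = 0, b = 0)), 2))
  expect_true(all(parameter_cv(ens_same)$cv == 0))
  expect_error(parameter_cv(make_archive(list(p1), list(c(a = 0, b = 0)))),
               "2 ensemble members")
})

test_that("random controls scatter log-uniformly within the stated decade", {
  p <- network_params(chain_net(1, 1, 1))
  set.seed(2)
  ctrl <- random_control_params(p, n = 500, decades = 1)
  ratios <- log10(vapply(ctrl, function(q) q$k[["src"]], numeric(1)))
  expect_true(all(ratios >= -1 & ratios <= 1))
  expect_lt(abs(mean(ratios)), 0.1)
  expect_true(all(vapply(ctrl, function(q) identical(q$x0, p$x0), logical(1))))
})
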