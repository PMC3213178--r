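test_that("forward sensitivities match the linear-decay closed form", {
  net <- decay_net(k = 0.8, x0 = 1)
  proto <- stim_protocol(stimulus_amount = 0, horizon = 5,
                         equilibrate = FALSE, label = "free")
  fld <- solve_sensitivities(net, network_params(net), proto,
                             t_grid = seq(0, 5, 0.25))
  got <- fld$s[, "A", "dec"]
  want <- -fld$times * exp(-0.8 * fld$times)
  expect_lt(max(abs(got - want)), 1e-5)
  expect_equal(got[1], 0)   # s(0) = 0 for rate-constant parameters
})

test_that("forward sensitivities match finite differences on a random network", {
  net <- random_network(8, 12, seed = 21)
  params <- network_params(net)
  proto <- stim_protocol(stimulus_amount = 0, horizon = 5,
                         equilibrate = FALSE, label = "free")
  grid <- seq(0, 5, 1)
  set.seed(2)
  subset_ids <- sample(net$reactions$id, 5)
  fld <- solve_sensitivities(net, params, proto, param_subset = subset_ids,
                             t_grid = grid, rtol = 1e-9, atol = 1e-11)
  for (pid in subset_ids) {
    h <- 1e-4 * params$k[[pid]]
    pp <- params; pp$k[[pid]] <- pp$k[[pid]] + h
    pm <- params; pm$k[[pid]] <- pm$k[[pid]] - h
    up <- integrate_network(net, pp, grid, rtol = 1e-10, atol = 1e-12)
    dn <- integrate_network(net, pm, grid, rtol = 1e-10, atol = 1e-12)
    fd <- (up$states - dn$states) / (2 * h)
    expect_lt(rel_err(fld$s[, , pid], fd), 1e-3)
  }
})

test_that("parameters decoupled from the trajectory have zero sensitivity", {
  # A -> B while isolated Z has a self-loop reaction that never fires
  net <- rxn_network(
    tibble::tibble(id = c("A", "B", "Z"), initial_amount = c(1, 0, 0)),
    tibble::tibble(id = c("ab", "zz"), rate_constant = c(1, 3),
                   reactants = list(c(A = 1), c(Z = 1)),
                   products = list(c(B = 1), no_species())))
  proto <- stim_protocol(stimulus_amount = 0, horizon = 5,
                         equilibrate = FALSE, label = "free")
  fld <- solve_sensitivities(net, network_params(net), proto,
                             t_grid = seq(0, 5, 1))
  expect_equal(max(abs(fld$s[, , "zz"])), 0)
  expect_gt(max(abs(fld$s[, , "ab"])), 0)
})

test_that("trapezoid time-averaging reproduces constants, ramps and quadrature", {
  mk_field <- function(times, svals, states = NULL) {
    n <- length(times)
    if (is.null(states)) states <- matrix(1, n, 1, dimnames = list(NULL, "A"))
    structure(list(times = times, states = states,
                   s = array(svals, c(n, 1, 1),
                             dimnames = list(NULL, "A", "k1")),
                   k = c(k1 = 1), species = "A", param_ids = "k1",
                   protocol_label = "t"), class = "sensitivity_field")
  }
  t <- seq(0, 10, 0.5)
  expect_equal(scale_and_time_average(mk_field(t, rep(3, length(t))))[1, 1], 3)
  expect_equal(scale_and_time_average(mk_field(t, 0.7 * t / 10))[1, 1], 0.35,
               tolerance = 1e-12)
  # random sampled curve vs dense quadrature of the same interpolant
  set.seed(4)
  f <- splinefun(seq(0, 10, 2), runif(6))
  coarse <- mk_field(t, f(t))
  got <- scale_and_time_average(coarse)[1, 1]
  dense_t <- seq(0, 10, 0.001)
  y <- approx(t, f(t), dense_t)$y
  oracle <- sum(diff(dense_t) * (head(y, -1) + y[-1]) / 2) / 10
  expect_equal(got, oracle, tolerance = 1e-6)
  # the log-scaling multiplies by k/x
  states <- matrix(2, length(t), 1, dimnames = list(NULL, "A"))
  fld <- mk_field(t, rep(3, length(t)), states)
  fld$k <- c(k1 = 4)
  expect_equal(scale_and_time_average(fld)[1, 1], 3 * 4 / 2)
  expect_error(scale_and_time_average(mk_field(t, t), window = c(2, 2)),
               "positive width")
})

test_that("SVD fragility scores match a direct recomputation", {
  # single dominant row -> that parameter scores 1 and tops the ranking
  A <- matrix(rnorm(5 * 12, sd = 0.001), 5, 12)
  A[3, ] <- 100
  arr <- structure(list(A = A, member_index = rep(1:2, each = 6),
                        species_index = rep(sprintf("s%d", 1:6), 2),
                        param_ids = sprintf("p%d", 1:5),
                        species = sprintf("s%d", 1:6)),
                   class = "sensitivity_array")
  rk <- svd_rank(arr, k_vectors = 1, threshold = 1e-3)
  expect_equal(rk$parameter_scores$score[3], 1)
  expect_equal(which.max(rk$parameter_scores$score), 3L)

  # identity array scores all indices equally
  rk_id <- svd_rank(diag(4), k_vectors = 4, threshold = 1e-3)
  expect_true(all(rk_id$parameter_scores$score ==
                    rk_id$parameter_scores$score[1]))

  # random array vs independent recomputation from a full SVD
  set.seed(8)
  M <- matrix(rnorm(20 * 30), 20, 30)
  arr2 <- structure(list(A = M, member_index = rep(1:3, each = 10),
                         species_index = rep(sprintf("s%d", 1:10), 3),
                         param_ids = sprintf("p%d", 1:20),
                         species = sprintf("s%d", 1:10)),
                    class = "sensitivity_array")
  rk2 <- svd_rank(arr2, k_vectors = 5, threshold = 1e-3)
  dec <- svd(M)
  for (pi in seq_len(20)) {
    frac <- mean(vapply(1:5, function(v) abs(dec$u[pi, v]) > 1e-3, logical(1)))
    expect_equal(rk2$parameter_scores$score[pi], frac)
  }
  for (si in seq_len(10)) {
    rows <- which(arr2$species_index == sprintf("s%d", si))
    frac <- mean(vapply(1:5, function(v) {
      any(abs(dec$v[rows, v]) > 1e-3)
    }, logical(1)))
    expect_equal(rk2$species_scores$score[si], frac)
  }
  expect_warning(svd_rank(arr2, k_vectors = 50), "clamp")
})

test_that("ranking is invariant to the order of ensemble members", {
  set.seed(12)
  mats <- lapply(1:4, function(i) {
    matrix(rnorm(6 * 5), 6, 5,
           dimnames = list(sprintf("s%d", 1:6), sprintf("p%d", 1:5)))
  })
  r1 <- svd_rank(assemble_sensitivity_array(mats), k_vectors = 3)
  r2 <- svd_rank(assemble_sensitivity_array(rev(mats)), k_vectors = 3)
  expect_equal(r1$species_scores[order(r1$species_scores$species), ],
               r2$species_scores[order(r2$species_scores$species), ])
  expect_equal(r1$parameter_scores, r2$parameter_scores)
})

test_that("ranking comparisons pair scores and detect universe mismatches", {
  bundle <- toy_bundle(noise_cv = 0, seed = 1)
  ens <- structure(list(
    entries = tibble::tibble(member = 1L, iteration = 0L, fold_id = 0L,
                             rank = 0L, errors = list(NULL),
                             params = list(bundle$truth_params)),
    trace = NULL, objective_ids = NULL, config = NULL, seed = 1L),
    class = "poets_archive")
  rk_ins <- sensitivity_ranking(bundle$network, ens,
                                bundle$protocols$insulin,
                                t_grid = seq(0, 40, 2))
  cmp_same <- ranking_comparison(rk_ins, rk_ins)
  expect_true(all(cmp_same$score_a == cmp_same$score_b))
  rk_other <- rk_ins
  rk_other$species <- rk_other$species[-1, ]
  expect_error(ranking_comparison(rk_ins, rk_other), "universes")
})
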