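mk_traj <- function(times, values, label = "t") {
  structure(list(times = times,
                 states = matrix(values, ncol = 1,
                                 dimnames = list(NULL, "M")),
                 protocol_label = label), class = "trajectory")
}

test_that("robustness coefficient is an integral ratio with exact null limit", {
  t <- seq(0, 10, 0.5)
  nominal <- mk_traj(t, 1 + sin(t))
  expect_equal(robustness_coefficient(nominal, nominal, "M"), 1,
               tolerance = 1e-12)
  doubled <- mk_traj(t, 2 * (1 + sin(t)))
  expect_equal(robustness_coefficient(doubled, nominal, "M"), 2,
               tolerance = 1e-12)
  # sampled curves vs a dense quadrature oracle
  set.seed(5)
  f1 <- splinefun(seq(0, 10, 2), runif(6, 0.5, 2))
  f2 <- splinefun(seq(0, 10, 2), runif(6, 0.5, 2))
  got <- robustness_coefficient(mk_traj(t, f1(t)), mk_traj(t, f2(t)), "M")
  dense <- seq(0, 10, 0.001)
  trap <- function(y) sum(diff(dense) * (head(y, -1) + y[-1]) / 2)
  oracle <- trap(approx(t, f1(t), dense)$y) / trap(approx(t, f2(t), dense)$y)
  expect_equal(got, oracle, tolerance = 1e-6)
  zero <- mk_traj(t, rep(0, length(t)))
  expect_error(robustness_coefficient(nominal, zero, "M"), "never produced")
  expect_error(robustness_coefficient(nominal, nominal, "X"), "not in trajectory")
})

test_that("null perturbations give coefficient 1 across random networks", {
  for (seed in 1:5) {
    net <- random_network(5, 7, seed = seed)
    p <- network_params(net)
    tr <- integrate_network(net, p, seq(0, 10, 1))
    expect_equal(robustness_coefficient(tr, tr, net$species$id[2]), 1,
                 tolerance = 1e-12)
  }
})

test_that("a target uncoupled from the marker leaves the coefficient at 1", {
  net <- rxn_network(
    tibble::tibble(id = c("A", "M", "Z"), initial_amount = c(1, 0, 1)),
    tibble::tibble(id = c("am", "zdec"), rate_constant = c(0.5, 1),
                   reactants = list(c(A = 1), c(Z = 1)),
                   products = list(c(M = 1), no_species())))
  proto <- list(free = stim_protocol(stimulus_amount = 0, horizon = 10,
                                     equilibrate = FALSE, label = "free"))
  screen <- knockdown_screen(net, list(network_params(net)),
                             targets = list("Z"), conditions = proto,
                             marker = "M", t_step = 1)
  expect_equal(screen$cells$coefficient, 1, tolerance = 1e-6)
  expect_equal(screen$summary$category, "none")
})

test_that("knocking the initiation-promoting branch lowers the 80S marker", {
  net <- build_toy_insulin_network()
  ens <- list(toy_truth_params())
  screen <- knockdown_screen(net, ens,
                             targets = list(PI3K = "PI3K",
                                            Rheb = c("RhebGDP", "RhebGTP")),
                             conditions = toy_protocols()["insulin"],
                             t_step = 2)
  med <- screen$summary$median
  names(med) <- screen$summary$target
  expect_lt(med[["PI3K"]], 1)
  expect_lt(med[["Rheb"]], 1)
  # one member: the histogram is a single spike at the coefficient
  expect_equal(dplyr::n_distinct(screen$cells$member), 1)
  expect_equal(screen$summary$median,
               screen$cells$coefficient[match(screen$summary$target,
                                              screen$cells$target)])
})

test_that("effect classification follows the documented thresholds", {
  expect_equal(classify_effect(rep(1, 5)), "none")
  expect_equal(classify_effect(rep(2.5, 5)), "increase")
  expect_equal(classify_effect(rep(0.25, 5)), "severe_decrease")  # closed boundary
  expect_equal(classify_effect(rep(0.5, 5)), "moderate_decrease")
  expect_equal(classify_effect(c(NA, NaN)), "undetermined")
  expect_equal(classify_effect(rep(1.05, 3)), "none")
  expect_equal(classify_effect(rep(1.2, 3), delta = 0.1), "increase")
})

test_that("subpopulation reports recover planted fold-change counts", {
  set.seed(6)
  coefs <- c(rep(2.5, 5), rep(1.2, 15), rep(0.8, 70), rep(0.4, 10))
  cells <- tibble::tibble(member = seq_along(coefs), target = "T",
                          condition = "c", coefficient = coefs,
                          failed = FALSE)
  screen <- structure(list(cells = cells, summary = NULL, marker = "M",
                           delta = 0.1, c_sev = 0.25),
                      class = "knockdown_screen")
  rep_t <- subpopulation_report(screen, "T")
  expect_equal(rep_t$n_twofold_up, 5)
  expect_equal(rep_t$n_increase, 20)
  expect_equal(rep_t$n_decrease, 80)
  expect_equal(rep_t$n_twofold_down, 10)
  expect_equal(rep_t$n_increase + rep_t$n_decrease, rep_t$n_members)
  expect_error(subpopulation_report(screen, "missing"), "not in screen")
})

test_that("category stability is reported across nested subsample sizes", {
  set.seed(7)
  # members 1..40 decrease, 41..80 increase: category flips as size grows
  coefs <- c(rep(0.5, 40), rep(3, 40))
  cells <- tibble::tibble(member = seq_along(coefs), target = "T",
                          condition = "c", coefficient = coefs,
                          failed = FALSE)
  screen <- structure(list(cells = cells, summary = NULL, marker = "M",
                           delta = 0.1, c_sev = 0.25),
                      class = "knockdown_screen")
  conv <- screen_convergence(screen, sizes = c(40, 80))
  expect_equal(nrow(conv), 2)
  expect_false(any(conv$stable))
  stable_cells <- cells
  stable_cells$coefficient <- rep(0.5, 80)
  screen2 <- structure(list(cells = stable_cells, summary = NULL,
                            marker = "M", delta = 0.1, c_sev = 0.25),
                       class = "knockdown_screen")
  expect_true(all(screen_convergence(screen2, sizes = c(40, 80))$stable))
})
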