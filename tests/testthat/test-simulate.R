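test_that("integration matches closed forms and detailed balance", {
  net <- decay_net(k = 1, x0 = 1)
  tr <- integrate_network(net, network_params(net), t_grid = c(0, 1),
                          rtol = 1e-9, atol = 1e-12)
  expect_equal(unname(tr$states[2, "A"]), exp(-1), tolerance = 1e-6)

  split <- split_reversible(ab_rev_net(kf = 2, kr = 1, a0 = 1, b0 = 0))
  tr2 <- integrate_network(split, network_params(split),
                           t_grid = seq(0, 30, 5))
  final <- tr2$states[nrow(tr2$states), ]
  expect_equal(unname(final["B"] / final["A"]), 2, tolerance = 1e-4)
})

test_that("stiff integration agrees with a tight-tolerance Runge-Kutta oracle", {
  net <- random_network(8, 12, seed = 4)
  params <- network_params(net)
  grid <- seq(0, 10, 1)
  tr <- integrate_network(net, params, grid, rtol = 1e-8, atol = 1e-10)
  cp <- net$compiled
  k <- as.numeric(params$k)
  oracle <- deSolve::ode(
    y = as.numeric(params$x0), times = grid,
    func = function(t, y, p) list(poetsim:::.ma_rhs(pmax(y, 0), k, cp$S,
                                                    cp$ri, cp$rj, cp$re)),
    parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$states - oracle[, -1])), 1e-5)
})

test_that("steady-state search satisfies its contract", {
  # closed-form balance: source k=1, sink k=2 -> x = 0.5
  net <- rxn_network(
    tibble::tibble(id = "A", initial_amount = 0),
    tibble::tibble(id = c("src", "snk"), rate_constant = c(1, 2),
                   reactants = list(no_species(), c(A = 1)),
                   products = list(c(A = 1), no_species())))
  ss <- find_steady_state(net, network_params(net))
  expect_equal(unname(ss["A"]), 0.5, tolerance = 1e-3)

  # starting exactly at the fixed point returns after one window
  p2 <- network_params(net)
  p2$x0["A"] <- 0.5
  ss2 <- find_steady_state(net, p2)
  expect_equal(attr(ss2, "windows"), 1)
  expect_equal(unname(ss2["A"]), 0.5, tolerance = 1e-6)

  # linear chain vs nullspace/linear-solve oracle: src k1, A->B k2, B-> k3
  cnet <- chain_net(k_in = 1.2, k_ab = 0.8, k_out = 2.5)
  ss3 <- find_steady_state(cnet, network_params(cnet))
  expect_equal(unname(ss3["A"]), 1.2 / 0.8, tolerance = 1e-3)
  expect_equal(unname(ss3["B"]), 1.2 / 2.5, tolerance = 1e-3)

  # residual shrinks with eps
  r_loose <- attr(find_steady_state(cnet, network_params(cnet), eps = 1e-2),
                  "residual")
  r_tight <- attr(find_steady_state(cnet, network_params(cnet), eps = 1e-4),
                  "residual")
  expect_lt(r_tight, r_loose)

  # non-convergence names the worst species
  growth <- rxn_network(
    tibble::tibble(id = "A", initial_amount = 1),
    tibble::tibble(id = "auto", rate_constant = 0.5,
                   reactants = list(c(A = 1)), products = list(c(A = 2))))
  expect_error(find_steady_state(growth, network_params(growth),
                                 max_windows = 20), "A")
})

test_that("protocols equilibrate, add the stimulus, and a null stimulus stays flat", {
  bundle_net <- build_toy_insulin_network()
  truth <- toy_truth_params()
  null_proto <- stim_protocol(stimulus_species = "Ins", stimulus_amount = 0,
                              horizon = 50, label = "null")
  tr <- simulate_protocol(bundle_net, truth, null_proto)
  drift <- max(abs(sweep(tr$states, 2, tr$states[1, ])))
  expect_lt(drift, 10 * 1e-3)

  # two-phase protocol equals one integration from the jumped state
  proto <- stim_protocol(stimulus_species = "Ins", stimulus_amount = 1,
                         horizon = 20, label = "ins")
  tr2 <- simulate_protocol(bundle_net, truth, proto)
  ss <- attr(tr2, "steady_state")
  x_jump <- as.numeric(ss)
  x_jump[bundle_net$species$id == "Ins"] <- x_jump[bundle_net$species$id == "Ins"] + 1
  direct <- integrate_network(bundle_net, truth, seq(0, 20, 1), x0 = x_jump)
  expect_equal(unname(tr2$states), unname(direct$states), tolerance = 1e-8)

  # downstream readout responds to the stimulus
  basal <- simulate_protocol(bundle_net, truth,
                             stim_protocol(stimulus_amount = 0, horizon = 50,
                                           label = "basal"))
  ins <- simulate_protocol(bundle_net, truth,
                           stim_protocol(stimulus_species = "Ins",
                                         stimulus_amount = 1, horizon = 50,
                                         label = "ins"))
  expect_gt(max(ins$states[, "Akta"]), max(basal$states[, "Akta"]))
})

test_that("trajectories stay nonnegative across random networks", {
  for (seed in 1:10) {
    net <- random_network(6, 9, seed = seed)
    tr <- integrate_network(net, network_params(net), seq(0, 20, 2))
    expect_true(min(tr$states) >= 0)
    expect_gte(attr(tr, "min_raw"), -1e-8)
  }
})

test_that("knockdown removes the node's reactions and is idempotent", {
  net <- build_toy_insulin_network()
  truth <- toy_truth_params()
  kd <- knockdown(net, truth, "PTEN")
  expect_false(any(vapply(kd$net$reactions$reactants,
                          function(v) "PTEN" %in% names(v), logical(1))))
  expect_equal(unname(kd$params$x0["PTEN"]), 0)
  expect_lt(nrow(kd$net$reactions), nrow(net$reactions))
  kd2 <- knockdown(kd$net, kd$params, "PTEN")
  expect_equal(tidy(kd2$net), tidy(kd$net))
  expect_error(knockdown(net, truth, "NOPE"), "unknown")

  # chain A -> B -> C, knocking B severs C from its source
  cnet <- rxn_network(
    tibble::tibble(id = c("A", "B", "C"), initial_amount = c(1, 0, 0.2)),
    tibble::tibble(id = c("ab", "bc"), rate_constant = c(1, 1),
                   reactants = list(c(A = 1), c(B = 1)),
                   products = list(c(B = 1), c(C = 1))))
  kd3 <- knockdown(cnet, network_params(cnet), "B")
  tr <- integrate_network(kd3$net, kd3$params, seq(0, 10, 1))
  expect_equal(unname(tr$states[, "C"]), rep(0.2, 11), tolerance = 1e-10)

  # knocking down an isolated species leaves all other trajectories intact
  iso <- rxn_network(
    dplyr::bind_rows(cnet$species, tibble::tibble(id = "Z", initial_amount = 1)),
    cnet$reactions)
  kd4 <- knockdown(iso, network_params(iso), "Z")
  tr_iso <- integrate_network(iso, network_params(iso), seq(0, 5, 1))
  tr_kd <- integrate_network(kd4$net, kd4$params, seq(0, 5, 1))
  expect_equal(tr_kd$states[, c("A", "B", "C")],
               tr_iso$states[, c("A", "B", "C")], tolerance = 1e-10)
})

test_that("a screen issues one perturbed simulation per target and condition", {
  net <- build_toy_insulin_network()
  targets <- as.list(c("PTEN", "PI3K", "S6K1", "RhebGDP", "TSC"))
  screen <- knockdown_screen(net, list(toy_truth_params()), targets,
                             conditions = toy_protocols()["basal"],
                             t_step = 5)
  expect_equal(nrow(screen$cells), length(targets))
  expect_equal(sort(unique(screen$cells$target)), sort(unlist(targets)))
})
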