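# Synthetic study system: a reduced insulin -> PI3K/Akt/mTOR -> translation
# initiation network (~29 species), ground-truth kinetics, stimulus and
# inhibitor protocols, and pseudo-immunoblot training objectives. This is
# the desk-scale stand-in for the full literature-derived interactome: the
# motifs (receptor activation, IRS-1 adaptor, PIP2/PIP3 cycling opposed by
# PTEN, Akt -> TSC1/2 -> Rheb -> mTORC1, mTORC2, S6K1 negative feedback on
# IRS-1, 4E-BP1 sequestration of eIF4E, GTP-consuming 80S assembly) are
# the pathway's, the rate constants are hand-tuned once and frozen.

toy_reaction_table <- function() {
  rxn <- function(id, k, reactants, products) {
    tibble(id = id, rate_constant = k, rate_constant_rev = NA_real_,
           reversible = FALSE, reactants = list(reactants),
           products = list(products))
  }
  none <- setNames(numeric(0), character(0))
  dplyr::bind_rows(
    rxn("bind",          2,    c(Ins = 1, IR = 1),      c(IRa = 1)),
    rxn("rec_deact",     0.2,  c(IRa = 1),              c(IR = 1)),
    rxn("irs_act",       2,    c(IRa = 1, IRS1 = 1),    c(IRa = 1, IRS1a = 1)),
    rxn("irs_deact",     0.3,  c(IRS1a = 1),            c(IRS1 = 1)),
    rxn("pi3k_act",      2,    c(IRS1a = 1, PI3K = 1),  c(IRS1a = 1, PI3Ka = 1)),
    rxn("pi3k_basal",    0.02, c(PI3K = 1),             c(PI3Ka = 1)),
    rxn("pi3k_deact",    0.5,  c(PI3Ka = 1),            c(PI3K = 1)),
    rxn("pip3_form",     2,    c(PI3Ka = 1, PIP2 = 1),  c(PI3Ka = 1, PIP3 = 1)),
    rxn("pip3_deg",      4,    c(PTEN = 1, PIP3 = 1),   c(PTEN = 1, PIP2 = 1)),
    rxn("akt_act",       2,    c(PIP3 = 1, Akt = 1),    c(PIP3 = 1, Akta = 1)),
    rxn("akt_deact",     1,    c(Akta = 1),             c(Akt = 1)),
    rxn("mtorc2_act",    2,    c(PIP3 = 1, mTORC2 = 1), c(PIP3 = 1, mTORC2a = 1)),
    rxn("mtorc2_deact",  0.2,  c(mTORC2a = 1),          c(mTORC2 = 1)),
    rxn("akt_act2",      0.5,  c(mTORC2a = 1, Akt = 1), c(mTORC2a = 1, Akta = 1)),
    rxn("tsc_inh",       4,    c(Akta = 1, TSC = 1),    c(Akta = 1, TSCi = 1)),
    rxn("tsc_react",     0.5,  c(TSCi = 1),             c(TSC = 1)),
    rxn("rheb_load",     0.5,  c(RhebGDP = 1, GTP = 1), c(RhebGTP = 1)),
    rxn("rheb_gap",      3,    c(TSC = 1, RhebGTP = 1), c(TSC = 1, RhebGDP = 1)),
    rxn("rheb_hyd",      0.02, c(RhebGTP = 1),          c(RhebGDP = 1)),
    rxn("mtorc1_act",    4,    c(RhebGTP = 1, mTORC1 = 1),
                               c(RhebGTP = 1, mTORC1a = 1)),
    rxn("mtorc1_deact",  0.6,  c(mTORC1a = 1),          c(mTORC1 = 1)),
    rxn("s6k_act",       2,    c(mTORC1a = 1, S6K1 = 1),
                               c(mTORC1a = 1, S6K1a = 1)),
    rxn("s6k_deact",     0.5,  c(S6K1a = 1),            c(S6K1 = 1)),
    rxn("irs_fb",        1,    c(S6K1a = 1, IRS1a = 1), c(S6K1a = 1, IRS1i = 1)),
    rxn("irs_fb_rec",    0.2,  c(IRS1i = 1),            c(IRS1 = 1)),
    rxn("bp1_phos",      3,    c(mTORC1a = 1, E4EBP = 1),
                               c(mTORC1a = 1, eIF4E = 1, p4EBP = 1)),
    rxn("bp1_phos2",     1,    c(mTORC2a = 1, E4EBP = 1),
                               c(mTORC2a = 1, eIF4E = 1, p4EBP = 1)),
    rxn("bp1_dephos",    0.8,  c(p4EBP = 1),            c(BP1 = 1)),
    rxn("seq",           20,   c(BP1 = 1, eIF4E = 1),   c(E4EBP = 1)),
    rxn("basal_rel",     0.02, c(E4EBP = 1),            c(eIF4E = 1, BP1 = 1)),
    rxn("assembly",      2,    c(eIF4E = 1, GTP = 2),   c(eIF4E = 1, GTP = 1, R80S = 1)),
    rxn("r80s_decay",    0.5,  c(R80S = 1),             none),
    rxn("gtp_deg",       0.5,  c(GTP = 1),              none),
    rxn("gtp_syn",       0.5,  none,                    c(GTP = 1))
  )
}

toy_species_table <- function() {
  tibble(
    id = c("Ins", "IR", "IRa", "IRS1", "IRS1a", "IRS1i", "PI3K", "PI3Ka",
           "PIP2", "PIP3", "PTEN", "Akt", "Akta", "mTORC2", "mTORC2a",
           "TSC", "TSCi", "RhebGDP", "RhebGTP", "GTP", "mTORC1", "mTORC1a",
           "S6K1", "S6K1a", "E4EBP", "eIF4E", "p4EBP", "BP1", "R80S"),
    initial_amount = c(0, 1, 0, 1, 0, 0, 1, 0,
                       1, 0, 0.5, 1, 0, 1, 0,
                       0.8, 0, 1, 0, 1, 1, 0,
                       1, 0, 0.5, 0.05, 0, 0.6, 0)
  )
}

#' Reduced insulin translation-initiation network
#'
#' Builds the deterministic ~29-species toy network: insulin/receptor
#' binding, IRS-1 adaptor activation, PI3K and basal PI3K activity,
#' PIP2/PIP3 interconversion opposed by PTEN, Akt activation (by PIP3 and
#' by mTORC2), Akt inhibition of the TSC1/2 GAP, Rheb GDP/GTP cycling
#' whose loading consumes a finite GTP pool, Rheb-GTP activation of
#' mTORC1, S6K1 activation, the removable S6K1 -> IRS-1 negative feedback,
#' mTORC1 phosphorylation of 4E-BP1 releasing eIF4E from its sequestering
#' complex, and eIF4E-dependent, GTP-consuming assembly of an 80S proxy
#' (`R80S`), the translation-initiation marker.
#'
#' @return an irreversible `rxn_network`
#' @export
build_toy_insulin_network <- function() {
  rxn_network(toy_species_table(), toy_reaction_table())
}

#' Ground-truth parameters of the toy network
#'
#' The frozen hand-tuned kinetics. The `"strong_rheb_gtp"` variant raises
#' the Rheb-GTP association constant so that Rheb cycling drains the GTP
#' pool — the regime in which a Rheb knockdown paradoxically *increases*
#' initiation by releasing GTP for 80S assembly.
#'
#' @param variant `"nominal"` or `"strong_rheb_gtp"`
#' @return a `param_vec` for [build_toy_insulin_network()]
#' @export
toy_truth_params <- function(variant = c("nominal", "strong_rheb_gtp")) {
  variant <- match.arg(variant)
  p <- network_params(build_toy_insulin_network())
  if (variant == "strong_rheb_gtp") {
    p$k[["rheb_load"]] <- 12
  }
  p
}

#' Stimulus and inhibitor protocols for the toy network
#'
#' Seven conditions: unstimulated basal, saturating and sub-saturating
#' insulin doses, insulin with a PI3K-inhibitor analogue (PI3K activation
#' rates zeroed, wortmannin style), insulin with an mTORC1-inhibitor
#' analogue (mTORC1 activation zeroed, rapamycin style), and
#' insulin/basal with the S6K1 -> IRS-1 feedback switched off.
#'
#' @param insulin_amount stimulus amount added to `Ins` at time 0
#' @param horizon simulation horizon (minutes)
#' @return named list of [stim_protocol()]
#' @export
toy_protocols <- function(insulin_amount = 1, horizon = 100) {
  ins <- function(label, zero = character(0)) {
    stim_protocol(stimulus_species = "Ins", stimulus_amount = insulin_amount,
                  horizon = horizon, zero_rates = zero, label = label)
  }
  list(
    basal = stim_protocol(stimulus_amount = 0, horizon = horizon,
                          label = "basal"),
    insulin = ins("insulin"),
    insulin_low = stim_protocol(stimulus_species = "Ins",
                                stimulus_amount = insulin_amount * 0.3,
                                horizon = horizon, label = "insulin_low"),
    insulin_pi3k_inhibitor = ins("insulin_pi3k_inhibitor",
                                 c("pi3k_act", "pi3k_basal")),
    insulin_mtorc1_inhibitor = ins("insulin_mtorc1_inhibitor", "mtorc1_act"),
    insulin_no_feedback = ins("insulin_no_feedback", "irs_fb"),
    basal_no_feedback = stim_protocol(stimulus_amount = 0, horizon = horizon,
                                      zero_rates = "irs_fb",
                                      label = "basal_no_feedback")
  )
}

toy_readouts <- function() {
  list(pAkt = "Akta", pS6K1 = "S6K1a", p4EBP1 = "p4EBP", r80S = "R80S")
}

#' Generate pseudo-immunoblot training objectives
#'
#' Simulates the toy network with the supplied (truth) parameters and
#' turns the readouts into 24 noisy objectives shaped like an immunoblot
#' training table: 20 time-course objectives (4 phospho/assembly readouts
#' under 5 stimulated conditions, 7 time points over 100 min) and 4
#' condition-bar objectives (each readout compared across all 7 conditions,
#' including the unstimulated basal controls, at 60 min). Every objective
#' carries dynamic or cross-condition signal; flat noise-only series are
#' deliberately absent, mirroring a training table of informative
#' measurements.
#' Raw values are the simulated readout times multiplicative lognormal
#' noise with coefficient of variation `noise_cv`; `noise_cv = 0` returns
#' exact data (truth parameters then score < 1e-6 on every objective).
#'
#' @param net the toy network
#' @param params ground-truth `param_vec`
#' @param protocols protocol list from [toy_protocols()]
#' @param noise_cv multiplicative noise CV (immunoblot quantitation error)
#' @param seed RNG seed for the noise
#' @param times time-course sampling grid (minutes)
#' @param bar_time the single comparison time of the bar objectives
#' @return list of [objective_series()] (length 24)
#' @export
generate_objectives <- function(net, params, protocols, noise_cv = 0.1,
                                seed = 1L,
                                times = c(0, 5, 10, 20, 40, 60, 100),
                                bar_time = 60) {
  set.seed(seed)
  readouts <- toy_readouts()
  tc_conditions <- c("insulin", "insulin_low", "insulin_pi3k_inhibitor",
                     "insulin_mtorc1_inhibitor", "insulin_no_feedback")
  sims <- lapply(protocols, function(pr) {
    simulate_protocol(net, params, pr, t_step = 1)
  })
  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(v) {
    if (noise_cv == 0) return(v)
    v * rlnorm(length(v), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  objectives <- list()
  i <- 0L
  for (cn in tc_conditions) {
    for (rn in names(readouts)) {
      i <- i + 1L
      vals <- readout_values(sims[[cn]], readouts[[rn]], times)
      objectives[[i]] <- objective_series(
        objective_id = sprintf("O%02d", i),
        readout = readouts[[rn]], protocol = cn,
        times = times, values = noisy(vals), kind = "timecourse")
    }
  }
  bar_conditions <- names(protocols)
  for (rn in names(readouts)) {
    i <- i + 1L
    vals <- vapply(bar_conditions, function(cn) {
      readout_values(sims[[cn]], readouts[[rn]], bar_time)
    }, numeric(1))
    objectives[[i]] <- objective_series(
      objective_id = sprintf("O%02d", i),
      readout = readouts[[rn]], protocol = bar_conditions,
      times = bar_time, values = noisy(vals), kind = "bars")
  }
  objectives
}

#' Assemble the complete toy study bundle
#'
#' Network, frozen truth parameters, the six protocols, and the 24 noisy
#' training objectives, with the seed recorded. The bundle is what the
#' estimation and interrogation pipeline consumes end to end.
#'
#' @inheritParams generate_objectives
#' @param variant truth-parameter variant (see [toy_truth_params()])
#' @param insulin_amount stimulus amount
#' @return a `toy_bundle` list: `network`, `truth_params`, `protocols`,
#'   `objectives`, `noise_cv`, `seed`
#' @export
toy_bundle <- function(noise_cv = 0.1, seed = 1L,
                       variant = "nominal", insulin_amount = 1) {
  net <- build_toy_insulin_network()
  truth <- toy_truth_params(variant)
  protocols <- toy_protocols(insulin_amount = insulin_amount)
  objectives <- generate_objectives(net, truth, protocols,
                                    noise_cv = noise_cv, seed = seed)
  structure(list(network = net, truth_params = truth, protocols = protocols,
                 objectives = objectives, noise_cv = noise_cv, seed = seed),
            class = "toy_bundle")
}

#' @export
print.toy_bundle <- function(x, ...) {
  cat("<toy_bundle> ", nrow(x$network$species), " species, ",
      nrow(x$network$reactions), " reactions, ",
      length(x$objectives), " objectives (noise cv ", x$noise_cv,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a toy bundle to disk in pipeline formats
#'
#' Network as plain text and SBML, truth parameters as CSV, objectives as
#' YAML plus one CSV of (time, value) pairs per objective — exactly the
#' formats the pipeline stages consume.
#'
#' @param bundle a `toy_bundle`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_toy_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(bundle$network, file.path(dir, "network.txt"), "text")
  write_network(bundle$network, file.path(dir, "network.xml"), "sbml")
  tp <- bundle$truth_params
  write.csv(data.frame(parameter = c(names(tp$k), names(tp$x0)),
                       type = rep(c("rate_constant", "initial_condition"),
                                  c(length(tp$k), length(tp$x0))),
                       value = c(unname(tp$k), unname(tp$x0))),
            file.path(dir, "truth_params.csv"), row.names = FALSE)
  obj_dir <- file.path(dir, "objectives")
  dir.create(obj_dir, showWarnings = FALSE)
  meta <- lapply(bundle$objectives, function(ob) {
    csv <- file.path(obj_dir, paste0(ob$objective_id, ".csv"))
    if (ob$kind == "timecourse") {
      write.csv(data.frame(time = ob$times, value = ob$values), csv,
                row.names = FALSE)
    } else {
      write.csv(data.frame(protocol = ob$protocol, time = ob$times,
                           value = ob$values), csv, row.names = FALSE)
    }
    list(id = ob$objective_id, readout = as.list(ob$readout),
         protocol = as.list(ob$protocol), kind = ob$kind,
         data = basename(csv))
  })
  yaml::write_yaml(list(objectives = meta), file.path(dir, "objectives.yaml"))
  invisible(dir)
}

#' Read objectives written by [write_toy_bundle()]
#'
#' @param dir bundle directory containing `objectives.yaml`
#' @return list of [objective_series()]
#' @export
read_objectives <- function(dir) {
  spec <- yaml::read_yaml(file.path(dir, "objectives.yaml"))
  lapply(spec$objectives, function(m) {
    d <- read.csv(file.path(dir, "objectives", m$data))
    objective_series(m$id, unlist(m$readout), unlist(m$protocol),
                     if (m$kind == "bars") unique(d$time) else d$time,
                     d$value, m$kind)
  })
}

#' Random mass-action network for property tests
#'
#' Builds a connected random network: a conversion chain linking all
#' species, then extra random uni/bimolecular reactions with positive
#' random rate constants. In `closed` mode every reaction conserves
#' molecule count, so all stoichiometric-matrix columns sum to zero and
#' total concentration is invariant.
#'
#' @param n_species,n_reactions network size; `n_reactions` must be at
#'   least `n_species - 1` so the chain can connect every species
#' @param seed RNG seed
#' @param closed generate only count-conserving conversions?
#' @return an irreversible `rxn_network`
#' @export
random_network <- function(n_species, n_reactions, seed = 1L,
                           closed = FALSE) {
  if (n_reactions < 1) abort("need at least one reaction")
  if (n_species < 2) abort("need at least two species")
  if (n_reactions < n_species - 1) {
    abort("n_reactions must be >= n_species - 1 for a connected network")
  }
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_species))
  rows <- list()
  for (j in seq_len(n_species - 1)) {
    rows[[j]] <- tibble(id = sprintf("r%03d", j),
                        rate_constant = rlnorm(1, 0, 0.5),
                        rate_constant_rev = NA_real_, reversible = FALSE,
                        reactants = list(setNames(1, ids[j])),
                        products = list(setNames(1, ids[j + 1])))
  }
  for (j in seq(n_species, length.out = n_reactions - (n_species - 1))) {
    n_re <- sample(1:2, 1)
    re_sp <- sample(ids, n_re)
    n_pr <- if (closed) n_re else sample(1:2, 1)
    pr_sp <- sample(ids, n_pr)
    if (setequal(pr_sp, re_sp)) {
      pr_sp[1] <- ids[(match(pr_sp[1], ids) %% n_species) + 1L]
      pr_sp <- unique(pr_sp)
    }
    rows[[j]] <- tibble(id = sprintf("r%03d", j),
                        rate_constant = rlnorm(1, 0, 0.5),
                        rate_constant_rev = NA_real_, reversible = FALSE,
                        reactants = list(setNames(rep(1, n_re), re_sp)),
                        products = list(setNames(rep(1, length(pr_sp)), pr_sp)))
  }
  species <- tibble(id = ids, initial_amount = runif(n_species, 0.1, 1))
  rxn_network(species, dplyr::bind_rows(rows))
}

#' End-to-end parameter-recovery experiment on the toy bundle
#'
#' Runs POETs (reduced budget) on the bundle's noisy objectives starting
#' from a jittered copy of the truth, selects a low-correlation rank-0
#' sub-ensemble across the requested cross-validation folds, and reports:
#' per-rate-constant truth coverage by the sub-ensemble percentile
#' interval; per-objective trained errors (sub-ensemble mean) against a
#' random-parameter control (mean over log-uniform draws within one
#' decade of truth — the ensemble-vs-random table convention); held-out
#' validation errors per fold; and the qualitative knockdown switch table
#' (PTEN knockdown under basal conditions, PI3K knockdown under insulin).
#' Objectives whose truth dynamics are flat under their condition score
#' zero for any parameters; a 0-0 tie counts as not worse than random.
#'
#' @param bundle a [toy_bundle()]
#' @param config a [poets_config()] (the iteration budget)
#' @param seed integer seed controlling folds, POETs and controls
#' @param folds which fold ids to run (default `1:2`; all eight at full
#'   budget)
#' @param n_per_fold sub-ensemble members per fold
#' @param interval coverage percentile interval (default 5th-95th)
#' @param n_controls random control parameter sets
#' @param init_jitter multiplicative jitter applied to truth to form the
#'   starting candidate
#' @return a `recovery_report` list; see Details
#' @export
recovery_experiment <- function(bundle, config = poets_config(),
                                seed = 1L, folds = 1:2, n_per_fold = 50,
                                interval = c(0.05, 0.95), n_controls = 10,
                                init_jitter = 0.5) {
  net <- bundle$network
  truth <- bundle$truth_params
  obj_ids <- vapply(bundle$objectives, `[[`, character(1), "objective_id")
  set.seed(seed)
  cv <- make_cv_folds(obj_ids, holdout = 3)
  init <- truth
  init$k <- init$k * runif(length(init$k), 1 - init_jitter, 1 + init_jitter)

  archives <- list()
  validation <- list()
  for (f in folds) {
    fold <- cv[[f]]
    train_obj <- bundle$objectives[obj_ids %in% fold$train_ids]
    arch <- run_poets(net, train_obj, bundle$protocols, init,
                      config = config, seed = seed + f, fold_id = f)
    archives[[length(archives) + 1L]] <- arch
    val_obj <- bundle$objectives[obj_ids %in% fold$validation_ids]
    best <- arch$entries[arch$entries$rank == 0, ]
    val_err <- vapply(seq_along(val_obj), function(i) {
      errs <- vapply(head(best$params, 10), function(p) {
        evaluate_single_objective(net, p, val_obj[[i]], bundle$protocols,
                                  t_step = config$t_step)
      }, numeric(1))
      median(errs)
    }, numeric(1))
    validation[[length(validation) + 1L]] <- tibble(
      fold_id = f, objective_id = fold$validation_ids,
      median_error = val_err)
  }
  sub <- select_subensemble(archives, n_per_fold = n_per_fold)

  K <- do.call(cbind, lapply(sub$entries$params, `[[`, "k"))
  qs <- apply(K, 1, quantile, probs = interval)
  coverage <- tibble(parameter = rownames(K),
                     truth = unname(truth$k[rownames(K)]),
                     lo = qs[1, ], hi = qs[2, ]) |>
    dplyr::mutate(covered = .data$truth >= .data$lo & .data$truth <= .data$hi)

  controls <- random_control_params(truth, n = n_controls, decades = 1)
  ctrl_err <- sapply(controls, function(p) {
    evaluate_objectives(net, p, bundle$objectives, bundle$protocols,
                        t_step = config$t_step)
  })
  trained_err <- sapply(sub$entries$params, function(p) {
    evaluate_objectives(net, p, bundle$objectives, bundle$protocols,
                        t_step = config$t_step)
  })
  obj_comparison <- tibble(
    objective_id = obj_ids,
    trained_error = apply(trained_err, 1, function(e) mean(e[is.finite(e)])),
    random_error = apply(ctrl_err, 1, function(e) mean(e[is.finite(e)])),
  ) |>
    dplyr::mutate(trained_beats_random = .data$trained_error < .data$random_error |
                    (.data$trained_error == 0 & .data$random_error == 0))

  switch_members <- head(sub$entries$params, 10)
  switch_table <- dplyr::bind_rows(
    toy_switch_row(net, switch_members, "PTEN", "basal", "increase",
                   bundle$protocols),
    toy_switch_row(net, switch_members, "PI3K", "insulin", "partial_decrease",
                   bundle$protocols))

  structure(list(coverage = coverage,
                 coverage_fraction = mean(coverage$covered),
                 objective_comparison = obj_comparison,
                 validation = dplyr::bind_rows(validation),
                 switch_table = switch_table,
                 subensemble = sub,
                 mean_pairwise_correlation =
                   attr(sub, "mean_pairwise_correlation"),
                 seed = seed),
            class = "recovery_report")
}

toy_switch_row <- function(net, params_list, target, condition, expected,
                           protocols) {
  coefs <- vapply(params_list, function(p) {
    nominal <- simulate_protocol(net, p, protocols[[condition]], t_step = 2)
    proto_kd <- protocols[[condition]]
    proto_kd$knockdowns <- target
    pert <- simulate_protocol(net, p, proto_kd, t_step = 2)
    robustness_coefficient(pert, nominal, "R80S")
  }, numeric(1))
  m <- median(coefs)
  ok <- switch(expected,
               increase = m > 1,
               partial_decrease = m < 1 && m > 0,
               NA)
  tibble(perturbation = target, condition = condition,
         median_coefficient = m, expected = expected, ok = ok)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n  truth coverage: ",
      round(100 * x$coverage_fraction, 1), "% of rate constants in the [",
      "5th, 95th] sub-ensemble interval\n  trained beats random on ",
      sum(x$objective_comparison$trained_beats_random), "/",
      nrow(x$objective_comparison), " objectives\n", sep = "")
  print(x$switch_table)
  invisible(x)
}

#' @export
glance.recovery_report <- function(x, ...) {
  tibble(coverage_fraction = x$coverage_fraction,
         n_trained_beats_random = sum(x$objective_comparison$trained_beats_random),
         n_objectives = nrow(x$objective_comparison),
         mean_pairwise_correlation = x$mean_pairwise_correlation,
         switch_ok = all(x$switch_table$ok))
}
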