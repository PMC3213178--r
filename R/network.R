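#' Reaction networks under mass-action kinetics
#'
#' A `rxn_network` represents a biochemical reaction network: an ordered set
#' of species, an ordered set of (possibly reversible) reactions with
#' mass-action rate constants, and the signed stoichiometric matrix `S`
#' (species x reactions). The model equations are `dx/dt = S r(x, k)` with
#' `r_j(x, k) = k_j * prod_s x_s^sigma_sj` over the reactants of reaction `j`.
#'
#' @param species a data frame with columns `id` (unique character),
#'   `initial_amount` (>= 0) and optionally `name`, `compartment`.
#' @param reactions a data frame with columns `id`, `rate_constant`,
#'   `reversible` (logical), `rate_constant_rev` (reverse-rate constant, `NA`
#'   for irreversible reactions) and list-columns `reactants`, `products`,
#'   each element a named numeric vector of stoichiometric coefficients
#'   (e.g. `c(A = 1, B = 2)`; empty vectors are allowed for sources/sinks).
#'
#' @return an object of class `rxn_network` with elements `species`
#'   (tibble), `reactions` (tibble), `S` (integer matrix) and a compiled
#'   kinetic form used by the solvers.
#' @export
rxn_network <- function(species, reactions) {
  species <- as_tibble(species)
  if (!all(c("id", "initial_amount") %in% names(species))) {
    abort("`species` needs columns `id` and `initial_amount`")
  }
  if (anyDuplicated(species$id)) {
    abort(paste0("duplicate species id: ",
                 paste(unique(species$id[duplicated(species$id)]), collapse = ", ")))
  }
  if (any(species$initial_amount < 0)) abort("initial amounts must be >= 0")
  if (!"name" %in% names(species)) species$name <- species$id
  if (!"compartment" %in% names(species)) species$compartment <- "cell"
  species <- species[, c("id", "name", "initial_amount", "compartment")]

  reactions <- as_tibble(reactions)
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  if (!"rate_constant_rev" %in% names(reactions)) {
    reactions$rate_constant_rev <- NA_real_
  }
  if (anyDuplicated(reactions$id)) abort("duplicate reaction ids")
  if (any(reactions$rate_constant < 0, na.rm = TRUE)) {
    abort("rate constants must be >= 0")
  }
  for (side in c("reactants", "products")) {
    bad <- vapply(reactions[[side]], function(v) {
      length(v) > 0 && (is.null(names(v)) || any(!names(v) %in% species$id) ||
                          any(v < 1) || any(v != round(v)))
    }, logical(1))
    if (any(bad)) {
      abort(paste0("reaction ", reactions$id[which(bad)[1]], ": ", side,
                   " must be named integer coefficients >= 1 over known species"))
    }
  }
  net <- structure(list(species = species, reactions = reactions),
                   class = "rxn_network")
  recompile_network(net)
}

#' @export
print.rxn_network <- function(x, ...) {
  cat("<rxn_network> ", nrow(x$species), " species, ", nrow(x$reactions),
      " reactions (", sum(x$reactions$reversible), " reversible)\n", sep = "")
  invisible(x)
}

# Rebuild S and the flat (species, reaction, exponent) incidence arrays the
# C++ kernels consume. Reversible reactions contribute a single signed column
# of S; they must be split before simulation.
recompile_network <- function(net) {
  sp_ids <- net$species$id
  n_sp <- length(sp_ids)
  n_rxn <- nrow(net$reactions)
  S <- matrix(0L, n_sp, n_rxn, dimnames = list(sp_ids, net$reactions$id))
  for (j in seq_len(n_rxn)) {
    for (v in list(-1L * net$reactions$reactants[[j]], net$reactions$products[[j]])) {
      if (length(v)) S[names(v), j] <- S[names(v), j] + as.integer(v)
    }
  }
  ri <- integer(0); rj <- integer(0); re <- numeric(0)
  for (j in seq_len(n_rxn)) {
    v <- net$reactions$reactants[[j]]
    if (length(v)) {
      ri <- c(ri, match(names(v), sp_ids) - 1L)
      rj <- c(rj, rep(j - 1L, length(v)))
      re <- c(re, unname(v))
    }
  }
  net$S <- S
  net$compiled <- list(ri = ri, rj = rj, re = re,
                       S = matrix(as.numeric(S), n_sp, n_rxn))
  net
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reversible reaction `A <-> B` with constants `(kf, kr)` is replaced
#' by two irreversible reactions `A -> B` (rate `kf`) and `B -> A` (rate
#' `kr`) with independent rate constants; irreversible reactions pass
#' through unchanged. The operation is idempotent.
#'
#' @param net a [rxn_network()]
#' @return a `rxn_network` with no reversible reactions
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "rxn_network"))
  if (!any(net$reactions$reversible)) return(net)
  rows <- vector("list", nrow(net$reactions))
  for (j in seq_len(nrow(net$reactions))) {
    r <- net$reactions[j, ]
    if (!r$reversible) {
      rows[[j]] <- r
    } else {
      fwd <- r
      fwd$reversible <- FALSE
      fwd$rate_constant_rev <- NA_real_
      rev <- fwd
      rev$id <- paste0(r$id, "_rev")
      rev$rate_constant <- r$rate_constant_rev
      rev$reactants <- r$products
      rev$products <- r$reactants
      rows[[j]] <- dplyr::bind_rows(fwd, rev)
    }
  }
  rxn_network(net$species, dplyr::bind_rows(rows))
}

#' Mass-action rate of a single reaction
#'
#' Returns `k * prod_s x_s^sigma_s` over the reaction's reactants; a
#' zeroth-order source returns `k`.
#'
#' @param reactants named numeric vector of reactant coefficients (may be
#'   empty)
#' @param k rate constant
#' @param x named concentration vector covering the reactant species
#' @export
massaction_rate <- function(reactants, k, x) {
  if (any(x < 0)) abort("negative concentration")
  if (!length(reactants)) return(k)
  k * prod(x[names(reactants)]^reactants)
}

#' Right-hand side of the network ODEs
#'
#' @param net a `rxn_network` with no reversible reactions
#' @param x concentration vector in species order
#' @param k rate-constant vector in reaction order (defaults to the network's
#'   nominal constants)
#' @return `dx/dt = S r(x, k)`, named by species
#' @export
network_rhs <- function(net, x, k = net$reactions$rate_constant) {
  check_irreversible(net)
  if (length(x) != nrow(net$species) || length(k) != nrow(net$reactions)) {
    abort("dimension mismatch between x/k and the network")
  }
  cp <- net$compiled
  setNames(as.numeric(.ma_rhs(as.numeric(x), as.numeric(k), cp$S,
                              cp$ri, cp$rj, cp$re)),
           net$species$id)
}

#' Reaction rate vector at a state
#' @inheritParams network_rhs
#' @return rates named by reaction id
#' @export
network_rates <- function(net, x, k = net$reactions$rate_constant) {
  check_irreversible(net)
  cp <- net$compiled
  setNames(as.numeric(.ma_rates(as.numeric(x), as.numeric(k),
                                cp$ri, cp$rj, cp$re)),
           net$reactions$id)
}

#' Analytical Jacobian and parameter-derivative matrices
#'
#' Evaluates `J = d(S r)/dx` (n_species x n_species) and
#' `B = d(S r)/dk` (n_species x n_reactions) analytically at `(x, k)`.
#' These feed the stiff integrator and the forward sensitivity equations.
#'
#' @inheritParams network_rhs
#' @return list with elements `J`, `B` and `rates`
#' @export
network_jacobian <- function(net, x, k = net$reactions$rate_constant) {
  check_irreversible(net)
  cp <- net$compiled
  out <- .ma_jac_dfdk(as.numeric(x), as.numeric(k), cp$S,
                      cp$ri, cp$rj, cp$re, TRUE, TRUE)
  dimnames(out$J) <- list(net$species$id, net$species$id)
  dimnames(out$B) <- list(net$species$id, net$reactions$id)
  out
}

check_irreversible <- function(net) {
  if (any(net$reactions$reversible)) {
    abort("network contains reversible reactions; call split_reversible() first")
  }
  invisible(net)
}

#' Nominal parameter vector of a network
#'
#' The full unknown-parameter vector of a mass-action model is the
#' concatenation of the reaction rate constants and the species initial
#' conditions, in network order.
#'
#' @param net a `rxn_network`
#' @return a `param_vec`: list with named numeric `k` (rates) and `x0`
#'   (initial conditions)
#' @export
network_params <- function(net) {
  structure(list(k = setNames(net$reactions$rate_constant, net$reactions$id),
                 x0 = setNames(net$species$initial_amount, net$species$id)),
            class = "param_vec")
}

#' @export
print.param_vec <- function(x, ...) {
  cat("<param_vec> ", length(x$k), " rate constants + ", length(x$x0),
      " initial conditions\n", sep = "")
  invisible(x)
}

#' @rdname network_params
#' @param x a `param_vec`
#' @param ... unused
#' @export
as.double.param_vec <- function(x, ...) c(unname(x$k), unname(x$x0))

as_param_vec <- function(v, net) {
  nk <- nrow(net$reactions)
  structure(list(k = setNames(v[seq_len(nk)], net$reactions$id),
                 x0 = setNames(v[nk + seq_len(nrow(net$species))],
                               net$species$id)),
            class = "param_vec")
}

validate_params <- function(params, net) {
  if (!inherits(params, "param_vec")) abort("`params` must be a param_vec")
  if (length(params$k) != nrow(net$reactions) ||
      length(params$x0) != nrow(net$species)) {
    abort("parameter vector does not match network dimensions")
  }
  if (any(c(params$k, params$x0) < 0)) abort("parameters must be >= 0")
  invisible(params)
}

#' Tidy network summary tables
#'
#' @param x a `rxn_network`
#' @param ... unused
#' @return a tibble with one row per reaction: id, formatted equation,
#'   rate constant, reversibility
#' @export
tidy.rxn_network <- function(x, ...) {
  fmt_side <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v > 1, paste0(v, "*", names(v)), names(v)), collapse = " + ")
  }
  tibble(
    id = x$reactions$id,
    equation = vapply(seq_len(nrow(x$reactions)), function(j) {
      paste(fmt_side(x$reactions$reactants[[j]]),
            if (x$reactions$reversible[j]) "<->" else "->",
            fmt_side(x$reactions$products[[j]]))
    }, character(1)),
    rate_constant = x$reactions$rate_constant,
    rate_constant_rev = x$reactions$rate_constant_rev,
    reversible = x$reactions$reversible
  )
}

#' @export
glance.rxn_network <- function(x, ...) {
  tibble(n_species = nrow(x$species),
         n_reactions = nrow(x$reactions),
         n_reversible = sum(x$reactions$reversible),
         n_parameters = nrow(x$reactions) + sum(x$reactions$reversible) +
           nrow(x$species))
}
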