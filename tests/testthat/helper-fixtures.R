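# Small networks used across the suite; all built in code.

no_species <- function() setNames(numeric(0), character(0))

# dx/dt = -k x
decay_net <- function(k = 1, x0 = 1) {
  rxn_network(
    tibble::tibble(id = "A", initial_amount = x0),
    tibble::tibble(id = "dec", rate_constant = k,
                   reactants = list(c(A = 1)), products = list(no_species()))
  )
}

# source -> A -> B -> sink
chain_net <- function(k_in = 1, k_ab = 2, k_out = 3) {
  rxn_network(
    tibble::tibble(id = c("A", "B"), initial_amount = c(0, 0)),
    tibble::tibble(id = c("src", "conv", "snk"),
                   rate_constant = c(k_in, k_ab, k_out),
                   reactants = list(no_species(), c(A = 1), c(B = 1)),
                   products = list(c(A = 1), c(B = 1), no_species()))
  )
}

# A <-> B, reversible
ab_rev_net <- function(kf = 2, kr = 1, a0 = 1, b0 = 0) {
  rxn_network(
    tibble::tibble(id = c("A", "B"), initial_amount = c(a0, b0)),
    tibble::tibble(id = "iso", rate_constant = kf, rate_constant_rev = kr,
                   reversible = TRUE,
                   reactants = list(c(A = 1)), products = list(c(B = 1)))
  )
}

# finite-difference oracles (central differences)
fd_jacobian <- function(net, x, k) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(x[i]), 1)
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- max(xm[i] - h, 0)
    J[, i] <- (network_rhs(net, xp, k) - network_rhs(net, xm, k)) /
      (xp[i] - xm[i])
  }
  J
}

fd_dfdk <- function(net, x, k) {
  p <- length(k)
  B <- matrix(0, length(x), p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(abs(k[j]), 1)
    kp <- k; kp[j] <- kp[j] + h
    km <- k; km[j] <- max(km[j] - h, 0)
    B[, j] <- (network_rhs(net, x, kp) - network_rhs(net, x, km)) /
      (kp[j] - km[j])
  }
  B
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

expect_network_invariants <- function(net) {
  # stored S matches a reconstruction from the reaction list
  S2 <- matrix(0L, nrow(net$species), nrow(net$reactions))
  rownames(S2) <- net$species$id
  for (j in seq_len(nrow(net$reactions))) {
    re <- net$reactions$reactants[[j]]
    pr <- net$reactions$products[[j]]
    if (length(re)) S2[names(re), j] <- S2[names(re), j] - as.integer(re)
    if (length(pr)) S2[names(pr), j] <- S2[names(pr), j] + as.integer(pr)
  }
  expect_equal(unname(net$S), unname(S2))
  expect_true(all(net$species$initial_amount >= 0))
  expect_false(anyDuplicated(net$species$id) > 0)
}
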