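# Shared test utilities.

# central finite-difference Jacobian used as the independent oracle
fd_jacobian <- function(variant, state, params) {
  f <- function(x) hpt_rhs(variant, x, params)
  pracma::jacobian(f, as.numeric(state))
}

# random strictly positive states, reproducibly
random_states <- function(n, lo = 0.2, hi = 5, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) hpt_state(runif(1, lo, hi), runif(1, lo, hi),
                                           runif(1, lo, hi), runif(1, lo, hi)))
}

# random parameter overrides within [lo, hi] for the given names
random_params <- function(variant, names, lo = 0.5, hi = 2) {
  ov <- as.list(stats::setNames(runif(length(names), lo, hi), names))
  hpt_parameters(ov, base = hpt_default_parameters(variant))
}

equilibrium_ft3 <- function(variant, ...) {
  p <- if (...length()) hpt_parameters(..., base = hpt_default_parameters(variant))
  else hpt_default_parameters(variant)
  hpt_equilibrium(variant, p)$state[["FT3"]]
}
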