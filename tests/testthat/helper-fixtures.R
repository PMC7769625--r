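# shared fixtures, computed once per test run

post_params <- csc_params("post")
pre_params <- csc_params("pre")

# cache heavier simulations across test files
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tonic_post <- function() fixture("tonic_post",
  csc_simulate(post_params, 3000))

tonic_pre <- function() fixture("tonic_pre",
  csc_simulate(pre_params, 3000))

# a configuration where the full system bursts (fold/sub-Hopf cycles)
bursting_params <- function() csc_set(post_params, g_KCa = 4, g_HVA = 0.22)

bursting_traj <- function() fixture("bursting_traj",
  csc_simulate(bursting_params(), 16000, dt = 0.1))

# numerical Jacobian of the R right-hand side, used as the oracle
numerical_jacobian <- function(state, params, eps = 1e-6) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n)
    e[j] <- eps * max(1, abs(state[j]))
    s1 <- state + e; s2 <- state - e
    J[, j] <- (csc_rhs(s1, params) - csc_rhs(s2, params)) / (2 * e[j])
  }
  J
}
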