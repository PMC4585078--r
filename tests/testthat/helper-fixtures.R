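# shared fixtures, generated in code and cached per session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

default_leg <- function() cached("leg", leg_model())

# a small noiseless cohort for round-trip tests
noiseless_cohort <- function(n = 4, seed = 7) {
  cached(sprintf("clean_%d_%d", n, seed), {
    spec <- cohort_spec(n_trials = n, seed = seed, marker_noise_sd = 0)
    generate_cohort(default_leg(), spec)
  })
}

# one noiseless trial fitted through the whole pipeline
fitted_clean_trial <- function() {
  cached("fit_clean", {
    coh <- noiseless_cohort()
    fit_swing_dynamics(coh$trials[[1]], default_leg())
  })
}

# independent OLS oracle via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum(res^2) / ss_tot)
}

# closed-form static torque about one joint: gravitational moment of the
# distal segments (independent re-derivation used as the oracle)
static_oracle <- function(leg, theta, joint) {
  L <- leg$segments$length
  a <- leg$segments$a
  m <- leg$segments$mass
  jx <- c(0, cumsum(L * cos(theta)))[joint]
  tau <- 0
  for (i in joint:4) {
    com_x <- sum(L[seq_len(i - 1)] * cos(theta[seq_len(i - 1)])) +
      a[i] * cos(theta[i])
    tau <- tau + m[i] * leg$g * (com_x - jx)
  }
  tau
}
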