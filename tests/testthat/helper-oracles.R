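# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (loops, normal equations, base t.test) so they share
# no code path with the package's vectorized implementations.

# literal step-up: q_i = min over ranks j >= rank(i) of p_(j) * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q[order(o)]
}

# OLS by explicitly solving the normal equations
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  list(intercept = beta[1], slope = beta[2], slope_se = se,
       residual_sd = sqrt(s2))
}

pooled_t_oracle <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

# small deterministic bundle builders
make_bundle <- function(n_cpgs = 1000, seed = 1, ...) {
  suppressMessages(generate_dataset(
    simulation_config(n_cpgs = n_cpgs, seed = seed, ...)))
}

noiseless_bundle <- function(target, n_cpgs = 1000, seed = 1,
                             noise_sd = 0, within_subject_sd = 0, ...) {
  suppressMessages(generate_dataset(simulation_config(
    n_cpgs = n_cpgs, noise_sd = noise_sd,
    within_subject_sd = within_subject_sd,
    proportion_mode = "fixed_remainder", target = target, seed = seed, ...)))
}
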