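# Independent oracles and small fixtures used across the suite.  All are
# deliberately written against the model equations directly (no shared code
# with the package's deSolve-based solver).

# Fixed-step classical RK4 integration of the joint (depot, central, enzyme)
# system.  Dose times must be multiples of dt; doses are applied as exact
# depot jumps.  Returns a function giving the state at any grid time.
rk4_oracle <- function(pk, pd, regimen, t_end, dt = 0.001) {
  n <- round(t_end / dt)
  e0 <- if (!is.null(pd)) pd$ksyn / pd$kdeg else 0
  deriv <- function(y) {
    conc <- y[2] / pk$v
    c(-pk$ka * y[1],
      pk$ka * y[1] - pk$vmax * conc / (pk$km + conc),
      if (!is.null(pd)) pd$ksyn - pd$kdeg * y[3] - pd$k * conc * y[3] else 0)
  }
  out <- matrix(NA_real_, n + 1, 3)
  y <- c(0, 0, e0)
  dose_steps <- round(regimen$time / dt)
  for (i in 0:n) {
    hit <- which(dose_steps == i)
    if (length(hit)) y[1] <- y[1] + sum(regimen$amt[hit])
    out[i + 1, ] <- y
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  times <- (0:n) * dt
  function(t) out[round(t / dt) + 1, , drop = FALSE]
}

# tiny two-arm design for fast fitting tests
tiny_design <- function(n = 3) {
  study_design(list(
    study_arm(n, 2.5, n_doses = 1, sampled_days = 1),
    study_arm(n, 5, n_doses = 1, sampled_days = 1)))
}

# population model with all randomness switched off
noise_free_model <- function(pk = default_pk_params(),
                             pd = default_pd_params()) {
  pop_model(pk = pk, pd = pd,
            residual = residual_spec(pk_prop_sd = 0, pd_add_sd = 0,
                                     pd_mult_sd = 0))
}

# fast estimation settings for small fixtures
fast_config <- function(...) {
  estimation_config(n_starts = 2, maxit = 300, ...)
}
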