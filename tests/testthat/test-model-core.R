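pk3 <- default_pk_params()   # published Table-style typical PK values
pd4 <- default_pd_params()

test_that("PK right-hand side matches the structural equations", {
  # half-saturation: at C = Km the elimination rate is Vmax/2
  st <- c(0, pk3$km * pk3$v)
  expect_equal(pk_rhs(st, pk3)[2], -pk3$vmax / 2)
  # empty system is stationary
  expect_equal(pk_rhs(c(0, 0), pk3), c(0, 0))
  # elimination off: depot loss equals central gain (mass conservation)
  pk0 <- pk_params(ka = 0.5, v = 100, vmax = 0, km = 50)
  d <- pk_rhs(c(1000, 500), pk0)
  expect_equal(sum(d), 0)
  expect_error(pk_rhs(c(NaN, 1), pk3), "finite")
})

test_that("concentration is amount over volume", {
  expect_equal(concentration(447580, 447.58), 1000)
  expect_equal(concentration(0, 447.58), 0)
  expect_equal(concentration(2.5e6, 447.58), 2.5e6 / 447.58, tolerance = 1e-12)
  expect_equal(round(concentration(2.5e6, 447.58), 1), 5585.6)
  expect_error(concentration(1, 0), "v must be > 0")
})

test_that("turnover right-hand side and its fixed points", {
  e0 <- baseline_enzyme(pd4)
  expect_equal(e0, 88.501 / 0.515)
  # drug-free baseline is an equilibrium
  expect_equal(pd_rhs(e0, 0, pd4), 0)
  # hand arithmetic at published values
  expect_equal(pd_rhs(171.85, 100, pd4),
               88.501 - 0.515 * 171.85 - 0.002 * 100 * 171.85)
  # no inactivation: dynamics independent of C
  pd0 <- pd_params(beta = 0.5, ksyn = 10, kdeg = 0.5, k = 1e-12)
  expect_equal(pd_rhs(20, 500, pd0), pd_rhs(20, 0, pd0), tolerance = 1e-6)
  expect_error(pd_rhs(-1, 0, pd4), ">= 0")

  # steady state under constant concentration
  expect_equal(eact_steady_state(0, pd4), e0)
  expect_equal(eact_steady_state(171.4, pd4),
               88.501 / (0.515 + 0.002 * 171.4))
  expect_lt(eact_steady_state(1e9, pd4), 1e-3)
  # monotone decreasing in C
  cs <- c(0, 10, 100, 1000)
  expect_true(all(diff(eact_steady_state(cs, pd4)) < 0))
})

test_that("PAR maps the active-enzyme fraction to percent", {
  e0 <- baseline_enzyme(pd4)
  expect_equal(par_from_eact(e0, e0, 0.475), 47.5)
  expect_equal(par_from_eact(0, e0, 0.475), 0)
  expect_equal(par_from_eact(123.6, 171.85, 0.475),
               0.475 * 123.6 / 171.85 * 100)
  expect_error(par_from_eact(1, 0, 0.5), "e0 must be > 0")
})

test_that("Bateman profile: boundary, integral and flip-flop symmetry", {
  expect_equal(bateman_profile(1e3, 0.3, 100, 2, 0), 0)
  # total AUC equals dose/(V * kel)
  f <- function(t) bateman_profile(1e3, 0.3, 100, 2, t)
  auc <- integrate(f, 0, Inf)$value
  expect_equal(auc, 1e3 / (100 * 2), tolerance = 1e-6)
  # swapping ka and kel leaves the curve unchanged (flip-flop ambiguity)
  tt <- seq(0, 24, 0.5)
  expect_equal(bateman_profile(1e3, 0.3, 100, 2, tt) * 2 / 0.3,
               bateman_profile(1e3, 2, 100, 0.3, tt))
  # confluent limit ka == kel
  expect_equal(bateman_profile(1e3, 0.5, 100, 0.5, 2),
               1e3 * 0.5 * 2 * exp(-1) / 100)
})

test_that("typical simulation: drug-free, mass balance and non-negativity", {
  tt <- seq(0, 14, 0.5)
  # no dosing: flat at baseline
  prof0 <- simulate_typical(regimen(numeric(0), numeric(0)), pk3, pd4,
                            times = tt)
  expect_equal(prof0$conc, rep(0, length(tt)))
  expect_equal(prof0$par, rep(47.5, length(tt)))
  # elimination off: depot + central = administered dose at all times
  pk0 <- pk_params(ka = 0.21, v = 447.58, vmax = 0, km = 237.6)
  out <- txspkpd:::solve_pkpd(pk0, NULL, single_dose_regimen(2.5), times = tt)
  expect_equal(out[, "aa"] + out[, "a1"], rep(2.5e6, length(tt)),
               tolerance = 1e-7)
  # states non-negative along a dosing trajectory
  out2 <- txspkpd:::solve_pkpd(pk3, pd4, daily_regimen(5, 3),
                               times = seq(0, 72, 0.25))
  expect_true(all(out2[, c("aa", "a1", "eact")] > -1e-7))
})

test_that("linear limit: tiny dose converges to the Bateman solution", {
  kel <- pk3$vmax / (pk3$km * pk3$v)
  expect_equal(kel, 11.78, tolerance = 1e-3)
  tt <- seq(0.25, 14, 0.25)
  num <- simulate_typical(regimen(0, 1), pk3, NULL, times = tt)$conc
  ana <- bateman_profile(1, pk3$ka, pk3$v, kel, tt)
  expect_lt(max(abs(num / ana - 1)), 0.005)
})

test_that("flip-flop: terminal slope equals -Ka", {
  # late window where the quasi-steady-state saturation correction is < 1%
  tt <- seq(16, 24, 0.5)
  prof <- simulate_typical(single_dose_regimen(2.5), pk3, NULL, times = tt)
  slope <- coef(lm(log(prof$conc) ~ tt))[[2]]
  expect_equal(slope, -pk3$ka, tolerance = 0.02)
})

test_that("dose monotonicity: higher dose, higher C, lower PAR", {
  tt <- seq(0, 14, 0.25)
  lo <- simulate_typical(single_dose_regimen(1), pk3, pd4, times = tt)
  hi <- simulate_typical(single_dose_regimen(4), pk3, pd4, times = tt)
  expect_true(all(hi$conc >= lo$conc - 1e-9))
  expect_true(all(hi$par <= lo$par + 1e-9))
})

test_that("adaptive integration agrees with the fixed-step RK4 oracle", {
  reg <- single_dose_regimen(2.5)
  grid <- c(0.5, seq(1, 14, 1))  # on the RK4 dt = 0.001 lattice
  oracle <- rk4_oracle(pk3, pd4, reg, t_end = 14, dt = 0.001)
  prof <- simulate_typical(reg, pk3, pd4, times = grid)
  ref <- oracle(grid)
  conc_ref <- ref[, 2] / pk3$v
  par_ref <- 0.475 * ref[, 3] / baseline_enzyme(pd4) * 100
  expect_equal(prof$conc, conc_ref, tolerance = 5e-4)  # 3 significant figures
  expect_equal(prof$par, par_ref, tolerance = 5e-4)
  # the PAR nadir agrees with the oracle to 3 significant figures
  fine <- seq(0.5, 8, 0.01)
  nadir <- min(simulate_typical(reg, pk3, pd4, times = round(fine, 3))$par)
  nadir_ref <- min(0.475 * oracle(round(fine, 3))[, 3] /
                     baseline_enzyme(pd4) * 100)
  expect_equal(nadir, nadir_ref, tolerance = 5e-4)
})

test_that("PD equilibrium under constant concentration is reached", {
  # closed form for constant C: exponential approach to the fixed point
  cc <- 171.4
  rate <- pd4$kdeg + pd4$k * cc
  ss <- eact_steady_state(cc, pd4)
  e0 <- baseline_enzyme(pd4)
  # independent RK4 on the scalar turnover equation with C held constant
  dt <- 0.001
  t_end <- 20 / rate
  y <- e0
  for (i in seq_len(round(t_end / dt))) {
    f <- function(e) pd4$ksyn - pd4$kdeg * e - pd4$k * cc * e
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(y, ss, tolerance = 1e-3)
  # monotone approach from baseline
  expect_true(ss < e0)
})

test_that("regimen and parameter validation", {
  expect_error(regimen(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(regimen(-1, 1), ">= 0")
  expect_error(regimen(0, 0), "> 0")
  expect_error(pk_params(0, 1, 1, 1), "> 0")
  expect_error(pd_params(1.2, 1, 1, 1), "beta")
  expect_error(simulate_typical(single_dose_regimen(1), pk3, pd4,
                                times = c(1, 0.5)), "strictly increasing")
})
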