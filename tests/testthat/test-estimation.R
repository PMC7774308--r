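test_that("ELS objective matches hand computation", {
  # perfect fit leaves only the irreducible log-variance term
  y <- c(10, 20, 40)
  err <- list(type = "proportional", sigma = 0.1)
  expect_equal(els_objective(y, y, err), sum(log((0.1 * y)^2)))
  # single observation with additive error is minimized at f = y
  f_grid <- seq(4, 6, 0.01)
  obj <- vapply(f_grid, function(f)
    els_objective(5, f, list(type = "additive", sigma = 1)), numeric(1))
  expect_equal(f_grid[which.min(obj)], 5)
  # doubling sigma: SSR term scales by 1/4, log term adds n log 4
  y3 <- c(1, 2, 3); f3 <- c(1.1, 1.9, 3.2)
  o1 <- els_objective(y3, f3, list(type = "additive", sigma = 1))
  o2 <- els_objective(y3, f3, list(type = "additive", sigma = 2))
  ssr <- sum((y3 - f3)^2)
  expect_equal(o2 - o1, 3 * log(4) + ssr / 4 - ssr)
  # mixed error variance
  expect_equal(els_objective(50, 40, list(type = "mixed", sigma = 0.003,
                                          mult_sd = 0.122)),
               100 / (0.003^2 + 40^2 * 0.122^2) +
                 log(0.003^2 + 40^2 * 0.122^2))
  expect_error(els_objective(numeric(0), numeric(0), err), ">= 1")
})

test_that("subject PK fit recovers noise-free data", {
  st <- generate_study(study_design(list(study_arm(1, 2.5))),
                       noise_free_model(), seed = 3)
  truth <- unlist(unclass(default_pk_params()))
  # initialized at the truth: essentially exact recovery
  f <- fit_subject_pk(st, 1, estimation_config(
    n_starts = 1, pk_init = c(truth, sigma = 0.05)))
  expect_lt(max(abs(unlist(unclass(f$params)) / truth - 1)), 1e-4)
  # initialized 3x off on every parameter, with multi-start
  f2 <- fit_subject_pk(st, 1, estimation_config(
    n_starts = 8, pk_init = c(truth * 3, sigma = 0.05)))
  expect_lt(max(abs(unlist(unclass(f2$params)) / truth - 1)), 1e-3)
})

test_that("subject PK fit guards identifiability and BLQ", {
  st <- generate_study(study_design(list(study_arm(1, 2.5))),
                       noise_free_model(), seed = 3)
  d <- st$data
  # keep only 3 quantifiable concentrations
  keep <- d$EVID == 1 | (d$DVID == 1 & d$BLQ == 0 &
                           d$TIME %in% c(0.25, 1, 4))
  expect_error(fit_subject_pk(d[keep, ], 1, fast_config()),
               "unfittable")
  # all-BLQ subject
  d2 <- d
  d2$BLQ[d2$EVID == 0 & d2$DVID == 1] <- 1L
  expect_error(fit_subject_pk(d2, 1, fast_config()), "unfittable")
})

test_that("population PK: degenerate and cross-method consistency", {
  # identical subjects, no noise: tv = shared values, omega^2 ~ 0
  st <- generate_study(tiny_design(2), noise_free_model(), seed = 9)
  truth <- unlist(unclass(default_pk_params()))
  cfg <- fast_config(pk_init = c(truth, sigma = 0.05))
  ts <- fit_population_pk(st, cfg)
  expect_lt(max(abs(ts$params / truth - 1)), 1e-3)
  expect_lt(max(ts$omega2[c("ka", "v", "km")]), 1e-5)
  # two-stage and naive-pooled agree with omega = 0 and small noise
  m_small <- pop_model(default_pk_params(), default_pd_params(),
                       residual = residual_spec(pk_prop_sd = 0.01,
                                                pd_add_sd = 0,
                                                pd_mult_sd = 0))
  st2 <- generate_study(tiny_design(2), m_small, seed = 10)
  cfg2 <- fast_config(pk_init = c(truth, sigma = 0.02))
  f_ts <- fit_population_pk(st2, cfg2)
  cfg2p <- fast_config(pk_init = c(truth, sigma = 0.02),
                       method = "naive_pooled")
  f_np <- fit_population_pk(st2, cfg2p)
  expect_lt(max(abs(f_ts$params / f_np$params[names(f_ts$params)] - 1)), 0.02)
  # pooled fit reports CV% from the objective curvature
  expect_true(all(is.finite(f_np$cv_pct[c("ka", "v", "vmax", "km")])))
})

test_that("sequential PD fit recovers noise-free data and reports ksyn via e0", {
  st <- generate_study(tiny_design(2), noise_free_model(), seed = 4)
  pd_truth <- unlist(unclass(default_pd_params()))
  e0 <- baseline_enzyme(default_pd_params())
  cfg <- fast_config(pd_init = c(beta = 0.475, kdeg = 0.515, k = 0.002,
                                 mult_sd = 0.01),
                     pd_sigma_add = 0.1, e0_ref = e0, map_iterations = 0)
  fd <- fit_population_pd_sequential(st, st$truth, cfg)
  expect_lt(max(abs(fd$params[c("beta", "kdeg", "k")] /
                      pd_truth[c("beta", "kdeg", "k")] - 1)), 1e-3)
  expect_equal(fd$params[["ksyn"]], e0 * fd$params[["kdeg"]])
  # without a baseline-enzyme reference the synthesis rate stays unreported
  cfg_no <- fast_config(pd_init = c(beta = 0.475, kdeg = 0.515, k = 0.002,
                                    mult_sd = 0.01),
                        pd_sigma_add = 0.1, map_iterations = 0)
  fd2 <- fit_population_pd_sequential(st, st$truth, cfg_no)
  expect_true(is.na(fd2$params[["ksyn"]]))
  expect_true(is.na(rse(fd2)[["ksyn"]]))
})

test_that("PD fit flags non-identifiable kdeg/k when no drug dynamics inform them", {
  # baseline-only PAR records: constant PAR carries no turnover information
  st <- generate_study(study_design(list(study_arm(2, 2.5))),
                       noise_free_model(), seed = 6)
  d <- st$data
  # replace all PAR values by the baseline (as if the drug had no effect)
  d$DV[d$EVID == 0 & d$DVID == 2] <- 47.5
  cfg <- fast_config(pd_sigma_add = 0.1, map_iterations = 0)
  fd <- suppressWarnings(fit_population_pd_sequential(d, st$truth, cfg))
  expect_true(all(!fd$individual$identifiable))
})

test_that("PD results are invariant to subject order", {
  m <- pop_model(default_pk_params(), default_pd_params(),
                 omega_pd = default_pd_omega(),
                 residual = residual_spec(0, 0.003, 0.05))
  st <- generate_study(tiny_design(2), m, seed = 12)
  cfg <- fast_config(e0_ref = 100, map_iterations = 0)
  f1 <- fit_population_pd_sequential(st, st$truth, cfg)
  d_rev <- st$data[order(-st$data$ID, st$data$TIME, st$data$EVID), ]
  f2 <- fit_population_pd_sequential(d_rev, st$truth, cfg)
  expect_equal(sort(f1$individual$ID), sort(f2$individual$ID))
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
})

test_that("optimizer trace is monotone non-increasing", {
  st <- generate_study(study_design(list(study_arm(1, 2.5))),
                       beagle_pop_model(), seed = 8)
  f <- fit_subject_pk(st, 1, fast_config())
  expect_true(all(diff(f$trace) <= 0))
  expect_gt(length(f$trace), 3)
})

test_that("structural model comparison favours the generating model", {
  # data simulated from the 1-compartment MM model at the study doses
  m <- pop_model(default_pk_params(), NULL,
                 residual = residual_spec(pk_prop_sd = 0.05))
  st <- generate_study(tiny_design(2), m, seed = 21)
  cand <- data.frame(n_comp = c(1, 1), elim = c("linear", "mm"),
                     stringsAsFactors = FALSE)
  cfg <- fast_config(method = "naive_pooled")
  tab <- compare_structural_models(st, cand, cfg)
  obj_mm <- tab$objective[tab$elim == "mm"]
  obj_lin <- tab$objective[tab$elim == "linear"]
  dpar <- tab$n_params[tab$elim == "mm"] - tab$n_params[tab$elim == "linear"]
  expect_lt(obj_mm, obj_lin + 2 * dpar)
  expect_true(all(c("aic", "daic") %in% names(tab)))
  expect_error(compare_structural_models(st, cand[0, ], cfg), "empty")
})

test_that("linear-regime data leave Michaelis-Menten and linear models tied", {
  # tiny dose: C << Km, elimination effectively first order
  m <- pop_model(default_pk_params(), NULL,
                 residual = residual_spec(pk_prop_sd = 0.05))
  st <- generate_study(study_design(list(study_arm(3, 0.001)), lloq = 0),
                       m, seed = 22)
  cand <- data.frame(n_comp = c(1, 1), elim = c("linear", "mm"),
                     stringsAsFactors = FALSE)
  tab <- compare_structural_models(st, cand, fast_config(method = "naive_pooled"))
  # the MM model cannot beat the linear one by more than noise
  expect_lt(abs(diff(tab$objective)), 3)
})
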