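test_that("goodness of fit: self-fit on noise-free data has zero residuals", {
  st <- generate_study(tiny_design(2), noise_free_model(), seed = 31)
  truth <- unlist(unclass(default_pk_params()))
  cfg <- fast_config(pk_init = c(truth, sigma = 0.05))
  fit <- fit_population_pk(st, cfg)
  g <- gof(st, fit)
  expect_true(all(g$DVID == 1))
  expect_lt(max(abs(g$res / g$obs)), 1e-3)
  expect_equal(g$obs, g$ipred, tolerance = 1e-3)
  expect_equal(g$obs, g$pred, tolerance = 1e-3)
  # BLQ rows never appear
  expect_false(any(paste(g$ID, g$TIME) %in%
    with(st$data[st$data$BLQ == 1, ], paste(ID, TIME))))
})

test_that("obs vs PRED slope is ~1 for a well-specified fit", {
  m <- pop_model(default_pk_params(), NULL,
                 omega_pk = omega_spec(v = 0.01),
                 residual = residual_spec(pk_prop_sd = 0.05))
  st <- generate_study(tiny_design(3), m, seed = 32)
  truth <- unlist(unclass(default_pk_params()))
  # pooled fit: both dose levels inform Km/Vmax jointly
  fit <- fit_population_pk(st, fast_config(pk_init = c(truth, sigma = 0.05),
                                           method = "naive_pooled"))
  g <- gof(st, fit)
  slope <- coef(lm(obs ~ pred, data = g))[[2]]
  expect_equal(slope, 1, tolerance = 0.1)
})

test_that("Monte-Carlo CWRES of self-simulated data are standard normal", {
  model <- beagle_pop_model()
  des <- study_design(list(study_arm(9, 2.5), study_arm(9, 5)))
  st <- generate_study(des, model, seed = 33)
  cw <- cwres(st, model, n_sim = 300, seed = 99)
  x <- cw$cwres
  expect_gte(length(x), 300)
  expect_lt(abs(mean(x)), 0.1)
  expect_gt(sd(x), 0.85); expect_lt(sd(x), 1.15)
  expect_gte(mean(x > -2 & x < 2), 0.90)
  # normality sanity: skewness and excess kurtosis
  sk <- mean((x - mean(x))^3) / sd(x)^3
  ku <- mean((x - mean(x))^4) / sd(x)^4 - 3
  expect_lt(abs(sk), 0.5)
  expect_lt(abs(ku), 1)
  # degenerate model refused
  expect_error(cwres(st, noise_free_model(), n_sim = 200), "variability")
  expect_error(cwres(st, model, n_sim = 100), ">= 200")
})

test_that("VPC: percentile ordering, degenerate bands and coverage", {
  model <- beagle_pop_model()
  des <- tiny_design(3)
  v <- vpc(model, des, n_reps = 200, seed = 7)
  expect_true(all(v$bands$lo <= v$bands$med + 1e-12))
  expect_true(all(v$bands$med <= v$bands$hi + 1e-12))
  expect_error(vpc(model, des, n_reps = 1), ">= 2")
  # deterministic under a fixed seed
  v2 <- vpc(model, des, n_reps = 200, seed = 7)
  expect_identical(v$bands, v2$bands)
  # no variability: all three percentile curves collapse onto the typical
  v0 <- vpc(noise_free_model(), tiny_design(2), n_reps = 5, seed = 1)
  expect_equal(v0$bands$lo, v0$bands$hi, tolerance = 1e-9)
  prof <- simulate_typical(single_dose_regimen(2.5), default_pk_params(),
                           default_pd_params(),
                           times = sort(unique(
                             v0$bands$TIME[v0$bands$ARM == 1])))
  b1 <- v0$bands[v0$bands$ARM == 1 & v0$bands$DVID == 1, ]
  expect_equal(b1$med, prof$conc[match(b1$TIME, prof$time)],
               tolerance = 1e-8)
  # coverage: ~90% of fresh self-simulated observations inside the band
  big <- vpc(model, study_design(list(study_arm(12, 2.5), study_arm(12, 5))),
             n_reps = 300, seed = 8)
  fresh <- generate_study(study_design(list(study_arm(12, 2.5),
                                            study_arm(12, 5))),
                          model, seed = 909)
  od <- fresh$data[fresh$data$EVID == 0, ]
  key <- paste(od$ARM, od$DVID, od$TIME)
  bkey <- paste(big$bands$ARM, big$bands$DVID, big$bands$TIME)
  m <- match(key, bkey)
  inside <- od$DV >= big$bands$lo[m] & od$DV <= big$bands$hi[m]
  expect_equal(mean(inside), 0.90, tolerance = 0.045)
})

test_that("multiple-dose prediction: superposition, trough and reduction", {
  model <- pop_model(default_pk_params(), default_pd_params())
  p <- predict_multidose(model, dose_mg_kg = 5, n_days = 7, n_reps = 0)
  # negligible accumulation at 24 h dosing: the ~1.3 ng/ml trough carried
  # into day 7 is amplified by the saturable elimination to a peak
  # concentration deviation of ~2% (around Cmax) and ~1.3% in PAR, decaying
  # below 1% by the end of the interval
  cdev <- abs(p$typical$conc_last / p$typical$conc_day1 - 1)
  pdev <- abs(p$typical$par_last / p$typical$par_day1 - 1)
  expect_lt(max(cdev), 0.025)
  expect_lt(max(pdev), 0.015)
  expect_lt(cdev[length(cdev)], 0.01)
  expect_lt(pdev[length(pdev)], 0.01)
  # day-7 pre-dose trough below the assay LLOQ: no cumulative effect
  expect_lt(p$trough_conc, 7.8)
  # a single dose reduces exactly to the single-dose simulator
  p1 <- predict_multidose(model, dose_mg_kg = 2.5, n_days = 1, n_reps = 0)
  prof <- simulate_typical(single_dose_regimen(2.5), default_pk_params(),
                           default_pd_params(),
                           times = beagle_sampling_offsets())
  expect_equal(p1$typical$conc_day1, prof$conc, tolerance = 1e-10)
  expect_equal(p1$typical$conc_last, prof$conc, tolerance = 1e-10)
  # bands are ordered and reproducible
  pb <- predict_multidose(beagle_pop_model(), n_reps = 50, seed = 5)
  expect_true(all(pb$bands$lo <= pb$bands$hi))
  pb2 <- predict_multidose(beagle_pop_model(), n_reps = 50, seed = 5)
  expect_identical(pb$bands, pb2$bands)
})
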