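#' Assemble a population model from fitted results
#'
#' Builds the simulation model (typical values, omega^2, residual error) from
#' a population PK fit and optionally a sequential PD fit, for use by the
#' simulation-based diagnostics ([vpc], [cwres], [predict_multidose]).  When
#' the PD fit carries no synthesis-rate estimate (no `e0_ref`), the enzyme
#' pool is simulated on the normalized scale (`ksyn = kdeg`, `e0 = 1`), which
#' leaves every observable quantity unchanged.
#'
#' @param pk_fit a `pkpd_fit` of type "pk"
#' @param pd_fit optional `pkpd_fit` of type "pd"
#' @return A [pop_model].
#' @export
fits_to_model <- function(pk_fit, pd_fit = NULL) {
  stopifnot(inherits(pk_fit, "pkpd_fit"), pk_fit$type == "pk")
  pk <- do.call(pk_params, as.list(pk_fit$params[c("ka", "v", "vmax", "km")]))
  om_pk <- pk_fit$omega2[!is.na(pk_fit$omega2)]
  pd <- NULL; om_pd <- numeric(0)
  pd_sigma <- 0.003; pd_mult <- 0.122
  if (!is.null(pd_fit)) {
    stopifnot(inherits(pd_fit, "pkpd_fit"), pd_fit$type == "pd")
    kdeg <- pd_fit$params[["kdeg"]]
    ksyn <- pd_fit$params[["ksyn"]]
    if (!is.finite(ksyn)) ksyn <- kdeg  # normalized enzyme scale, e0 = 1
    pd <- pd_params(beta = pd_fit$params[["beta"]], ksyn = ksyn,
                    kdeg = kdeg, k = pd_fit$params[["k"]])
    om_pd <- pd_fit$omega2[!is.na(pd_fit$omega2)]
    pd_sigma <- pd_fit$residual$sigma
    pd_mult <- pd_fit$residual$mult_sd
  }
  pop_model(pk = pk, pd = pd,
            omega_pk = do.call(omega_spec, as.list(om_pk)),
            omega_pd = do.call(omega_spec, as.list(om_pd)),
            residual = residual_spec(pk_prop_sd = pk_fit$residual$sigma,
                                     pd_add_sd = pd_sigma,
                                     pd_mult_sd = pd_mult))
}

time_after_dose <- function(sub_times, dose_times) {
  vapply(sub_times, function(t) {
    prior <- dose_times[dose_times <= t]
    if (!length(prior)) t else t - max(prior)
  }, numeric(1))
}

#' Goodness-of-fit table
#'
#' Per non-BLQ observation: the observed value, the population prediction
#' (PRED, typical parameters), the individual prediction (IPRED, the
#' subject's own estimates where available), residuals and the
#' error-model-weighted residual `(obs - pred)/g(pred)`, plus the time after
#' the most recent dose.
#'
#' @param x a `pkpd_study` or dataset data frame
#' @param pk_fit `pkpd_fit` of type "pk"
#' @param pd_fit optional `pkpd_fit` of type "pd" (adds PAR rows)
#' @return Data frame with columns `ID`, `ARM`, `TIME`, `TAD`, `DVID`,
#'   `obs`, `pred`, `ipred`, `res`, `wres`.
#' @export
gof <- function(x, pk_fit, pd_fit = NULL) {
  data <- study_data(x)
  stopifnot(inherits(pk_fit, "pkpd_fit"))
  if (!pk_fit$converged) stop("gof: PK fit did not converge", call. = FALSE)
  model <- fits_to_model(pk_fit, pd_fit)
  have_ipred_pk <- !is.null(pk_fit$individual)
  have_ipred_pd <- !is.null(pd_fit) && !is.null(pd_fit$individual)
  if (!have_ipred_pk)
    message("gof: no individual PK estimates; IPRED uses typical parameters")
  rows <- list()
  for (id in unique(data$ID)) {
    sub <- data[data$ID == id, , drop = FALSE]
    keep <- sub$EVID == 0 & sub$BLQ == 0 &
      (sub$DVID == 1 | (!is.null(pd_fit) & sub$DVID == 2))
    obs <- sub[keep, , drop = FALSE]
    if (!nrow(obs)) next
    reg <- subject_regimen(sub)
    times <- sort(unique(obs$TIME))
    pred_prof <- simulate_typical(reg, model$pk, model$pd, times = times)
    ipk <- model$pk; ipd <- model$pd
    if (have_ipred_pk && id %in% pk_fit$individual$ID) {
      r <- pk_fit$individual[pk_fit$individual$ID == id, ][1, ]
      ipk <- pk_params(r$ka, r$v, r$vmax, r$km)
    }
    if (have_ipred_pd && id %in% pd_fit$individual$ID) {
      r <- pd_fit$individual[pd_fit$individual$ID == id, ][1, ]
      ipd <- pd_params(r$beta, ksyn = r$kdeg, kdeg = r$kdeg, k = r$k)
    }
    ipred_prof <- simulate_typical(reg, ipk, ipd, times = times)
    ti <- match(obs$TIME, times)
    pred <- ifelse(obs$DVID == 1, pred_prof$conc[ti], pred_prof$par[ti])
    ipred <- ifelse(obs$DVID == 1, ipred_prof$conc[ti], ipred_prof$par[ti])
    g <- ifelse(obs$DVID == 1,
                pmax(model$residual$pk_prop_sd * pred, 1e-10),
                sqrt(model$residual$pd_add_sd^2 +
                       pred^2 * model$residual$pd_mult_sd^2))
    rows[[length(rows) + 1L]] <- data.frame(
      ID = id, ARM = sub$ARM[1], TIME = obs$TIME,
      TAD = time_after_dose(obs$TIME, reg$time), DVID = obs$DVID,
      obs = obs$DV, pred = pred, ipred = ipred, res = obs$DV - pred,
      wres = (obs$DV - pred) / g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional weighted residuals (Monte-Carlo)
#'
#' Simulation-based standardized residuals: `n_sim` replicate datasets are
#' simulated from the population model at each subject's observed design
#' (inter-individual variability plus residual error), and each observation
#' is standardized by the mean and SD of its simulated counterparts,
#' `CWRES_i = (obs_i - mean_i)/sd_i`.  Under a correct model these are
#' approximately N(0, 1).  Strictly positive concentration observations are
#' standardized on the log scale (`log_conc = TRUE`): their predictive
#' distribution under log-normal inter-individual variability is heavily
#' right-skewed on the natural scale, and log standardization restores the
#' near-normal self-consistency the diagnostic relies on.  (The exact
#' FOCE-linearized CWRES requires marginal-likelihood machinery that is out
#' of scope; this Monte-Carlo analogue plays the same role.)
#'
#' @param x a `pkpd_study` or dataset data frame
#' @param model a [pop_model] (e.g. from [fits_to_model])
#' @param n_sim number of simulation replicates (>= 200)
#' @param seed integer seed
#' @param log_conc standardize concentration rows on the log scale
#' @return The non-BLQ observation rows with columns `sim_mean`, `sim_sd`
#'   and `cwres` appended (`sim_mean`/`sim_sd` on the standardization
#'   scale).
#' @export
cwres <- function(x, model, n_sim = 500, seed = 1, log_conc = TRUE) {
  data <- study_data(x)
  stopifnot(inherits(model, "pop_model"))
  if (n_sim < 200) stop("cwres: n_sim must be >= 200", call. = FALSE)
  if (length(model$omega_pk) == 0 && model$residual$pk_prop_sd == 0)
    stop("cwres: the model has no variability; simulated SDs would be zero",
         call. = FALSE)
  obs <- data[data$EVID == 0 & data$BLQ == 0, , drop = FALSE]
  ids <- unique(obs$ID)
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  for (r in seq_len(n_sim)) {
    for (id in ids) {
      sel <- which(obs$ID == id)
      sub <- data[data$ID == id, , drop = FALSE]
      reg <- subject_regimen(sub)
      times <- sort(unique(obs$TIME[sel]))
      set.seed(subject_seed(seed + 31L * r, 97L, id))
      indiv <- sample_individual(model)
      sol <- solve_pkpd(indiv$pk, indiv$pd, reg, times = times)
      conc <- apply_pk_residual(concentration(sol[, "a1"], indiv$pk$v),
                                model$residual)
      par <- if (!is.null(indiv$pd))
        apply_pd_residual(par_from_eact(sol[, "eact"],
                                        baseline_enzyme(indiv$pd),
                                        indiv$pd$beta), model$residual)
      ti <- match(obs$TIME[sel], times)
      sims[sel, r] <- ifelse(obs$DVID[sel] == 1, conc[ti], par[ti])
    }
  }
  y <- obs$DV
  if (log_conc) {
    cc <- obs$DVID == 1
    sims[cc, ] <- log(pmax(sims[cc, , drop = FALSE], 1e-6))
    y[cc] <- log(pmax(y[cc], 1e-6))
  }
  m <- rowMeans(sims)
  s <- apply(sims, 1, sd)
  if (any(s == 0))
    stop("cwres: zero simulated variance at some observations; ",
         "the model needs nonzero residual or inter-individual noise",
         call. = FALSE)
  out <- obs
  out$sim_mean <- m
  out$sim_sd <- s
  out$cwres <- (y - m) / s
  rownames(out) <- NULL
  out
}

#' Visual predictive check
#'
#' Simulates `n_reps` replicate studies from the population model
#' (inter-individual variability and residual error) under the given design
#' and aggregates, per arm, observation type and nominal sampling time, the
#' lower, median and upper percentiles of the simulated observations (5th
#' and 95th for the default 90% interval).  Observations are grouped by
#' nominal design time (all subjects share the sampling schedule, so no
#' adaptive binning is needed).
#'
#' @param model a [pop_model] (e.g. from [fits_to_model])
#' @param design a [study_design]
#' @param n_reps number of replicate studies (>= 2; 1000 for the study's
#'   reference procedure)
#' @param interval central prediction-interval width in percent
#' @param seed integer seed
#' @param observed optional `pkpd_study` (or dataset) overlaid as observed
#'   values
#' @return Object of class `vpc_result`: list with `bands` (per ARM, DVID,
#'   TIME: `lo`, `med`, `hi`), `observed`, `n_reps`, `interval`.
#' @export
vpc <- function(model, design, n_reps = 1000, interval = 90, seed = 1,
                observed = NULL) {
  stopifnot(inherits(model, "pop_model"), inherits(design, "study_design"))
  if (n_reps < 2) stop("vpc: n_reps must be >= 2", call. = FALSE)
  if (interval <= 0 || interval >= 100)
    stop("vpc: interval must be in (0, 100)", call. = FALSE)
  sims <- lapply(seq_len(n_reps), function(r) {
    st <- generate_study(design, model, seed = (seed * 131L + r) %% 2147483629)
    d <- st$data[st$data$EVID == 0, c("ARM", "TIME", "DVID", "DV")]
    d
  })
  all <- do.call(rbind, sims)
  pr <- c((100 - interval) / 200, 0.5, 1 - (100 - interval) / 200)
  agg <- aggregate(DV ~ ARM + DVID + TIME, data = all, FUN = function(v)
    quantile(v, probs = pr, names = FALSE))
  bands <- data.frame(agg[c("ARM", "DVID", "TIME")],
                      lo = agg$DV[, 1], med = agg$DV[, 2], hi = agg$DV[, 3])
  bands <- bands[order(bands$ARM, bands$DVID, bands$TIME), ]
  rownames(bands) <- NULL
  obs <- NULL
  if (!is.null(observed)) {
    od <- study_data(observed)
    obs <- od[od$EVID == 0, c("ID", "ARM", "TIME", "DVID", "DV", "BLQ")]
  }
  structure(list(bands = bands, observed = obs, n_reps = n_reps,
                 interval = interval, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat("<vpc_result>", x$n_reps, "replicates,", x$interval,
      "% prediction interval,", nrow(x$bands), "time bins\n")
  invisible(x)
}

#' Multiple-dose prediction
#'
#' Simulates a once-daily regimen and summarizes the last dosing day: the
#' typical (variability-free) day-1 and day-7 profiles at the sampling
#' offsets, simulation-based percentile bands for the last day
#' (inter-individual variability plus residual error), and the last-day
#' pre-dose trough concentration of the typical subject.  With a single
#' dose the typical profile reduces exactly to [simulate_typical].
#'
#' @param model a [pop_model] (e.g. from [fits_to_model] or the simulation
#'   truth)
#' @param dose_mg_kg once-daily dose (mg/kg)
#' @param n_days number of daily doses
#' @param offsets within-day sampling offsets (h post-dose)
#' @param n_reps simulated subjects for the percentile bands (0 to skip)
#' @param interval prediction-interval width in percent
#' @param seed integer seed
#' @return List with `typical` (per offset: day-1 and last-day conc and
#'   PAR), `bands` (per offset and DV type: lo/med/hi across simulated
#'   subjects), `trough_conc` (typical pre-dose concentration on the last
#'   day, ng/ml) and `regimen`.
#' @export
predict_multidose <- function(model, dose_mg_kg = 5, n_days = 7,
                              offsets = beagle_sampling_offsets(),
                              n_reps = 200, interval = 90, seed = 1) {
  stopifnot(inherits(model, "pop_model"))
  reg <- if (n_days == 1) single_dose_regimen(dose_mg_kg)
         else daily_regimen(dose_mg_kg, n_days = n_days)
  last0 <- (n_days - 1) * 24
  t_day1 <- offsets
  t_last <- last0 + offsets
  times <- sort(unique(c(0, t_day1, last0, t_last)))
  prof <- simulate_typical(reg, model$pk, model$pd, times = times)
  i1 <- match(t_day1, prof$time)
  i7 <- match(t_last, prof$time)
  typical <- data.frame(offset = offsets,
                        conc_day1 = prof$conc[i1],
                        conc_last = prof$conc[i7])
  if (!is.null(model$pd)) {
    typical$par_day1 <- prof$par[i1]
    typical$par_last <- prof$par[i7]
  }
  trough <- prof$conc[match(last0, prof$time)]
  bands <- NULL
  if (n_reps > 0) {
    pr <- c((100 - interval) / 200, 0.5, 1 - (100 - interval) / 200)
    sim_c <- matrix(NA_real_, length(t_last), n_reps)
    sim_p <- matrix(NA_real_, length(t_last), n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(subject_seed(seed, 53L, r))
      indiv <- sample_individual(model)
      sol <- solve_pkpd(indiv$pk, indiv$pd, reg, times = t_last)
      sim_c[, r] <- apply_pk_residual(
        concentration(sol[, "a1"], indiv$pk$v), model$residual)
      if (!is.null(indiv$pd))
        sim_p[, r] <- apply_pd_residual(
          par_from_eact(sol[, "eact"], baseline_enzyme(indiv$pd),
                        indiv$pd$beta), model$residual)
    }
    qs <- function(m) t(apply(m, 1, quantile, probs = pr, names = FALSE))
    qc <- qs(sim_c)
    bands <- data.frame(offset = offsets, dv = "conc",
                        lo = qc[, 1], med = qc[, 2], hi = qc[, 3])
    if (!is.null(model$pd)) {
      qp <- qs(sim_p)
      bands <- rbind(bands,
                     data.frame(offset = offsets, dv = "par",
                                lo = qp[, 1], med = qp[, 2], hi = qp[, 3]))
    }
  }
  list(typical = typical, bands = bands, trough_conc = trough,
       regimen = reg, n_days = n_days)
}
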