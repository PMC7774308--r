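#' Study design: arms, sampling schedule, quantification limit
#'
#' A `study_arm` is one treatment group: `n` subjects on a once-daily oral
#' regimen, with rich sampling on the listed study days.  A `study_design`
#' bundles the arms with the within-day sampling offsets and the assay lower
#' limit of quantification (LLOQ).  On every sampled day, observations are
#' taken pre-dose and at each offset after that day's dose; concentration and
#' PAR are sampled from the same draws.
#'
#' @param n number of subjects in the arm (>= 1)
#' @param dose_mg_kg once-daily oral dose (mg/kg)
#' @param n_doses number of daily doses administered
#' @param sampled_days study days (1-based) with rich sampling
#' @param label arm label
#' @return `study_arm()`: an object of class `study_arm`;
#'   `study_design()`: an object of class `study_design`.
#' @export
study_arm <- function(n, dose_mg_kg, n_doses = 1, sampled_days = 1,
                      label = NULL) {
  stopifnot(n >= 1, dose_mg_kg > 0, n_doses >= 1,
            all(sampled_days >= 1), all(sampled_days <= n_doses))
  structure(list(n = as.integer(n), dose_mg_kg = dose_mg_kg,
                 n_doses = as.integer(n_doses),
                 sampled_days = as.integer(sort(unique(sampled_days))),
                 label = if (is.null(label))
                   paste0(dose_mg_kg, " mg/kg") else label),
            class = "study_arm")
}

#' @rdname study_arm
#' @param arms list of [study_arm] objects
#' @param offsets within-day sampling offsets (h post-dose), strictly
#'   increasing
#' @param lloq concentration lower limit of quantification (ng/ml)
#' @export
study_design <- function(arms, offsets = beagle_sampling_offsets(),
                         lloq = 7.8) {
  if (!length(arms)) stop("study_design: no arms", call. = FALSE)
  stopifnot(all(vapply(arms, inherits, logical(1), "study_arm")),
            all(offsets > 0), all(diff(offsets) > 0), lloq >= 0)
  structure(list(arms = arms, offsets = as.numeric(offsets),
                 lloq = lloq),
            class = "study_design")
}

#' @rdname study_arm
#' @export
beagle_sampling_offsets <- function() {
  c(0.0833, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 14)
}

#' Default beagle study design
#'
#' The two drug arms of the beagle trial that the simulator emulates: six
#' dogs on a single oral 2.5 mg/kg dose with day-1 sampling, and six dogs on
#' 5 mg/kg once daily for 7 days with sampling after the first and last dose.
#' Sampling is pre-dose plus 0.0833-14 h post-dose; concentration LLOQ is
#' 7.8 ng/ml.  The vehicle and aspirin comparator arms carry no drug model
#' and are not simulated.
#'
#' @param n_per_arm subjects per arm (default 6, the study's group size)
#' @return A [study_design].
#' @export
default_beagle_design <- function(n_per_arm = 6) {
  study_design(list(
    study_arm(n_per_arm, 2.5, n_doses = 1, sampled_days = 1,
              label = "2.5 mg/kg single"),
    study_arm(n_per_arm, 5, n_doses = 7, sampled_days = c(1, 7),
              label = "5 mg/kg QD x 7")
  ))
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>  LLOQ", x$lloq, "ng/ml;",
      length(x$offsets), "post-dose offsets/day\n")
  for (a in x$arms)
    cat("  arm:", a$label, "- n =", a$n, ", doses =", a$n_doses,
        ", sampled days:", paste(a$sampled_days, collapse = ", "), "\n")
  invisible(x)
}

arm_regimen <- function(arm) {
  if (arm$n_doses == 1) single_dose_regimen(arm$dose_mg_kg)
  else daily_regimen(arm$dose_mg_kg, n_days = arm$n_doses)
}

# observation times (h) for one arm; pre-dose times marked separately
arm_obs_times <- function(arm, offsets) {
  do.call(rbind, lapply(arm$sampled_days, function(d) {
    base <- (d - 1) * 24
    data.frame(time = c(base, base + offsets),
               predose = c(TRUE, rep(FALSE, length(offsets))))
  }))
}

#' Draw one individual's parameters with log-normal variability
#'
#' Each structural parameter with an entry in the omega specification is
#' drawn as `tvP * exp(eta)`, `eta ~ N(0, omega^2)`; parameters without IIV
#' are copied.  Uses the current RNG state (seed it for reproducibility).
#'
#' @param model [pop_model] with the typical values and omega specifications
#' @return List with elements `pk` ([pk_params]) and `pd` ([pd_params] or
#'   `NULL`).
#' @export
sample_individual <- function(model) {
  stopifnot(inherits(model, "pop_model"))
  perturb <- function(typ, omega) {
    vals <- unclass(typ)[names(typ)]
    for (nm in names(omega))
      vals[[nm]] <- vals[[nm]] * exp(rnorm(1, 0, sqrt(omega[[nm]])))
    vals
  }
  pk <- do.call(pk_params, perturb(model$pk, model$omega_pk))
  pd <- if (!is.null(model$pd))
    do.call(pd_params, perturb(model$pd, model$omega_pd))
  list(pk = pk, pd = pd)
}

#' Apply the residual error models
#'
#' `apply_pk_residual` draws the proportional concentration error
#' `Cobs = C (1 + eps)`, `eps ~ N(0, sd^2)`; negative draws are floored at 0
#' (attribute `"floored"` carries which were).  `apply_pd_residual` draws the
#' mixed additive-multiplicative PAR error with effective SD
#' `sqrt(add_sd^2 + PAR^2 mult_sd^2)` and clamps the result to 0-100.
#' Both use the current RNG state.
#'
#' @param conc predicted concentrations (ng/ml), >= 0
#' @param par predicted PAR (percent), >= 0
#' @param spec [residual_spec]
#' @return Numeric vector of observed values.
#' @export
apply_pk_residual <- function(conc, spec) {
  stopifnot(inherits(spec, "residual_spec"), all(conc >= 0))
  obs <- conc * (1 + rnorm(length(conc), 0, spec$pk_prop_sd))
  floored <- obs < 0
  obs[floored] <- 0
  structure(obs, floored = floored)
}

#' @rdname apply_pk_residual
#' @export
apply_pd_residual <- function(par, spec) {
  stopifnot(inherits(spec, "residual_spec"), all(par >= 0))
  eff_sd <- sqrt(spec$pd_add_sd^2 + par^2 * spec$pd_mult_sd^2)
  pmin(pmax(par + rnorm(length(par), 0, eff_sd), 0), 100)
}

# deterministic per-subject seed so adding subjects or arms never perturbs
# existing ones; kept below 2^31
subject_seed <- function(master, arm_idx, subj_idx) {
  h <- (as.numeric(master) * 2654435761 + arm_idx * 40503 + subj_idx * 9973)
  as.integer(h %% 2147483629) + 1L
}

#' Simulate a population study (the synthetic-data generator)
#'
#' Emulates the trial: for each subject, individual parameters are drawn with
#' log-normal inter-individual variability, the coupled PK/PD system is
#' simulated over the subject's full regimen, observations are taken at the
#' design's sampling times, residual errors are applied, and concentrations
#' below the LLOQ are flagged (BLQ).  Each subject uses an RNG sub-stream
#' derived from the master seed, so the dataset is reproducible and adding
#' subjects does not perturb existing ones.
#'
#' The dataset is NONMEM-style long format with columns `ID`, `ARM`, `TIME`
#' (h since first dose), `AMT` (ng/kg), `EVID` (1 dose, 0 observation), `DV`,
#' `DVID` (1 concentration ng/ml, 2 PAR percent), `MDV` and `BLQ`.  Pre-dose
#' observations share the dose's clock time and are ordered before the dose
#' record.  True individual parameters are retained in the `truth` sidecar.
#'
#' @param design [study_design]
#' @param model [pop_model]
#' @param seed integer master seed
#' @return Object of class `pkpd_study`: list with `data` (data frame),
#'   `truth` (per-subject true parameters), `design`, `model`, `seed`.
#' @examples
#' study <- generate_study(default_beagle_design(), beagle_pop_model(),
#'                         seed = 42)
#' head(study$data)
#' @export
generate_study <- function(design, model, seed) {
  stopifnot(inherits(design, "study_design"), inherits(model, "pop_model"))
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("generate_study: an explicit integer seed is required", call. = FALSE)
  has_pd <- !is.null(model$pd)

  rows <- list(); truths <- list(); id <- 0L
  for (ai in seq_along(design$arms)) {
    arm <- design$arms[[ai]]
    reg <- arm_regimen(arm)
    obs <- arm_obs_times(arm, design$offsets)
    for (si in seq_len(arm$n)) {
      id <- id + 1L
      set.seed(subject_seed(seed, ai, si))
      indiv <- sample_individual(model)
      sol <- solve_pkpd(indiv$pk, indiv$pd, reg, times = obs$time)
      conc_true <- concentration(sol[, "a1"], indiv$pk$v)
      conc_obs <- apply_pk_residual(conc_true, model$residual)
      sub <- data.frame(ID = id, ARM = ai, TIME = obs$time, AMT = 0,
                        EVID = 0L, DV = as.numeric(conc_obs), DVID = 1L,
                        MDV = 0L, BLQ = as.integer(conc_obs < design$lloq))
      if (has_pd) {
        par_true <- par_from_eact(sol[, "eact"],
                                  baseline_enzyme(indiv$pd), indiv$pd$beta)
        par_obs <- apply_pd_residual(par_true, model$residual)
        sub <- rbind(sub,
                     data.frame(ID = id, ARM = ai, TIME = obs$time, AMT = 0,
                                EVID = 0L, DV = par_obs, DVID = 2L,
                                MDV = 0L, BLQ = 0L))
      }
      dose <- data.frame(ID = id, ARM = ai, TIME = reg$time, AMT = reg$amt,
                         EVID = 1L, DV = NA_real_, DVID = NA_integer_,
                         MDV = 1L, BLQ = 0L)
      sub <- rbind(sub, dose)
      # stable sort: time, then observations before dose events at equal
      # times (pre-dose convention), then DVID
      sub <- sub[order(sub$TIME, sub$EVID, sub$DVID), ]
      rows[[id]] <- sub
      tr <- c(ID = id, ARM = ai, unlist(unclass(indiv$pk)))
      if (has_pd) tr <- c(tr, unlist(unclass(indiv$pd)))
      truths[[id]] <- tr
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- as.data.frame(do.call(rbind, truths))
  structure(list(data = data, truth = truth, design = design,
                 model = model, seed = as.integer(seed)),
            class = "pkpd_study")
}

#' @export
print.pkpd_study <- function(x, ...) {
  nobs <- sum(x$data$EVID == 0)
  cat("<pkpd_study>  seed", x$seed, "-", length(unique(x$data$ID)),
      "subjects,", nobs, "observations (",
      sum(x$data$EVID == 0 & x$data$DVID == 1), "conc /",
      sum(x$data$EVID == 0 & x$data$DVID == 2), "PAR ),",
      sum(x$data$BLQ == 1), "BLQ\n")
  invisible(x)
}
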