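#' PK right-hand side: oral absorption with Michaelis-Menten elimination
#'
#' Time derivatives of the absorption-depot and central-compartment amounts,
#' \deqn{dA_a/dt = -K_a A_a, \quad dA_1/dt = +K_a A_a - V_{max} C/(K_m + C)}
#' with \eqn{C = A_1/V}.  The absorption input into the central compartment
#' enters with a positive sign (first-order absorption).
#'
#' @param state numeric vector `c(aa, a1)` (ng/kg), non-negative
#' @param params [pk_params]
#' @return Numeric vector `c(daa, da1)` (ng/kg/h).
#' @export
pk_rhs <- function(state, params) {
  stopifnot(inherits(params, "pk_params"))
  if (length(state) != 2L || any(!is.finite(state)))
    stop("pk_rhs: state must be two finite numbers (solver divergence?)",
         call. = FALSE)
  aa <- state[[1]]; a1 <- state[[2]]
  conc <- a1 / params$v
  c(-params$ka * aa,
    params$ka * aa - params$vmax * conc / (params$km + conc))
}

#' Plasma concentration from central-compartment amount
#'
#' @param a1 amount in the central compartment (ng/kg)
#' @param v apparent volume of distribution (ml/kg), > 0
#' @return Concentration in ng/ml.
#' @export
concentration <- function(a1, v) {
  if (!is.numeric(v) || any(v <= 0))
    stop("concentration: v must be > 0", call. = FALSE)
  a1 / v
}

#' Turnover right-hand side with irreversible inactivation
#'
#' \deqn{dE_{act}/dt = K_{syn} - K_{deg} E_{act} - K \, C \, E_{act}}
#'
#' @param eact amount of active enzyme (ng), >= 0
#' @param conc plasma drug concentration (ng/ml), >= 0
#' @param params [pd_params]
#' @return dEact/dt in ng/h.
#' @export
pd_rhs <- function(eact, conc, params) {
  stopifnot(inherits(params, "pd_params"))
  if (any(eact < 0) || any(conc < 0))
    stop("pd_rhs: eact and conc must be >= 0", call. = FALSE)
  params$ksyn - params$kdeg * eact - params$k * conc * eact
}

#' Baseline active-enzyme amount
#'
#' The drug-free equilibrium of the turnover model, `e0 = ksyn / kdeg`.
#'
#' @param params [pd_params]
#' @return e0 in ng.
#' @export
baseline_enzyme <- function(params) {
  stopifnot(inherits(params, "pd_params"))
  params$ksyn / params$kdeg
}

#' Platelet aggregation rate from active enzyme
#'
#' `PAR = beta * (eact / e0) * 100`, in percent.
#'
#' @param eact active-enzyme amount (ng), >= 0
#' @param e0 baseline active-enzyme amount (ng), > 0
#' @param beta efficacy coefficient
#' @return PAR in percent.
#' @export
par_from_eact <- function(eact, e0, beta) {
  if (any(e0 <= 0)) stop("par_from_eact: e0 must be > 0", call. = FALSE)
  if (any(eact < 0)) stop("par_from_eact: eact must be >= 0", call. = FALSE)
  beta * (eact / e0) * 100
}

#' Active-enzyme steady state under constant concentration
#'
#' Fixed point of [pd_rhs] at constant drug concentration:
#' `ksyn / (kdeg + k * conc)`.  Decreases monotonically from `e0` (at
#' `conc = 0`) towards 0 as the concentration grows.
#'
#' @param conc constant plasma concentration (ng/ml), >= 0
#' @param params [pd_params]
#' @return Steady-state Eact in ng.
#' @export
eact_steady_state <- function(conc, params) {
  stopifnot(inherits(params, "pd_params"))
  if (any(conc < 0)) stop("eact_steady_state: conc must be >= 0", call. = FALSE)
  params$ksyn / (params$kdeg + params$k * conc)
}

#' Closed-form concentration profile in the linear limit
#'
#' Bateman solution of first-order absorption with first-order elimination,
#' the limit of the Michaelis-Menten model for concentrations far below Km
#' (with `kel = vmax / (km * v)`):
#' \deqn{C(t) = \frac{D K_a}{V (k_{el} - K_a)} (e^{-K_a t} - e^{-k_{el} t}).}
#' When `ka == kel` the confluent limit `D ka t e^{-ka t} / V` is used.
#'
#' @param dose dose amount (ng/kg) placed in the depot at t = 0
#' @param ka absorption rate constant (1/h)
#' @param v volume (ml/kg)
#' @param kel first-order elimination rate constant (1/h)
#' @param times time grid (h), >= 0
#' @return Concentration series (ng/ml) on `times`.
#' @export
bateman_profile <- function(dose, ka, v, kel, times) {
  stopifnot(dose > 0, ka > 0, v > 0, kel > 0, all(times >= 0))
  if (isTRUE(all.equal(ka, kel))) {
    dose * ka * times * exp(-ka * times) / v
  } else {
    dose * ka / (v * (kel - ka)) * (exp(-ka * times) - exp(-kel * times))
  }
}

#' Dosing regimens
#'
#' A regimen is a data frame with columns `time` (h since first dose) and
#' `amt` (ng/kg deposited into the absorption depot).  `single_dose_regimen`
#' builds a single oral dose at t = 0; `daily_regimen` a once-daily course.
#'
#' @param dose_mg_kg dose in mg per kg body weight
#' @param n_days number of daily doses
#' @param interval_h dosing interval in hours
#' @return A data frame of class `regimen` with columns `time`, `amt`.
#' @examples
#' single_dose_regimen(2.5)       # the 2.5 mg/kg arm
#' daily_regimen(5, n_days = 7)   # 5 mg/kg once daily x 7
#' @export
single_dose_regimen <- function(dose_mg_kg) {
  regimen(time = 0, amt = dose_mg_kg * 1e6)
}

#' @rdname single_dose_regimen
#' @export
daily_regimen <- function(dose_mg_kg, n_days = 7, interval_h = 24) {
  regimen(time = interval_h * (seq_len(n_days) - 1),
          amt = rep(dose_mg_kg * 1e6, n_days))
}

#' @rdname single_dose_regimen
#' @param time dose times (h), >= 0, strictly increasing
#' @param amt dose amounts (ng/kg), > 0
#' @export
regimen <- function(time, amt) {
  if (length(time) != length(amt))
    stop("regimen: time and amt must be of equal length", call. = FALSE)
  # an empty regimen (no dosing) is valid and yields the drug-free profile
  if (any(time < 0) || any(!is.finite(time)))
    stop("regimen: dose times must be finite and >= 0", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("regimen: dose times must be strictly increasing (no overlapping events)",
         call. = FALSE)
  if (any(amt <= 0) || any(!is.finite(amt)))
    stop("regimen: dose amounts must be finite and > 0", call. = FALSE)
  structure(data.frame(time = as.numeric(time), amt = as.numeric(amt)),
            class = c("regimen", "data.frame"))
}

#' Simulate the typical (or an individual) concentration/PAR profile
#'
#' Integrates the coupled three-state system (depot, central compartment,
#' active enzyme) over a dosing regimen with an adaptive stiff-capable
#' integrator (lsoda).  Dose events are applied as exact jumps of the depot
#' amount with integration restarted at the event time.  The initial state is
#' drug-free at enzyme baseline: `aa = a1 = 0`, `eact = e0`.
#'
#' @param regimen a [regimen] (or data frame with `time`, `amt` in ng/kg)
#' @param pk [pk_params]
#' @param pd [pd_params] or `NULL` to simulate PK only
#' @param times strictly increasing output grid (h)
#' @param rtol,atol solver relative/absolute tolerances
#' @return A data frame `time`, `conc` (ng/ml) and, when `pd` is given,
#'   `par` (percent).
#' @examples
#' prof <- simulate_typical(single_dose_regimen(2.5), default_pk_params(),
#'                          default_pd_params(), times = seq(0, 14, 0.5))
#' range(prof$par)
#' @export
simulate_typical <- function(regimen, pk, pd = NULL,
                             times = seq(0, 24, by = 0.1),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(pk, "pk_params"))
  if (!is.data.frame(regimen) || !all(c("time", "amt") %in% names(regimen)))
    stop("simulate_typical: regimen must have columns time, amt", call. = FALSE)
  regimen <- regimen(regimen$time, regimen$amt)   # revalidate
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("simulate_typical: times must be strictly increasing", call. = FALSE)
  if (nrow(regimen) && min(regimen$time) > max(times))
    stop("simulate_typical: all dose events lie after the output grid",
         call. = FALSE)
  out <- solve_pkpd(pk = pk, pd = pd, regimen = regimen, times = times,
                    rtol = rtol, atol = atol)
  res <- data.frame(time = out[, "time"],
                    conc = concentration(out[, "a1"], pk$v))
  if (!is.null(pd)) {
    stopifnot(inherits(pd, "pd_params"))
    res$par <- par_from_eact(out[, "eact"], baseline_enzyme(pd), pd$beta)
  }
  res
}
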