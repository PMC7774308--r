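#' Pharmacokinetic structural parameters
#'
#' Container for the one-compartment oral-absorption model with saturable
#' Michaelis-Menten elimination.  All amounts are carried per kg body weight,
#' so doses in mg/kg (\eqn{\times 10^6} to ng/kg), `v` in ml/kg and `vmax` in
#' ng/h/kg are mutually consistent and concentrations come out in ng/ml
#' without a body-weight covariate.
#'
#' @param ka first-order absorption rate constant (1/h)
#' @param v apparent volume of distribution (ml/kg)
#' @param vmax maximum elimination rate (ng/h/kg)
#' @param km Michaelis constant (ng/ml)
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(ka = 0.21, v = 447.58, vmax = 1252830, km = 237.60)
#' @export
pk_params <- function(ka, v, vmax, km) {
  x <- list(ka = ka, v = v, vmax = vmax, km = km)
  for (nm in names(x)) {
    val <- x[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop("pk_params: '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  # vmax = 0 switches elimination off (useful for mass-balance checks);
  # the remaining parameters must be strictly positive
  for (nm in c("ka", "v", "km"))
    if (x[[nm]] <= 0)
      stop("pk_params: '", nm, "' must be > 0", call. = FALSE)
  structure(x, class = "pk_params")
}

#' Pharmacodynamic structural parameters
#'
#' Container for the turnover model with irreversible second-order enzyme
#' inactivation.  The active-enzyme baseline is `e0 = ksyn / kdeg`, and the
#' platelet aggregation rate is `PAR = beta * Eact / e0 * 100` (percent).
#'
#' @param beta efficacy coefficient mapping the fraction of active enzyme to
#'   PAR (dimensionless, in (0, 1])
#' @param ksyn zero-order enzyme synthesis rate (ng/h)
#' @param kdeg first-order enzyme degradation rate constant (1/h)
#' @param k second-order irreversible inactivation rate constant (ml/ng/h)
#' @return An object of class `pd_params`.
#' @examples
#' pd_params(beta = 0.475, ksyn = 88.501, kdeg = 0.515, k = 0.002)
#' @export
pd_params <- function(beta, ksyn, kdeg, k) {
  x <- list(beta = beta, ksyn = ksyn, kdeg = kdeg, k = k)
  for (nm in names(x)) {
    val <- x[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0)
      stop("pd_params: '", nm, "' must be a single finite positive number",
           call. = FALSE)
  }
  if (beta > 1)
    stop("pd_params: 'beta' must lie in (0, 1]", call. = FALSE)
  structure(x, class = "pd_params")
}

#' Published beagle-dog typical parameter values
#'
#' Typical values estimated in the beagle study that this package emulates:
#' Ka 0.21 1/h, V 447.58 ml/kg, Vmax 1,252,830 ng/h/kg, Km 237.60 ng/ml for
#' the PK model; beta 0.475, Ksyn 88.501 ng/h, Kdeg 0.515 1/h,
#' K 0.002 ml/ng/h for the PD model.  These serve as the default simulation
#' truth throughout.
#'
#' @return `default_pk_params()` a [pk_params] object; `default_pd_params()`
#'   a [pd_params] object.
#' @export
default_pk_params <- function() {
  pk_params(ka = 0.21, v = 447.58, vmax = 1252830, km = 237.60)
}

#' @rdname default_pk_params
#' @export
default_pd_params <- function() {
  pd_params(beta = 0.475, ksyn = 88.501, kdeg = 0.515, k = 0.002)
}

#' Inter-individual variability specification
#'
#' Named vector of variances (omega^2) of the log-scale random effects: an
#' individual's parameter is `tvP * exp(eta)`, `eta ~ N(0, omega^2)`.  A
#' parameter absent from the vector carries no IIV.  The defaults reproduce
#' the study's retained random effects: PK omega^2 of 0.015 (ka), 0.474 (v),
#' 0.041 (km); PD omega^2 of 0.466 (kdeg) and 0.775 (k).
#'
#' @param ... named variances, e.g. `omega_spec(v = 0.474, km = 0.041)`
#' @return A named numeric vector of class `omega_spec`.
#' @export
omega_spec <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- setNames(numeric(0), character(0))
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("omega_spec: all entries must be named", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("omega_spec: variances must be finite and >= 0", call. = FALSE)
  structure(x, class = "omega_spec")
}

#' @rdname omega_spec
#' @export
default_pk_omega <- function() omega_spec(ka = 0.015, v = 0.474, km = 0.041)

#' @rdname omega_spec
#' @export
default_pd_omega <- function() omega_spec(kdeg = 0.466, k = 0.775)

#' Residual (within-subject) error specification
#'
#' Concentrations carry a proportional error, `Cobs = C * (1 + eps)` with
#' `eps ~ N(0, pk_prop_sd^2)`.  PAR carries the mixed additive-multiplicative
#' error with effective standard deviation
#' `sqrt(pd_add_sd^2 + PAR^2 * pd_mult_sd^2)`.  The defaults are the study's
#' PD estimates (additive SD 0.003, multiplicative SD 0.122) and a 10%
#' proportional concentration error typical of an LC-MS/MS assay.
#'
#' @param pk_prop_sd SD of the proportional concentration error
#' @param pd_add_sd additive SD of the PAR error (percent units)
#' @param pd_mult_sd multiplicative SD of the PAR error
#' @return An object of class `residual_spec`.
#' @export
residual_spec <- function(pk_prop_sd = 0.10, pd_add_sd = 0.003,
                          pd_mult_sd = 0.122) {
  x <- list(pk_prop_sd = pk_prop_sd, pd_add_sd = pd_add_sd,
            pd_mult_sd = pd_mult_sd)
  for (nm in names(x))
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L ||
        !is.finite(x[[nm]]) || x[[nm]] < 0)
      stop("residual_spec: '", nm, "' must be a single finite number >= 0",
           call. = FALSE)
  structure(x, class = "residual_spec")
}

#' Population model: typicals, random effects and residual error
#'
#' Bundles the typical structural parameters with the inter-individual and
#' residual variability used for trial simulation, VPC and CWRES.
#'
#' @param pk [pk_params] typical PK parameters
#' @param pd [pd_params] typical PD parameters, or `NULL` for a PK-only model
#' @param omega_pk,omega_pd [omega_spec] random-effect variances
#' @param residual [residual_spec]
#' @return An object of class `pop_model`.
#' @export
pop_model <- function(pk, pd = NULL,
                      omega_pk = omega_spec(), omega_pd = omega_spec(),
                      residual = residual_spec()) {
  stopifnot(inherits(pk, "pk_params"),
            is.null(pd) || inherits(pd, "pd_params"),
            inherits(residual, "residual_spec"))
  omega_pk <- as_omega(omega_pk)
  omega_pd <- as_omega(omega_pd)
  bad <- setdiff(names(omega_pk), names(pk))
  if (length(bad))
    stop("pop_model: omega_pk names not PK parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(pd)) {
    bad <- setdiff(names(omega_pd), names(pd))
    if (length(bad))
      stop("pop_model: omega_pd names not PD parameters: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(pk = pk, pd = pd, omega_pk = omega_pk, omega_pd = omega_pd,
                 residual = residual),
            class = "pop_model")
}

as_omega <- function(x) {
  if (inherits(x, "omega_spec")) return(x)
  do.call(omega_spec, as.list(x))
}

#' Default beagle population model
#'
#' The published typical values with their retained random effects and
#' residual error models; the simulation truth used by the acceptance
#' experiments.
#'
#' @return A [pop_model].
#' @export
beagle_pop_model <- function() {
  pop_model(pk = default_pk_params(), pd = default_pd_params(),
            omega_pk = default_pk_omega(), omega_pd = default_pd_omega(),
            residual = residual_spec())
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  ka =", x$ka, "1/h, v =", x$v, "ml/kg, vmax =",
      x$vmax, "ng/h/kg, km =", x$km, "ng/ml\n")
  invisible(x)
}

#' @export
print.pd_params <- function(x, ...) {
  cat("<pd_params>  beta =", x$beta, ", ksyn =", x$ksyn, "ng/h, kdeg =",
      x$kdeg, "1/h, k =", x$k, "ml/ng/h  (e0 =",
      round(baseline_enzyme(x), 3), "ng)\n")
  invisible(x)
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model>\n")
  print(x$pk)
  if (!is.null(x$pd)) print(x$pd)
  if (length(x$omega_pk))
    cat("  omega^2 (PK):", paste(names(x$omega_pk), unclass(x$omega_pk),
                                 sep = " = ", collapse = ", "), "\n")
  if (length(x$omega_pd))
    cat("  omega^2 (PD):", paste(names(x$omega_pd), unclass(x$omega_pd),
                                 sep = " = ", collapse = ", "), "\n")
  cat("  residual: prop SD", x$residual$pk_prop_sd, "(conc); add SD",
      x$residual$pd_add_sd, "+ mult SD", x$residual$pd_mult_sd, "(PAR)\n")
  invisible(x)
}
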