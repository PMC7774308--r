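# Internal event-aware ODE driver around deSolve's lsoda with the compiled
# right-hand side in src/pkpdmod.c.  All structural variants used for model
# selection (1-3 compartments, linear or Michaelis-Menten elimination) share
# the same compiled system; unused rate constants are zero.

# theta: named numeric vector of structural parameters.  Required: ka, v and
# either (vmax, km) [elim = "mm"] or cl [elim = "linear"]; optional k12, k21,
# k13, k31; optional PD block ksyn, kdeg, kirr.
solve_structural <- function(theta, elim = c("mm", "linear"), pd_on = FALSE,
                             regimen, times, rtol = 1e-8, atol = 1e-10,
                             eact0 = NULL) {
  elim <- match.arg(elim)
  g <- function(nm, default = 0) if (nm %in% names(theta)) theta[[nm]] else default
  parms <- c(ka = g("ka"), v = g("v", 1), vmax = g("vmax"), km = g("km", 1),
             cl = g("cl"), k12 = g("k12"), k21 = g("k21"),
             k13 = g("k13"), k31 = g("k31"),
             ksyn = g("ksyn"), kdeg = g("kdeg"), kirr = g("kirr"),
             elim_mm = if (elim == "mm") 1 else 0,
             pd_on = if (pd_on) 1 else 0)
  if (any(!is.finite(parms)))
    stop("solve_structural: non-finite parameter", call. = FALSE)

  t0 <- min(times[1], if (nrow(regimen)) regimen$time[1] else Inf, 0)
  y0 <- c(aa = 0, a1 = 0, a2 = 0, a3 = 0,
          eact = if (pd_on) {
            if (is.null(eact0)) parms[["ksyn"]] / parms[["kdeg"]] else eact0
          } else 0)

  # doses at or before the integration start are folded into the depot;
  # later doses become add-events with integration restart
  early <- regimen$time <= t0
  y0[["aa"]] <- sum(regimen$amt[early])
  evt <- regimen[!early & regimen$time <= max(times), , drop = FALSE]

  grid <- sort(unique(c(t0, times, evt$time)))
  events <- if (nrow(evt))
    list(data = data.frame(var = 1, time = evt$time, value = evt$amt,
                           method = "add"))
  else NULL

  out <- deSolve::lsoda(y = y0, times = grid, func = "txspkpd_derivs",
                        parms = parms, dllname = "txspkpd",
                        initfunc = "txspkpd_initmod",
                        rtol = rtol, atol = atol, events = events)
  if (nrow(out) < length(grid))
    stop("solve_structural: solver failed after t = ",
         signif(out[nrow(out), "time"], 6), " h", call. = FALSE)
  out[match(times, out[, "time"]), , drop = FALSE]
}

# Convenience driver for the final model (1-compartment MM PK + turnover PD).
solve_pkpd <- function(pk, pd = NULL, regimen, times,
                       rtol = 1e-8, atol = 1e-10) {
  theta <- c(ka = pk$ka, v = pk$v, vmax = pk$vmax, km = pk$km)
  if (!is.null(pd))
    theta <- c(theta, ksyn = pd$ksyn, kdeg = pd$kdeg, kirr = pd$k)
  solve_structural(theta, elim = "mm", pd_on = !is.null(pd),
                   regimen = regimen, times = times, rtol = rtol, atol = atol)
}
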