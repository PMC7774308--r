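#' Trapezoidal area under the concentration-time curve
#'
#' Piecewise trapezoid AUC from time zero to the last quantifiable sample.
#' With `rule = "linuplogdown"`, segments where the concentration declines
#' between two positive points use the log-trapezoid
#' `(C1 - C2) * dt / log(C1/C2)`; all other segments use the linear
#' trapezoid.
#'
#' @param times strictly increasing sample times (h)
#' @param conc concentrations (ng/ml), >= 0
#' @param rule `"linear"` or `"linuplogdown"`
#' @return AUC in ng*h/ml.
#' @export
auc_trapezoid <- function(times, conc, rule = c("linear", "linuplogdown")) {
  rule <- match.arg(rule)
  if (length(times) < 2L)
    stop("auc_trapezoid: need >= 2 points", call. = FALSE)
  if (length(times) != length(conc) || any(diff(times) <= 0))
    stop("auc_trapezoid: times must be strictly increasing and match conc",
         call. = FALSE)
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- (c1 + c2) / 2 * dt
  if (rule == "linuplogdown") {
    dn <- c2 < c1 & c2 > 0 & c1 > 0
    lin[dn] <- (c1[dn] - c2[dn]) * dt[dn] / log(c1[dn] / c2[dn])
  }
  sum(lin)
}

#' Per-subject non-compartmental analysis
#'
#' Computes, for every subject and sampled dosing interval, the exposure
#' metrics from the quantifiable concentration records: AUC from the dose
#' time to the last quantifiable sample, Cmax, Tmax (time after dose), the
#' administered dose and the dose-normalized AUC.  Subjects with fewer than
#' two quantifiable samples are excluded with a warning.
#'
#' @param x a `pkpd_study` or NONMEM-style dataset data frame
#' @param rule trapezoid rule, see [auc_trapezoid]
#' @return List with `subjects` (one row per subject: `ID`, `ARM`, `dose`
#'   ng/kg, `auc_last` ng*h/ml, `cmax`, `tmax`, `dn_auc` h*kg/ml) and
#'   `groups` (per arm: n, mean and SD of the dose-normalized AUC; the SD is
#'   `NA` when n < 2).
#' @export
nca_table <- function(x, rule = c("linuplogdown", "linear")) {
  rule <- match.arg(rule)
  data <- study_data(x)
  ids <- unique(data$ID)
  rows <- list()
  for (id in ids) {
    sub <- data[data$ID == id, , drop = FALSE]
    dose_rows <- sub[sub$EVID == 1, , drop = FALSE]
    if (!nrow(dose_rows)) next
    t_dose <- dose_rows$TIME[1]
    t_next <- if (nrow(dose_rows) > 1) dose_rows$TIME[2] else Inf
    obs <- sub[sub$EVID == 0 & sub$DVID == 1 & sub$BLQ == 0 &
                 sub$TIME >= t_dose & sub$TIME < t_next, , drop = FALSE]
    if (nrow(obs) < 2) {
      warning("nca_table: subject ", id,
              " has < 2 quantifiable concentrations in the first interval; ",
              "excluded", call. = FALSE)
      next
    }
    obs <- obs[order(obs$TIME), ]
    auc <- auc_trapezoid(obs$TIME - t_dose, obs$DV, rule = rule)
    imax <- which.max(obs$DV)
    dose <- dose_rows$AMT[1]
    rows[[length(rows) + 1L]] <-
      data.frame(ID = id, ARM = sub$ARM[1], dose = dose, auc_last = auc,
                 cmax = obs$DV[imax], tmax = obs$TIME[imax] - t_dose,
                 dn_auc = auc / dose)
  }
  if (!length(rows)) stop("nca_table: no analysable subjects", call. = FALSE)
  subjects <- do.call(rbind, rows)
  groups <- do.call(rbind, lapply(split(subjects, subjects$ARM), function(g)
    data.frame(ARM = g$ARM[1], n = nrow(g), dose = g$dose[1],
               mean_dn_auc = mean(g$dn_auc),
               sd_dn_auc = if (nrow(g) >= 2) sd(g$dn_auc) else NA_real_)))
  rownames(groups) <- NULL
  list(subjects = subjects, groups = groups)
}

#' Two-sample t test on dose-normalized AUC
#'
#' The dose-proportionality comparison: a two-sided two-sample t test of the
#' dose-normalized AUC between two dose groups, either from the raw
#' per-subject values or from group summary statistics (mean, SD, n).  Both
#' the pooled-variance (classical Student) and Welch variants are available.
#'
#' @param group1,group2 numeric vectors of per-subject dose-normalized AUC
#' @param variant `"pooled"` (Student, default) or `"welch"`
#' @return List with `t`, `df`, `p`, and the group means.
#' @examples
#' # the study's printed summaries: p ~ 0.017
#' dose_normalized_auc_test_summary(0.030, 0.008, 6, 0.046, 0.011, 6)
#' @export
dose_normalized_auc_test <- function(group1, group2,
                                     variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(group1) < 2 || length(group2) < 2)
    stop("dose_normalized_auc_test: need n >= 2 per group", call. = FALSE)
  dose_normalized_auc_test_summary(mean(group1), sd(group1), length(group1),
                                   mean(group2), sd(group2), length(group2),
                                   variant = variant)
}

#' @rdname dose_normalized_auc_test
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics
#' @export
dose_normalized_auc_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("dose_normalized_auc_test: zero variance in both groups",
         call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (mean2 - mean1) / se
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
       mean1 = mean1, mean2 = mean2, se = se, variant = variant)
}
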