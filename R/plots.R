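#' Diagnostic plots
#'
#' Base-graphics diagnostics mirroring the usual population PK/PD panels:
#' `plot_gof` draws observed vs population predictions and weighted
#' residuals vs time after dose; `plot` on a `vpc_result` draws the
#' percentile ribbon with the observed overlay.
#'
#' @param g a goodness-of-fit table from [gof]
#' @param dvid observation type to plot (1 concentration, 2 PAR)
#' @export
plot_gof <- function(g, dvid = 1) {
  gg <- g[g$DVID == dvid, ]
  lab <- if (dvid == 1) "concentration (ng/ml)" else "PAR (%)"
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(gg$pred, gg$obs, xlab = paste("predicted", lab),
       ylab = paste("observed", lab), main = "Obs vs PRED")
  abline(0, 1, lty = 2)
  plot(gg$TAD, gg$wres, xlab = "time after dose (h)",
       ylab = "weighted residual", main = "WRES vs TAD")
  abline(h = c(-2, 0, 2), lty = c(3, 2, 3))
  invisible(g)
}

#' @rdname plot_gof
#' @param x a `vpc_result`
#' @param arm arm index to plot
#' @param log_y logarithmic concentration axis
#' @param ... ignored
#' @export
plot.vpc_result <- function(x, dvid = 1, arm = 1, log_y = dvid == 1, ...) {
  b <- x$bands[x$bands$DVID == dvid & x$bands$ARM == arm, ]
  lab <- if (dvid == 1) "concentration (ng/ml)" else "PAR (%)"
  ylim <- range(b$lo, b$hi)
  if (log_y) ylim[1] <- max(ylim[1], 0.1)
  plot(b$TIME, b$med, type = "l", ylim = ylim, log = if (log_y) "y" else "",
       xlab = "time (h)", ylab = lab,
       main = sprintf("VPC (%d reps, %g%% PI)", x$n_reps, x$interval))
  polygon(c(b$TIME, rev(b$TIME)),
          pmax(c(b$lo, rev(b$hi)), if (log_y) 0.1 else -Inf),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  lines(b$TIME, b$med, lwd = 2)
  if (!is.null(x$observed)) {
    o <- x$observed[x$observed$DVID == dvid & x$observed$ARM == arm &
                      x$observed$BLQ == 0, ]
    points(o$TIME, o$DV, pch = 1)
  }
  invisible(x)
}
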