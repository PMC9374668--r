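#' @export
print.pacc_trajectory <- function(x, ...) {
  cat("2N+/PACC trajectory:", x$mode$hypothesis,
      if (x$mode$drug != "none") paste0("+ ", x$mode$drug), "\n")
  cat(sprintf("  %d time points over [0, %g]%s\n", nrow(x$data), x$t_end,
              if (x$terminated_early) " (terminated at extinction)" else ""))
  cat("  final state:",
      paste(signif(x$final_state, 6), collapse = ", "), "\n")
  if (!is.null(x$outcome)) cat("  outcome:", x$outcome$label, "\n")
  invisible(x)
}

#' @export
summary.pacc_trajectory <- function(object, ...) {
  d <- object$data
  single <- !is_structured(object$mode)
  tot <- if (single) d$x1 else d$x1 + d$x2
  res <- list(
    mode = object$mode,
    t_end = object$t_end,
    final_state = object$final_state,
    v_final = d$v[nrow(d)],
    min_total = min(tot),
    t_min_total = d$t[which.min(tot)],
    extinction = object$extinction,
    outcome = if (is.null(object$outcome))
      classify_outcome(object)$label else object$outcome$label)
  class(res) <- "summary.pacc_trajectory"
  res
}

#' @export
print.summary.pacc_trajectory <- function(x, ...) {
  cat("hypothesis:", x$mode$hypothesis, "| drug:", x$mode$drug, "\n")
  cat(sprintf("horizon: %g | outcome: %s\n", x$t_end, x$outcome))
  cat(sprintf("final state: %s | v(final) = %.4g\n",
              paste(signif(x$final_state, 6), collapse = ", "), x$v_final))
  cat(sprintf("population minimum %.4g at t = %g\n",
              x$min_total, x$t_min_total))
  for (nm in names(x$extinction))
    if (!is.na(x$extinction[[nm]]))
      cat(sprintf("%s extinct at t = %g\n", nm, x$extinction[[nm]]))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Draws the compartment densities on the left axis and the resistance
#' trait on the right axis; therapy windows are shaded.
#'
#' @param x A `pacc_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.pacc_trajectory <- function(x, ...) {
  d <- x$data
  single <- !is_structured(x$mode)
  dens <- if (single) cbind(d$x1) else cbind(d$x1, d$x2)
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(d$t, dens, type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick")[seq_len(ncol(dens))],
                    xlab = "time", ylab = "cell density", ...)
  shade <- function(w, col) {
    if (nrow(w) > 0L)
      graphics::rect(w$start, graphics::par("usr")[3], w$end,
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor(col, 0.12), border = NA)
  }
  shade(x$schedule$chemo, "green")
  shade(x$schedule$targeted, "orange")
  graphics::par(new = TRUE)
  graphics::plot(d$t, d$v, type = "l", lwd = 2, col = "black", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("resistance trait v", side = 4, line = 2.5)
  leg <- if (single) c("x (2N+)", "v") else c("x1 (2N+)", "x2 (PACC)", "v")
  graphics::legend("topright", legend = leg, lty = 1, lwd = 2,
                   col = c(if (single) "steelblue" else
                     c("steelblue", "firebrick"), "black"), bty = "n")
  invisible(x)
}
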