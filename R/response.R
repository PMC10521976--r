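# Dose-response IC50 fitting and small response metrics.

#' Normalize raw viability signal to percent of control
#'
#' @param signal Numeric raw readings (e.g. luminescence).
#' @param vehicle_signal Raw readings of the vehicle-control wells.
#' @return `100 * signal / mean(vehicle_signal)`.
#' @export
percent_of_control <- function(signal, vehicle_signal) {
  100 * signal / mean(vehicle_signal)
}

#' Fit a normalized log-inhibitor dose-response model
#'
#' Least-squares fit of the three-parameter normalized response model
#' `Y = 100 / (1 + 10^(X - log_ic50))` with `X = log10(concentration)`:
#' top and bottom asymptotes are pinned at 100% and 0% and the slope at -1,
#' leaving `log_ic50` as the single free parameter (a variable Hill slope can
#' be freed with `variable_slope = TRUE`). The optimizer is deterministic: a
#' coarse grid over `[min(X) - 3, max(X) + 3]` picks the start, refined by
#' golden-section search ([stats::optimize()]; Nelder-Mead when the slope is
#' free). A grid optimum on the boundary (no half-maximal inhibition within
#' range) yields a non-converged result rather than a silent value.
#'
#' @param data data.frame with `concentration` (positive) and `response`
#'   (percent of control); at least 4 distinct concentrations.
#' @param variable_slope Also fit a Hill slope (default FALSE).
#' @param unit Concentration unit label carried through (default "uM").
#' @return An object of class `ic50_fit`: `log_ic50`, `ic50`
#'   (`10^log_ic50`), optional `hill_slope`, `residual_norm`, `converged`,
#'   `data`, `unit`. When the fit fails, `converged` is `FALSE` and the
#'   estimates are `NA`.
#' @examples
#' d <- simulate_dose_response(0.5, 10^seq(-2, 3, length.out = 8),
#'                             noise_sd = 0, seed = 1)
#' fit_ic50(d)
#' @export
fit_ic50 <- function(data, variable_slope = FALSE, unit = "uM") {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  if (any(data$concentration <= 0))
    stop("concentrations must be positive")
  if (length(unique(data$concentration)) < 4L)
    stop("need at least 4 distinct concentrations")
  x <- log10(data$concentration)
  y <- data$response

  fail <- function(msg) structure(
    list(log_ic50 = NA_real_, ic50 = NA_real_, hill_slope = NA_real_,
         residual_norm = NA_real_, converged = FALSE, message = msg,
         data = data, unit = unit), class = "ic50_fit")

  grid <- seq(min(x) - 3, max(x) + 3, by = 0.05)
  sse1 <- function(g) sum((y - 100 / (1 + 10^(x - g)))^2)
  g0 <- grid[which.min(vapply(grid, sse1, 0))]
  if (g0 <= grid[1L] + 0.05 || g0 >= grid[length(grid)] - 0.05)
    return(fail("no half-maximal inhibition within the tested range"))

  if (variable_slope) {
    sse2 <- function(p) sum((y - 100 / (1 + 10^(p[2L] * (x - p[1L]))))^2)
    opt <- stats::optim(c(g0, 1), sse2, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    logI <- opt$par[1L]; slope <- opt$par[2L]; rss <- opt$value
  } else {
    opt <- stats::optimize(sse1, c(g0 - 0.1, g0 + 0.1), tol = 1e-10)
    logI <- opt$minimum; slope <- -1; rss <- opt$objective
  }
  if (!is.finite(logI) || !is.finite(rss))
    return(fail("optimization did not converge"))

  structure(list(
    log_ic50 = logI,
    ic50 = 10^logI,
    hill_slope = slope,
    residual_norm = sqrt(rss),
    converged = TRUE, message = "ok",
    data = data, unit = unit), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$converged) {
    cat("IC50 fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("IC50 fit (normalized log-inhibitor model)\n"))
  cat(sprintf("  log10(IC50) = %.4f   IC50 = %.4g %s\n",
              x$log_ic50, x$ic50, x$unit))
  cat(sprintf("  residual norm = %.3f over %d points\n",
              x$residual_norm, nrow(x$data)))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(log_ic50 = object$log_ic50, ic50 = object$ic50)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else newdata$concentration
  x <- log10(conc)
  s <- if (is.null(object$hill_slope) || is.na(object$hill_slope)) 1
       else abs(object$hill_slope)
  100 / (1 + 10^(s * (x - object$log_ic50)))
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(log10(d$concentration), d$response,
                 xlab = sprintf("log10 concentration (%s)", x$unit),
                 ylab = "viability (% of control)", ...)
  if (x$converged) {
    xs <- seq(min(log10(d$concentration)), max(log10(d$concentration)),
              length.out = 200)
    graphics::lines(xs, 100 / (1 + 10^(xs - x$log_ic50)))
    graphics::abline(v = x$log_ic50, lty = 2)
  }
  invisible(x)
}

#' Resistance fold change between two IC50 values
#'
#' @param ic50_treated,ic50_control Positive IC50 values (or `ic50_fit`
#'   objects) in the same unit.
#' @param unit_treated,unit_control Optional unit labels; a mismatch is a
#'   hard error.
#' @return `ic50_treated / ic50_control`.
#' @export
resistance_fold_change <- function(ic50_treated, ic50_control,
                                   unit_treated = NULL, unit_control = NULL) {
  if (inherits(ic50_treated, "ic50_fit")) {
    unit_treated <- ic50_treated$unit; ic50_treated <- ic50_treated$ic50
  }
  if (inherits(ic50_control, "ic50_fit")) {
    unit_control <- ic50_control$unit; ic50_control <- ic50_control$ic50
  }
  if (!is.null(unit_treated) && !is.null(unit_control) &&
      unit_treated != unit_control)
    stop(sprintf("unit mismatch: %s vs %s", unit_treated, unit_control))
  stopifnot(ic50_treated > 0, ic50_control > 0)
  ic50_treated / ic50_control
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator)`; the fold change is
#' `2^-ddCt`. Assumes amplification efficiency 2 for both genes.
#'
#' @param ct_target_sample,ct_ref_sample Ct of the target and reference gene
#'   in the sample condition.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of the target and
#'   reference gene in the calibrator condition.
#' @return List with `ddct` and `fold`.
#' @examples
#' ddct_fold_change(20, 15, 24, 15)  # ddCt = -4, fold = 16
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample,
           ct_target_calibrator, ct_ref_calibrator)
  if (length(cts) != 4L || anyNA(cts))
    stop("all four Ct values are required")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  list(ddct = ddct, fold = 2^(-ddct))
}
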