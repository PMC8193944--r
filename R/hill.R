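#' Percent inhibition
#'
#' \code{100 * (1 - drug / control)}, the convention for expressing block of
#' a current or transient relative to its own control.
#'
#' @param control_value,drug_value Measurements in the same units; control
#'   must be nonzero.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(238, 65.5)  # 72.5
#' @export
percent_inhibition <- function(control_value, drug_value) {
  chk_num(control_value, "control_value", len = length(control_value))
  chk_num(drug_value, "drug_value", len = length(drug_value))
  if (any(control_value == 0)) stop_invalid("zero control value")
  100 * (1 - drug_value / control_value)
}

hill_curve <- function(conc, ec50, h, emax) {
  emax * conc^h / (conc^h + ec50^h)
}

#' Fit a Hill concentration-response curve
#'
#' Unweighted (optionally weighted) least squares of
#' \deqn{y = E_{max} C^h / (C^h + EC_{50}^h)}
#' to percent-inhibition points. The optimizer is restarted from a log-spaced
#' grid of EC50 values crossed with Hill slopes in [0.3, 4]; the best
#' sum-of-squares solution is kept, so the returned SSE is never above that
#' of any start.
#'
#' @param points A data frame with columns \code{concentration_um} and
#'   \code{inhibition_pct} (optional \code{sem_pct}, \code{n_cells}), or a
#'   numeric vector of concentrations if \code{inhibition_pct} is supplied.
#' @param inhibition_pct Optional numeric responses when \code{points} is a
#'   concentration vector.
#' @param emax_fixed Fixed maximal effect (default 100%); set
#'   \code{free_emax = TRUE} to fit it.
#' @param free_emax Fit Emax as a third parameter.
#' @param weights Optional per-point weights for the residual sum of squares
#'   (e.g. \code{1/sem^2}); default unweighted.
#' @return An object of class \code{hill_fit} with components
#'   \code{ec50_um}, \code{hill_h}, \code{emax_pct}, \code{sse},
#'   \code{converged}, \code{data}, \code{weights}, \code{free_emax}.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}.
#' @examples
#' fit <- fit_hill(ami_dose_response())
#' coef(fit)
#' @export
fit_hill <- function(points, inhibition_pct = NULL, emax_fixed = 100,
                     free_emax = FALSE, weights = NULL) {
  if (is.numeric(points) && !is.null(inhibition_pct))
    points <- data.frame(concentration_um = points,
                         inhibition_pct = inhibition_pct)
  if (!is.data.frame(points) ||
      !all(c("concentration_um", "inhibition_pct") %in% names(points)))
    stop_invalid("'points' needs columns concentration_um and inhibition_pct")
  conc <- points$concentration_um
  y <- points$inhibition_pct
  if (any(conc <= 0)) stop_invalid("concentrations must be positive")
  if (length(unique(conc)) < 3)
    stop_invalid("at least 3 distinct concentrations required")
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (length(w) != length(y) || any(w <= 0))
    stop_invalid("'weights' must be positive, one per point")

  obj <- function(p) {
    ec50 <- 10^p[1]; h <- exp(p[2])
    em <- if (free_emax) p[3] else emax_fixed
    sum(w * (y - hill_curve(conc, ec50, h, em))^2)
  }
  lg <- log10(range(conc))
  starts <- expand.grid(lec = seq(lg[1] - 1, lg[2] + 1, length.out = 9),
                        h0 = c(0.3, 0.5, 1, 1.5, 2, 3, 4))
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$lec[i], log(starts$h0[i]), if (free_emax) max(y))
    o <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  fit <- structure(list(
    ec50_um = 10^best$par[1],
    hill_h = exp(best$par[2]),
    emax_pct = if (free_emax) best$par[3] else emax_fixed,
    sse = best$value,
    converged = any_conv,
    data = points, weights = if (is.null(weights)) NULL else weights,
    free_emax = free_emax), class = "hill_fit")
  if (!any_conv)
    stop(structure(class = c("synphys_hill_no_convergence", "error", "condition"),
                   list(message = "Hill fit did not converge from any start",
                        call = sys.call(), fit = fit)))
  fit
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("<hill_fit>\n")
  cat(sprintf("  EC50 = %s uM, Hill coefficient h = %s, Emax = %s%% (%s)\n",
              format(x$ec50_um, digits = digits),
              format(x$hill_h, digits = digits),
              format(x$emax_pct, digits = digits),
              if (x$free_emax) "fitted" else "fixed"))
  cat(sprintf("  SSE = %s over %d points\n",
              format(x$sse, digits = digits), nrow(x$data)))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50_um = object$ec50_um, hill_h = object$hill_h,
    emax_pct = object$emax_pct)
}

#' Predict from a Hill fit
#'
#' Evaluates the fitted Hill equation; strictly increasing in concentration
#' for h > 0.
#'
#' @param object A \code{hill_fit}.
#' @param concentration Concentrations (same units as the fit); must be
#'   non-negative.
#' @param ... Unused.
#' @return Predicted percent inhibition.
#' @export
predict.hill_fit <- function(object, concentration = object$data$concentration_um,
                             ...) {
  chk_num(concentration, "concentration", len = length(concentration))
  if (any(concentration < 0)) stop_invalid("negative concentration")
  hill_curve(concentration, object$ec50_um, object$hill_h, object$emax_pct)
}

#' Hill-equation prediction (function form)
#' @inheritParams predict.hill_fit
#' @param fit A \code{hill_fit}.
#' @export
predict_hill <- function(fit, concentration) {
  stopifnot(inherits(fit, "hill_fit"))
  predict(fit, concentration)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...)
  object$data$inhibition_pct - fitted(object)

#' @export
summary.hill_fit <- function(object, ...) {
  out <- list(coef = coef(object), sse = object$sse,
              rmse = sqrt(mean(residuals(object)^2)),
              n = nrow(object$data), converged = object$converged,
              free_emax = object$free_emax)
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Hill concentration-response fit\n")
  print(round(x$coef, 4))
  cat(sprintf("SSE %.4g, RMSE %.4g over %d points; Emax %s; converged: %s\n",
              x$sse, x$rmse, x$n, if (x$free_emax) "fitted" else "fixed",
              x$converged))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  cc <- 10^seq(log10(min(d$concentration_um)) - 0.5,
               log10(max(d$concentration_um)) + 0.5, length.out = 200)
  graphics::plot(d$concentration_um, d$inhibition_pct, log = "x", pch = 16,
                 xlab = "concentration (uM)", ylab = "inhibition (%)",
                 ylim = range(0, d$inhibition_pct, x$emax_pct), ...)
  if (!is.null(d$sem_pct))
    graphics::arrows(d$concentration_um, d$inhibition_pct - d$sem_pct,
                     d$concentration_um, d$inhibition_pct + d$sem_pct,
                     angle = 90, code = 3, length = 0.03)
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}
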