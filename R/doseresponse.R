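# Hyperbolic iron / hemoglobin dose-response fitting and P50 extraction
# from oxygen-saturation curves.

.dr_columns <- function(data, a, b) {
  if (!is.data.frame(data)) abort_validation("'data' must be a data frame")
  nm <- names(data)
  if (all(c(a, b) %in% nm)) return(data[, c(a, b)])
  num <- which(vapply(data, is.numeric, TRUE))
  if (length(num) < 2) abort_validation("need two numeric columns ('%s', '%s')", a, b)
  out <- data[, num[1:2]]
  names(out) <- c(a, b)
  out
}

#' Fit the hyperbolic iron/hemoglobin dose-response model
#'
#' Nonlinear least squares fit of
#' \deqn{Hb = Hb_{max} \frac{[Fe^{3+}]}{EC_{50} + [Fe^{3+}]}}
#' to per-cell hemoglobin content measured at increasing medium iron
#' concentration. Fitting is on the untransformed scale (the response is
#' plotted and reported untransformed), with deterministic initial values:
#' `hb_max` starts at the largest observed response and `ec50` at the
#' positive concentration whose response is nearest half of it.
#'
#' @param data Data frame with columns `fe_conc` (umol/L chelated Fe3+)
#'   and `hb` (pg/cell), or any two numeric columns in that order. At
#'   least 3 distinct concentrations, at least one positive.
#' @return An object of class `"dr_fit"` with components `coefficients`
#'   (`hb_max`, `ec50`), `rss`, `converged`, `n_obs`, `data`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' d <- data.frame(fe_conc = c(0, 1.3, 2.6, 5.2, 13, 26, 52))
#' d$hb <- 30 * d$fe_conc / (5 + d$fe_conc)
#' coef(fit_hyperbolic(d))
#' @export
fit_hyperbolic <- function(data) {
  d <- .dr_columns(data, "fe_conc", "hb")
  if (any(!is.finite(d$fe_conc)) || any(!is.finite(d$hb)))
    abort_validation("non-finite values in dose-response data")
  if (any(d$fe_conc < 0) || any(d$hb < 0))
    abort_validation("concentrations and responses must be >= 0")
  if (length(unique(d$fe_conc)) < 3)
    abort_validation("need >= 3 distinct concentrations")
  if (!any(d$fe_conc > 0))
    abort_validation("need at least one positive concentration")
  if (all(d$hb == 0))
    abort_validation("all responses are zero; dose-response fit is degenerate")
  hb_max0 <- max(d$hb)
  pos <- d$fe_conc > 0
  ec50_0 <- d$fe_conc[pos][which.min(abs(d$hb[pos] - hb_max0 / 2))]
  if (ec50_0 <= 0) ec50_0 <- stats::median(d$fe_conc[pos])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      hb ~ hb_max * fe_conc / (ec50 + fe_conc), data = d,
      start = list(hb_max = hb_max0, ec50 = ec50_0),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) abort_solver("dose-response fit failed: %s",
                                     conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(
    list(coefficients = c(hb_max = unname(cf[["hb_max"]]),
                          ec50 = unname(cf[["ec50"]])),
         rss = sum(stats::residuals(fit)^2),
         converged = isTRUE(fit$convInfo$isConv),
         n_obs = nrow(d), data = d, fit = fit),
    class = "dr_fit")
}

#' Predicted hemoglobin at a medium iron concentration
#'
#' @param fit A `"dr_fit"`.
#' @param conc Concentrations, umol/L.
#' @return Predicted hemoglobin, pg/cell.
#' @export
predict_hb <- function(fit, conc) {
  if (!inherits(fit, "dr_fit")) abort_validation("'fit' must be a dr_fit")
  if (any(conc < 0)) abort_validation("'conc' must be >= 0")
  cf <- fit$coefficients
  cf[["hb_max"]] * conc / (cf[["ec50"]] + conc)
}

#' @export
coef.dr_fit <- function(object, ...) object$coefficients

#' @export
fitted.dr_fit <- function(object, ...) predict_hb(object, object$data$fe_conc)

#' @export
residuals.dr_fit <- function(object, ...) object$data$hb - fitted(object)

#' @export
predict.dr_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$fe_conc
          else if (is.data.frame(newdata)) newdata$fe_conc
          else newdata
  predict_hb(object, conc)
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("Hyperbolic dose-response fit: Hb = Hb_max * c / (EC50 + c)\n")
  cat(sprintf("  Hb_max = %.4g pg/cell, EC50 = %.4g umol/L\n",
              x$coefficients[["hb_max"]], x$coefficients[["ec50"]]))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              x$n_obs, x$rss, x$converged))
  invisible(x)
}

#' @export
summary.dr_fit <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(coefficients = s$coefficients, rss = object$rss,
              n_obs = object$n_obs, sigma = s$sigma)
  class(out) <- "summary.dr_fit"
  out
}

#' @export
print.summary.dr_fit <- function(x, ...) {
  cat("Hyperbolic dose-response fit\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Residual sd %.4g on %d observations\n", x$sigma, x$n_obs))
  invisible(x)
}

#' @export
plot.dr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$fe_conc, d$hb, pch = 16,
                 xlab = "chelated Fe3+ (umol/L)", ylab = "Hb (pg/cell)", ...)
  cc <- seq(0, max(d$fe_conc), length.out = 200)
  graphics::lines(cc, predict_hb(x, cc), col = "firebrick", lwd = 2)
  invisible(x)
}

# first 0.5-crossing of the saturation curve by linear interpolation
.p50_interp <- function(po2, sat) {
  o <- order(po2)
  po2 <- po2[o]; sat <- sat[o]
  agg <- tapply(sat, po2, mean)
  p <- as.numeric(names(agg)); s <- as.numeric(agg)
  for (i in seq_len(length(s) - 1)) {
    if ((s[i] - 0.5) * (s[i + 1] - 0.5) <= 0 && s[i] != s[i + 1]) {
      return(p[i] + (0.5 - s[i]) * (p[i + 1] - p[i]) / (s[i + 1] - s[i]))
    }
    if (s[i] == 0.5) return(p[i])
  }
  NA_real_
}

#' Fit a Hill curve to an oxygen-saturation measurement
#'
#' Least-squares fit of the Hill model
#' \deqn{S = \frac{pO_2^{\,n}}{P_{50}^{\,n} + pO_2^{\,n}}}
#' to fractional hemoglobin saturation versus oxygen partial pressure.
#' P50 is the partial pressure giving 50% saturation. A model-free P50
#' obtained by linear interpolation at the 0.5 crossing is reported
#' alongside as a cross-check (`p50_interp`); the curve must actually
#' span 0.5 or an error is raised.
#'
#' @param curve Data frame with columns `po2` (mmHg, >= 0) and
#'   `saturation` (fraction in [0, 1]).
#' @return An object of class `"hill_fit"` with `coefficients` (`p50`,
#'   `hill_n`), `p50_interp`, `rss`, `converged`, `n_obs`, `data`.
#' @examples
#' po2 <- seq(1, 120, by = 4)
#' curve <- data.frame(po2 = po2,
#'                     saturation = po2^2.7 / (26.8^2.7 + po2^2.7))
#' coef(fit_hill(curve))
#' @export
fit_hill <- function(curve) {
  d <- .dr_columns(curve, "po2", "saturation")
  if (any(!is.finite(d$po2)) || any(!is.finite(d$saturation)))
    abort_validation("non-finite values in oxygen-saturation curve")
  if (any(d$po2 < 0)) abort_validation("'po2' must be >= 0")
  if (any(d$saturation < 0 | d$saturation > 1))
    abort_validation("'saturation' must be in [0, 1]")
  if (min(d$saturation) > 0.5 || max(d$saturation) < 0.5)
    abort_validation("saturation curve does not span 0.5; P50 is undefined")
  p50_0 <- .p50_interp(d$po2, d$saturation)
  if (!is.finite(p50_0) || p50_0 <= 0) p50_0 <- stats::median(d$po2[d$po2 > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      saturation ~ po2^hill_n / (p50^hill_n + po2^hill_n), data = d,
      start = list(p50 = p50_0, hill_n = 2.7),
      lower = c(1e-6, 0.1), upper = c(Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) abort_solver("Hill fit failed: %s", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(
    list(coefficients = c(p50 = unname(cf[["p50"]]),
                          hill_n = unname(cf[["hill_n"]])),
         p50_interp = p50_0,
         rss = sum(stats::residuals(fit)^2),
         converged = isTRUE(fit$convInfo$isConv),
         n_obs = nrow(d), data = d, fit = fit),
    class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  po2 <- if (is.null(newdata)) object$data$po2
         else if (is.data.frame(newdata)) newdata$po2
         else newdata
  cf <- object$coefficients
  po2^cf[["hill_n"]] / (cf[["p50"]]^cf[["hill_n"]] + po2^cf[["hill_n"]])
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill oxygen-saturation fit: S = pO2^n / (P50^n + pO2^n)\n")
  cat(sprintf("  P50 = %.4g mmHg (interpolated: %.4g), n = %.3g\n",
              x$coefficients[["p50"]], x$p50_interp, x$coefficients[["hill_n"]]))
  cat(sprintf("  n_obs = %d, RSS = %.4g, converged: %s\n",
              x$n_obs, x$rss, x$converged))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$po2, d$saturation, pch = 16,
                 xlab = "pO2 (mmHg)", ylab = "fractional saturation", ...)
  pp <- seq(0, max(d$po2), length.out = 300)
  graphics::lines(pp, predict(x, pp), col = "firebrick", lwd = 2)
  graphics::abline(h = 0.5, v = x$coefficients[["p50"]], lty = 3, col = "grey50")
  invisible(x)
}
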