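#' Fit the power-law (Ostwald-de Waele) model to a flow curve
#'
#' Linear least squares of log viscosity on log shear rate:
#' eta = K gamma_dot^(n-1), so the log-log slope is n - 1 and the
#' intercept is log K. Fitting in log-log space is the field
#' convention for power-law indices and matches the straight-line
#' appearance of shear-thinning flow curves.
#'
#' @param curve a `flow_curve` or data frame with columns
#'   `shear_rate` (1/s) and `viscosity` (Pa.s); needs at least 4
#'   points spanning at least half a decade.
#' @return List with `K` (Pa.s^n), `n` (dimensionless) and
#'   `r_squared` (of the log-log fit).
#' @examples
#' fit_power_law(gen_flow_curve(K = 0.05, n = 0.4))
#' @export
fit_power_law <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("shear_rate", "viscosity") %in% names(curve)))
  if (any(curve$viscosity <= 0) || any(curve$shear_rate <= 0))
    stop("shear rates and viscosities must be positive")
  if (nrow(curve) < 4) stop("need at least 4 points")
  if (diff(range(log10(curve$shear_rate))) < 0.5)
    stop("shear rates must span at least half a decade")
  fit <- stats::lm(log(viscosity) ~ log(shear_rate), data = curve)
  cf <- stats::coef(fit)
  sst <- sum((log(curve$viscosity) - mean(log(curve$viscosity)))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(K = exp(cf[["(Intercept)"]]), n = 1 + cf[["log(shear_rate)"]],
       r_squared = r2)
}

#' Classify a flow curve as Newtonian
#'
#' A fitted flow behaviour index within `n_tol` of 1 counts as
#' Newtonian (viscosity variation within instrument sensitivity).
#'
#' @param fit result of [fit_power_law()].
#' @param n_tol tolerance on |n - 1| (default 0.1).
#' @return `TRUE` if Newtonian.
#' @export
classify_newtonian <- function(fit, n_tol = 0.1) {
  stopifnot(is.list(fit), !is.null(fit$n))
  abs(fit$n - 1) <= n_tol
}

#' Read a flow curve from CSV
#'
#' Expects columns `shear_rate_1_per_s` and `viscosity_Pa_s` (or
#' plain `shear_rate` / `viscosity`).
#'
#' @param path CSV file path.
#' @return A `flow_curve` data frame.
#' @export
read_flow_curve <- function(path) {
  d <- utils::read.csv(path)
  if (all(c("shear_rate_1_per_s", "viscosity_Pa_s") %in% names(d)))
    d <- data.frame(shear_rate = d$shear_rate_1_per_s,
                    viscosity = d$viscosity_Pa_s)
  stopifnot(all(c("shear_rate", "viscosity") %in% names(d)))
  class(d) <- c("flow_curve", "data.frame")
  d
}
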