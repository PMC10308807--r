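#' Physical properties of a wetting agent
#'
#' Container for the bulk properties the pipeline needs: density and
#' surface tension for drop-shape and retention-force work, and the
#' optional power-law (Ostwald-de Waele) parameters describing
#' shear-thinning suspensions, eta = K * gamma_dot^(n - 1).
#'
#' @param density liquid density, kg/m^3.
#' @param surface_tension liquid-vapour surface tension, N/m.
#' @param power_law_K consistency index K, Pa.s^n (optional).
#' @param power_law_n flow behaviour index n, dimensionless (optional;
#'   n = 1 is Newtonian, n < 1 shear-thinning).
#' @return An object of class `fluid_properties`.
#' @examples
#' minimal_medium <- fluid_properties(997, 0.072)
#' suspension <- fluid_properties(1200, 0.069, power_law_K = 0.05, power_law_n = 0.4)
#' @export
fluid_properties <- function(density, surface_tension,
                             power_law_K = NA_real_, power_law_n = NA_real_) {
  stopifnot(is.numeric(density), length(density) == 1L, density > 0,
            is.numeric(surface_tension), length(surface_tension) == 1L,
            surface_tension > 0)
  if (!is.na(power_law_K) && power_law_K <= 0)
    stop("power_law_K must be positive")
  if (!is.na(power_law_n) && power_law_n <= 0)
    stop("power_law_n must be positive")
  structure(list(density = density,
                 surface_tension = surface_tension,
                 power_law_K = power_law_K,
                 power_law_n = power_law_n),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> rho = %g kg/m^3, sigma = %g N/m\n",
              x$density, x$surface_tension))
  if (!is.na(x$power_law_K))
    cat(sprintf("  power law: K = %g Pa.s^n, n = %g\n",
                x$power_law_K, x$power_law_n))
  invisible(x)
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
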