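#' Excess area per molecule of a binary film
#'
#' The excess area at surface pressure \eqn{\pi} is
#' \eqn{\Delta A(\pi) = A_{12}(\pi) - X_1 A_1(\pi) - X_2 A_2(\pi)}, the
#' deviation of the mixed film's mean molecular area from the ideal
#' mole-fraction-weighted sum of the pure-component areas. Negative values
#' indicate condensation (attractive interactions), positive values expansion.
#'
#' @param series A [mixture_series()].
#' @param x2 Mole fraction of component 2, in `[0, 1]`. Values 0 and 1 denote
#'   the pure components (excess area is identically zero there).
#' @param pi_target Surface pressure (mN/m) reachable on all three isotherms.
#' @return Excess area in \eqn{\mathrm{\AA}^2}/molecule.
#' @export
excess_area <- function(series, x2, pi_target) {
  stopifnot(inherits(series, "mixture_series"))
  if (!is.finite(x2) || x2 < 0 || x2 > 1) {
    stop_monofilm("x2 must lie in [0, 1]", "monofilm_domain_error")
  }
  if (x2 == 0 || x2 == 1) return(0)
  mix <- series_mixture(series, x2)
  a12 <- area_at_pressure(mix, pi_target)
  a1 <- area_at_pressure(series$component1, pi_target)
  a2 <- area_at_pressure(series$component2, pi_target)
  a12 - ((1 - x2) * a1 + x2 * a2)
}

series_mixture <- function(series, x2) {
  k <- which(abs(series$fractions - x2) < 1e-9)
  if (!length(k)) {
    stop_monofilm(
      sprintf("no mixture isotherm at X2 = %g (available: %s)", x2,
              paste(series$fractions, collapse = ", ")),
      "monofilm_domain_error"
    )
  }
  series$mixtures[[k[[1L]]]]
}

#' Excess Gibbs free energy of mixing of a binary film
#'
#' Integrates the excess area over surface pressure from 0 to `pi_target` and
#' converts to molar energy:
#' \deqn{\Delta G^{exc} = N_A \int_0^{\pi} (A_{12} - X_1 A_1 - X_2 A_2)\, d\pi}
#' Negative values mean energetically favourable (attractive) mixing, zero
#' means ideal mixing or immiscibility. The integral uses the trapezoid rule
#' on a uniform pressure grid with step `dpi`; areas below the first recorded
#' pressure of a curve are taken constant at its lift-off area.
#'
#' @inheritParams excess_area
#' @param dpi Pressure step of the integration grid (mN/m, default 0.1).
#' @return \eqn{\Delta G^{exc}} in J/mol.
#' @export
#' @examples
#' gen <- generate_mixture_series(mixture_model(excess = "constant",
#'                                              excess_params = list(c = -1)),
#'                                fractions = 0.5, pi_max = 40, seed = 1)
#' excess_gibbs(gen$series, 0.5, 35)       # close to -1 * 35 * 6.02214
excess_gibbs <- function(series, x2, pi_target, dpi = 0.1) {
  stopifnot(inherits(series, "mixture_series"))
  if (!is.finite(x2) || x2 < 0 || x2 > 1) {
    stop_monofilm("x2 must lie in [0, 1]", "monofilm_domain_error")
  }
  if (x2 == 0 || x2 == 1) return(0)
  grid <- pressure_grid(pi_target, dpi)
  da <- vapply(grid, function(p) excess_area(series, x2, p), numeric(1L))
  trapz(grid, da) * physical_constants$unit_factor
}

#' Excess-Gibbs curve over film composition
#'
#' Evaluates [excess_gibbs()] at every mole fraction available in the series
#' and augments the curve with the exact pure-component endpoints
#' \eqn{\Delta G^{exc}(0) = \Delta G^{exc}(1) = 0}.
#'
#' @inheritParams excess_gibbs
#' @return An object of class `excess_curve`: list with `pi_target`,
#'   `mole_fractions`, `gexc` (J/mol) and `excess_area`
#'   (\eqn{\mathrm{\AA}^2} at `pi_target`).
#' @export
excess_gibbs_curve <- function(series, pi_target, dpi = 0.1) {
  stopifnot(inherits(series, "mixture_series"))
  xs <- series$fractions
  g <- vapply(xs, function(x) excess_gibbs(series, x, pi_target, dpi),
              numeric(1L))
  da <- vapply(xs, function(x) excess_area(series, x, pi_target), numeric(1L))
  structure(
    list(pi_target = pi_target,
         mole_fractions = c(0, xs, 1),
         gexc = c(0, g, 0),
         excess_area = c(0, da, 0)),
    class = "excess_curve"
  )
}

#' @export
print.excess_curve <- function(x, ...) {
  cat(sprintf("<excess_curve> at pi = %g mN/m\n", x$pi_target))
  print(data.frame(X2 = x$mole_fractions, dA_A2 = x$excess_area,
                   gexc_J_mol = x$gexc), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.excess_curve <- function(x, ...) {
  data.frame(X2 = x$mole_fractions, dA_A2 = x$excess_area,
             gexc_J_mol = x$gexc)
}

#' Largest-magnitude interior extremum of an excess curve
#'
#' The composition of the extremum of \eqn{\Delta G^{exc}(X_2)} identifies the
#' most strongly interacting film composition; a minimum at a simple rational
#' fraction suggests a surface complex of that stoichiometry (see
#' [stoichiometry_from_fraction()]).
#'
#' @param curve An `excess_curve` from [excess_gibbs_curve()].
#' @return List with `x2`, `value` (J/mol); `NULL` elements when the curve is
#'   identically zero (no extremum).
#' @export
curve_extremum <- function(curve) {
  stopifnot(inherits(curve, "excess_curve"))
  n <- length(curve$gexc)
  if (n < 3L) {
    stop_monofilm("curve needs at least 3 points", "monofilm_domain_error")
  }
  interior <- 2:(n - 1L)
  mag <- abs(curve$gexc[interior])
  if (max(mag) == 0) return(list(x2 = NULL, value = NULL))
  # ties broken toward smaller X2 (fractions are stored sorted)
  k <- interior[[which.max(mag)]]
  list(x2 = curve$mole_fractions[[k]], value = curve$gexc[[k]])
}

#' Integer complex stoichiometry from a mole fraction
#'
#' Finds the smallest integer pair \eqn{(n_1, n_2)} whose composition
#' \eqn{n_2/(n_1+n_2)} is closest to `x2`, with \eqn{n_1+n_2} bounded by
#' `max_denominator`. A \eqn{\Delta G^{exc}} minimum at \eqn{X_2 = 0.25}
#' thus maps to a 3:1 surface complex.
#'
#' @param x2 Mole fraction of component 2, strictly between 0 and 1.
#' @param max_denominator Upper bound on \eqn{n_1 + n_2} (default 12).
#' @return Integer vector `c(n1, n2)`.
#' @export
#' @examples
#' stoichiometry_from_fraction(0.25)  # 3:1
stoichiometry_from_fraction <- function(x2, max_denominator = 12L) {
  if (!is.finite(x2) || x2 <= 0 || x2 >= 1) {
    stop_monofilm("x2 must lie strictly between 0 and 1",
                  "monofilm_domain_error")
  }
  best <- NULL
  best_err <- Inf
  for (total in 2:max_denominator) {
    for (n2 in 1:(total - 1L)) {
      err <- abs(n2 / total - x2)
      # strict improvement keeps the smallest total for equally good ratios
      if (err < best_err - 1e-12) {
        best_err <- err
        best <- c(total - n2, n2)
      }
    }
  }
  as.integer(best)
}

#' Percent change of the compressional modulus upon mixing
#'
#' Positive values mean the mixed film is stiffer than the reference pure
#' film (condensation); negative values mean fluidization.
#'
#' @param cs_mix Modulus of the mixed film (mN/m).
#' @param cs_ref Modulus of the reference pure film (mN/m), positive.
#' @return Percent change, `100 * (cs_mix - cs_ref) / cs_ref`.
#' @export
percent_modulus_change <- function(cs_mix, cs_ref) {
  if (any(!is.finite(cs_ref)) || any(cs_ref <= 0)) {
    stop_monofilm("cs_ref must be positive", "monofilm_domain_error")
  }
  100 * (cs_mix - cs_ref) / cs_ref
}
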