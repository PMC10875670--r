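#' Parametric isotherm models for synthetic data
#'
#' Three equation-of-state shapes cover the curve families seen on Langmuir
#' troughs:
#' \describe{
#'   \item{`"ideal-gas"`}{\eqn{\pi = C/A}, the 2D ideal gas. Default
#'     \eqn{C = 404.6} mN/m \eqn{\cdot \mathrm{\AA}^2} (\eqn{k_B T} at 20 C in
#'     surface units), for which \eqn{C_s^{-1} = \pi} exactly.}
#'   \item{`"condensed"`}{linear condensed-type film without plateau:
#'     \eqn{\pi = s\,(A_0 - A)} above lift-off \eqn{A_0}, optionally followed
#'     by a collapse (pressure falling past the collapse point).}
#'   \item{`"le-plateau-lc"`}{DPPC-like piecewise-linear isotherm: zero
#'     pressure above lift-off, a liquid-expanded rise, a horizontal LE--LC
#'     coexistence plateau, a steep liquid-condensed rise, then collapse.
#'     Defaults: lift-off 90 \eqn{\mathrm{\AA}^2}, plateau at 5 mN/m between
#'     78 and 58 \eqn{\mathrm{\AA}^2}, collapse at 55 mN/m and 42
#'     \eqn{\mathrm{\AA}^2}.}
#' }
#' The model is continuous in \eqn{\pi}; an optional Gaussian noise standard
#' deviation on \eqn{\pi} (`noise_sd`, mN/m) emulates Wilhelmy-plate noise.
#'
#' @param kind Model kind; one of `"ideal-gas"`, `"condensed"`,
#'   `"le-plateau-lc"`.
#' @param ... Named parameters overriding the kind's defaults (see Details).
#' @param noise_sd Gaussian noise on pressure, mN/m (default 0).
#' @return An `isotherm_model` object with fields `kind`, `params`,
#'   `noise_sd`, plus closed-form `pi_of_A`, `dpi_dA` functions and a
#'   `features` record (lift-off, plateau bounds, collapse).
#' @export
#' @examples
#' m <- isotherm_model("le-plateau-lc")
#' m$features$plateau_pressure
isotherm_model <- function(kind = c("ideal-gas", "condensed", "le-plateau-lc"),
                           ..., noise_sd = 0) {
  kind <- match.arg(kind)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_monofilm("noise_sd must be non-negative", "monofilm_domain_error")
  }
  p <- switch(kind,
    "ideal-gas" = list(C = 404.6, a_range = c(12, 60)),
    "condensed" = list(liftoff = 52, slope = 2.8, collapse_pressure = 57,
                       post_slope = 1.5, a_range = c(28, 60)),
    "le-plateau-lc" = list(liftoff = 90, plateau_pressure = 5,
                           plateau_onset_area = 78, plateau_end_area = 58,
                           collapse_pressure = 55, collapse_area = 42,
                           post_slope = 1.5, a_range = c(38, 100))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop_monofilm(sprintf("unknown parameter(s) for %s model: %s", kind,
                          paste(unknown, collapse = ", ")),
                  "monofilm_domain_error")
  }
  p <- modifyList(p, dots)

  if (kind == "ideal-gas") {
    if (p$C <= 0) stop_monofilm("C must be positive", "monofilm_domain_error")
    pi_of_A <- function(A) p$C / A
    dpi_dA <- function(A) -p$C / A^2
    features <- list(collapse_pressure = p$C / min(p$a_range))
  } else if (kind == "condensed") {
    if (p$slope <= 0 || p$post_slope < 0) {
      stop_monofilm("slopes must be positive", "monofilm_domain_error")
    }
    a_col <- p$liftoff - p$collapse_pressure / p$slope
    pi_of_A <- function(A) {
      ifelse(A >= p$liftoff, 0,
        ifelse(A >= a_col, p$slope * (p$liftoff - A),
          p$collapse_pressure - p$post_slope * (a_col - A)))
    }
    dpi_dA <- function(A) {
      ifelse(A >= p$liftoff, 0, ifelse(A >= a_col, -p$slope, p$post_slope))
    }
    features <- list(liftoff_area = p$liftoff,
                     collapse_pressure = p$collapse_pressure,
                     collapse_area = a_col,
                     le_slope = p$slope)
  } else {
    s_le <- p$plateau_pressure / (p$liftoff - p$plateau_onset_area)
    s_lc <- (p$collapse_pressure - p$plateau_pressure) /
            (p$plateau_end_area - p$collapse_area)
    if (s_le <= 0 || s_lc <= 0 || p$post_slope < 0) {
      stop_monofilm("model areas must decrease through lift-off, plateau and collapse",
                    "monofilm_domain_error")
    }
    pi_of_A <- function(A) {
      ifelse(A >= p$liftoff, 0,
      ifelse(A >= p$plateau_onset_area, s_le * (p$liftoff - A),
      ifelse(A >= p$plateau_end_area, p$plateau_pressure,
      ifelse(A >= p$collapse_area,
             p$plateau_pressure + s_lc * (p$plateau_end_area - A),
             p$collapse_pressure - p$post_slope * (p$collapse_area - A)))))
    }
    dpi_dA <- function(A) {
      ifelse(A >= p$liftoff, 0,
      ifelse(A >= p$plateau_onset_area, -s_le,
      ifelse(A >= p$plateau_end_area, 0,
      ifelse(A >= p$collapse_area, -s_lc, p$post_slope))))
    }
    features <- list(
      liftoff_area = p$liftoff,
      plateau_pressure = p$plateau_pressure,
      plateau_onset_area = p$plateau_onset_area,
      plateau_end_area = p$plateau_end_area,
      collapse_pressure = p$collapse_pressure,
      collapse_area = p$collapse_area,
      le_slope = s_le,
      lc_slope = s_lc
    )
  }
  # analytic crossing area for a lift-off threshold t (linear first rise)
  if (!is.null(features$liftoff_area)) {
    slope0 <- if (kind == "condensed") p$slope else features$le_slope
    features$liftoff_area_at <- local({
      a0 <- features$liftoff_area; s0 <- slope0
      function(threshold) a0 - threshold / s0
    })
  }
  structure(
    list(kind = kind, params = p, noise_sd = noise_sd,
         pi_of_A = pi_of_A, dpi_dA = dpi_dA, features = features),
    class = "isotherm_model"
  )
}

#' Generate a synthetic isotherm with its analytic ground truth
#'
#' Samples the model on a uniform descending area grid and (optionally) adds
#' Gaussian pressure noise. The model's closed-form \eqn{\pi(A)},
#' \eqn{\pi'(A)} and feature locations are returned alongside the data so
#' that recovery tests never hard-code expectations. Identical seeds give
#' identical output.
#'
#' @param model An [isotherm_model()].
#' @param n_points Number of sampled points (at least 20).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param label Label for the resulting isotherm.
#' @return List with `isotherm` (an [isotherm()]) and `truth` (the model's
#'   `pi_of_A`, `dpi_dA`, `features`, the noise level and the area grid).
#' @export
generate_isotherm <- function(model, n_points = 200L, seed, label = model$kind) {
  stopifnot(inherits(model, "isotherm_model"))
  if (n_points < 20L) {
    stop_monofilm("n_points must be at least 20", "monofilm_domain_error")
  }
  a <- seq(max(model$params$a_range), min(model$params$a_range),
           length.out = n_points)
  p <- model$pi_of_A(a)
  if (any(p < 0)) {
    stop_monofilm("model produced negative pressure before noise",
                  "monofilm_domain_error")
  }
  if (model$noise_sd > 0) {
    p <- with_seed(seed, p + rnorm(n_points, sd = model$noise_sd))
    p <- pmax(p, -0.49)  # keep within the sensor-noise tolerance
  }
  list(
    isotherm = isotherm(a, p, label = label),
    truth = list(pi_of_A = model$pi_of_A, dpi_dA = model$dpi_dA,
                 features = model$features, noise_sd = model$noise_sd,
                 area_grid = a)
  )
}

#' Binary-mixture models with prescribed excess area
#'
#' Couples two pure-component [isotherm_model()]s with an excess-area
#' function \eqn{\Delta A(\pi, X)} from a small family with closed-form
#' \eqn{\pi}-integrals, providing the analytic oracle for the excess-Gibbs
#' computation:
#' \describe{
#'   \item{`"zero"`}{ideal mixing, \eqn{\Delta A = 0}.}
#'   \item{`"constant"`}{\eqn{\Delta A = c} at every pressure (default
#'     \eqn{c = -1} \eqn{\mathrm{\AA}^2}).}
#'   \item{`"triangular"`}{\eqn{\Delta A} rises linearly from 0 at
#'     \eqn{\pi = 0} to \eqn{c} at `pi_peak`, falls back to 0 at
#'     `2 pi_peak`, and stays 0 beyond.}
#'   \item{`"xscaled"`}{\eqn{\Delta A = 4 c\, X(1-X)}, composition-dependent
#'     with extremum at \eqn{X = 0.5}.}
#' }
#'
#' @param component1,component2 Pure-component [isotherm_model()]s; defaults
#'   are two condensed-type films with different lift-off areas, sampled from
#'   lift-off down (no zero-pressure plateau region), so that \eqn{A(\pi)} is
#'   globally linear and exactly interpolable.
#' @param excess Excess-area kind (see Details).
#' @param excess_params Named list of parameters: `c` (\eqn{\mathrm{\AA}^2}),
#'   `pi_peak` (mN/m, triangular only).
#' @return A `mixture_model` object with `delta_A(pi, X)` and its closed-form
#'   integral `gexc_closed(X, pi_target)` in J/mol.
#' @export
mixture_model <- function(component1 = isotherm_model("condensed",
                                                      liftoff = 52, slope = 2.8,
                                                      a_range = c(32, 52)),
                          component2 = isotherm_model("condensed",
                                                      liftoff = 40, slope = 3.6,
                                                      a_range = c(28.5, 40)),
                          excess = c("zero", "constant", "triangular", "xscaled"),
                          excess_params = list()) {
  stopifnot(inherits(component1, "isotherm_model"),
            inherits(component2, "isotherm_model"))
  excess <- match.arg(excess)
  ep <- modifyList(list(c = -1, pi_peak = 17.5), excess_params)
  u <- physical_constants$unit_factor
  delta_A <- switch(excess,
    zero = function(pi, X) rep(0, length(pi)),
    constant = function(pi, X) rep(ep$c, length(pi)),
    triangular = function(pi, X) {
      ifelse(pi <= ep$pi_peak, ep$c * pi / ep$pi_peak,
        ifelse(pi <= 2 * ep$pi_peak, ep$c * (2 - pi / ep$pi_peak), 0))
    },
    xscaled = function(pi, X) rep(4 * ep$c * X * (1 - X), length(pi))
  )
  gexc_closed <- switch(excess,
    zero = function(X, pi_t) 0,
    constant = function(X, pi_t) ep$c * pi_t * u,
    triangular = function(X, pi_t) {
      pk <- ep$pi_peak
      area <- if (pi_t <= pk) {
        ep$c * pi_t^2 / (2 * pk)
      } else if (pi_t <= 2 * pk) {
        ep$c * pk / 2 + ep$c * (2 * (pi_t - pk) - (pi_t^2 - pk^2) / (2 * pk))
      } else {
        ep$c * pk
      }
      area * u
    },
    xscaled = function(X, pi_t) 4 * ep$c * X * (1 - X) * pi_t * u
  )
  structure(
    list(component1 = component1, component2 = component2,
         excess = excess, excess_params = ep,
         delta_A = delta_A, gexc_closed = gexc_closed),
    class = "mixture_model"
  )
}

#' Generate a binary mixture series with closed-form excess Gibbs energy
#'
#' The pure components are sampled from their models on an area grid; each
#' mixture isotherm is then built on a uniform pressure grid as
#' \eqn{A_{12}(\pi) = X_1 A_1(\pi) + X_2 A_2(\pi) + \Delta A(\pi, X_2)},
#' where \eqn{A_1, A_2} are read off the *sampled* pure isotherms with
#' [area_at_pressure()]. Because mixture and integration grids share their
#' pressure nodes, the ideal (`"zero"`) model yields an excess of exactly
#' zero at every node, and the closed-form \eqn{\Delta G^{exc}} record is an
#' exact oracle for the piecewise-linear excess families.
#'
#' @param model A [mixture_model()].
#' @param fractions Mole fractions \eqn{X_2} strictly inside (0, 1).
#' @param pi_max Largest pressure on the mixture grids (mN/m); must be
#'   reachable on both pure components.
#' @param seed Integer seed (noise reproducibility).
#' @param dpi Pressure grid step for the mixture curves (default 0.1 mN/m,
#'   matching the default integration step of [excess_gibbs()]).
#' @param n_points Sample count for the pure-component isotherms.
#' @return List with `series` (a [mixture_series()]) and `truth`
#'   (`gexc_closed(X, pi_target)`, `delta_A`, the component truths).
#' @export
generate_mixture_series <- function(model = mixture_model(), fractions,
                                    pi_max = 40, seed = 1L, dpi = 0.1,
                                    n_points = 200L) {
  stopifnot(inherits(model, "mixture_model"))
  fr <- as.numeric(fractions)
  if (!length(fr) || any(fr <= 0) || any(fr >= 1)) {
    stop_monofilm("fractions must lie strictly between 0 and 1",
                  "monofilm_domain_error")
  }
  g1 <- generate_isotherm(model$component1, n_points, seed = seed,
                          label = "component1")
  g2 <- generate_isotherm(model$component2, n_points, seed = seed + 1L,
                          label = "component2")
  grid <- pressure_grid(pi_max, dpi)
  if (pi_max > max(g1$isotherm$pressure) || pi_max > max(g2$isotherm$pressure)) {
    stop_monofilm("pi_max exceeds a pure-component isotherm",
                  "monofilm_range_error")
  }
  a1 <- vapply(grid, function(p) area_at_pressure(g1$isotherm, p), numeric(1L))
  a2 <- vapply(grid, function(p) area_at_pressure(g2$isotherm, p), numeric(1L))
  mixtures <- lapply(fr, function(x2) {
    a12 <- (1 - x2) * a1 + x2 * a2 + model$delta_A(grid, x2)
    isotherm(a12, grid, label = sprintf("mixture_X2_%g", x2))
  })
  names(mixtures) <- as.character(fr)
  list(
    series = mixture_series(g1$isotherm, g2$isotherm, mixtures),
    truth = list(gexc_closed = model$gexc_closed, delta_A = model$delta_A,
                 excess = model$excess, excess_params = model$excess_params,
                 component1 = g1$truth, component2 = g2$truth)
  )
}
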