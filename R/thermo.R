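#' Surface compressional modulus along an isotherm
#'
#' Computes \eqn{C_s^{-1} = -A \, (\partial\pi / \partial A)}, the in-plane
#' elastic modulus of the film, on the pre-collapse compression branch. The
#' derivative is estimated by a Savitzky--Golay-style local polynomial fit of
#' \eqn{\pi(A)} (default: 11-point window, order 3), since differentiation
#' amplifies experimental noise.
#'
#' @param iso An [isotherm()] with at least as many points as the smoothing
#'   window.
#' @param window Odd number of points in the local fit window.
#' @param order Polynomial order of the local fit (must be below `window`).
#' @return An object of class `modulus_curve`: list with `pressure` (smoothed
#'   \eqn{\pi}, mN/m, compression order), `area` (\eqn{\mathrm{\AA}^2}),
#'   `modulus` (\eqn{C_s^{-1}}, mN/m), `source_label`, and `smoothing`
#'   parameters. Restricted to the branch up to the first global maximum of
#'   the smoothed pressure.
#' @export
#' @examples
#' iso <- generate_isotherm(isotherm_model("ideal-gas"), n_points = 100, seed = 1)
#' mc <- compressional_modulus(iso$isotherm)
#' # for a 2D ideal gas Cs^-1 equals pi itself
#' head(cbind(mc$pressure, mc$modulus))
compressional_modulus <- function(iso, window = 11L, order = 3L) {
  stopifnot(inherits(iso, "isotherm"))
  if (any(iso$area == 0)) {
    stop_monofilm("zero area encountered", "monofilm_domain_error")
  }
  a <- iso$area
  p <- iso$pressure
  p_s <- local_poly(a, p, window = window, order = order, deriv = 0L)
  dpda <- local_poly(a, p, window = window, order = order, deriv = 1L)
  cs <- -a * dpda
  imax <- which.max(p_s)
  keep <- seq_len(imax)
  structure(
    list(pressure = p_s[keep], area = a[keep], modulus = cs[keep],
         source_label = iso$label,
         smoothing = list(window = as.integer(window), order = as.integer(order))),
    class = "modulus_curve"
  )
}

#' @export
print.modulus_curve <- function(x, ...) {
  cat(sprintf(
    "<modulus_curve> %s: %d points, Cs^-1 max %.4g mN/m (window %d, order %d)\n",
    x$source_label, length(x$modulus), max(x$modulus),
    x$smoothing$window, x$smoothing$order
  ))
  invisible(x)
}

#' @export
as.data.frame.modulus_curve <- function(x, ...) {
  data.frame(pi_mN_m = x$pressure, cs_inv_mN_m = x$modulus)
}

#' Classify the 2D phase state of a film from its compressional modulus
#'
#' The classical modulus ranges: below 25 mN/m low-density liquid, 25--50
#' liquid-expanded, 100--250 liquid-condensed, above 500 solid. The literature
#' ranges leave gaps, which are labelled rather than silently extended:
#' (50, 100) is `"intermediate"` and (250, 500] is `"transitional"`.
#'
#' @param modulus \eqn{C_s^{-1}} value(s) in mN/m; finite and non-negative.
#' @return Character vector of phase labels, one of `"low-density-liquid"`,
#'   `"liquid-expanded"`, `"intermediate"`, `"liquid-condensed"`,
#'   `"transitional"`, `"solid"`.
#' @export
#' @examples
#' classify_phase(c(10, 40, 75, 150, 300, 600))
classify_phase <- function(modulus) {
  if (!is.numeric(modulus) || any(!is.finite(modulus)) || any(modulus < 0)) {
    stop_monofilm("modulus must be finite and non-negative",
                  "monofilm_domain_error")
  }
  vapply(modulus, function(m) {
    if (m < 25) "low-density-liquid"
    else if (m <= 50) "liquid-expanded"
    else if (m < 100) "intermediate"
    else if (m <= 250) "liquid-condensed"
    else if (m <= 500) "transitional"
    else "solid"
  }, character(1L))
}

#' Lift-off point of an isotherm
#'
#' The lift-off point is the molecular area at which surface pressure first
#' rises above the baseline on compression. The criterion used here is the
#' largest area at which the smoothed pressure first exceeds `threshold`,
#' linearly interpolated between the bracketing points.
#'
#' @param iso An [isotherm()].
#' @param threshold Pressure threshold in mN/m (default 0.5).
#' @param window,order Smoothing parameters as in [compressional_modulus()].
#' @return Lift-off area (\eqn{\mathrm{\AA}^2}). If the pressure already
#'   exceeds the threshold at the largest recorded area, that area is returned
#'   with attribute `boundary = TRUE`.
#' @export
detect_liftoff <- function(iso, threshold = 0.5, window = 11L, order = 3L) {
  stopifnot(inherits(iso, "isotherm"))
  if (!is.finite(threshold) || threshold < 0) {
    stop_monofilm("threshold must be finite and non-negative",
                  "monofilm_domain_error")
  }
  p_s <- local_poly(iso$area, iso$pressure, window = window, order = order)
  above <- which(p_s > threshold)
  if (!length(above)) {
    stop_monofilm(
      sprintf("pressure never exceeds %.3g mN/m on %s", threshold, iso$label),
      "monofilm_feature_error"
    )
  }
  i <- above[[1L]]
  if (i == 1L) {
    return(structure(iso$area[[1L]], boundary = TRUE))
  }
  w <- (threshold - p_s[[i - 1L]]) / (p_s[[i]] - p_s[[i - 1L]])
  iso$area[[i - 1L]] + w * (iso$area[[i]] - iso$area[[i - 1L]])
}

#' Collapse pressure of an isotherm
#'
#' Collapse is the pressure maximum at which the monolayer fails and ejects
#' material into the third dimension. Detected as the smoothed pressure at its
#' first global maximum along compression (ties broken toward larger area).
#' When the pressure is still rising at the smallest recorded area the film
#' never collapsed within the experiment; the last pressure is returned with
#' attribute `censored = TRUE`.
#'
#' @inheritParams detect_liftoff
#' @return Collapse pressure (mN/m), possibly with attributes `censored` and
#'   `area` (the area at collapse).
#' @export
detect_collapse <- function(iso, window = 11L, order = 3L) {
  stopifnot(inherits(iso, "isotherm"))
  p_s <- local_poly(iso$area, iso$pressure, window = window, order = order)
  i <- which.max(p_s)
  censored <- i == length(p_s)
  structure(p_s[[i]], censored = censored, area = iso$area[[i]])
}

#' LE--LC coexistence plateau from a modulus curve
#'
#' In the phase-coexistence plateau the isotherm is nearly horizontal, so
#' \eqn{C_s^{-1}} dips close to zero between the liquid-expanded and
#' liquid-condensed branches. A plateau is reported when the modulus falls
#' below `ceiling` between two local maxima that each exceed 25 mN/m (i.e.
#' both neighbouring branches reach at least the liquid-expanded range);
#' onset and end are the pressures at which the modulus crosses the ceiling.
#'
#' Because the derivative uses a centred smoothing window, the ceiling
#' crossings land a fraction of a window inside the horizontal plateau; on a
#' near-ideal plateau the reported onset/end pressures are therefore accurate
#' to about 0.1 mN/m (plus pressure noise), the detection resolution of this
#' estimator.
#'
#' @param mc A `modulus_curve` from [compressional_modulus()].
#' @param ceiling Modulus ceiling defining the dip (mN/m, default 10).
#' @return `NULL` when no plateau is found, otherwise a list with
#'   `pi_onset`, `pi_end` (mN/m), `A_onset`, `A_end` (\eqn{\mathrm{\AA}^2})
#'   and `min_modulus`.
#' @export
detect_plateau <- function(mc, ceiling = 10) {
  stopifnot(inherits(mc, "modulus_curve"))
  cs <- mc$modulus
  n <- length(cs)
  if (n < 3L) return(NULL)
  # interior local maxima of the modulus exceeding the LE floor
  is_max <- vapply(seq_len(n), function(i) {
    if (i == 1L || i == n) return(cs[[i]] >= max(cs) - 1e-12)
    cs[[i]] >= cs[[i - 1L]] && cs[[i]] >= cs[[i + 1L]]
  }, logical(1L))
  peaks <- which(is_max & cs > 25)
  if (length(peaks) < 2L) return(NULL)
  left <- peaks[[1L]]
  right <- peaks[[length(peaks)]]
  seg <- left:right
  imin <- seg[[which.min(cs[seg])]]
  if (cs[[imin]] >= ceiling) return(NULL)

  cross_pressure <- function(i, j) {
    # modulus crosses `ceiling` between i and j; interpolate in pressure
    w <- (ceiling - cs[[i]]) / (cs[[j]] - cs[[i]])
    mc$pressure[[i]] + w * (mc$pressure[[j]] - mc$pressure[[i]])
  }
  cross_area <- function(i, j) {
    w <- (ceiling - cs[[i]]) / (cs[[j]] - cs[[i]])
    mc$area[[i]] + w * (mc$area[[j]] - mc$area[[i]])
  }
  i_on <- imin
  while (i_on > left && cs[[i_on - 1L]] < ceiling) i_on <- i_on - 1L
  i_end <- imin
  while (i_end < right && cs[[i_end + 1L]] < ceiling) i_end <- i_end + 1L
  if (i_on == left || i_end == right) return(NULL)
  list(
    pi_onset = cross_pressure(i_on - 1L, i_on),
    pi_end = cross_pressure(i_end + 1L, i_end),
    A_onset = cross_area(i_on - 1L, i_on),
    A_end = cross_area(i_end + 1L, i_end),
    min_modulus = cs[[imin]]
  )
}

#' Feature report for a single isotherm
#'
#' Convenience wrapper combining [detect_liftoff()], [detect_collapse()],
#' [detect_plateau()] and the maximum compressional modulus into one record.
#'
#' @inheritParams detect_liftoff
#' @param plateau_ceiling Passed to [detect_plateau()].
#' @return A list of class `isotherm_features` with fields `label`,
#'   `liftoff_area`, `collapse_pressure`, `collapse_censored`, `plateau`
#'   (or `NULL`), `max_modulus`, `phase_at_max`.
#' @export
isotherm_features <- function(iso, threshold = 0.5, plateau_ceiling = 10,
                              window = 11L, order = 3L) {
  mc <- compressional_modulus(iso, window = window, order = order)
  collapse <- detect_collapse(iso, window = window, order = order)
  liftoff <- detect_liftoff(iso, threshold = threshold,
                            window = window, order = order)
  structure(
    list(
      label = iso$label,
      liftoff_area = as.numeric(liftoff),
      liftoff_boundary = isTRUE(attr(liftoff, "boundary")),
      collapse_pressure = as.numeric(collapse),
      collapse_censored = isTRUE(attr(collapse, "censored")),
      plateau = detect_plateau(mc, ceiling = plateau_ceiling),
      max_modulus = max(mc$modulus),
      phase_at_max = classify_phase(max(0, max(mc$modulus)))
    ),
    class = "isotherm_features"
  )
}

#' @export
print.isotherm_features <- function(x, ...) {
  cat(sprintf("<isotherm_features> %s\n", x$label))
  cat(sprintf("  lift-off: %.2f A^2%s\n", x$liftoff_area,
              if (x$liftoff_boundary) " (boundary)" else ""))
  cat(sprintf("  collapse: %.2f mN/m%s\n", x$collapse_pressure,
              if (x$collapse_censored) " (censored)" else ""))
  if (is.null(x$plateau)) {
    cat("  plateau: none\n")
  } else {
    cat(sprintf("  plateau: pi %.2f-%.2f mN/m, A %.2f-%.2f A^2\n",
                x$plateau$pi_onset, x$plateau$pi_end,
                x$plateau$A_onset, x$plateau$A_end))
  }
  cat(sprintf("  max Cs^-1: %.1f mN/m (%s)\n", x$max_modulus, x$phase_at_max))
  invisible(x)
}
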