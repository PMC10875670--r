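#' Construct a surface pressure--area isotherm
#'
#' An `isotherm` is the experimental unit of the thermodynamic track: surface
#' pressure \eqn{\pi} (mN/m) recorded against mean molecular area A
#' (\eqn{\mathrm{\AA}^2}/molecule) during compression. Rows are stored in
#' compression order (strictly decreasing area); duplicate areas are collapsed
#' by averaging their pressures.
#'
#' Small negative pressures are Wilhelmy-plate sensor noise: values in
#' \eqn{[-0.5, 0)} mN/m are clipped to zero, values below \eqn{-0.5} are
#' rejected rather than silently accepted.
#'
#' @param area Numeric vector of areas per molecule (\eqn{\mathrm{\AA}^2}),
#'   strictly positive.
#' @param pressure Numeric vector of surface pressures (mN/m), same length.
#' @param label Compound identifier.
#' @param temperature Subphase temperature in degrees Celsius.
#' @param subphase Free-text subphase description (e.g. "water", "0.1 M NaCl").
#' @return An object of class `isotherm`: a list with fields `area`,
#'   `pressure`, `label`, `temperature`, `subphase`.
#' @export
#' @examples
#' iso <- isotherm(c(60, 50, 40), c(0.1, 5, 20), label = "demo")
#' area_at_pressure(iso, 5)
isotherm <- function(area, pressure, label = "unnamed",
                     temperature = 20, subphase = "water") {
  if (!is.numeric(area) || !is.numeric(pressure)) {
    stop_monofilm("area and pressure must be numeric", "monofilm_format_error")
  }
  if (length(area) != length(pressure)) {
    stop_monofilm("area and pressure must have equal length",
                  "monofilm_format_error")
  }
  if (length(area) < 3L) {
    stop_monofilm("an isotherm needs at least 3 points",
                  "monofilm_format_error")
  }
  if (anyNA(area) || anyNA(pressure)) {
    stop_monofilm("area and pressure must not contain missing values",
                  "monofilm_format_error")
  }
  if (any(area <= 0)) {
    stop_monofilm("area per molecule must be strictly positive",
                  "monofilm_domain_error")
  }
  if (any(pressure < -0.5)) {
    stop_monofilm(
      "surface pressure below -0.5 mN/m: more than sensor-noise tolerance",
      "monofilm_domain_error"
    )
  }
  pressure[pressure < 0] <- 0

  # compression order; duplicate areas averaged
  o <- order(area, decreasing = TRUE)
  area <- area[o]
  pressure <- pressure[o]
  if (anyDuplicated(area)) {
    grp <- match(area, unique(area))
    pressure <- as.numeric(tapply(pressure, grp, mean))
    area <- unique(area)
  }
  if (length(area) < 3L) {
    stop_monofilm("fewer than 3 distinct areas after collapsing duplicates",
                  "monofilm_format_error")
  }
  structure(
    list(area = area, pressure = pressure, label = label,
         temperature = temperature, subphase = subphase),
    class = "isotherm"
  )
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf(
    "<isotherm> %s: %d points, A %.4g-%.4g A^2, pi %.4g-%.4g mN/m (%g degC, %s)\n",
    x$label, length(x$area), min(x$area), max(x$area),
    min(x$pressure), max(x$pressure), x$temperature, x$subphase
  ))
  invisible(x)
}

#' @export
as.data.frame.isotherm <- function(x, ...) {
  data.frame(area_A2 = x$area, pi_mN_m = x$pressure)
}

#' Read an isotherm from its CSV dialect
#'
#' The dialect is fixed: one header line `area_A2,pi_mN_m`, comma separator,
#' `#` comment lines. [write_isotherm()] emits the identical dialect so that
#' read-write-read round trips are exact.
#'
#' @param path Path to a CSV file.
#' @param label Compound identifier; defaults to the file name without
#'   extension.
#' @param temperature,subphase Metadata passed to [isotherm()].
#' @return A validated [isotherm()].
#' @export
read_isotherm <- function(path, label = NULL, temperature = 20,
                          subphase = "water") {
  if (!file.exists(path)) {
    stop_monofilm(sprintf("file not found: %s", path), "monofilm_format_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) < 1L) {
    stop_monofilm(sprintf("%s: empty file", path), "monofilm_format_error")
  }
  header <- trimws(strsplit(lines[[1L]], ",")[[1L]])
  i_area <- match("area_A2", header)
  i_pi <- match("pi_mN_m", header)
  if (is.na(i_area) || is.na(i_pi)) {
    stop_monofilm(
      sprintf("%s line %d: header must contain columns area_A2 and pi_mN_m",
              path, lineno[[1L]]),
      "monofilm_format_error"
    )
  }
  body <- lines[-1L]
  body_lineno <- lineno[-1L]
  if (length(body) < 3L) {
    stop_monofilm(sprintf("%s: fewer than 3 data rows", path),
                  "monofilm_format_error")
  }
  cells <- strsplit(body, ",")
  n_col <- max(i_area, i_pi)
  area <- pressure <- numeric(length(body))
  for (k in seq_along(body)) {
    row <- trimws(cells[[k]])
    if (length(row) < n_col) {
      stop_monofilm(sprintf("%s line %d: expected %d columns, found %d",
                            path, body_lineno[[k]], n_col, length(row)),
                    "monofilm_format_error")
    }
    a <- suppressWarnings(as.numeric(row[[i_area]]))
    p <- suppressWarnings(as.numeric(row[[i_pi]]))
    if (is.na(a) || is.na(p)) {
      stop_monofilm(sprintf("%s line %d: non-numeric cell",
                            path, body_lineno[[k]]),
                    "monofilm_format_error")
    }
    area[[k]] <- a
    pressure[[k]] <- p
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  isotherm(area, pressure, label = label, temperature = temperature,
           subphase = subphase)
}

#' Write an isotherm in the package CSV dialect
#'
#' @param iso An [isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  lines <- c(
    sprintf("# %s, %g degC, %s", iso$label, iso$temperature, iso$subphase),
    "area_A2,pi_mN_m",
    paste(fmt_num(iso$area), fmt_num(iso$pressure), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

# Index of the collapse point: first global maximum of pressure in
# compression order (ties resolved toward larger area).
collapse_index <- function(pressure) which.max(pressure)

#' Area per molecule at a target surface pressure
#'
#' Inverts the compression branch A(\eqn{\pi}) by linear interpolation. The
#' branch is truncated at the first global pressure maximum (collapse); where
#' \eqn{\pi} is non-monotonic within that branch (plateau noise), the first
#' crossing coming from the large-area side is used, so the largest qualifying
#' area is returned. A query below the first recorded pressure returns the
#' first recorded (largest) area: the film area is taken as constant at its
#' lift-off value before the pressure sensor responds.
#'
#' @param iso An [isotherm()].
#' @param pi_target Surface pressure (mN/m), within `[0, max(pi)]` of the
#'   truncated branch.
#' @return Area per molecule in \eqn{\mathrm{\AA}^2}.
#' @export
area_at_pressure <- function(iso, pi_target) {
  stopifnot(inherits(iso, "isotherm"))
  if (!is.finite(pi_target) || pi_target < 0) {
    stop_monofilm("pi_target must be finite and non-negative",
                  "monofilm_domain_error")
  }
  imax <- collapse_index(iso$pressure)
  p <- iso$pressure[seq_len(imax)]
  a <- iso$area[seq_len(imax)]
  if (pi_target > p[[imax]] && pi_target > max(p)) {
    stop_monofilm(
      sprintf("pi_target %.4g mN/m above the compression branch maximum %.4g (%s)",
              pi_target, max(p), iso$label),
      "monofilm_range_error"
    )
  }
  hit <- which(p == pi_target)
  if (length(hit)) {
    # exactly recorded grid point: in the flat-plateau case the first hit is
    # the largest area, matching the first-crossing rule
    return(a[[hit[[1L]]]])
  }
  if (pi_target < p[[1L]]) return(a[[1L]])
  for (i in seq_len(length(p) - 1L)) {
    lo <- min(p[[i]], p[[i + 1L]])
    hi <- max(p[[i]], p[[i + 1L]])
    if (pi_target >= lo && pi_target <= hi) {
      w <- (pi_target - p[[i]]) / (p[[i + 1L]] - p[[i]])
      return(a[[i]] + w * (a[[i + 1L]] - a[[i]]))
    }
  }
  stop_monofilm(
    sprintf("pi_target %.4g mN/m not reachable on isotherm %s",
            pi_target, iso$label),
    "monofilm_range_error"
  )
}

#' Bundle pure components and their binary mixtures
#'
#' A `mixture_series` holds the two pure-component isotherms and mixture
#' isotherms indexed by the mole fraction \eqn{X_2} of component 2
#' (\eqn{X_1 = 1 - X_2}). It is the input to the excess-area and excess-Gibbs
#' computations.
#'
#' @param component1,component2 Pure-component [isotherm()]s.
#' @param mixtures Named list of [isotherm()]s; names are the mole fractions
#'   \eqn{X_2 \in (0,1)} (e.g. `"0.25"`).
#' @return An object of class `mixture_series`.
#' @export
mixture_series <- function(component1, component2, mixtures) {
  stopifnot(inherits(component1, "isotherm"), inherits(component2, "isotherm"))
  if (!is.list(mixtures) || length(mixtures) == 0L || is.null(names(mixtures))) {
    stop_monofilm("`mixtures` must be a named list of isotherms",
                  "monofilm_format_error")
  }
  x2 <- as.numeric(names(mixtures))
  if (anyNA(x2) || any(x2 <= 0) || any(x2 >= 1)) {
    stop_monofilm("mixture mole fractions must be strictly between 0 and 1",
                  "monofilm_domain_error")
  }
  if (!all(vapply(mixtures, inherits, logical(1L), "isotherm"))) {
    stop_monofilm("every mixture entry must be an isotherm",
                  "monofilm_format_error")
  }
  o <- order(x2)
  structure(
    list(component1 = component1, component2 = component2,
         mixtures = mixtures[o], fractions = x2[o]),
    class = "mixture_series"
  )
}

#' @export
print.mixture_series <- function(x, ...) {
  cat(sprintf("<mixture_series> %s / %s, X2 = %s\n",
              x$component1$label, x$component2$label,
              paste(x$fractions, collapse = ", ")))
  invisible(x)
}
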