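test_that("compressional modulus matches closed forms (ideal gas, linear, plateau)", {
  # 2D ideal gas pi = C/A has Cs^-1 = pi exactly
  gas <- generate_isotherm(isotherm_model("ideal-gas"), n_points = 250, seed = 1)
  mc <- compressional_modulus(gas$isotherm)
  interior <- 6:(length(mc$modulus) - 5)
  expect_lt(max(abs(mc$modulus[interior] / mc$pressure[interior] - 1)), 0.01)

  # linear isotherm pi = 70 - A: dpi/dA = -1 so Cs^-1 = A; at pi = 35, A = 35
  lin <- linear_isotherm(n = 101)
  mc2 <- compressional_modulus(lin)
  i35 <- which.min(abs(mc2$pressure - 35))
  expect_equal(mc2$modulus[[i35]], 35, tolerance = 0.02)

  # an ideal constant-pressure plateau has zero modulus on the segment
  gen <- generate_isotherm(isotherm_model("le-plateau-lc"), n_points = 300,
                           seed = 1)
  mc3 <- compressional_modulus(gen$isotherm)
  ft <- gen$truth$features
  on_plateau <- mc3$area < ft$plateau_onset_area - 2 &
    mc3$area > ft$plateau_end_area + 2
  expect_true(any(on_plateau))
  expect_lt(max(abs(mc3$modulus[on_plateau])), 1e-6)
})

test_that("modulus recovers the analytic -A pi'(A) on parametric models", {
  for (kind in c("ideal-gas", "condensed")) {
    gen <- generate_isotherm(isotherm_model(kind), n_points = 250, seed = 5)
    mc <- compressional_modulus(gen$isotherm)
    truth <- -mc$area * gen$truth$dpi_dA(mc$area)
    interior <- which(mc$pressure > 1 & seq_along(mc$area) > 5 &
                        seq_along(mc$area) < length(mc$area) - 5 &
                        abs(truth) > 1)
    # skip points whose smoothing window straddles a kink of the model
    if (kind == "condensed") {
      lift <- gen$truth$features$liftoff_area
      dx <- diff(range(mc$area)) / length(mc$area) * 6
      interior <- interior[abs(mc$area[interior] - lift) > dx]
    }
    rel <- abs(mc$modulus[interior] / truth[interior] - 1)
    expect_lt(max(rel), 0.02)
  }
})

test_that("modulus computation guards its preconditions", {
  iso <- isotherm(c(60, 50, 40), c(0, 5, 20))
  expect_error(compressional_modulus(iso), class = "monofilm_config_error")
  expect_error(compressional_modulus(linear_isotherm(), order = 15),
               class = "monofilm_config_error")
})

test_that("phase classification follows the modulus ranges and fills the gaps", {
  expect_equal(classify_phase(150), "liquid-condensed")
  expect_equal(classify_phase(600), "solid")
  expect_equal(classify_phase(75), "intermediate")
  expect_equal(
    classify_phase(c(0, 24.9, 25, 50, 50.1, 99.9, 100, 250, 250.1, 500, 500.1)),
    c("low-density-liquid", "low-density-liquid", "liquid-expanded",
      "liquid-expanded", "intermediate", "intermediate", "liquid-condensed",
      "liquid-condensed", "transitional", "transitional", "solid")
  )
  # total deterministic partition of [0, Inf)
  grid <- seq(0, 800, by = 0.25)
  labels <- classify_phase(grid)
  expect_true(all(labels %in% c("low-density-liquid", "liquid-expanded",
                                "intermediate", "liquid-condensed",
                                "transitional", "solid")))
  expect_identical(labels, classify_phase(grid))
  expect_error(classify_phase(-1), class = "monofilm_domain_error")
  expect_error(classify_phase(Inf), class = "monofilm_domain_error")
})

test_that("lift-off detection finds the constructed onset and is monotone in threshold", {
  # pi = 0 above 60 A^2, rising linearly below
  a <- seq(80, 30, by = -0.5)
  p <- pmax(0, (60 - a) * 0.8)
  iso <- isotherm(a, p)
  expect_equal(detect_liftoff(iso, threshold = 0.5), 60 - 0.5 / 0.8,
               tolerance = 0.5)
  thresholds <- c(0.2, 0.5, 1, 2, 5)
  lifts <- vapply(thresholds, function(t) detect_liftoff(iso, t), numeric(1))
  expect_true(all(diff(lifts) <= 1e-9))

  # pressure above threshold everywhere: boundary flag on the largest area
  iso_hi <- isotherm(seq(60, 40, by = -1), seq(5, 45, by = 2))
  lift <- detect_liftoff(iso_hi)
  expect_equal(as.numeric(lift), 60)
  expect_true(attr(lift, "boundary"))

  # all-zero pressure: feature not found
  flat <- isotherm(seq(80, 30, by = -1), rep(0, 51))
  expect_error(detect_liftoff(flat), class = "monofilm_feature_error")
})

test_that("plateau detection brackets a constructed LE-LC plateau and rejects others", {
  gen <- generate_isotherm(isotherm_model("le-plateau-lc"), n_points = 300,
                           seed = 2)
  mc <- compressional_modulus(gen$isotherm)
  pl <- detect_plateau(mc)
  ft <- gen$truth$features
  expect_false(is.null(pl))
  # crossing pressures are accurate to the ~0.1 mN/m detection resolution
  expect_lte(pl$pi_onset, ft$plateau_pressure + 0.1)
  expect_gte(pl$pi_end, ft$plateau_pressure - 0.1)
  expect_lt(pl$min_modulus, 10)
  # area bounds land at the prescribed plateau edges
  expect_equal(pl$A_onset, ft$plateau_onset_area, tolerance = 1.5)
  expect_equal(pl$A_end, ft$plateau_end_area, tolerance = 1.5)

  # strictly convex condensed-type isotherm: no plateau
  cond <- generate_isotherm(isotherm_model("condensed"), n_points = 200,
                            seed = 3)
  expect_null(detect_plateau(compressional_modulus(cond$isotherm)))

  # monotone modulus rising from ~0: dip is not between two qualifying maxima
  gas <- generate_isotherm(isotherm_model("ideal-gas"), n_points = 100,
                           seed = 4)
  expect_null(detect_plateau(compressional_modulus(gas$isotherm)))
})

test_that("collapse detection reports the first pressure maximum or censors", {
  gen <- generate_isotherm(isotherm_model("le-plateau-lc",
                                          collapse_pressure = 57),
                           n_points = 300, seed = 6)
  col <- detect_collapse(gen$isotherm)
  expect_equal(as.numeric(col), 57, tolerance = 0.5)
  expect_false(attr(col, "censored"))

  rising <- isotherm(seq(60, 40, by = -1), seq(0, 40, by = 2))
  col2 <- detect_collapse(rising)
  expect_true(attr(col2, "censored"))
  expect_equal(as.numeric(col2), max(compressional_modulus(rising)$pressure),
               tolerance = 1)

  # two identically shaped maxima: tie broken toward larger area
  peak <- c(seq(0, 50, by = 5), seq(45, 0, by = -5))
  p <- c(peak, peak)
  a <- seq(80, by = -1, length.out = length(p))
  iso <- isotherm(a, p)
  col3 <- detect_collapse(iso, window = 5, order = 1)
  expect_equal(attr(col3, "area"), a[[which.max(peak)]])
})

test_that("isotherm_features assembles a consistent report", {
  gen <- generate_isotherm(isotherm_model("le-plateau-lc", noise_sd = 0.05),
                           n_points = 250, seed = 9)
  ft <- isotherm_features(gen$isotherm)
  expect_s3_class(ft, "isotherm_features")
  expect_gt(ft$liftoff_area, ft$plateau$A_onset)
  expect_gt(ft$plateau$A_onset, ft$plateau$A_end)
  expect_gt(ft$collapse_pressure, ft$plateau$pi_end)
  expect_equal(ft$phase_at_max, classify_phase(ft$max_modulus))
  expect_output(print(ft), "plateau")
})
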