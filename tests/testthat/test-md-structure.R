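test_that("PDB frames round-trip with boxes, elements and electron counts", {
  # three waters, one frame
  coords <- matrix(c(0, 0, 0, 0.96, 0, 0, -0.24, 0.93, 0,
                     5, 5, 5, 5.96, 5, 5, 4.76, 5.93, 5,
                     2, 8, 3, 2.96, 8, 3, 1.76, 8.93, 3),
                   ncol = 3, byrow = TRUE)
  tf <- make_frames(rep(c("O", "H", "H"), 3), coords, box = c(30, 30, 30),
                    resname = "WAT", resid = rep(1:3, each = 3),
                    name = rep(c("O", "H1", "H2"), 3))
  expect_equal(tf$atoms$electron_count, rep(c(8L, 1L, 1L), 3))

  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames(tf, path)
  back <- read_frames(path)
  expect_equal(length(back$coords), 1)
  expect_equal(nrow(back$atoms), 9)
  expect_equal(back$atoms$element, tf$atoms$element)
  expect_equal(back$atoms$electron_count, tf$atoms$electron_count)
  expect_equal(back$coords[[1]], tf$coords[[1]], tolerance = 1e-3)
  expect_equal(back$boxes[1, ], c(30, 30, 30), ignore_attr = TRUE)
})

test_that("extended-XYZ frames round-trip at full precision across frames", {
  set.seed(7)
  c1 <- matrix(runif(12, 0, 10), 4, 3)
  c2 <- c1 + 0.123456789
  tf <- make_frames(c("Na", "O", "C", "P"), list(c1, c2), box = c(25, 25, 40),
                    resname = "LIP", resid = c(1, 1, 2, 2))
  path <- withr::local_tempfile(fileext = ".extxyz")
  write_frames(tf, path)
  back <- read_frames(path)
  expect_equal(length(back$coords), 2)
  expect_equal(back$coords[[2]], tf$coords[[2]], tolerance = 1e-9)
  expect_equal(back$atoms$resname, tf$atoms$resname)
  expect_equal(back$atoms$resid, tf$atoms$resid)
  expect_equal(back$boxes[2, ], c(25, 25, 40), ignore_attr = TRUE)
})

test_that("malformed trajectories fail with the frame named", {
  path <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c(
    "2", 'Lattice="10 0 0 0 10 0 0 0 10"', "O 0 0 0", "H 1 0 0",
    "2", 'Lattice="10 0 0 0 10 0 0 0 10"', "O 0 0 0"
  ), path)
  expect_error(read_frames(path), "frame 2", class = "monofilm_format_error")

  nolat <- withr::local_tempfile(fileext = ".extxyz")
  writeLines(c("1", "no lattice here", "O 0 0 0"), nolat)
  expect_error(read_frames(nolat), "Lattice", class = "monofilm_format_error")

  nobox <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   WAT     1       0.000   0.000   0.000           O",
    "END"
  ), nobox)
  expect_error(read_frames(nobox), "CRYST1", class = "monofilm_format_error")

  expect_error(electron_count("Xx"), class = "monofilm_format_error")
})

test_that("slab electron density shows the predicted plateau and conserves electrons", {
  gen <- generate_slab_configuration(1000, element = "O",
                                     slab_bounds = c(-10, 10),
                                     box = c(50, 50, 100), n_frames = 20,
                                     seed = 31)
  prof <- electron_density_profile(gen$frames, bin_width = 0.5,
                                   reference = "none")
  # plateau: 1000 * 8 / (50 * 50 * 20) = 0.16 e/A^3, away from slab edges
  inside <- abs(prof$bin_centers) < 8
  expect_equal(mean(prof$density[inside]), gen$truth$plateau_density,
               tolerance = 0.05)
  outside <- abs(prof$bin_centers) > 11
  if (any(outside)) expect_lt(max(prof$density[outside]), 1e-12)
  # conservation: integral x (Lx Ly) = total selected electrons
  integral <- sum(prof$density) * prof$bin_width * prof$area_xy
  expect_equal(integral, gen$truth$total_electrons, tolerance = 1e-3)
})

test_that("density profile respects symmetry and rejects empty selections", {
  z <- seq(-9.75, 9.75, by = 0.5)
  coords <- cbind(rep(0, length(z)), rep(0, length(z)), z)
  tf <- make_frames(rep("C", length(z)), coords, box = c(20, 20, 40))
  prof <- electron_density_profile(tf, bin_width = 0.5, reference = "midplane")
  expect_equal(prof$density, rev(prof$density), tolerance = 1e-12)
  expect_error(electron_density_profile(tf, selection = list(element = "U")),
               class = "monofilm_selection_error")
})

test_that("rdf histogram equals a brute-force minimum-image double loop", {
  set.seed(13)
  n <- 60
  coords <- lapply(1:3, function(f) matrix(runif(n * 3, 0, 18), n, 3))
  tf <- make_frames(rep(c("Na", "O"), n / 2), coords, box = c(18, 18, 18))
  ia <- select_atoms(tf, element = "Na")
  ib <- select_atoms(tf, element = "O")
  res <- radial_distribution(tf, ia, ib, dr = 0.1, rmax = 8)
  expect_identical(res$counts, brute_rdf_counts(tf, ia, ib, 0.1, 8))
  # overlapping selections exclude self pairs
  res_self <- radial_distribution(tf, ia, ia, dr = 0.1, rmax = 8)
  expect_identical(res_self$counts, brute_rdf_counts(tf, ia, ia, 0.1, 8))
  # n(rmax) equals total in-range pairs per center per frame
  expect_equal(tail(res$n_of_r, 1), sum(res$counts) / length(ia))
})

test_that("shell configurations give exact coordination numbers", {
  gen <- generate_shell_configuration(64, shell_radius = 2.2,
                                      partners_per_center = 1,
                                      box = c(120, 120, 120), n_frames = 3,
                                      seed = 17, min_separation = 17)
  res <- radial_distribution(gen$frames, gen$truth$center_selection,
                             gen$truth$partner_selection, dr = 0.05, rmax = 8)
  i3 <- max(which(res$r < 3.0))
  expect_equal(res$n_of_r[[i3]], 1.0)
  # occupied bins concentrate at the shell radius
  occupied <- which(res$counts > 0)
  expect_true(all(abs(res$r[occupied] - 2.2) <= 0.05))

  gen3 <- generate_shell_configuration(32, shell_radius = 2.2,
                                       partners_per_center = 3,
                                       box = c(120, 120, 120), n_frames = 2,
                                       seed = 18, min_separation = 17)
  res3 <- radial_distribution(gen3$frames, gen3$truth$center_selection,
                              gen3$truth$partner_selection,
                              dr = 0.05, rmax = 8)
  expect_equal(res3$n_of_r[[max(which(res3$r < 3.0))]], 3.0)

  # no B atoms within rmax: g and n(r) identically zero
  far <- make_frames(c("Na", "O"), matrix(c(1, 1, 1, 25, 25, 25), 2, 3,
                                          byrow = TRUE), box = c(50, 50, 50))
  res0 <- radial_distribution(far, list(element = "Na"),
                              list(element = "O"), rmax = 8)
  expect_true(all(res0$g == 0))
  expect_true(all(res0$n_of_r == 0))
})

test_that("homogeneous ideal gas has g(r) = 1 within 3 standard errors", {
  set.seed(19)
  nf <- 200
  n <- 160
  coords <- lapply(seq_len(nf), function(f) matrix(runif(n * 3, 0, 20), n, 3))
  tf <- make_frames(rep(c("Na", "O"), n / 2), coords, box = c(20, 20, 20))
  res <- radial_distribution(tf, list(element = "Na"), list(element = "O"),
                             dr = 0.25, rmax = 8)
  keep <- res$r > 1
  se_g <- rdf_empirical_se(tf, list(element = "Na"), list(element = "O"),
                           dr = 0.25, rmax = 8)[keep]
  # per-bin 3-sigma confidence, Sidak-corrected for testing all bins jointly
  z_joint <- stats::qnorm(1 - 0.0027 / (2 * sum(keep)))
  expect_true(all(abs(res$g[keep] - 1) <= z_joint * se_g))
  # no systematic normalization bias across the flat region
  expect_equal(mean(res$g[keep]), 1,
               tolerance = 3 * sqrt(mean(se_g^2) / sum(keep)))
  expect_error(radial_distribution(tf, list(element = "Na"),
                                   list(element = "O"), rmax = 15),
               class = "monofilm_domain_error")
})

test_that("tilt angles reproduce simple geometries and fixed poses", {
  # explicit P->N vectors: +z, +x, and the diagonal
  coords <- matrix(c(0, 0, 10, 0, 0, 11,
                     5, 0, 10, 6, 0, 10,
                     0, 5, 10, 1, 5, 11),
                   ncol = 3, byrow = TRUE)
  tf <- make_frames(rep(c("P", "N"), 3), coords, box = c(30, 30, 30),
                    resname = "LIP", resid = rep(1:3, each = 2),
                    name = rep(c("P", "N"), 3))
  ang <- vector_tilt_angles(tf)
  expect_equal(ang$values, c(0, 90, 45), tolerance = 1e-9)

  gh <- generate_headgroup_ensemble(9, tilt_deg = 70, n_frames = 3, seed = 23)
  got <- vector_tilt_angles(gh$frames)
  expect_equal(got$values, rep(as.vector(t(gh$truth$tilt_deg)), 1),
               tolerance = 1e-6)
  expect_equal(got$mean, 70, tolerance = 1e-6)

  # ambiguous selection errors
  bad <- make_frames(c("P", "P", "N"), matrix(0, 3, 3), resname = "LIP",
                     resid = c(1, 1, 1), name = c("P", "P", "N"))
  expect_error(vector_tilt_angles(bad), class = "monofilm_selection_error")
})

test_that("tilt is invariant under translation and rotation about z", {
  gh <- generate_headgroup_ensemble(6, tilt_deg = function(n) runif(n, 10, 170),
                                    n_frames = 2, seed = 29)
  base <- vector_tilt_angles(gh$frames)
  moved <- transform_frames(gh$frames, rot_matrix(c(0, 0, 1), 40),
                            shift = c(3, -7, 11))
  expect_equal(vector_tilt_angles(moved)$values, base$values,
               tolerance = 1e-6)
})

test_that("torsions recover planar references, posed angles, and rigid invariance", {
  # planar anti (180) and syn (0) arrangements
  p_anti <- matrix(c(-1, 1, 0, 0, 0, 0, 1.5, 0, 0, 2.5, -1, 0),
                   ncol = 3, byrow = TRUE)
  p_syn <- matrix(c(-1, 1, 0, 0, 0, 0, 1.5, 0, 0, 2.5, 1, 0),
                  ncol = 3, byrow = TRUE)
  tf <- make_frames(rep("C", 4), list(p_anti, p_syn), box = c(20, 20, 20),
                    resname = "LIP", resid = rep(1, 4),
                    name = c("C1", "C2", "C3", "C4"))
  td <- torsion_definition("t", c("C1", "C2", "C3", "C4"))
  ang <- torsion_angles(tf, td)
  expect_equal(abs(ang$values[[1]]), 180, tolerance = 1e-9)
  expect_equal(ang$values[[2]], 0, tolerance = 1e-9)

  # constructive rotation oracle: rotating atom 4 right-handed about the
  # 2->3 axis adds the rotation to the IUPAC dihedral (180 + 60 -> -120)
  R <- rot_matrix(c(1, 0, 0), 60)  # central bond along +x
  p_rot <- p_anti
  p_rot[4, ] <- as.vector(R %*% (p_anti[4, ] - p_anti[3, ])) + p_anti[3, ]
  tf_rot <- make_frames(rep("C", 4), p_rot, box = c(20, 20, 20),
                        resname = "LIP", resid = rep(1, 4),
                        name = c("C1", "C2", "C3", "C4"))
  expect_equal(torsion_angles(tf_rot, td)$values, -120, tolerance = 1e-6)

  gh <- generate_headgroup_ensemble(
    5, tilt_deg = 70,
    torsion_spec = list(a1 = function(n) c(60, -60, 175, -120, 10)[seq_len(n)]),
    n_frames = 2, seed = 37
  )
  base <- torsion_angles(gh$frames, gh$truth$definitions$a1)
  expect_equal(base$values, rep(c(60, -60, 175, -120, 10), 2),
               tolerance = 1e-6)
  moved <- transform_frames(gh$frames, rot_matrix(c(1, 2, 3), 73),
                            shift = c(-4, 2, 9))
  expect_equal(torsion_angles(moved, gh$truth$definitions$a1)$values,
               base$values, tolerance = 1e-6)
})

test_that("dihedral sign convention matches an independent implementation", {
  skip_if_not_installed("bio3d")
  gh <- generate_headgroup_ensemble(
    4, tilt_deg = 70,
    torsion_spec = list(a1 = function(n) c(60, -60, 175, -120)[seq_len(n)]),
    n_frames = 1, seed = 41
  )
  ours <- torsion_angles(gh$frames, gh$truth$definitions$a1)$values
  m <- gh$frames$coords[[1]]
  at <- gh$frames$atoms
  ref <- vapply(1:4, function(r) {
    idx <- which(at$resid == r & at$name %in% c("C1", "C2", "C3", "C4"))
    bio3d::torsion.xyz(as.vector(t(m[idx, ])), atm.inc = 4)
  }, numeric(1))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("conformer classification follows the synclinal/anti-periplanar windows", {
  expect_equal(classify_conformer(65), "+sin-clinical")
  expect_equal(classify_conformer(175), "anti-periplanar")
  expect_equal(classify_conformer(-120), "other")
  # closed-interval boundaries belong to the named class
  expect_equal(classify_conformer(c(30, 90, -30, -90, 150, -150, 180)),
               c("+sin-clinical", "+sin-clinical", "-sin-clinical",
                 "-sin-clinical", "anti-periplanar", "anti-periplanar",
                 "anti-periplanar"))
  expect_equal(classify_conformer(c(29.999, 90.001, 149.999)),
               c("other", "other", "other"))
  expect_error(classify_conformer(200), class = "monofilm_domain_error")
})

test_that("conformer fractions are recovered exactly from deterministic ensembles", {
  spec <- function(n) rep(c(60, 60, -60, 180), length.out = n)
  gh <- generate_headgroup_ensemble(20, tilt_deg = 70,
                                    torsion_spec = list(a1 = spec),
                                    n_frames = 2, seed = 43)
  labels <- classify_conformer(torsion_angles(gh$frames,
                                              gh$truth$definitions$a1)$values)
  frac <- table(labels) / length(labels)
  expect_equal(as.numeric(frac[["+sin-clinical"]]), 0.5)
  expect_equal(as.numeric(frac[["-sin-clinical"]]), 0.25)
  expect_equal(as.numeric(frac[["anti-periplanar"]]), 0.25)
})

test_that("torsion doublets count same-sign and reversed synclinal sequences", {
  mk <- function(vals, label) {
    structure(list(values = vals, frame = rep(1L, length(vals)),
                   resid = seq_along(vals), mean = mean(vals), label = label),
              class = "angle_series")
  }
  same <- torsion_doublet_table(mk(rep(60, 8), "a1"), mk(rep(60, 8), "a2"))
  expect_equal(same$fraction_same_sign, 1)
  rev <- torsion_doublet_table(mk(rep(60, 8), "a1"), mk(rep(-60, 8), "a2"))
  expect_equal(rev$fraction_sign_reversed, 1)
  half <- torsion_doublet_table(mk(rep(60, 8), "a1"),
                                mk(rep(c(60, -60), 4), "a2"))
  expect_equal(half$fraction_same_sign, 0.5)
  expect_equal(half$n_both_synclinal, 8)
  expect_error(torsion_doublet_table(mk(rep(60, 8), "a1"),
                                     mk(rep(60, 7), "a2")),
               class = "monofilm_alignment_error")
})

test_that("area per molecule averages the box cross-section", {
  tf <- make_frames(c("P"), matrix(0, 1, 3), box = c(80, 80, 60))
  expect_equal(area_per_molecule(tf, 64), 100)
  tf2 <- make_frames(c("P"), list(matrix(0, 1, 3), matrix(0, 1, 3)),
                     box = rbind(c(60, 60, 60), c(80, 80, 60)))
  expect_equal(area_per_molecule(tf2, 64), (56.25 + 100) / 2)
  expect_error(area_per_molecule(tf, 0), class = "monofilm_domain_error")
})
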