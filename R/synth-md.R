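#' Generate a uniform slab of atoms (density-profile oracle)
#'
#' Places `n_atoms` of one element uniformly inside a z-slab of an
#' orthorhombic box, independently each frame. The expected plateau electron
#' density is `n_atoms * Z / (Lx * Ly * slab thickness)` and is returned in
#' the ground-truth record.
#'
#' @param n_atoms Number of atoms (0 allowed: empty profile).
#' @param element Element symbol (default `"O"`).
#' @param slab_bounds Length-2 z-interval of the slab in Angstrom, inside the
#'   box.
#' @param box Length-3 box dimensions in Angstrom; z spans
#'   `[-Lz/2, Lz/2]`.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List with `frames` (a [trajectory_frames()]) and `truth`
#'   (`plateau_density` in e\eqn{^-}/\eqn{\mathrm{\AA}^3}, `total_electrons`,
#'   `slab_bounds`, `box`).
#' @export
generate_slab_configuration <- function(n_atoms, element = "O",
                                        slab_bounds = c(-10, 10),
                                        box = c(50, 50, 100),
                                        n_frames = 10L, seed) {
  if (n_atoms < 0) stop_monofilm("n_atoms must be >= 0", "monofilm_domain_error")
  if (slab_bounds[[1L]] >= slab_bounds[[2L]] ||
      slab_bounds[[1L]] < -box[[3L]] / 2 || slab_bounds[[2L]] > box[[3L]] / 2) {
    stop_monofilm("slab must be a non-empty interval inside the box",
                  "monofilm_domain_error")
  }
  n_eff <- max(n_atoms, 1L)  # keep a valid container even for an empty slab
  z_e <- electron_count(element)
  atoms <- data.frame(
    element = rep(element, n_eff),
    name = rep(element, n_eff),
    resname = rep("SLB", n_eff),
    resid = seq_len(n_eff),
    electron_count = rep(if (n_atoms > 0) z_e else 0L, n_eff)
  )
  coords <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      cbind(runif(n_eff, -box[[1L]] / 2, box[[1L]] / 2),
            runif(n_eff, -box[[2L]] / 2, box[[2L]] / 2),
            runif(n_eff, slab_bounds[[1L]], slab_bounds[[2L]]))
    })
  })
  thickness <- slab_bounds[[2L]] - slab_bounds[[1L]]
  list(
    frames = trajectory_frames(atoms, coords, box),
    truth = list(
      plateau_density = n_atoms * z_e / (box[[1L]] * box[[2L]] * thickness),
      total_electrons = n_atoms * z_e,
      slab_bounds = slab_bounds,
      box = box
    )
  )
}

#' Generate centers with partners on a fixed-radius shell (RDF oracle)
#'
#' Centers (default Na) are placed on a cubic sub-lattice guaranteeing a
#' minimum separation; each center receives exactly `partners_per_center`
#' partner atoms (default O) at distance `shell_radius` in random directions.
#' The running coordination number of partners around centers therefore
#' equals `partners_per_center` exactly just beyond the shell radius.
#'
#' @param n_centers Number of central atoms.
#' @param shell_radius Shell radius in Angstrom (default 2.2, a typical
#'   Na--phosphate-oxygen contact distance).
#' @param partners_per_center Partners per center (0 allowed).
#' @param box Length-3 box in Angstrom.
#' @param n_frames Number of frames (partner directions resampled per frame).
#' @param seed Integer seed.
#' @param min_separation Minimum center--center distance; default
#'   `2 * (shell_radius + 0.5)`.
#' @param center_element,partner_element Element symbols.
#' @return List with `frames` and `truth` (`shell_radius`,
#'   `partners_per_center`, selections for centers and partners).
#' @export
generate_shell_configuration <- function(n_centers, shell_radius = 2.2,
                                         partners_per_center = 1L,
                                         box = c(60, 60, 60), n_frames = 1L,
                                         seed, min_separation = NULL,
                                         center_element = "Na",
                                         partner_element = "O") {
  if (n_centers < 1L) {
    stop_monofilm("need at least one center", "monofilm_domain_error")
  }
  if (shell_radius >= min(box) / 2) {
    stop_monofilm("shell_radius must be below half the smallest box length",
                  "monofilm_domain_error")
  }
  sep <- min_separation %||% (2 * (shell_radius + 0.5))
  n_side <- floor(box / sep)
  if (prod(n_side) < n_centers) {
    stop_monofilm(
      sprintf("box too small for %d centers at separation %.2f A",
              n_centers, sep),
      "monofilm_placement_error"
    )
  }
  # cubic sub-lattice, filled in order
  grid_idx <- seq_len(n_centers) - 1L
  gx <- grid_idx %% n_side[[1L]]
  gy <- (grid_idx %/% n_side[[1L]]) %% n_side[[2L]]
  gz <- grid_idx %/% (n_side[[1L]] * n_side[[2L]])
  centers <- cbind((gx + 0.5) * box[[1L]] / n_side[[1L]] - box[[1L]] / 2,
                   (gy + 0.5) * box[[2L]] / n_side[[2L]] - box[[2L]] / 2,
                   (gz + 0.5) * box[[3L]] / n_side[[3L]] - box[[3L]] / 2)
  k <- as.integer(partners_per_center)
  n_part <- n_centers * k
  atoms <- data.frame(
    element = c(rep(center_element, n_centers),
                rep(partner_element, n_part)),
    name = c(rep("CEN", n_centers), rep("PRT", n_part)),
    resname = c(rep("ION", n_centers), rep("PRT", n_part)),
    resid = c(seq_len(n_centers),
              rep(seq_len(n_centers), each = k)),
    stringsAsFactors = FALSE
  )
  coords <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      if (k > 0) {
        # isotropic random directions
        u <- rnorm(n_centers * k * 3)
        dir <- matrix(u, ncol = 3L)
        dir <- dir / sqrt(rowSums(dir * dir))
        partners <- centers[rep(seq_len(n_centers), each = k), , drop = FALSE] +
          shell_radius * dir
        rbind(centers, partners)
      } else {
        centers
      }
    })
  })
  list(
    frames = trajectory_frames(atoms, coords, box),
    truth = list(
      shell_radius = shell_radius,
      partners_per_center = k,
      center_selection = list(name = "CEN"),
      partner_selection = list(name = "PRT"),
      min_separation = sep
    )
  )
}

#' Generate pseudo-lipid headgroups with prescribed tilt and torsions
#'
#' Builds minimal pseudo-lipids (residue name `LIP`) on an xy grid in the
#' upper half-space, each with a P--N pair posed at the requested tilt from
#' the +z axis and, per requested torsion label, a four-atom chain posed at
#' the requested dihedral. Angles may be fixed numbers (deterministic poses)
#' or sampler functions `function(n)` returning n angles (stochastic mode).
#' Torsion chains use synthetic atom names `C1..C4`, `D1..D4`, ... in label
#' order; the matching [torsion_definition()]s are returned in the truth
#' record.
#'
#' @param n_lipids Number of pseudo-lipids.
#' @param tilt_deg Tilt of the P-to-N vector from +z, degrees in
#'   `[0, 180]`, or a sampler function.
#' @param torsion_spec Named list mapping torsion labels to fixed dihedral
#'   angles in `(-180, 180]` or sampler functions; may be empty.
#' @param n_frames Number of frames (angles re-sampled per frame in
#'   stochastic mode, re-posed identically in deterministic mode).
#' @param seed Integer seed.
#' @param pn_length P--N distance in Angstrom (default 4.5).
#' @return List with `frames`, `truth` (`tilt_deg` per frame/lipid,
#'   `torsions` per label, `definitions` of the torsion chains).
#' @export
generate_headgroup_ensemble <- function(n_lipids, tilt_deg = 70,
                                        torsion_spec = list(), n_frames = 1L,
                                        seed, pn_length = 4.5) {
  if (n_lipids < 1L) {
    stop_monofilm("need at least one lipid", "monofilm_domain_error")
  }
  labels <- names(torsion_spec)
  if (length(torsion_spec) && is.null(labels)) {
    stop_monofilm("torsion_spec must be a named list", "monofilm_config_error")
  }
  chain_names <- lapply(seq_along(labels), function(j) {
    paste0(LETTERS[[2L + j]], 1:4)  # C1..C4, D1..D4, ...
  })
  sample_angles <- function(spec, n) {
    if (is.function(spec)) spec(n) else rep(as.numeric(spec), n)
  }
  check_range <- function(x, lo, hi, what) {
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
      stop_monofilm(sprintf("%s must lie in [%g, %g]", what, lo, hi),
                    "monofilm_config_error")
    }
  }

  per_lipid_atoms <- 2L + 4L * length(labels)
  atoms <- do.call(rbind, lapply(seq_len(n_lipids), function(l) {
    data.frame(
      element = c("P", "N", rep("C", 4L * length(labels))),
      name = c("P", "N", unlist(chain_names)),
      resname = "LIP",
      resid = l,
      stringsAsFactors = FALSE
    )
  }))
  # lipid anchor positions: xy grid, all in the upper half-space
  n_side <- ceiling(sqrt(n_lipids))
  spacing <- 10
  anchor <- cbind(
    (seq_len(n_lipids) - 1L) %% n_side * spacing,
    (seq_len(n_lipids) - 1L) %/% n_side * spacing,
    20
  )
  box <- c(max(n_side * spacing, 20), max(n_side * spacing, 20), 80)

  truth_tilt <- matrix(0, nrow = n_frames, ncol = n_lipids)
  truth_tors <- lapply(labels, function(l) matrix(0, n_frames, n_lipids))
  names(truth_tors) <- labels

  build <- function() {
    coords <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      tilt <- sample_angles(tilt_deg, n_lipids)
      check_range(tilt, 0, 180, "tilt angles")
      truth_tilt[f, ] <<- tilt
      m <- matrix(0, nrow = n_lipids * per_lipid_atoms, ncol = 3L)
      tors_f <- lapply(labels, function(lab) {
        a <- sample_angles(torsion_spec[[lab]], n_lipids)
        check_range(a, -180, 180, sprintf("torsion %s", lab))
        a
      })
      names(tors_f) <- labels
      for (lab in labels) truth_tors[[lab]][f, ] <<- tors_f[[lab]]
      theta_b <- 109.47 * pi / 180  # tetrahedral bond angle
      for (l in seq_len(n_lipids)) {
        base <- (l - 1L) * per_lipid_atoms
        t_rad <- tilt[[l]] * pi / 180
        m[base + 1L, ] <- anchor[l, ]                        # P
        m[base + 2L, ] <- anchor[l, ] +
          pn_length * c(sin(t_rad), 0, cos(t_rad))           # N
        for (j in seq_along(labels)) {
          phi <- tors_f[[j]][[l]] * pi / 180
          # canonical four-atom chain, 1.5 A bonds, tetrahedral angles;
          # central bond p2->p3 along +x. p4 starts anti-periplanar
          # (dihedral 180 deg) in the chain plane, then rotates about the
          # central bond by (180 deg - phi) to pose the requested dihedral.
          o <- anchor[l, ] + c(0, 4 * j, -4)
          p2 <- o
          p3 <- o + c(1.5, 0, 0)
          p1 <- p2 + 1.5 * c(cos(theta_b), sin(theta_b), 0)
          rel_anti <- 1.5 * c(-cos(theta_b), -sin(theta_b), 0)
          rot <- phi - pi
          rel <- c(rel_anti[[1L]],
                   cos(rot) * rel_anti[[2L]] - sin(rot) * rel_anti[[3L]],
                   sin(rot) * rel_anti[[2L]] + cos(rot) * rel_anti[[3L]])
          p4 <- p3 + rel
          span <- base + 2L + (j - 1L) * 4L + 1:4
          m[span[[1L]], ] <- p1
          m[span[[2L]], ] <- p2
          m[span[[3L]], ] <- p3
          m[span[[4L]], ] <- p4
        }
      }
      coords[[f]] <- m
    }
    coords
  }
  coords <- with_seed(seed, build())
  defs <- lapply(seq_along(labels), function(j) {
    torsion_definition(labels[[j]], chain_names[[j]], resname = "LIP")
  })
  names(defs) <- labels
  list(
    frames = trajectory_frames(atoms, coords, box),
    truth = list(tilt_deg = truth_tilt, torsions = truth_tors,
                 definitions = defs, pn_length = pn_length)
  )
}
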