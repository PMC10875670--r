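# z-origin used by profile and leaflet logic: centre of mass (unweighted mean
# z) of the water selection, or the mid-plane of all atoms when no water is
# present.
.water_resnames <- c("WAT", "HOH", "SOL", "TIP3", "OPC", "SPC")

z_reference <- function(tf, frame, reference = c("water_com", "midplane", "none")) {
  reference <- match.arg(reference)
  if (reference == "none") return(0)
  z <- tf$coords[[frame]][, 3L]
  if (reference == "water_com") {
    wat <- select_atoms(tf, resname = .water_resnames)
    if (length(wat)) return(mean(z[wat]))
  }
  (min(z) + max(z)) / 2
}

#' Electron density profile along the interface normal
#'
#' Histograms the z coordinates of the selected atoms, weighting each atom by
#' its electron count (integer atomic number), averages over frames and
#' divides by the bin volume \eqn{L_x L_y \Delta z}. z is referenced to the
#' centre of mass of the water selection by default (falling back to the
#' atom mid-plane when no water is present), so that z = 0 sits in the
#' aqueous region of a monolayer slab.
#'
#' @param tf A [trajectory_frames()] object.
#' @param selection Integer atom indices (from [select_atoms()]) or a list of
#'   filter arguments passed to [select_atoms()]. Default: all atoms.
#' @param bin_width Bin width in Angstrom (default 0.5).
#' @param reference z-origin convention: `"water_com"` (default),
#'   `"midplane"`, or `"none"` (raw coordinates).
#' @return An object of class `density_profile`: list with `bin_centers`
#'   (\eqn{\mathrm{\AA}}), `density` (e\eqn{^-}/\eqn{\mathrm{\AA}^3}),
#'   `n_frames`, `electrons_per_frame`, `area_xy` (mean \eqn{L_x L_y}).
#' @export
electron_density_profile <- function(tf, selection = NULL, bin_width = 0.5,
                                     reference = c("water_com", "midplane",
                                                   "none")) {
  stopifnot(inherits(tf, "trajectory_frames"))
  reference <- match.arg(reference)
  idx <- resolve_selection(tf, selection)
  if (!length(idx)) {
    stop_monofilm("empty atom selection", "monofilm_selection_error")
  }
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop_monofilm("bin_width must be positive", "monofilm_domain_error")
  }
  w <- tf$atoms$electron_count[idx]
  nf <- n_frames(tf)
  zs <- lapply(seq_len(nf), function(f) {
    tf$coords[[f]][idx, 3L] - z_reference(tf, f, reference)
  })
  zmin <- min(vapply(zs, min, numeric(1L)))
  zmax <- max(vapply(zs, max, numeric(1L)))
  lo <- floor(zmin / bin_width) * bin_width
  nbin <- max(1L, ceiling((zmax - lo) / bin_width + 1e-9))
  dens <- numeric(nbin)
  for (f in seq_len(nf)) {
    bin <- pmin(nbin, pmax(1L, floor((zs[[f]] - lo) / bin_width) + 1L))
    counts <- vapply(split(w, factor(bin, levels = seq_len(nbin))),
                     sum, numeric(1L))
    area_xy <- tf$boxes[f, 1L] * tf$boxes[f, 2L]
    dens <- dens + counts / (area_xy * bin_width)
  }
  dens <- dens / nf
  structure(
    list(
      bin_centers = lo + (seq_len(nbin) - 0.5) * bin_width,
      density = unname(dens),
      bin_width = bin_width,
      n_frames = nf,
      electrons_per_frame = sum(w),
      area_xy = mean(tf$boxes[, 1L] * tf$boxes[, 2L]),
      reference = reference
    ),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf(
    "<density_profile> %d bins of %.2f A, peak %.4g e-/A^3, %d frame(s)\n",
    length(x$density), x$bin_width, max(x$density), x$n_frames
  ))
  invisible(x)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  data.frame(z_A = x$bin_centers, density_e_A3 = x$density)
}

resolve_selection <- function(tf, selection) {
  if (is.null(selection)) return(seq_len(nrow(tf$atoms)))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.list(selection)) return(do.call(select_atoms, c(list(tf), selection)))
  stop_monofilm("selection must be atom indices or a filter list",
                "monofilm_selection_error")
}

# Minimum-image pair distances between coordinate sets a (n_a x 3) and
# b (n_b x 3) under an orthorhombic box; returns the n_a x n_b matrix.
min_image_dist <- function(a, b, box) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    dk <- dk - box[[k]] * round(dk / box[[k]])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Radial distribution function with running coordination number
#'
#' Histogram of minimum-image A--B pair distances, normalized per shell
#' volume \eqn{4\pi r^2 \Delta r} and per the mean number density of B in the
#' box (homogeneous normalization, the common convention for trajectory
#' analysis even in interfacial systems; the normalization record is attached
#' to the result). `n_of_r` is the running mean count of B atoms within r of
#' an A atom -- the coordination number when read at a g(r) minimum.
#' Self-pairs are excluded when the selections share atoms.
#'
#' @param tf A [trajectory_frames()] object.
#' @param sel_a,sel_b Atom selections (indices or filter lists) for the
#'   central (A) and distributed (B) species.
#' @param dr Bin width in Angstrom (default 0.05).
#' @param rmax Histogram range in Angstrom (default 8); must not exceed half
#'   the smallest box length.
#' @return An object of class `rdf_result`: list with `r` (bin centres), `g`,
#'   `n_of_r`, `counts` (mean pair counts per bin), and `normalization`.
#' @export
radial_distribution <- function(tf, sel_a, sel_b, dr = 0.05, rmax = 8.0) {
  stopifnot(inherits(tf, "trajectory_frames"))
  ia <- resolve_selection(tf, sel_a)
  ib <- resolve_selection(tf, sel_b)
  if (!length(ia) || !length(ib)) {
    stop_monofilm("empty atom selection", "monofilm_selection_error")
  }
  if (!is.finite(dr) || dr <= 0) {
    stop_monofilm("dr must be positive", "monofilm_domain_error")
  }
  if (rmax > min(tf$boxes) / 2 + 1e-9) {
    stop_monofilm("rmax must not exceed half the smallest box length",
                  "monofilm_domain_error")
  }
  nbin <- as.integer(ceiling(rmax / dr - 1e-9))
  counts <- numeric(nbin)
  nf <- n_frames(tf)
  rho_b <- 0
  for (f in seq_len(nf)) {
    m <- tf$coords[[f]]
    d <- min_image_dist(m[ia, , drop = FALSE], m[ib, , drop = FALSE],
                        tf$boxes[f, ])
    shared <- intersect(ia, ib)
    if (length(shared)) {
      d[cbind(match(shared, ia), match(shared, ib))] <- Inf
    }
    dv <- d[d < rmax]
    if (length(dv)) {
      bin <- pmin(nbin, floor(dv / dr) + 1L)
      tb <- tabulate(bin, nbins = nbin)
      counts <- counts + tb
    }
    rho_b <- rho_b + length(ib) / prod(tf$boxes[f, ])
  }
  counts <- counts / nf
  rho_b <- rho_b / nf
  r_centers <- (seq_len(nbin) - 0.5) * dr
  shell_vol <- 4 * pi * r_centers^2 * dr
  g <- counts / (length(ia) * shell_vol * rho_b)
  structure(
    list(
      r = r_centers,
      g = g,
      n_of_r = cumsum(counts) / length(ia),
      counts = counts,
      normalization = list(rho_b = rho_b, n_a = length(ia), n_b = length(ib),
                           dr = dr, rmax = rmax, n_frames = nf,
                           convention = "mean box density of B")
    ),
    class = "rdf_result"
  )
}

#' @export
print.rdf_result <- function(x, ...) {
  imax <- which.max(x$g)
  cat(sprintf(
    "<rdf_result> %d bins to %.2f A; g peak %.3g at %.2f A; n(rmax) = %.3g\n",
    length(x$r), max(x$r) + x$normalization$dr / 2, x$g[[imax]], x$r[[imax]],
    tail(x$n_of_r, 1L)
  ))
  invisible(x)
}

#' @export
as.data.frame.rdf_result <- function(x, ...) {
  data.frame(r_A = x$r, g_r = x$g, n_r = x$n_of_r)
}

#' Headgroup P--N tilt angles relative to the interface normal
#'
#' For every lipid residue and frame, the angle between the tail-atom to
#' head-atom vector (e.g. phosphorus to choline nitrogen) and the outward
#' interface normal. Leaflets are identified by the side of the tail atom
#' relative to the water centre of mass: the reference axis is +z for the
#' upper leaflet and -z for the lower, so 0 deg always means "head pointing
#' away from the water". Single-leaflet systems are treated as upper.
#'
#' @param tf A [trajectory_frames()] object.
#' @param tail_sel,head_sel Filter lists (see [select_atoms()]) resolving to
#'   exactly one tail atom (P) and one head atom (N) per lipid residue.
#' @param residues Residue ids to analyse; default: all residues in which the
#'   tail selection matches.
#' @return An object of class `angle_series`: list with `values` (degrees, in
#'   `[0, 180]`), `frame`, `resid`, `mean`, and `convention`.
#' @export
#' @examples
#' tf <- generate_headgroup_ensemble(n_lipids = 4, tilt_deg = 70, seed = 1)
#' mean(vector_tilt_angles(tf$frames)$values)  # 70
vector_tilt_angles <- function(tf, tail_sel = list(name = "P"),
                               head_sel = list(name = "N"), residues = NULL) {
  stopifnot(inherits(tf, "trajectory_frames"))
  it <- resolve_selection(tf, tail_sel)
  ih <- resolve_selection(tf, head_sel)
  rid <- if (is.null(residues)) sort(unique(tf$atoms$resid[it])) else residues
  tails <- heads <- integer(length(rid))
  for (k in seq_along(rid)) {
    tk <- it[tf$atoms$resid[it] == rid[[k]]]
    hk <- ih[tf$atoms$resid[ih] == rid[[k]]]
    if (length(tk) != 1L || length(hk) != 1L) {
      stop_monofilm(
        sprintf("residue %d: tail/head selection matched %d/%d atoms (need 1/1)",
                rid[[k]], length(tk), length(hk)),
        "monofilm_selection_error"
      )
    }
    tails[[k]] <- tk
    heads[[k]] <- hk
  }
  nf <- n_frames(tf)
  values <- numeric(nf * length(rid))
  frame_ix <- integer(length(values))
  resid_ix <- integer(length(values))
  pos <- 0L
  wat <- select_atoms(tf, resname = .water_resnames)
  for (f in seq_len(nf)) {
    m <- tf$coords[[f]]
    # leaflet split: side of the tail atom relative to the water centre of
    # mass, or to the mean tail height when no water is present (a
    # single-leaflet system then counts as upper)
    zref <- if (length(wat)) mean(m[wat, 3L]) else mean(m[tails, 3L])
    v <- m[heads, , drop = FALSE] - m[tails, , drop = FALSE]
    axis_sign <- ifelse(m[tails, 3L] >= zref, 1, -1)
    cosang <- axis_sign * v[, 3L] / sqrt(rowSums(v * v))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    span <- pos + seq_along(rid)
    values[span] <- ang
    frame_ix[span] <- f
    resid_ix[span] <- rid
    pos <- pos + length(rid)
  }
  structure(
    list(values = values, frame = frame_ix, resid = resid_ix,
         mean = mean(values),
         convention = "tilt in [0,180] deg from the outward leaflet normal"),
    class = "angle_series"
  )
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples, mean %.2f deg (%s)\n",
              length(x$values), x$mean, x$convention))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(frame = x$frame, resid = x$resid, value_deg = x$values)
}

#' Define a torsion by four atom names within a residue
#'
#' @param label Torsion label (e.g. `"alpha1"`, `"theta4"`).
#' @param atom_names Character vector of four atom names, in chain order.
#' @param resname Optional residue-name filter.
#' @return A `torsion_definition` object.
#' @export
torsion_definition <- function(label, atom_names, resname = NULL) {
  if (length(atom_names) != 4L || anyDuplicated(atom_names)) {
    stop_monofilm("a torsion needs four distinct atom names",
                  "monofilm_config_error")
  }
  structure(list(label = label, atom_names = atom_names, resname = resname),
            class = "torsion_definition")
}

# Signed dihedral (IUPAC convention) for the four points of each row set;
# p1..p4 are n x 3 matrices. Returns degrees in (-180, 180].
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v) {
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2 * b2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(-y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Torsion (dihedral) angles per lipid per frame
#'
#' Computes the signed dihedral angle, IUPAC convention, in
#' \eqn{(-180, 180]} degrees, for the four atoms named in a
#' [torsion_definition()], resolved within each residue.
#'
#' @param tf A [trajectory_frames()] object.
#' @param td A [torsion_definition()].
#' @param residues Residue ids; default: all residues in which the first
#'   torsion atom resolves.
#' @return An `angle_series` (see [vector_tilt_angles()]) with
#'   `label = td$label`.
#' @export
torsion_angles <- function(tf, td, residues = NULL) {
  stopifnot(inherits(tf, "trajectory_frames"),
            inherits(td, "torsion_definition"))
  sel <- lapply(td$atom_names, function(nm) {
    resolve_selection(tf, list(name = nm, resname = td$resname))
  })
  rid <- if (is.null(residues)) sort(unique(tf$atoms$resid[sel[[1L]]]))
         else residues
  idx <- matrix(0L, nrow = length(rid), ncol = 4L)
  for (k in seq_along(rid)) {
    for (j in 1:4) {
      a <- sel[[j]][tf$atoms$resid[sel[[j]]] == rid[[k]]]
      if (length(a) != 1L) {
        stop_monofilm(
          sprintf("torsion %s: atom %s matched %d atoms in residue %d (need 1)",
                  td$label, td$atom_names[[j]], length(a), rid[[k]]),
          "monofilm_selection_error"
        )
      }
      idx[k, j] <- a
    }
  }
  nf <- n_frames(tf)
  values <- numeric(nf * length(rid))
  frame_ix <- integer(length(values))
  resid_ix <- integer(length(values))
  pos <- 0L
  for (f in seq_len(nf)) {
    m <- tf$coords[[f]]
    ang <- dihedral_deg(m[idx[, 1L], , drop = FALSE],
                        m[idx[, 2L], , drop = FALSE],
                        m[idx[, 3L], , drop = FALSE],
                        m[idx[, 4L], , drop = FALSE])
    span <- pos + seq_along(rid)
    values[span] <- ang
    frame_ix[span] <- f
    resid_ix[span] <- rid
    pos <- pos + length(rid)
  }
  structure(
    list(values = values, frame = frame_ix, resid = resid_ix,
         mean = mean(values), label = td$label,
         convention = "signed dihedral in (-180,180] deg, IUPAC"),
    class = "angle_series"
  )
}

#' Classify a torsion angle into rotamer conformers
#'
#' Windows follow the usual rotamer nomenclature for lipid headgroup
#' torsions: synclinal (gauche) at \eqn{\pm(60 \pm 30)} degrees and
#' anti-periplanar at \eqn{180 \pm 30} degrees. Windows are closed intervals,
#' so boundary values (exactly 30, 90, 150 deg) belong to the named class;
#' everything else is `"other"`.
#'
#' @param angle Numeric vector of torsion angles in \eqn{(-180, 180]} degrees.
#' @return Character vector with levels `"+sin-clinical"`, `"-sin-clinical"`,
#'   `"anti-periplanar"`, `"other"`.
#' @export
#' @examples
#' classify_conformer(c(65, -65, 175, -120))
classify_conformer <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle)) ||
      any(angle <= -180 - 1e-9) || any(angle > 180 + 1e-9)) {
    stop_monofilm("angles must lie in (-180, 180] degrees",
                  "monofilm_domain_error")
  }
  vapply(angle, function(a) {
    if (a >= 30 && a <= 90) "+sin-clinical"
    else if (a >= -90 && a <= -30) "-sin-clinical"
    else if (abs(a) >= 150) "anti-periplanar"
    else "other"
  }, character(1L))
}

#' Joint conformer table for a pair of torsions
#'
#' Cross-tabulates the conformer labels of two aligned torsion series (same
#' lipid and frame indexing) and reports, among samples where both torsions
#' are synclinal, the fractions with the same sign versus reversed sign --
#' the signature distinguishing gauche sequences with and without a sign
#' reversal.
#'
#' @param a1,a2 `angle_series` objects from [torsion_angles()], aligned.
#' @return List with `table` (4 x 4 count matrix), `fraction_same_sign`,
#'   `fraction_sign_reversed`, `n_both_synclinal`.
#' @export
torsion_doublet_table <- function(a1, a2) {
  stopifnot(inherits(a1, "angle_series"), inherits(a2, "angle_series"))
  if (length(a1$values) != length(a2$values) ||
      !identical(a1$frame, a2$frame) || !identical(a1$resid, a2$resid)) {
    stop_monofilm("torsion series are not aligned (frame/residue indexing)",
                  "monofilm_alignment_error")
  }
  lv <- c("+sin-clinical", "-sin-clinical", "anti-periplanar", "other")
  c1 <- factor(classify_conformer(a1$values), levels = lv)
  c2 <- factor(classify_conformer(a2$values), levels = lv)
  tab <- table(c1, c2, dnn = c(a1$label %||% "torsion1",
                               a2$label %||% "torsion2"))
  sc <- lv[1:2]
  both <- c1 %in% sc & c2 %in% sc
  n_both <- sum(both)
  same <- sum(both & as.character(c1) == as.character(c2))
  list(
    table = tab,
    fraction_same_sign = if (n_both) same / n_both else NA_real_,
    fraction_sign_reversed = if (n_both) (n_both - same) / n_both else NA_real_,
    n_both_synclinal = n_both
  )
}

#' Area per molecule from box dimensions
#'
#' The standard monolayer-simulation observable: time average of
#' \eqn{L_x L_y} divided by the number of lipids per leaflet.
#'
#' @param tf A [trajectory_frames()] object.
#' @param lipids_per_leaflet Positive lipid count per leaflet.
#' @return Mean area per molecule in \eqn{\mathrm{\AA}^2}.
#' @export
area_per_molecule <- function(tf, lipids_per_leaflet) {
  stopifnot(inherits(tf, "trajectory_frames"))
  if (!is.finite(lipids_per_leaflet) || lipids_per_leaflet <= 0) {
    stop_monofilm("lipids_per_leaflet must be positive",
                  "monofilm_domain_error")
  }
  mean(tf$boxes[, 1L] * tf$boxes[, 2L]) / lipids_per_leaflet
}
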