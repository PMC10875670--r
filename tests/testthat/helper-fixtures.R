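# Shared builders for small in-code fixtures.

# a linear isotherm pi = 70 - A sampled on a uniform grid
linear_isotherm <- function(n = 71, a_from = 70, a_to = 20) {
  a <- seq(a_from, a_to, length.out = n)
  isotherm(a, pmax(0, 70 - a), label = "linear")
}

# minimal trajectory with explicit atoms/coordinates
make_frames <- function(elements, coords, box = c(20, 20, 20),
                        resname = "UNK", resid = seq_along(elements),
                        name = elements) {
  atoms <- data.frame(element = elements, name = name,
                      resname = rep_len(resname, length(elements)),
                      resid = resid, stringsAsFactors = FALSE)
  if (!is.list(coords)) coords <- list(coords)
  trajectory_frames(atoms, coords, box)
}

# brute-force minimum-image RDF histogram counts (independent oracle)
brute_rdf_counts <- function(tf, ia, ib, dr, rmax) {
  nbin <- as.integer(ceiling(rmax / dr - 1e-9))
  counts <- numeric(nbin)
  for (f in seq_along(tf$coords)) {
    m <- tf$coords[[f]]
    box <- tf$boxes[f, ]
    for (i in ia) for (j in ib) {
      if (i == j) next
      d <- m[i, ] - m[j, ]
      for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      r <- sqrt(sum(d^2))
      if (r < rmax) {
        b <- min(nbin, floor(r / dr) + 1)
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts / length(tf$coords)
}

# per-bin standard error of the mean g(r) estimated across frames
rdf_empirical_se <- function(tf, sel_a, sel_b, dr, rmax) {
  per_frame <- vapply(seq_along(tf$coords), function(f) {
    one <- tf
    one$coords <- tf$coords[f]
    one$boxes <- tf$boxes[f, , drop = FALSE]
    radial_distribution(one, sel_a, sel_b, dr = dr, rmax = rmax)$g
  }, numeric(as.integer(ceiling(rmax / dr - 1e-9))))
  apply(per_frame, 1, stats::sd) / sqrt(length(tf$coords))
}

# rotation matrix about an arbitrary unit axis (Rodrigues)
rot_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_frames <- function(tf, R = diag(3), shift = c(0, 0, 0)) {
  tf$coords <- lapply(tf$coords, function(m) {
    t(R %*% t(m)) + matrix(shift, nrow(m), 3, byrow = TRUE)
  })
  tf
}
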