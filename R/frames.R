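# Atomic numbers for the elements that occur in lipid/water/ion systems and
# the rest of the first six periods' common symbols.
.atomic_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30,
  Br = 35, Rb = 37, Sr = 38, I = 53, Cs = 55, Ba = 56
)

#' Electron count (atomic number) for element symbols
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Integer vector of atomic numbers.
#' @export
#' @examples
#' electron_count(c("O", "H", "P", "Na"))
electron_count <- function(element) {
  sym <- paste0(toupper(substr(element, 1, 1)),
                tolower(substr(element, 2, nchar(element))))
  z <- .atomic_numbers[sym]
  if (anyNA(z)) {
    stop_monofilm(
      sprintf("unknown element symbol(s): %s",
              paste(unique(element[is.na(z)]), collapse = ", ")),
      "monofilm_format_error"
    )
  }
  as.integer(z)
}

#' Construct a trajectory-frames container
#'
#' Holds an ordered atom table plus per-frame coordinates and orthorhombic box
#' dimensions. Atom order is constant across frames; coordinates are in
#' Angstrom.
#'
#' @param atoms `data.frame` with columns `element`, `name`, `resname`,
#'   `resid`; an `electron_count` column is added from `element` if absent.
#' @param coords List of numeric matrices, one per frame, each `n_atoms` x 3.
#' @param boxes Numeric matrix `n_frames` x 3 of box lengths (Lx, Ly, Lz, in
#'   Angstrom), or a length-3 vector recycled over frames.
#' @return An object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(atoms, coords, boxes) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "name", "resname", "resid")
  if (!all(need %in% names(atoms))) {
    stop_monofilm(sprintf("atoms table must have columns: %s",
                          paste(need, collapse = ", ")),
                  "monofilm_format_error")
  }
  if (!is.list(coords) || !length(coords)) {
    stop_monofilm("coords must be a non-empty list of frames",
                  "monofilm_format_error")
  }
  if (is.null(atoms$electron_count)) {
    atoms$electron_count <- electron_count(atoms$element)
  }
  n <- nrow(atoms)
  for (f in seq_along(coords)) {
    m <- coords[[f]]
    if (!is.matrix(m) || ncol(m) != 3L || nrow(m) != n) {
      stop_monofilm(
        sprintf("frame %d: expected a %d x 3 coordinate matrix", f, n),
        "monofilm_format_error"
      )
    }
  }
  if (is.null(dim(boxes))) boxes <- matrix(boxes, nrow = length(coords),
                                           ncol = 3L, byrow = TRUE)
  if (nrow(boxes) != length(coords) || ncol(boxes) != 3L) {
    stop_monofilm("boxes must be an n_frames x 3 matrix",
                  "monofilm_format_error")
  }
  if (any(boxes <= 0)) {
    stop_monofilm("box lengths must be positive", "monofilm_domain_error")
  }
  structure(
    list(atoms = atoms, coords = coords, boxes = boxes),
    class = "trajectory_frames"
  )
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf(
    "<trajectory_frames> %d atoms, %d frame(s), box %.4g x %.4g x %.4g A\n",
    nrow(x$atoms), length(x$coords),
    x$boxes[1, 1], x$boxes[1, 2], x$boxes[1, 3]
  ))
  invisible(x)
}

n_frames <- function(tf) length(tf$coords)

#' Select atoms by element, atom name, residue name or residue id
#'
#' All given criteria must match (logical AND); each criterion accepts a
#' vector of allowed values. With no criteria, all atoms are selected.
#'
#' @param tf A [trajectory_frames()] object.
#' @param element,name,resname,resid Optional filters.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(tf, element = NULL, name = NULL, resname = NULL,
                         resid = NULL) {
  stopifnot(inherits(tf, "trajectory_frames"))
  keep <- rep(TRUE, nrow(tf$atoms))
  if (!is.null(element)) keep <- keep & tf$atoms$element %in% element
  if (!is.null(name)) keep <- keep & tf$atoms$name %in% name
  if (!is.null(resname)) keep <- keep & tf$atoms$resname %in% resname
  if (!is.null(resid)) keep <- keep & tf$atoms$resid %in% resid
  which(keep)
}

#' Read monolayer configurations into a trajectory
#'
#' Supports multi-model PDB (`CRYST1` box, frames delimited by
#' `MODEL`/`ENDMDL`) and extended-XYZ (lattice in the comment line). Multiple
#' paths are concatenated as successive frames; the atom table must be
#' consistent across all frames.
#'
#' @param paths Character vector of file paths.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return A [trajectory_frames()] object with electron counts assigned from
#'   element symbols.
#' @export
read_frames <- function(paths, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  parts <- lapply(paths, function(p) {
    if (!file.exists(p)) {
      stop_monofilm(sprintf("file not found: %s", p), "monofilm_format_error")
    }
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.pdb$", p, ignore.case = TRUE)) "pdb" else "xyz"
    }
    if (fmt == "pdb") parse_pdb(p) else parse_extxyz(p)
  })
  atoms <- parts[[1L]]$atoms
  coords <- list()
  boxes <- NULL
  frame_no <- 0L
  for (part in parts) {
    for (f in seq_along(part$coords)) {
      frame_no <- frame_no + 1L
      if (nrow(part$atoms) != nrow(atoms) ||
          !identical(part$atoms$element, atoms$element)) {
        stop_monofilm(
          sprintf("frame %d: atom list inconsistent with frame 1", frame_no),
          "monofilm_format_error"
        )
      }
      coords[[frame_no]] <- part$coords[[f]]
    }
    boxes <- rbind(boxes, part$boxes)
  }
  trajectory_frames(atoms, coords, boxes)
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cryst <- lines[rec == "CRYST1"]
  if (!length(cryst)) {
    stop_monofilm(sprintf("%s: missing CRYST1 box record", path),
                  "monofilm_format_error")
  }
  box <- as.numeric(c(substr(cryst[[1L]], 7, 15), substr(cryst[[1L]], 16, 24),
                      substr(cryst[[1L]], 25, 33)))
  if (anyNA(box) || any(box <= 0)) {
    stop_monofilm(sprintf("%s: unreadable CRYST1 box", path),
                  "monofilm_format_error")
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(rec == "MODEL ")
  frames_idx <- if (length(model_starts)) {
    model_ends <- which(rec == "ENDMDL")
    if (length(model_ends) != length(model_starts)) {
      stop_monofilm(sprintf("%s: unbalanced MODEL/ENDMDL", path),
                    "monofilm_format_error")
    }
    lapply(seq_along(model_starts), function(k) {
      span <- model_starts[[k]]:model_ends[[k]]
      span[is_atom[span]]
    })
  } else {
    list(which(is_atom))
  }
  parse_atoms <- function(idx, frame) {
    ln <- lines[idx]
    name <- trimws(substr(ln, 13, 16))
    resname <- trimws(substr(ln, 18, 21))
    resid <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    elem <- trimws(substr(ln, 77, 78))
    # fall back to the first letter of the atom name when the element
    # column is absent
    elem[!nzchar(elem)] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                               name[!nzchar(elem)])
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop_monofilm(sprintf("%s frame %d: non-numeric coordinates",
                            path, frame),
                    "monofilm_format_error")
    }
    list(
      atoms = data.frame(element = elem, name = name, resname = resname,
                         resid = resid, stringsAsFactors = FALSE),
      xyz = cbind(x, y, z)
    )
  }
  first <- parse_atoms(frames_idx[[1L]], 1L)
  if (!nrow(first$atoms)) {
    stop_monofilm(sprintf("%s: no ATOM/HETATM records", path),
                  "monofilm_format_error")
  }
  coords <- vector("list", length(frames_idx))
  coords[[1L]] <- unname(first$xyz)
  for (f in seq_along(frames_idx)[-1L]) {
    p <- parse_atoms(frames_idx[[f]], f)
    if (nrow(p$atoms) != nrow(first$atoms)) {
      stop_monofilm(
        sprintf("%s frame %d: %d atoms, expected %d", path, f,
                nrow(p$atoms), nrow(first$atoms)),
        "monofilm_format_error"
      )
    }
    coords[[f]] <- unname(p$xyz)
  }
  first$atoms$electron_count <- electron_count(first$atoms$element)
  list(atoms = first$atoms, coords = coords,
       boxes = matrix(box, nrow = length(coords), ncol = 3L, byrow = TRUE))
}

parse_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  atoms0 <- NULL
  boxes <- NULL
  frame <- 0L
  while (pos <= length(lines) && nzchar(trimws(lines[[pos]]))) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[[pos]])))
    if (is.na(nat) || nat < 1L) {
      stop_monofilm(sprintf("%s frame %d: bad atom count line", path, frame),
                    "monofilm_format_error")
    }
    if (pos + 1L + nat > length(lines) + 0L) {
      stop_monofilm(sprintf("%s frame %d: truncated frame", path, frame),
                    "monofilm_format_error")
    }
    comment <- lines[[pos + 1L]]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (!length(lat)) {
      stop_monofilm(sprintf("%s frame %d: missing Lattice record",
                            path, frame),
                    "monofilm_format_error")
    }
    lat9 <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", lat)),
                                "\\s+")[[1L]])
    if (length(lat9) != 9L || anyNA(lat9)) {
      stop_monofilm(sprintf("%s frame %d: lattice must have 9 numbers",
                            path, frame),
                    "monofilm_format_error")
    }
    off_diag <- lat9[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off_diag) > 1e-8)) {
      stop_monofilm(sprintf("%s frame %d: only orthorhombic boxes supported",
                            path, frame),
                    "monofilm_format_error")
    }
    box <- lat9[c(1, 5, 9)]
    body <- lines[pos + 1L + seq_len(nat)]
    tok <- strsplit(trimws(body), "\\s+")
    ncols <- lengths(tok)
    if (any(ncols < 4L)) {
      stop_monofilm(sprintf("%s frame %d: atom lines need symbol + xyz",
                            path, frame),
                    "monofilm_format_error")
    }
    elem <- vapply(tok, `[[`, character(1L), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (anyNA(xyz)) {
      stop_monofilm(sprintf("%s frame %d: non-numeric coordinates",
                            path, frame),
                    "monofilm_format_error")
    }
    has_meta <- all(ncols >= 7L)
    atoms <- data.frame(
      element = elem,
      name = if (has_meta) vapply(tok, `[[`, character(1L), 5L) else elem,
      resname = if (has_meta) vapply(tok, `[[`, character(1L), 6L)
                else rep("UNK", nat),
      resid = if (has_meta) as.integer(vapply(tok, `[[`, character(1L), 7L))
              else seq_len(nat),
      stringsAsFactors = FALSE
    )
    if (is.null(atoms0)) {
      atoms0 <- atoms
    } else if (nrow(atoms) != nrow(atoms0) ||
               !identical(atoms$element, atoms0$element)) {
      stop_monofilm(sprintf("%s frame %d: atom list inconsistent with frame 1",
                            path, frame),
                    "monofilm_format_error")
    }
    frames[[frame]] <- xyz
    boxes <- rbind(boxes, box)
    pos <- pos + 2L + nat
  }
  if (!frame) {
    stop_monofilm(sprintf("%s: no frames found", path), "monofilm_format_error")
  }
  atoms0$electron_count <- electron_count(atoms0$element)
  list(atoms = atoms0, coords = frames, boxes = unname(boxes))
}

#' Write a trajectory to PDB or extended-XYZ
#'
#' The extended-XYZ writer keeps full coordinate precision (10 decimal
#' places) and carries atom name, residue name and residue id as extra
#' per-atom columns; the PDB writer uses the fixed-format 3-decimal
#' coordinate fields.
#'
#' @param tf A [trajectory_frames()] object.
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_frames <- function(tf, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(tf, "trajectory_frames"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  at <- tf$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    b <- tf$boxes[1L, ]
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[[1L]], b[[2L]], b[[3L]], 90, 90, 90
    ), con)
    for (f in seq_along(tf$coords)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      m <- tf$coords[[f]]
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        seq_len(nrow(at)) %% 100000L, substr(at$name, 1, 4),
        substr(at$resname, 1, 4), at$resid %% 10000L,
        m[, 1L], m[, 2L], m[, 3L], at$element
      ), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_along(tf$coords)) {
      b <- tf$boxes[f, ]
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf(
        'Lattice="%.10f 0.0 0.0 0.0 %.10f 0.0 0.0 0.0 %.10f" Properties=species:S:1:pos:R:3:name:S:1:resname:S:1:resid:I:1',
        b[[1L]], b[[2L]], b[[3L]]
      ), con)
      m <- tf$coords[[f]]
      writeLines(sprintf("%-2s %.10f %.10f %.10f %s %s %d",
                         at$element, m[, 1L], m[, 2L], m[, 3L],
                         at$name, at$resname, at$resid), con)
    }
  }
  invisible(path)
}
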