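## Trajectory data model and elementary per-frame observables.
##
## A Frame stores atomic positions (Angstrom) in an orthorhombic box together
## with the per-atom electrostatics of a polarizable force field: point
## charges q_i (e), static dipoles mu_i^sta and induced dipoles mu_i^ind
## (e*Angstrom). The box dipole ("polarization" in the extensive sense used
## throughout) is
##     P_a(t) = sum_i [ q_i a_i(t) + mu_ia^sta + mu_ia^ind(t) ],  a = x,y,z.

#' Construct a single trajectory frame
#'
#' @param positions N x 3 numeric matrix of positions (Angstrom).
#' @param box length-3 numeric vector of orthorhombic box edge lengths
#'   (Angstrom). Triclinic cells are not supported.
#' @param time frame time in ps.
#' @param charges optional length-N vector of point charges (e).
#' @param dipoles_static optional N x 3 matrix of static atomic dipoles
#'   (e*Angstrom).
#' @param dipoles_induced optional N x 3 matrix of induced atomic dipoles
#'   (e*Angstrom).
#' @return an object of class `cr_frame`.
#' @export
cr_frame <- function(positions, box, time = 0,
                     charges = NULL, dipoles_static = NULL,
                     dipoles_induced = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("positions must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) == 9L) {
    m <- matrix(box, 3, 3)
    if (any(abs(m[upper.tri(m) | lower.tri(m)]) > 1e-10))
      stop("triclinic boxes are not supported; box must be orthorhombic")
    box <- diag(m)
  }
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive orthorhombic edge lengths")
  n <- nrow(positions)
  chk_mat <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != n || ncol(x) != 3L)
      stop(sprintf("%s must be an N x 3 matrix matching positions", what))
    x
  }
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n)
      stop("charges must have one value per atom")
  }
  structure(list(
    time = as.numeric(time)[1],
    box = box,
    positions = positions,
    charges = charges,
    dipoles_static = chk_mat(dipoles_static, "dipoles_static"),
    dipoles_induced = chk_mat(dipoles_induced, "dipoles_induced")
  ), class = "cr_frame")
}

#' @export
print.cr_frame <- function(x, ...) {
  cat(sprintf("<cr_frame> %d atoms, t = %g ps, box = %s A\n",
              nrow(x$positions), x$time,
              paste(signif(x$box, 6), collapse = " x ")))
  cat(sprintf("  charges: %s, static dipoles: %s, induced dipoles: %s\n",
              !is.null(x$charges), !is.null(x$dipoles_static),
              !is.null(x$dipoles_induced)))
  invisible(x)
}

#' Construct a molecular topology
#'
#' Groups atoms into molecules and resolves the two named bonds of a
#' methanol-like molecule: the hydroxyl OH bond (O -> H, tail at O) and the
#' CO bond (C -> O, tail at C).
#'
#' @param elements character vector of element symbols, one per atom.
#' @param molecules optional list of integer atom-index vectors. When `NULL`,
#'   molecules are inferred from the element pattern: each carbon starts a new
#'   molecule (so both `C O H` and `C H H H O H` layouts work).
#' @return an object of class `cr_topology` with fields `elements`,
#'   `molecules`, `oh_bonds` (n_mol x 2 matrix: O index, H index) and
#'   `co_bonds` (n_mol x 2 matrix: C index, O index).
#' @export
cr_topology <- function(elements, molecules = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (is.null(molecules)) {
    starts <- which(elements == "C")
    if (length(starts) == 0L || starts[1] != 1L)
      stop("cannot infer topology: atoms must start with a carbon, or supply molecules explicitly")
    ends <- c(starts[-1] - 1L, n)
    molecules <- Map(seq.int, starts, ends)
  }
  covered <- sort(unlist(molecules))
  if (!identical(covered, seq_len(n)))
    stop("molecule atom groups must be disjoint and cover all atoms")
  nm <- length(molecules)
  oh <- matrix(NA_integer_, nm, 2, dimnames = list(NULL, c("O", "H")))
  co <- matrix(NA_integer_, nm, 2, dimnames = list(NULL, c("C", "O")))
  for (m in seq_len(nm)) {
    idx <- molecules[[m]]
    el <- elements[idx]
    iC <- idx[el == "C"]; iO <- idx[el == "O"]; iH <- idx[el == "H"]
    if (length(iC) != 1L || length(iO) != 1L || length(iH) < 1L)
      stop(sprintf("molecule %d is not methanol-like (needs exactly one C, one O, >= 1 H)", m))
    # hydroxyl H: first H after the O in atom order, else the last H
    after <- iH[iH > iO]
    oh[m, ] <- c(iO, if (length(after)) after[1] else iH[length(iH)])
    co[m, ] <- c(iC, iO)
  }
  structure(list(elements = elements, molecules = molecules,
                 oh_bonds = oh, co_bonds = co, n_molecules = nm),
            class = "cr_topology")
}

#' @export
print.cr_topology <- function(x, ...) {
  cat(sprintf("<cr_topology> %d atoms in %d molecules (OH and CO bonds resolved)\n",
              length(x$elements), x$n_molecules))
  invisible(x)
}

#' Specify an applied sinusoidal electric field
#'
#' The field is \eqn{E(t) = E_0 \sin(\omega t)\,\hat{n}} with the phase origin
#' at a zero-crossing going positive. Amplitude 0 denotes a field-free control
#' run that is still folded at the nominal frequency.
#'
#' @param amplitude field amplitude E0 in V/Angstrom (>= 0).
#' @param frequency_GHz linear frequency in GHz.
#' @param axis unit 3-vector of the field direction (default +z).
#' @param frames_per_cycle number of frames sampled per field period (>= 2).
#' @return an object of class `cr_field` with both `frequency_GHz` and the
#'   angular `omega` (rad/ps).
#' @export
cr_field <- function(amplitude, frequency_GHz, axis = c(0, 0, 1),
                     frames_per_cycle = 100L) {
  if (amplitude < 0) stop("field amplitude must be >= 0")
  if (frequency_GHz <= 0) stop("field frequency must be > 0")
  frames_per_cycle <- as.integer(frames_per_cycle)
  if (frames_per_cycle < 2L) stop("frames_per_cycle must be >= 2")
  axis <- as.numeric(axis)
  nr <- sqrt(sum(axis^2))
  if (nr == 0) stop("field axis must be a nonzero vector")
  structure(list(amplitude = amplitude,
                 frequency_GHz = frequency_GHz,
                 omega = ghz_to_radps(frequency_GHz),
                 axis = axis / nr,
                 frames_per_cycle = frames_per_cycle),
            class = "cr_field")
}

#' Construct a trajectory from frames
#'
#' @param frames list of [cr_frame()] objects with identical atom counts.
#' @param topology a [cr_topology()] (or `NULL` to infer later).
#' @param field optional [cr_field()] describing an applied field.
#' @return an object of class `cr_trajectory`.
#' @export
cr_trajectory <- function(frames, topology = NULL, field = NULL) {
  if (length(frames) == 0L) stop("trajectory must contain at least one frame")
  counts <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(counts)) != 1L)
    stop(sprintf("inconsistent atom counts across frames (frame %d has %d, frame 1 has %d)",
                 which(counts != counts[1])[1], counts[counts != counts[1]][1], counts[1]))
  if (!is.null(topology) && length(topology$elements) != counts[1])
    stop("topology atom count does not match frames")
  structure(list(frames = frames, topology = topology, field = field),
            class = "cr_trajectory")
}

#' @export
print.cr_trajectory <- function(x, ...) {
  cat(sprintf("<cr_trajectory> %d frames, %d atoms%s\n",
              length(x$frames), nrow(x$frames[[1]]$positions),
              if (!is.null(x$topology))
                sprintf(", %d molecules", x$topology$n_molecules) else ""))
  invisible(x)
}

#' @export
length.cr_trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param traj a `cr_trajectory`.
#' @return numeric vector of frame times in ps.
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time, numeric(1))
}

## minimum-image displacement(s) b - a in an orthorhombic box
min_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Total box polarization of a frame
#'
#' Sums per-atom charge, static-dipole and induced-dipole contributions into
#' the extensive box dipole,
#' \eqn{P_\alpha = \sum_i [ q_i \alpha_i + \mu_{i\alpha}^{sta} +
#' \mu_{i\alpha}^{ind} ]} for \eqn{\alpha \in \{x,y,z\}}. Positions are used
#' as stored; no periodic wrapping is applied here.
#'
#' @param frame a [cr_frame()] with charges present (missing dipole blocks are
#'   treated as zero).
#' @return length-3 numeric vector (e*Angstrom), names x/y/z.
#' @export
box_polarization <- function(frame) {
  if (is.null(frame$charges))
    stop("frame has no charges; cannot evaluate box polarization")
  p <- colSums(frame$positions * frame$charges)
  if (!is.null(frame$dipoles_static)) p <- p + colSums(frame$dipoles_static)
  if (!is.null(frame$dipoles_induced)) p <- p + colSums(frame$dipoles_induced)
  if (any(!is.finite(p))) stop("non-finite values in polarization inputs")
  names(p) <- c("x", "y", "z")
  p
}

#' Polarization of a single molecule
#'
#' The box-polarization sum restricted to one molecule's atoms. For a neutral
#' molecule the result is independent of the coordinate origin; for a charged
#' group it is origin-dependent, so the charge contribution is evaluated about
#' the group's centroid and a warning is raised.
#'
#' @param frame a [cr_frame()].
#' @param molecule integer vector of atom indices.
#' @param charge_tol net charges below this magnitude (e) count as neutral.
#' @return length-3 numeric vector (e*Angstrom).
#' @export
molecule_polarization <- function(frame, molecule, charge_tol = 1e-9) {
  molecule <- as.integer(molecule)
  if (any(molecule < 1L | molecule > nrow(frame$positions)))
    stop("molecule atom indices out of range")
  q <- if (is.null(frame$charges)) rep(0, length(molecule)) else frame$charges[molecule]
  pos <- frame$positions[molecule, , drop = FALSE]
  net <- sum(q)
  if (abs(net) > charge_tol) {
    warning(sprintf(
      "molecule has net charge %+.3g e; polarization is origin-dependent (evaluated about the group centroid)", net))
    pos <- sweep(pos, 2, colMeans(pos))
  }
  p <- colSums(pos * q)
  if (!is.null(frame$dipoles_static))
    p <- p + colSums(frame$dipoles_static[molecule, , drop = FALSE])
  if (!is.null(frame$dipoles_induced))
    p <- p + colSums(frame$dipoles_induced[molecule, , drop = FALSE])
  names(p) <- c("x", "y", "z")
  p
}

#' Angle between a named bond and a fixed axis
#'
#' Computes the angle (degrees, in [0, 180]) between the bond vector
#' tail -> head (O -> H for the hydroxyl bond, C -> O for the CO bond) and a
#' laboratory axis, conventionally the applied-field direction. The bond
#' vector is taken under the minimum-image convention, so bonds split across
#' the periodic boundary are handled.
#'
#' @param frame a [cr_frame()].
#' @param topology a [cr_topology()].
#' @param bond `"OH"` or `"CO"`.
#' @param axis length-3 axis vector (normalized internally; default +z).
#' @param molecules optional integer vector of molecule indices (default all).
#' @return numeric vector of angles in degrees, one per molecule.
#' @export
bond_angle_to_axis <- function(frame, topology, bond = c("OH", "CO"),
                               axis = c(0, 0, 1), molecules = NULL) {
  bond <- match.arg(bond)
  bm <- if (bond == "OH") topology$oh_bonds else topology$co_bonds
  if (is.null(molecules)) molecules <- seq_len(nrow(bm))
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  tail_i <- bm[molecules, 1]; head_i <- bm[molecules, 2]
  v <- frame$positions[head_i, , drop = FALSE] -
       frame$positions[tail_i, , drop = FALSE]
  v <- min_image(v, frame$box)
  nr <- sqrt(rowSums(v^2))
  if (any(nr < 1e-12)) stop("degenerate (zero-length) bond vector")
  cosang <- (v %*% axis) / nr
  cosang <- pmin(1, pmax(-1, cosang))
  as.numeric(acos(cosang) * 180 / pi)
}
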