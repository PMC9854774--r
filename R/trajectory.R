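#' Coordinate trajectory with atom metadata
#'
#' Container for an ordered set of coordinate frames sharing one atom
#' table. Coordinates are Cartesian Angstroms.
#'
#' @param coords numeric array `frames x atoms x 3`, or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param atoms data frame with one row per atom and columns `name`,
#'   `element`, `resname`, `resno`, `chain`, `role` (one of `protein`,
#'   `ligand`, `other`).
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(coords, atoms) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("coords must be a frames x atoms x 3 array", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  need <- c("name", "element", "resname", "resno", "chain", "role")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("atoms table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) != dim(coords)[2L])
    stop("atom table and coordinate array disagree on atom count",
         call. = FALSE)
  if (!all(atoms$role %in% c("protein", "ligand", "other")))
    stop("role must be protein, ligand or other", call. = FALSE)
  structure(list(coords = coords, atoms = atoms), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms (%d protein, %d ligand)\n",
              n_frames(x), nrow(x$atoms), sum(x$atoms$role == "protein"),
              sum(x$atoms$role == "ligand")))
  invisible(x)
}

#' @export
#' @rdname trajectory
n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range",
                                         call. = FALSE)
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Select atoms by metadata and geometry
#'
#' Deterministic atom selection evaluated on a reference frame. All
#' criteria are conjunctive; `NULL` means "no constraint".
#'
#' @param traj a [trajectory()].
#' @param role restrict to a role (`protein`, `ligand`, `other`).
#' @param elements character vector of element symbols.
#' @param resno integer vector of residue numbers.
#' @param resname character vector of residue names.
#' @param backbone if `TRUE`, keep only protein backbone atoms
#'   (names N, CA, C, O).
#' @param within_of if non-`NULL`, a list `list(selection, cutoff)`
#'   keeping atoms of residues having any atom within `cutoff` Angstrom of
#'   any atom of `selection`, evaluated on `ref_frame`. Used to define
#'   e.g. active-site backbone sets around a bound ligand.
#' @param ref_frame reference frame index for geometric criteria.
#' @return sorted integer vector of atom indices (error if empty).
#' @export
select_atoms <- function(traj, role = NULL, elements = NULL, resno = NULL,
                         resname = NULL, backbone = FALSE,
                         within_of = NULL, ref_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(elements)) keep <- keep & a$element %in% elements
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (backbone) keep <- keep & a$name %in% c("N", "CA", "C", "O")
  if (!is.null(within_of)) {
    target <- within_of$selection
    cutoff <- within_of$cutoff
    xyz <- frame_coords(traj, ref_frame)
    d <- pairwise_dist(xyz[, , drop = FALSE], xyz[target, , drop = FALSE])
    near_atom <- apply(d, 1L, min) <= cutoff
    near_res <- unique(paste(a$chain, a$resno)[near_atom])
    keep <- keep & paste(a$chain, a$resno) %in% near_res
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("atom selection is empty on the reference frame", call. = FALSE)
  idx
}

pairwise_dist <- function(a, b) {
  # n x m Euclidean distance matrix between two coordinate sets
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Kabsch least-squares rigid superposition
#'
#' Closed-form SVD solution for the proper rotation and translation
#' minimizing the RMSD between paired coordinate sets, with reflection
#' correction (the returned rotation always has determinant +1).
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates (paired rows).
#' @param selection optional integer indices: the atoms used to determine
#'   the fit (default all rows). The transform applies to all of `mobile`.
#' @return list with `rotation` (3 x 3), `translation` (length 3, applied
#'   after rotation about the selection centroid), `rmsd` (fitted RMSD
#'   over the selection), and `transformed` (all mobile coordinates after
#'   the fit).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L ||
      nrow(mobile) != nrow(reference))
    stop("mobile and reference must be paired n x 3 matrices",
         call. = FALSE)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L)
    stop("superposition needs >= 3 fit atoms", call. = FALSE)
  M <- mobile[selection, , drop = FALSE]
  R0 <- reference[selection, , drop = FALSE]
  cm <- colMeans(M); cr <- colMeans(R0)
  Mc <- sweep(M, 2L, cm); Rc <- sweep(R0, 2L, cr)
  # collinearity guard: centred fit atoms must span a plane
  if (svd(Mc)$d[2L] < 1e-8 * max(svd(Mc)$d[1L], 1))
    stop("fit atoms are collinear: rotation is underdetermined",
         call. = FALSE)
  H <- t(Mc) %*% Rc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  transformed <- sweep(sweep(mobile, 2L, cm) %*% t(rot), 2L, cr, "+")
  rmsd <- sqrt(mean(rowSums((transformed[selection, , drop = FALSE] -
                               R0)^2)))
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
       rmsd = rmsd, transformed = transformed)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD relative to a reference frame
#'
#' Each frame is rigidly superposed on the reference over `fit_selection`
#' (Kabsch); the RMSD is then measured over `measure_selection` without
#' refitting. This is the standard protocol for e.g. ligand RMSD after an
#' active-site backbone fit. With `fit_selection = NULL` frames are
#' compared as-is (no superposition).
#'
#' @param traj a [trajectory()].
#' @param ref_frame reference frame index (default 1).
#' @param fit_selection integer atom indices used for the superposition,
#'   or `NULL` for none.
#' @param measure_selection integer atom indices over which RMSD is
#'   measured (default: all atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, ref_frame = 1L, fit_selection = NULL,
                        measure_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(measure_selection))
    measure_selection <- seq_len(nrow(traj$atoms))
  if (length(measure_selection) == 0L)
    stop("measure selection is empty", call. = FALSE)
  ref <- frame_coords(traj, ref_frame)
  vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    if (!is.null(fit_selection))
      xyz <- kabsch_superpose(xyz, ref, fit_selection)$transformed
    rmsd_between(xyz[measure_selection, , drop = FALSE],
                 ref[measure_selection, , drop = FALSE])
  }, 0)
}

#' Per-atom root mean square fluctuation
#'
#' After optionally superposing every frame on the first over
#' `fit_selection`, computes for each selected atom the square root of
#' the mean squared deviation from its mean position across frames.
#'
#' @inheritParams rmsd_series
#' @param selection atoms for which RMSF is reported (default all).
#' @return named numeric vector of RMSF values (Angstrom) for
#'   `selection`.
#' @export
rmsf <- function(traj, selection = NULL, fit_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF requires >= 2 frames", call. = FALSE)
  if (is.null(selection)) selection <- seq_len(nrow(traj$atoms))
  ref <- frame_coords(traj, 1L)
  frames <- lapply(seq_len(nf), function(i) {
    xyz <- frame_coords(traj, i)
    if (!is.null(fit_selection))
      xyz <- kabsch_superpose(xyz, ref, fit_selection)$transformed
    xyz[selection, , drop = FALSE]
  })
  arr <- array(unlist(frames), c(length(selection), 3L, nf))
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- sweep(arr, c(1L, 2L), mean_pos)^2
  out <- sqrt(apply(dev2, 1L, mean) * 3)  # mean over coords*frames, x3 for per-atom
  names(out) <- traj$atoms$name[selection]
  out
}
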