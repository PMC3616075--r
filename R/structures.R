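#' @keywords internal
"_PACKAGE"

#' Construct a molecular structure object
#'
#' A `structure3d` holds an ordered atom table and one set of coordinates in
#' Angstrom. Atom order is preserved from the source and `(chain, resno,
#' elety)` must be unique. Column names follow the bio3d convention:
#' `chain`, `resno` (1-based residue number), `resid` (3-letter residue
#' name), `elety` (atom name, e.g. `"CA"`), `elesy` (element symbol).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `elesy`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param title optional character title.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resid", "elety", "elesy")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom identity: ", key[anyDuplicated(key)][1])
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, title = as.character(title)[1]),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d>", if (nzchar(x$title)) paste0(" ", x$title), "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms),
      "  chains: ", paste(unique(x$atoms$chain), collapse = ","),
      "  residues: ", length(unique(paste(x$atoms$chain, x$atoms$resno))), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x a `structure3d` or `trajectory3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory3d")) nrow(x$topology$atoms) else nrow(x$atoms)
}

#' Construct a trajectory object
#'
#' A `trajectory3d` is a fixed-atom-order topology plus per-frame coordinates
#' and a strictly increasing time axis in picoseconds. The integration
#' timestep and save interval are carried as metadata (trajectory file
#' headers are unreliable, so these default to the values used to produce
#' the trajectories this toolkit targets: 1.5 fs steps saved every 5000
#' steps, i.e. 7.5 ps between frames).
#'
#' @param topology a `structure3d`.
#' @param coords numeric array `[n_frames, n_atoms, 3]` in Angstrom.
#' @param times numeric vector of frame times in ps, strictly increasing.
#'   Default: multiples of `step_fs * save_interval_steps / 1000` starting at 0.
#' @param step_fs integration timestep in femtoseconds (metadata).
#' @param save_interval_steps steps between saved frames (metadata).
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, coords, times = NULL,
                         step_fs = 1.5, save_interval_steps = 5000L) {
  stopifnot(inherits(topology, "structure3d"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_atoms, 3] array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("coords atom count (", dim(coords)[2], ") does not match topology (",
         nrow(topology$atoms), ")")
  nf <- dim(coords)[1]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (is.null(times)) times <- (seq_len(nf) - 1) * step_fs * save_interval_steps / 1000
  if (length(times) != nf) stop("times length must equal number of frames")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 step_fs = step_fs, save_interval_steps = as.integer(save_interval_steps)),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("<trajectory3d> ", n_frames(x), " frames x ", n_atoms(x), " atoms, t = ",
      format(x$times[1]), " .. ", format(x$times[n_frames(x)]), " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory3d`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `trajectory3d`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix.
#' @export
frame_xyz <- function(traj, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Extract one frame as a structure
#' @inheritParams frame_xyz
#' @return a `structure3d` with the trajectory topology and frame coordinates.
#' @export
get_frame <- function(traj, i) {
  s <- traj$topology
  s$xyz <- frame_xyz(traj, i)
  s$title <- sprintf("%s frame %d (t = %g ps)", s$title, i, traj$times[i])
  s
}

# replace every frame's coordinates; internal
set_coords <- function(traj, coords) {
  traj$coords <- coords
  traj
}
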