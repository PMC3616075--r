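# flatten n x 3 coordinates to (x1,y1,z1,x2,...) vector; internal
flatten_xyz <- function(m) as.vector(t(m))

# align every frame's selection coordinates to the reference; returns
# n_frames x 3N matrix of aligned selection coordinates (and the fits)
aligned_frame_matrix <- function(traj, sel, reference, with_fits = FALSE) {
  ref <- reference$xyz[sel$indices, , drop = FALSE]
  nf <- n_frames(traj)
  X <- matrix(NA_real_, nf, 3L * length(sel$indices))
  fits <- if (with_fits) vector("list", nf) else NULL
  for (f in seq_len(nf)) {
    fx <- frame_xyz(traj, f)[sel$indices, , drop = FALSE]
    sp <- kabsch_fit(fx, ref)
    X[f, ] <- flatten_xyz(apply_superposition(fx, sp))
    if (with_fits) fits[[f]] <- sp
  }
  list(X = X, fits = fits)
}

#' Essential-dynamics PCA of a C-alpha trajectory
#'
#' Each frame's selection coordinates are Kabsch-aligned to the reference
#' (by default the starting structure), and the covariance matrix of the
#' aligned 3N coordinate vectors about their trajectory mean is
#' diagonalised. The unweighted covariance over CA atoms is used. Modes
#' are orthonormal 3N vectors sorted by decreasing eigenvalue (Angstrom^2);
#' the eigenvalue fraction of a mode is its share of the total CA
#' fluctuation. Eigenvector sign is fixed so the component of largest
#' magnitude is positive (the sign of a PCA mode is arbitrary).
#'
#' @param traj a `trajectory3d` with at least 2 frames.
#' @param sel `atom_selection` of N >= 3 atoms (default: all CA atoms).
#' @param reference alignment target `structure3d` (default: the
#'   trajectory topology, i.e. the starting coordinates).
#' @return object of class `ed_pca`: `selection`, `reference`, `mean`
#'   (3N), `modes` (3N x m orthonormal), `eigenvalues` (descending),
#'   `fractions`, `times`, `n_frames`.
#' @export
fit_pca <- function(traj, sel = NULL, reference = traj$topology) {
  if (is.null(sel)) {
    idx <- which(traj$topology$atoms$elety == "CA")
    if (!length(idx)) idx <- seq_len(n_atoms(traj))
    sel <- atom_selection(idx, "all CA")
  }
  check_selection(traj$topology, sel)
  check_selection(reference, sel)
  if (n_frames(traj) < 2L) stop("PCA needs at least 2 frames")
  if (length(sel$indices) < 3L) stop("degenerate selection: fewer than 3 atoms")
  X <- aligned_frame_matrix(traj, sel, reference)$X
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  modes <- e$vectors
  for (j in seq_len(ncol(modes))) {
    if (modes[which.max(abs(modes[, j])), j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(selection = sel, reference = reference, mean = mu,
                 modes = modes, eigenvalues = ev,
                 fractions = if (sum(ev) > 0) ev / sum(ev) else ev,
                 times = traj$times, n_frames = n_frames(traj)),
            class = "ed_pca")
}

#' @export
print.ed_pca <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat("<ed_pca> ", length(x$selection$indices), " atoms, ", x$n_frames,
      " frames\n", sep = "")
  cat("  top eigenvalue fractions: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$fractions[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ed_pca <- function(object, n = 10, ...) {
  n <- min(n, length(object$eigenvalues))
  data.frame(mode = seq_len(n),
             eigenvalue_A2 = object$eigenvalues[seq_len(n)],
             fraction = object$fractions[seq_len(n)],
             cumulative = cumsum(object$fractions)[seq_len(n)])
}

#' @export
plot.ed_pca <- function(x, n = 10, ...) {
  n <- min(n, length(x$eigenvalues))
  graphics::barplot(100 * x$fractions[seq_len(n)], names.arg = seq_len(n),
                    xlab = "PCA mode", ylab = "fraction of fluctuation (%)", ...)
  invisible(x)
}

# project a single flattened, aligned coordinate vector; internal
project_vector <- function(model, v, mode) {
  sum((v - model$mean) * model$modes[, mode])
}

#' Project a trajectory onto a PCA mode
#'
#' Per frame, the selection coordinates are aligned to the model's
#' reference and the signed amplitude along the chosen mode (deviation
#' from the model's trajectory mean) is returned, in Angstrom. The
#' trajectory may be a different run than the one the model was fitted on
#' (cross-projection), provided the atom correspondence holds.
#'
#' @param traj a `trajectory3d`.
#' @param model an `ed_pca`.
#' @param mode mode index (1-based).
#' @param align superpose each frame onto the model reference first
#'   (default). Use `FALSE` only for structures already expressed in the
#'   model's aligned frame, e.g. those built by [interpolate_mode()].
#' @param flip_sign negate the series (mode sign is arbitrary; flipping
#'   eases comparison between runs).
#' @return data.frame with columns `frame`, `time_ps`, `value` (Angstrom);
#'   attributes `mode`, `flip_sign`.
#' @export
project_trajectory <- function(traj, model, mode = 1L, align = TRUE,
                               flip_sign = FALSE) {
  stopifnot(inherits(model, "ed_pca"))
  if (mode < 1L || mode > ncol(model$modes)) stop("mode index out of range")
  sel <- model$selection
  check_selection(traj$topology, sel)
  if (!identical(traj$topology$atoms[sel$indices, c("chain", "resno", "elety")],
                 model$reference$atoms[sel$indices, c("chain", "resno", "elety")]))
    stop("trajectory atoms do not correspond to the model's selection")
  if (align) {
    X <- aligned_frame_matrix(traj, sel, model$reference)$X
  } else {
    X <- t(vapply(seq_len(n_frames(traj)),
                  function(f) flatten_xyz(frame_xyz(traj, f)[sel$indices, , drop = FALSE]),
                  numeric(3L * length(sel$indices))))
  }
  vals <- as.vector((sweep(X, 2, model$mean)) %*% model$modes[, mode])
  if (flip_sign) vals <- -vals
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
                    value = vals)
  attr(out, "mode") <- as.integer(mode)
  attr(out, "flip_sign") <- flip_sign
  out
}

#' Subspace overlap of a vector with the leading modes of a model
#'
#' Root-sum-of-squares of the inner products of `v` with the first `k`
#' modes: 1 means `v` lies inside the subspace they span, 0 means it is
#' orthogonal to it. At `k = 1` this is `|cos theta|` between the two
#' directions.
#'
#' @param v a 3N vector (normalised with a warning if needed), e.g. a mode
#'   of another run's model.
#' @param model an `ed_pca` with matching dimension.
#' @param k number of leading modes to span the subspace.
#' @return overlap coefficient in `[0, 1]`.
#' @export
subspace_overlap <- function(v, model, k = 2L) {
  stopifnot(inherits(model, "ed_pca"))
  if (k < 1L || k > ncol(model$modes)) stop("k exceeds the available modes")
  if (length(v) != nrow(model$modes)) stop("vector dimension does not match the model")
  nv <- sqrt(sum(v^2))
  if (abs(nv - 1) > 1e-8) {
    warning("input vector is not unit length; normalising")
    v <- v / nv
  }
  sqrt(sum((crossprod(model$modes[, seq_len(k), drop = FALSE], v))^2))
}

#' Pearson correlation between a projection and a distance series
#'
#' Validated wrapper around the product-moment correlation for the
#' standard check that a PCA mode embodies a collective-variable motion
#' (e.g. mode-1 projection vs the opening distance of the empty site).
#'
#' @param a,b numeric series of equal length >= 3 (or data.frames with a
#'   `value` column / a named series column).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
projection_distance_correlation <- function(a, b) {
  pull <- function(x) {
    if (is.data.frame(x)) {
      cn <- intersect(c("value", "site_apo", "rmsd"), names(x))
      if (!length(cn)) stop("data.frame series needs a value column")
      x <- x[[cn[1]]]
    }
    as.numeric(x)
  }
  a <- pull(a); b <- pull(b)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance in a series")
  stats::cor(a, b)
}

#' Frames attaining the extreme projections of a mode
#'
#' Returns the trajectory frames at the minimum and maximum projection
#' values, aligned (whole structure) onto the model's reference via the
#' selection fit. Ties take the earliest time. These two conformers are
#' the extremes of the transition the mode describes, and are the input
#' pair for hinge analysis.
#'
#' @param proj projection series from [project_trajectory()].
#' @param traj the `trajectory3d` the series was computed on.
#' @param model the `ed_pca` used for the projection.
#' @return list with `min_structure`, `max_structure` (aligned
#'   `structure3d`), `frames` (indices), `times` (ps), `values`.
#' @export
extreme_frames <- function(proj, traj, model) {
  if (!nrow(proj)) stop("empty projection series")
  i_min <- which.min(proj$value)
  i_max <- which.max(proj$value)
  aligned_full <- function(f) {
    s <- get_frame(traj, f)
    sp <- kabsch_fit(s$xyz[model$selection$indices, , drop = FALSE],
                     model$reference$xyz[model$selection$indices, , drop = FALSE])
    s$xyz <- apply_superposition(s$xyz, sp)
    s
  }
  list(min_structure = aligned_full(i_min), max_structure = aligned_full(i_max),
       frames = c(min = i_min, max = i_max),
       times = c(min = proj$time_ps[i_min], max = proj$time_ps[i_max]),
       values = c(min = proj$value[i_min], max = proj$value[i_max]))
}

#' Interpolated structures along a PCA mode
#'
#' Builds `n_inner + 2` structures at equally spaced projection values
#' between `p_lo` and `p_hi`, with coordinates `mean + p * mode` on the
#' model's selection atoms, as a multi-model trajectory (write with
#' [write_structures()]). These are in the model's aligned frame, so
#' re-projecting with `align = FALSE` returns the construction values.
#'
#' @param model an `ed_pca`.
#' @param mode mode index.
#' @param p_lo,p_hi projection range (Angstrom), `p_lo < p_hi`.
#' @param n_inner number of interior structures (default 8, giving 10
#'   models in total).
#' @return a `trajectory3d` over the selection atoms; frame f is at
#'   projection `p_lo + (f-1) * (p_hi - p_lo) / (n_inner + 1)`.
#' @export
interpolate_mode <- function(model, mode = 1L, p_lo, p_hi, n_inner = 8L) {
  stopifnot(inherits(model, "ed_pca"))
  if (mode < 1L || mode > ncol(model$modes)) stop("mode index out of range")
  if (!(p_lo < p_hi)) stop("p_lo must be less than p_hi")
  if (n_inner < 0L) stop("n_inner must be >= 0")
  ps <- seq(p_lo, p_hi, length.out = n_inner + 2L)
  sel <- model$selection
  topo <- structure3d(model$reference$atoms[sel$indices, , drop = FALSE],
                      matrix(model$mean, ncol = 3, byrow = TRUE),
                      title = sprintf("mode %d interpolation", mode))
  coords <- array(NA_real_, c(length(ps), length(sel$indices), 3L))
  for (f in seq_along(ps)) {
    coords[f, , ] <- matrix(model$mean + ps[f] * model$modes[, mode],
                            ncol = 3, byrow = TRUE)
  }
  out <- trajectory3d(topo, coords, times = seq_along(ps) - 1)
  attr(out, "projections") <- ps
  out
}

#' Export PCA modes as a plain-text matrix
#' @param model an `ed_pca`.
#' @param path output file (one whitespace-separated 3N row per mode).
#' @param n_modes number of leading modes to write.
#' @return `path`, invisibly.
#' @export
write_modes <- function(model, path, n_modes = 10L) {
  n_modes <- min(n_modes, ncol(model$modes))
  utils::write.table(t(model$modes[, seq_len(n_modes), drop = FALSE]),
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
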