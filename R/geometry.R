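row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMS
#' distance between `mobile` (moved) and `target`:
#' `aligned_i = R mobile_i + t`. Unweighted; the SVD solution with the
#' determinant correction that excludes reflections.
#'
#' @param mobile,target n x 3 coordinate matrices (Angstrom), n >= 3,
#'   non-collinear.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("mobile and target must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required for a rigid fit")
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); TT <- sweep(target, 2, ct)
  # collinear point sets leave the rotation under-determined
  for (P in list(M, TT)) {
    sv <- svd(P, nu = 0, nv = 0)$d
    if (sv[2] <= max(sv[1], 1) * 1e-10 && sv[1] > 0)
      stop("degenerate geometry: points are collinear")
  }
  H <- crossprod(M, TT)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.vector(R %*% cm)
  aligned <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - TT)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<superposition> rmsd = %.4f A, rotation %.2f deg\n", x$rmsd, ang))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param sp a `superposition`, or a list with `rotation` and `translation`.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sp) {
  coords %*% t(sp$rotation) +
    matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series against a reference structure
#'
#' Per frame, superposes the frame onto `reference` over `fit_sel` and
#' evaluates the RMSD over `calc_sel`. With `fit_sel == calc_sel` each
#' value equals the minimised Kabsch RMSD. Fitting and computing on
#' different selections is how subdomain stability is separated from
#' inter-domain rearrangement.
#'
#' @param traj a `trajectory3d`.
#' @param fit_sel,calc_sel `atom_selection`s valid on both the trajectory
#'   topology and `reference`.
#' @param reference a `structure3d` (defaults to the trajectory topology,
#'   i.e. deviation from the starting structure).
#' @return data.frame with columns `frame`, `time_ps`, `rmsd`.
#' @export
rmsd_series <- function(traj, fit_sel, calc_sel = fit_sel,
                        reference = traj$topology) {
  check_selection(traj$topology, fit_sel); check_selection(traj$topology, calc_sel)
  check_selection(reference, fit_sel); check_selection(reference, calc_sel)
  if (!identical(traj$topology$atoms[fit_sel$indices, c("chain", "resno", "elety")],
                 reference$atoms[fit_sel$indices, c("chain", "resno", "elety")]))
    stop("fit selection resolves different atoms in trajectory topology and reference")
  ref_fit <- reference$xyz[fit_sel$indices, , drop = FALSE]
  ref_calc <- reference$xyz[calc_sel$indices, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fx <- frame_xyz(traj, f)
    sp <- kabsch_fit(fx[fit_sel$indices, , drop = FALSE], ref_fit)
    rmsd_between(apply_superposition(fx[calc_sel$indices, , drop = FALSE], sp),
                 ref_calc)
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times, rmsd = vals)
}

check_selection <- function(struct, sel) {
  if (!inherits(sel, "atom_selection")) stop("selection must be an atom_selection")
  if (length(sel$indices) == 0L || max(sel$indices) > nrow(struct$atoms))
    stop("selection '", sel$label, "' is out of bounds for the structure")
  invisible(TRUE)
}

#' Trailing moving average
#'
#' Smooths a series with a trailing (not centred) window of `period`
#' samples; output length is `length(x) - period + 1`, element k averaging
#' `x[k .. k+period-1]`.
#'
#' @param x numeric series.
#' @param period window length, `1 <= period <= length(x)`.
#' @return smoothed numeric vector.
#' @export
moving_average <- function(x, period) {
  period <- as.integer(period)
  if (period < 1L) stop("period must be >= 1")
  if (period > length(x)) stop("period exceeds series length")
  if (period == 1L) return(as.numeric(x))
  f <- stats::filter(as.numeric(x), rep(1 / period, period), sides = 1)
  as.numeric(f[period:length(x)])
}

#' Rotation matrix about an axis (Rodrigues)
#' @param angle_deg rotation angle in degrees.
#' @param axis 3-vector (normalised internally).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(angle_deg, axis) {
  n <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -n[3], n[2], n[3], 0, -n[1], -n[2], n[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform of a screw motion
#'
#' Composes the rotation/translation pair of a screw: rotation by
#' `angle_deg` about `axis` through `pivot`, plus `pitch` Angstrom of
#' translation along the axis. Inverse of [screw_decomposition()].
#'
#' @param angle_deg angle in degrees.
#' @param axis 3-vector (normalised internally).
#' @param pivot point on the axis (Angstrom).
#' @param pitch translation along the axis (Angstrom).
#' @return list with `rotation` and `translation`, applicable with
#'   [apply_superposition()].
#' @export
screw_matrix <- function(angle_deg, axis, pivot, pitch = 0) {
  n <- axis / sqrt(sum(axis^2))
  R <- rotation_about_axis(angle_deg, n)
  t <- as.vector(pivot - R %*% pivot) + pitch * n
  list(rotation = R, translation = t)
}

#' Screw-axis decomposition of a rigid motion
#'
#' Decomposes a proper rigid transform `x -> R x + t` into rotation by an
#' angle about a unique axis line plus a pitch translation along it.
#' The angle comes from `acos((tr R - 1)/2)`; the axis from the
#' antisymmetric part of `R` (stabilised near 180 degrees via the
#' symmetric part); the pivot is the point on the axis closest to the
#' projection of the domain's geometric centre, which makes the reported
#' pivot unique (any point on the axis solves the screw equation). Also
#' reports `centre_displacement`, the distance moved by the domain's
#' geometric centre.
#'
#' Below `angle_min` the axis direction is numerically meaningless, so
#' axis, pivot and pitch are flagged undefined while angle and centre
#' displacement are still reported.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param t translation 3-vector (Angstrom).
#' @param domain_coords n x 3 coordinates of the moving domain (Angstrom).
#' @param angle_min smallest angle (degrees) for which an axis is reported.
#' @return object of class `screw_transform`: `angle_deg`, `axis`, `pivot`,
#'   `pitch`, `centre_displacement`, `axis_defined`.
#' @export
screw_decomposition <- function(R, t, domain_coords, angle_min = 1.0) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R must be a proper rotation matrix")
  domain_coords <- as.matrix(domain_coords)
  ctr <- colMeans(domain_coords)
  cd <- sqrt(sum((as.vector(R %*% ctr) + t - ctr)^2))
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  if (ang < angle_min) {
    return(structure(list(angle_deg = ang, axis = rep(NA_real_, 3),
                          pivot = rep(NA_real_, 3), pitch = NA_real_,
                          centre_displacement = cd, axis_defined = FALSE),
                     class = "screw_transform"))
  }
  th <- ang * pi / 180
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sin(th) > 1e-6) {
    n <- v / (2 * sin(th))
  } else {
    # near 180 deg: R + I = 2 n n^T; take its largest column
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    n <- M[, j] / sqrt(sum(M[, j]^2))
    if (n[which.max(abs(n))] < 0) n <- -n
  }
  n <- n / sqrt(sum(n^2))
  pitch <- sum(t * n)
  u <- t - pitch * n  # in-plane translation, absorbed by the pivot offset
  p0 <- 0.5 * u + 0.5 / tan(th / 2) * cross3(n, u)
  pivot <- p0 + sum((ctr - p0) * n) * n
  structure(list(angle_deg = ang, axis = n, pivot = pivot, pitch = pitch,
                 centre_displacement = cd, axis_defined = TRUE),
            class = "screw_transform")
}

#' @export
print.screw_transform <- function(x, ...) {
  if (x$axis_defined) {
    cat(sprintf(
      "<screw_transform> %.2f deg about (%.3f, %.3f, %.3f), pivot (%.1f, %.1f, %.1f), pitch %.2f A, centre moved %.2f A\n",
      x$angle_deg, x$axis[1], x$axis[2], x$axis[3],
      x$pivot[1], x$pivot[2], x$pivot[3], x$pitch, x$centre_displacement))
  } else {
    cat(sprintf("<screw_transform> %.3f deg (axis undefined), centre moved %.2f A\n",
                x$angle_deg, x$centre_displacement))
  }
  invisible(x)
}
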