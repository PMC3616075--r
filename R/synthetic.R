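# quasi-uniform points on a sphere (golden-angle spiral); internal
fib_sphere <- function(n, radius, centre = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(centre[1] + radius * r * cos(phi),
        centre[2] + radius * r * sin(phi),
        centre[3] + radius * z)
}

#' Build a toy single-chain structure
#'
#' A globular CA-only chain of `n_res` consecutive residues laid on a
#' quasi-uniform sphere, for constructing rigid-body test fixtures.
#'
#' @param n_res number of residues (numbered 1..n_res).
#' @param radius sphere radius in Angstrom.
#' @param centre centre of the blob.
#' @param chain chain identifier.
#' @return a `structure3d` of CA atoms.
#' @export
build_toy_chain <- function(n_res = 120L, radius = 12, centre = c(0, 0, 0),
                            chain = "A") {
  atoms <- data.frame(chain = chain, resno = seq_len(n_res), resid = "ALA",
                      elety = "CA", elesy = "C", stringsAsFactors = FALSE)
  structure3d(atoms, fib_sphere(n_res, radius, centre), title = "toy chain")
}

#' Build a toy NBD dimer structure
#'
#' A CA-only two-chain model that mirrors the NBD sandwich-dimer topology:
#' each monomer is a core blob (residues mapped into 1-90 and 164-228,
#' plus the Q-loop 91-93, Pro-loop 162-163 and C-terminal tail 229-235)
#' and a helical blob (94-161), with Walker A residues 43-46 and C-motif
#' residues 147-150 placed explicitly at the intermonomer interface.
#' Chain B is chain A rotated 180 degrees about the z axis (a C2 dimer),
#' so the two composite-site distances are exactly equal at the start.
#'
#' With `with_ligand = TRUE`, named pseudo-atoms needed by the contact
#' observables are planted: a nucleotide residue (ADP 301, chain A) with
#' beta-phosphate oxygens O1B/O2B/O3B and ribose hydroxyl O2' in the
#' nucleotide-bound site, the engaged C-motif serine hydroxyl OG (chain B
#' residue 147) placed 3.0 Angstrom from the nearest beta-phosphate
#' oxygen, and the C-motif glutamine sidechain amido atoms OE1/NE2
#' (chain B residue 150). Geometry is schematic, not stereochemical: the
#' analysis math only needs named atoms at known offsets.
#'
#' @param core_len residues in the core blob, taken in order from the core
#'   numbering (1..90, 164..228); must cover the Walker A motif (>= 46).
#' @param helical_len residues in the helical blob, taken in order from
#'   94..161; must cover the C-motif (>= 57).
#' @param with_ligand plant the ligand/sidechain pseudo-atoms (above).
#' @return a `structure3d` with chains A and B.
#' @export
build_toy_dimer <- function(core_len = 155L, helical_len = 68L,
                            with_ligand = TRUE) {
  core_numbering <- c(1:90, 164:228)
  hel_numbering <- 94:161
  if (core_len < 20L || helical_len < 20L) stop("block lengths must be >= 20")
  if (core_len > length(core_numbering) || helical_len > length(hel_numbering))
    stop("block length exceeds the residue numbering it maps into")
  core_res <- core_numbering[seq_len(core_len)]
  hel_res <- hel_numbering[seq_len(helical_len)]
  if (!all(43:46 %in% core_res))
    stop("core too short to host the Walker A motif (43-46)")
  if (!all(147:150 %in% hel_res))
    stop("helical block too short to host the C-motif (147-150)")
  extra_res <- c(91:93, setdiff(162:163, hel_res), 229:235)

  core_all <- sort(c(core_res, extra_res))
  pos_core <- fib_sphere(length(core_all), 12, c(15, -12, 0))
  pos_hel <- fib_sphere(length(hel_res), 10, c(-15, -12, 0))
  resno <- c(core_all, hel_res)
  xyz <- rbind(pos_core, pos_hel)
  o <- order(resno)
  resno <- resno[o]; xyz <- xyz[o, , drop = FALSE]
  # motif residues at the interface (overriding blob positions)
  for (k in 0:3) {
    xyz[resno == 43 + k, ] <- c(4.5 + k, -4, 0)   # Walker A centroid (6, -4, 0)
    xyz[resno == 147 + k, ] <- c(-15.5 + k, 4, 0) # C-motif centroid (-14, 4, 0)
  }
  resid <- rep("ALA", length(resno))
  resid[resno %in% 43:46] <- c("GLY", "LYS", "SER", "THR")
  resid[resno %in% 147:150] <- c("SER", "GLY", "GLY", "GLN")
  chainA <- data.frame(chain = "A", resno = resno, resid = resid,
                       elety = "CA", elesy = "C", stringsAsFactors = FALSE)
  flip <- diag(c(-1, -1, 1))  # C2 about z
  chainB <- chainA; chainB$chain <- "B"
  atoms <- rbind(chainA, chainB)
  coords <- rbind(xyz, xyz %*% flip)

  if (with_ligand) {
    extra <- data.frame(
      chain = c("B", "B", "B", rep("A", 4)),
      resno = c(147L, 150L, 150L, rep(301L, 4)),
      resid = c("SER", "GLN", "GLN", rep("ADP", 4)),
      elety = c("OG", "OE1", "NE2", "O1B", "O2B", "O3B", "O2'"),
      elesy = c("O", "O", "N", "O", "O", "O", "O"),
      stringsAsFactors = FALSE)
    extra_xyz <- rbind(c(11.5, -4, 0),     # OG, 3.0 A from O2B
                       c(10.0, -2.8, 0.6), # OE1
                       c(9.6, -5.0, -0.6), # NE2
                       c(6.8, -2.6, 0.9),  # O1B
                       c(8.5, -4, 0),      # O2B
                       c(6.2, -5.4, -0.8), # O3B
                       c(5.0, -3.0, 1.2))  # O2'
    atoms <- rbind(atoms, extra)
    coords <- rbind(coords, extra_xyz)
  }
  structure3d(atoms, coords, title = "toy NBD dimer")
}

new_truth <- function(...) structure(list(...), class = "synthetic_truth")

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed ", x$seed, ", noise sigma ", x$noise_sigma, " A\n",
      sep = "")
  if (!is.null(x$angle_schedule))
    cat("  opening: ", length(x$angle_schedule), " frames, max angle ",
        max(x$angle_schedule), " deg about (",
        paste(signif(x$hinge_axis, 3), collapse = ", "), ") through (",
        paste(signif(x$pivot, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic active-site opening trajectory
#'
#' Emulates the motion by which the empty (apo) active site of the NBD
#' dimer opens: the apo monomer's core block (core residues plus the
#' attached C-terminal tail, chain B) rotates outward by theta(t) about a
#' prescribed hinge axis through a pivot at the core/helical junction,
#' while everything else stays put; iid Gaussian coordinate noise of
#' `noise_sigma` Angstrom is added to every atom of every frame. Frames
#' are 7.5 ps apart. The ground truth carries the planted geometry and
#' the closed-form expected opening distance of the apo site per frame
#' (the rotated Walker A centroid to the static opposing C-motif
#' centroid); the nucleotide-bound site distance is constant by
#' construction.
#'
#' The angle schedule is `linear` (0 to `theta_max`) or `sigmoid` (a
#' logistic switch, mirroring how openings in real runs are switch-like);
#' default linear.
#'
#' @param dimer a [build_toy_dimer()] structure.
#' @param theta_max maximum rotation in degrees, in (0, 60].
#' @param n_frames number of frames, >= 50.
#' @param noise_sigma per-coordinate Gaussian noise in Angstrom.
#' @param schedule `"linear"` or `"sigmoid"`.
#' @param seed integer seed; all randomness derives from it.
#' @param scheme a [residue_scheme()] naming the moving chain and blocks.
#' @param axis,pivot hinge geometry; defaults are the z axis through the
#'   midpoint of the moving chain's core and helical centroids.
#' @return list with `trajectory` (`trajectory3d`) and `truth`
#'   (`synthetic_truth`).
#' @export
generate_opening_trajectory <- function(dimer, theta_max = 20, n_frames = 500L,
                                        noise_sigma = 0.2,
                                        schedule = c("linear", "sigmoid"),
                                        seed = 1L, scheme = residue_scheme(),
                                        axis = c(0, 0, 1), pivot = NULL) {
  schedule <- match.arg(schedule)
  if (theta_max <= 0 || theta_max > 60) stop("theta_max must be in (0, 60] degrees")
  if (n_frames < 50L) stop("n_frames must be >= 50")
  chain <- scheme$apo_monomer
  moving_res <- c(ranges_to_residues(scheme$core),
                  ranges_to_residues(scheme$c_term_tail))
  at <- dimer$atoms
  moving <- which(at$chain == chain & at$resno %in% moving_res)
  if (!length(moving)) stop("no atoms in the moving block")
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(pivot)) {
    core_c <- colMeans(dimer$xyz[at$chain == chain & at$elety == "CA" &
                                   at$resno %in% ranges_to_residues(scheme$core), ,
                                 drop = FALSE])
    hel_c <- colMeans(dimer$xyz[at$chain == chain & at$elety == "CA" &
                                  at$resno %in% ranges_to_residues(scheme$helical_domain), ,
                                drop = FALSE])
    pivot <- (core_c + hel_c) / 2
  }
  s <- (seq_len(n_frames) - 1) / (n_frames - 1)
  theta <- switch(schedule,
                  linear = theta_max * s,
                  sigmoid = theta_max / (1 + exp(-10 * (s - 0.5))))

  na <- nrow(at)
  coords <- array(NA_real_, c(n_frames, na, 3L))
  base <- dimer$xyz
  for (f in seq_len(n_frames)) {
    fx <- base
    sm <- screw_matrix(theta[f], axis, pivot)
    fx[moving, ] <- apply_superposition(base[moving, , drop = FALSE], sm)
    coords[f, , ] <- fx
  }
  if (noise_sigma > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(coords), sd = noise_sigma))
    coords <- coords + array(noise, dim(coords))
  }
  traj <- trajectory3d(dimer, coords, times = (seq_len(n_frames) - 1) * 7.5)

  sites <- paired_site_selections(dimer, scheme)
  w_apo0 <- colMeans(base[sites$site_apo$walker_a$indices, , drop = FALSE])
  c_apo <- colMeans(base[sites$site_apo$c_motif$indices, , drop = FALSE])
  d_nuc <- sqrt(sum((colMeans(base[sites$site_nuc$walker_a$indices, , drop = FALSE]) -
                       colMeans(base[sites$site_nuc$c_motif$indices, , drop = FALSE]))^2))
  expected <- vapply(theta, function(th) {
    w <- apply_superposition(matrix(w_apo0, 1, 3), screw_matrix(th, axis, pivot))
    sqrt(sum((w - c_apo)^2))
  }, numeric(1))
  truth <- new_truth(hinge_axis = axis, pivot = pivot, angle_schedule = theta,
                     moving_residues = list(chain = chain, resno = moving_res),
                     noise_sigma = noise_sigma, seed = as.integer(seed),
                     schedule = schedule, expected_opening = expected,
                     expected_nuc = rep(d_nuc, n_frames))
  list(trajectory = traj, truth = truth)
}

#' Generate a no-motion control trajectory
#'
#' Thermal-noise-only control: every frame is the input dimer plus iid
#' Gaussian coordinate noise, with no planted collective motion. This is
#' the closed-dimer counterpart of [generate_opening_trajectory()] for
#' contrast experiments (its PCA modes are pure noise, so they should
#' barely overlap an opening run's dominant mode).
#'
#' @param dimer a `structure3d`.
#' @param n_frames number of frames, >= 50.
#' @param noise_sigma per-coordinate Gaussian noise in Angstrom.
#' @param seed integer seed.
#' @return list with `trajectory` and `truth`.
#' @export
generate_control_trajectory <- function(dimer, n_frames = 500L,
                                        noise_sigma = 0.2, seed = 1L) {
  if (n_frames < 50L) stop("n_frames must be >= 50")
  na <- nrow(dimer$atoms)
  coords <- array(rep(dimer$xyz, each = n_frames), c(n_frames, na, 3L))
  if (noise_sigma > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(coords), sd = noise_sigma))
    coords <- coords + array(noise, dim(coords))
  }
  traj <- trajectory3d(dimer, coords, times = (seq_len(n_frames) - 1) * 7.5)
  truth <- new_truth(hinge_axis = NULL, pivot = NULL, angle_schedule = NULL,
                     moving_residues = NULL, noise_sigma = noise_sigma,
                     seed = as.integer(seed), schedule = "none",
                     expected_opening = NULL, expected_nuc = NULL)
  list(trajectory = traj, truth = truth)
}

#' Generate a rigid-body conformer pair with known screws
#'
#' The second structure is the first with each listed residue block
#' rigidly transformed by its screw (rotation about an axis through a
#' pivot, plus optional pitch); iid Gaussian noise is then added to the
#' second structure's coordinates. Blocks must be disjoint. The ground
#' truth records every planted screw.
#'
#' @param x a `structure3d` (e.g. from [build_toy_dimer()] or
#'   [build_toy_chain()]).
#' @param rotations list of `list(chain =, residues =, angle_deg =,
#'   axis =, pivot =, pitch = 0)`.
#' @param noise_sigma per-coordinate Gaussian noise added to the second
#'   structure (Angstrom).
#' @param seed integer seed.
#' @return list with `x`, `y` (the pair) and `truth`.
#' @export
generate_rigid_pair <- function(x, rotations = list(), noise_sigma = 0,
                                seed = 1L) {
  at <- x$atoms
  blocks <- lapply(rotations, function(r) {
    which(at$chain == r$chain & at$resno %in% r$residues)
  })
  if (length(blocks) > 1L) {
    all_idx <- unlist(blocks)
    if (anyDuplicated(all_idx)) stop("rotation residue blocks overlap")
  }
  y <- x
  for (k in seq_along(rotations)) {
    r <- rotations[[k]]
    sm <- screw_matrix(r$angle_deg, r$axis, r$pivot,
                       if (is.null(r$pitch)) 0 else r$pitch)
    y$xyz[blocks[[k]], ] <- apply_superposition(x$xyz[blocks[[k]], , drop = FALSE], sm)
  }
  if (noise_sigma > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(length(y$xyz), sd = noise_sigma))
    y$xyz <- y$xyz + matrix(noise, nrow(y$xyz), 3)
  }
  truth <- new_truth(screws = rotations, moving_blocks = blocks,
                     noise_sigma = noise_sigma, seed = as.integer(seed))
  list(x = x, y = y, truth = truth)
}

#' Serialise synthetic ground truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
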