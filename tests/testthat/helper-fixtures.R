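# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

toy_dimer <- function() cached("dimer", build_toy_dimer())

# moderate-length opening run shared across modules
opening_run <- function() cached("opening", {
  generate_opening_trajectory(toy_dimer(), theta_max = 20, n_frames = 150,
                              noise_sigma = 0.2, seed = 11)
})

# two spatially separated rigid blobs in one chain: residues 1-60 fixed,
# 61-120 to be rotated about the z axis through the origin
two_block_structure <- function() cached("two_block", {
  a <- build_toy_chain(60, 20, c(-28, 0, 0))
  b <- build_toy_chain(60, 20, c(38, 0, 0))
  b$atoms$resno <- 61:120
  structure3d(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz),
              title = "two-block chain")
})

two_block_pair <- function(angle = 20, noise_sigma = 0, seed = 1) {
  generate_rigid_pair(two_block_structure(),
                      list(list(chain = "A", residues = 61:120,
                                angle_deg = angle, axis = c(0, 0, 1),
                                pivot = c(0, 0, 0))),
                      noise_sigma = noise_sigma, seed = seed)
}

all_ca_selection <- function(struct) {
  atom_selection(which(struct$atoms$elety == "CA"), "all CA")
}

# independent brute-force superposition oracle: grid over axis-angle
# rotations followed by Nelder-Mead refinement of the rotation vector;
# translation handled by centroid matching (optimal for any fixed R)
oracle_rmsd <- function(mobile, target) {
  M <- sweep(mobile, 2, colMeans(mobile))
  TT <- sweep(target, 2, colMeans(target))
  obj_R <- function(R) sqrt(mean(rowSums((M %*% t(R) - TT)^2)))
  rotvec_to_R <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    rotation_about_axis(th * 180 / pi, v / th)
  }
  dirs <- rbind(c(0, 0, 1), fib_sphere_pts(80))
  best <- c(0, 0, 0); best_val <- obj_R(diag(3))
  for (ang in seq(10, 180, by = 10) * pi / 180) {
    for (i in seq_len(nrow(dirs))) {
      v <- ang * dirs[i, ]
      val <- obj_R(rotvec_to_R(v))
      if (val < best_val) { best_val <- val; best <- v }
    }
  }
  op <- stats::optim(best, function(v) obj_R(rotvec_to_R(v)),
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  min(op$value, best_val)
}

fib_sphere_pts <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

random_rotation <- function() {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
  rotation_about_axis(stats::runif(1, 0, 180), v)
}
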