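test_that("degenerate trajectories give zero eigenvalues", {
  d <- build_toy_chain(30)
  tr <- trajectory3d(d, array(rep(d$xyz, each = 4), c(4, 30, 3)))
  m <- fit_pca(tr, all_ca_selection(d))
  expect_true(all(m$eigenvalues < 1e-12))
  expect_error(fit_pca(trajectory3d(d, array(d$xyz, c(1, 30, 3)))), "2 frames")
})

test_that("a planted rank-1 displacement is recovered as mode 1", {
  d <- build_toy_chain(40)
  set.seed(8)
  dir <- rnorm(120)
  # remove the rigid-body content of the pattern so the per-frame
  # alignment is exactly the identity and the planted direction survives
  rigid <- matrix(0, 120, 6)
  ctr <- sweep(d$xyz, 2, colMeans(d$xyz))
  for (k in 1:3) rigid[seq(k, 120, by = 3), k] <- 1
  e <- diag(3)
  for (k in 1:3) {
    rigid[, 3 + k] <- as.vector(t(ctr %*% t(rbind(
      c(0, -e[k, 3], e[k, 2]), c(e[k, 3], 0, -e[k, 1]), c(-e[k, 2], e[k, 1], 0)))))
  }
  q <- qr.Q(qr(rigid))
  dir <- dir - q %*% crossprod(q, dir)
  dir <- dir / sqrt(sum(dir^2))
  s_t <- seq(-2, 2, length.out = 21)  # zero-mean amplitude schedule
  coords <- array(NA_real_, c(21, 40, 3))
  for (f in 1:21) coords[f, , ] <- d$xyz + s_t[f] * matrix(dir, 40, 3, byrow = TRUE)
  m <- fit_pca(trajectory3d(d, coords), all_ca_selection(d))
  expect_equal(m$fractions[1], 1, tolerance = 1e-6)
  # mode 1 is proportional to the planted direction (up to alignment residual)
  planted <- as.vector(t(matrix(dir, 40, 3, byrow = TRUE)))
  expect_gt(abs(sum(m$modes[, 1] * planted)), 0.999)
})

test_that("eigendecomposition matches an independent SVD factorisation", {
  g <- opening_run()
  tr <- subsample(g$trajectory, 15)
  sel <- all_ca_selection(toy_dimer())
  m <- fit_pca(tr, sel)
  # oracle: singular-value factorisation of the centred aligned data matrix
  X <- nbdtraj:::aligned_frame_matrix(tr, sel, toy_dimer())$X
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  lam <- sv$d^2 / (nrow(Xc) - 1)
  k <- sum(lam > 1e-6)
  expect_lt(max(abs(m$eigenvalues[1:k] - lam[1:k])), 1e-8)
  for (j in 1:min(k, 5))
    expect_equal(abs(sum(m$modes[, j] * sv$v[, j])), 1, tolerance = 1e-8)
  # eigenvalue sum equals the covariance trace; fractions sum to 1
  expect_equal(sum(m$eigenvalues), sum(diag(crossprod(Xc) / (nrow(Xc) - 1))),
               tolerance = 1e-6)
  expect_equal(sum(m$fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  # orthonormality of the mode basis
  MtM <- crossprod(m$modes[, 1:10])
  expect_lt(max(abs(MtM - diag(10))), 1e-8)
})

test_that("two planted orthogonal motions with 4:1 variance are recovered", {
  d <- build_toy_chain(50)
  n3 <- 150
  set.seed(21)
  d1 <- rnorm(n3); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(n3); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  nf <- 500
  s1 <- rnorm(nf, sd = 2); s2 <- rnorm(nf, sd = 1)  # variance ratio 4:1
  base <- as.vector(t(d$xyz))
  coords <- array(NA_real_, c(nf, 50, 3))
  for (f in 1:nf) {
    v <- base + s1[f] * d1 + s2[f] * d2 + rnorm(n3, sd = 0.05)
    coords[f, , ] <- matrix(v, 50, 3, byrow = TRUE)
  }
  m <- fit_pca(trajectory3d(d, coords), all_ca_selection(d))
  ratio <- m$eigenvalues[1] / m$eigenvalues[2]
  expect_equal(ratio, 4, tolerance = 0.1 * 4)
})

test_that("projection identities hold for self- and forced configurations", {
  g <- opening_run()
  tr <- subsample(g$trajectory, 15)
  sel <- all_ca_selection(toy_dimer())
  m <- fit_pca(tr, sel)
  mk_traj <- function(vec) {
    xyz <- matrix(vec, ncol = 3, byrow = TRUE)
    topo <- structure3d(toy_dimer()$atoms[sel$indices, ], xyz)
    trajectory3d(topo, array(xyz, c(1, nrow(xyz), 3)))
  }
  sub_sel <- atom_selection(seq_along(sel$indices))
  msub <- m; msub$selection <- sub_sel
  msub$reference <- structure3d(toy_dimer()$atoms[sel$indices, ],
                                matrix(m$mean, ncol = 3, byrow = TRUE))
  # the model's own mean projects to zero
  expect_equal(project_trajectory(mk_traj(m$mean), msub, 1, align = FALSE)$value, 0)
  # mean + 2.5 * mode1 projects to 2.5
  expect_equal(project_trajectory(mk_traj(m$mean + 2.5 * m$modes[, 1]), msub, 1,
                                  align = FALSE)$value, 2.5, tolerance = 1e-9)
  # and still does after re-alignment (the standard path)
  expect_equal(project_trajectory(mk_traj(m$mean + 2.5 * m$modes[, 1]), msub, 1,
                                  align = TRUE)$value, 2.5, tolerance = 1e-3)
  # self-projection variance equals the eigenvalue
  pr <- project_trajectory(tr, m, 1)
  expect_equal(stats::var(pr$value), m$eigenvalues[1], tolerance = 1e-6)
  expect_error(project_trajectory(tr, m, ncol(m$modes) + 1), "out of range")
})

test_that("subspace overlap measures containment in the leading modes", {
  g <- opening_run()
  m <- fit_pca(subsample(g$trajectory, 30), all_ca_selection(toy_dimer()))
  expect_equal(subspace_overlap(m$modes[, 1], m, k = 2), 1, tolerance = 1e-9)
  v <- (m$modes[, 1] + m$modes[, 2]) / sqrt(2)
  expect_equal(subspace_overlap(v, m, k = 1), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(subspace_overlap(m$modes[, 5], m, k = 2), 0, tolerance = 1e-9)
  expect_warning(subspace_overlap(2 * m$modes[, 1], m, k = 2), "unit")
  expect_error(subspace_overlap(m$modes[, 1], m, k = ncol(m$modes) + 1), "modes")
})

test_that("correlation wrapper validates and matches the hand computation", {
  expect_equal(projection_distance_correlation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(projection_distance_correlation(1:10, -(1:10)), -1)
  expect_equal(projection_distance_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(projection_distance_correlation(1:4, 1:5), "lengths")
  expect_error(projection_distance_correlation(rep(1, 5), 1:5), "variance")
})

test_that("extreme frames attain the projection extremes, earliest tie wins", {
  g <- opening_run()
  tr <- subsample(g$trajectory, 30)
  m <- fit_pca(tr, all_ca_selection(toy_dimer()))
  pr <- project_trajectory(tr, m, 1)
  ext <- extreme_frames(pr, tr, m)
  expect_equal(unname(ext$frames["min"]), which.min(pr$value))
  expect_equal(unname(ext$frames["max"]), which.max(pr$value))
  # the dominant-mode extremes bracket the opening: the max-|projection|
  # frame has the most extreme apo-site distance
  op <- opening_distance_series(tr)
  wide_frame <- which.max(op$site_apo)
  expect_true(wide_frame %in% ext$frames)
  # ties: a constant series returns the first frame twice
  prc <- pr; prc$value <- rep(1, nrow(pr))
  extc <- extreme_frames(prc, tr, m)
  expect_equal(unname(extc$frames), c(1L, 1L))
})

test_that("mode interpolation spans the projection range and round-trips", {
  g <- opening_run()
  m <- fit_pca(subsample(g$trajectory, 30), all_ca_selection(toy_dimer()))
  ip <- interpolate_mode(m, 1, p_lo = -3, p_hi = 3, n_inner = 8)
  expect_equal(n_frames(ip), 10L)
  ps <- attr(ip, "projections")
  expect_equal(diff(ps), rep(6 / 9, 9))
  # n_inner = 0: just the endpoints
  expect_equal(n_frames(interpolate_mode(m, 1, -1, 1, n_inner = 0)), 2L)
  # re-projection returns the construction values
  back <- project_trajectory(ip, m, 1, align = FALSE)
  expect_equal(back$value, ps, tolerance = 1e-9)
  expect_error(interpolate_mode(m, 1, 2, -2), "p_lo")
})
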