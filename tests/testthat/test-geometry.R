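test_that("Kabsch fit recovers exact rigid transforms", {
  set.seed(42)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  # identity
  sp <- kabsch_fit(pts, pts)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(sp$rmsd, 1e-12)
  # 30 degrees about z plus a translation
  R30 <- rotation_about_axis(30, c(0, 0, 1))
  tgt <- pts %*% t(R30) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  sp2 <- kabsch_fit(pts, tgt)
  ang <- acos((sum(diag(sp2$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)
  expect_lt(sp2$rmsd, 1e-9)
  # guards
  expect_error(kabsch_fit(pts[1:2, ], tgt[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_fit(line, line), "collinear")
})

test_that("Kabsch rmsd under iid noise sits in the expected band", {
  # target = mobile + N(0, sigma^2) per coordinate: rmsd concentrates
  # around sigma * sqrt(3) (minus the 6 fitted dof)
  sigma <- 0.1
  rmsds <- vapply(1:100, function(s) {
    set.seed(s)
    pts <- matrix(rnorm(30, sd = 5), 10, 3)
    kabsch_fit(pts, pts + matrix(rnorm(30, sd = sigma), 10, 3))$rmsd
  }, numeric(1))
  expect_true(all(rmsds >= 0.5 * sigma * sqrt(3)))
  expect_true(all(rmsds <= 1.5 * sigma * sqrt(3)))
})

test_that("Kabsch agrees with a brute-force rotation-grid oracle", {
  for (s in 1:3) {
    set.seed(s)
    mob <- matrix(rnorm(12, sd = 3), 4, 3)
    tgt <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(kabsch_fit(mob, tgt)$rmsd, oracle_rmsd(mob, tgt),
                 tolerance = 1e-3)
  }
})

test_that("Kabsch rmsd is invariant to common rigid transforms", {
  set.seed(7)
  mob <- matrix(rnorm(45, sd = 4), 15, 3)
  tgt <- mob + matrix(rnorm(45, sd = 0.3), 15, 3)
  base <- kabsch_fit(mob, tgt)$rmsd
  for (k in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 20)
    mob2 <- mob %*% t(R) + matrix(tr, 15, 3, byrow = TRUE)
    tgt2 <- tgt %*% t(R) + matrix(tr, 15, 3, byrow = TRUE)
    expect_equal(kabsch_fit(mob2, tgt2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("RMSD series separates rigid motion from internal change", {
  d <- toy_dimer()
  sel <- all_ca_selection(d)
  nf <- 5L
  # frames identical to the reference: zero series
  same <- trajectory3d(d, array(rep(d$xyz, each = nf), c(nf, nrow(d$xyz), 3)))
  expect_true(all(rmsd_series(same, sel)$rmsd < 1e-12))
  # frames rigidly rotated: still zero (superposition removes the motion)
  coords <- array(NA_real_, c(nf, nrow(d$xyz), 3))
  set.seed(1)
  for (f in 1:nf) coords[f, , ] <- d$xyz %*% t(random_rotation()) + 5 * f
  rigid <- trajectory3d(d, coords)
  expect_true(all(rmsd_series(rigid, sel)$rmsd < 1e-9))
})

test_that("opening trajectory: dimer RMSD grows while subdomains stay put", {
  g <- opening_run()
  tr <- g$trajectory
  d <- toy_dimer()
  scheme <- residue_scheme()
  dimer <- rmsd_series(tr, scheme_selection(d, scheme, "all"))$rmsd
  # monotone growth with the planted angle (check on the smoothed series)
  sm <- moving_average(dimer, 20)
  expect_gt(cor(sm, seq_along(sm)), 0.99)
  expect_gt(max(dimer), 1)
  # each subdomain is internally rigid: RMSD stays at the noise level
  for (ch in c("A", "B")) {
    for (what in c("core", "helical_rmsd")) {
      sub <- rmsd_series(tr, scheme_selection(d, scheme, what, chain = ch))$rmsd
      expect_lt(max(sub), 3 * g$truth$noise_sigma)
    }
  }
})

test_that("moving average uses a trailing window", {
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(7, 30), 20), rep(7, 11))
  expect_equal(moving_average(1:5, 1), as.numeric(1:5))
  expect_error(moving_average(1:5, 6), "exceeds")
})

test_that("screw decomposition reports angle, axis, pivot and pitch", {
  set.seed(3)
  dom <- matrix(rnorm(60, sd = 6), 20, 3)
  # identity: angle 0, axis undefined, centre unmoved
  s0 <- screw_decomposition(diag(3), c(0, 0, 0), dom)
  expect_equal(s0$angle_deg, 0)
  expect_false(s0$axis_defined)
  expect_equal(s0$centre_displacement, 0)
  # 90 degrees about z through (1, 0, 0), no pitch
  sm <- screw_matrix(90, c(0, 0, 1), c(1, 0, 0))
  s1 <- screw_decomposition(sm$rotation, sm$translation, dom)
  expect_equal(s1$angle_deg, 90, tolerance = 1e-9)
  expect_equal(abs(s1$axis), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(s1$pivot[1:2], c(1, 0), tolerance = 1e-6)
  expect_equal(s1$pitch, 0, tolerance = 1e-9)
  # near-180-degree rotations keep a stable axis
  sm179 <- screw_matrix(179.9999, c(1, 1, 0) / sqrt(2), c(0, 0, 0))
  s179 <- screw_decomposition(sm179$rotation, sm179$translation, dom)
  expect_equal(abs(s179$axis), c(1, 1, 0) / sqrt(2), tolerance = 1e-3)
})

test_that("a reported screw reconstructs the rigid transform", {
  set.seed(25)
  dom <- matrix(rnorm(45, sd = 8), 15, 3)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  sm <- screw_matrix(25, axis, rnorm(3, sd = 10), pitch = 2)
  s <- screw_decomposition(sm$rotation, sm$translation, dom)
  expect_equal(s$angle_deg, 25, tolerance = 1e-9)
  expect_equal(s$pitch, 2, tolerance = 1e-9)
  rebuilt <- screw_matrix(s$angle_deg, s$axis, s$pivot, s$pitch)
  expect_lt(max(abs(apply_superposition(dom, rebuilt) -
                      apply_superposition(dom, sm))), 1e-6)
  # screw equation residual: t = (I - R) p + pitch * axis
  resid <- sm$translation -
    (as.vector((diag(3) - sm$rotation) %*% s$pivot) + s$pitch * s$axis)
  expect_lt(sqrt(sum(resid^2)), 1e-6)
})

test_that("screw compose/decompose round-trips parameters", {
  set.seed(99)
  for (k in 1:10) {
    theta <- runif(1, 2, 178)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    pivot <- rnorm(3, sd = 10)
    pitch <- rnorm(1)
    dom <- matrix(rnorm(30, sd = 5), 10, 3)
    sm <- screw_matrix(theta, axis, pivot, pitch)
    s <- screw_decomposition(sm$rotation, sm$translation, dom)
    expect_equal(s$angle_deg, theta, tolerance = 1e-8)
    # axis up to sign; pivot compared via its perpendicular offset from
    # the planted axis line
    expect_equal(abs(sum(s$axis * axis)), 1, tolerance = 1e-8)
    off <- s$pivot - pivot
    off_perp <- off - sum(off * axis) * axis
    expect_lt(sqrt(sum(off_perp^2)), 1e-6)
    expect_equal(s$pitch, pitch * sum(s$axis * axis), tolerance = 1e-8)
  }
})
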