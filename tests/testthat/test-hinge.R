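test_that("identical conformers form a single all-residue rigid domain", {
  x <- two_block_structure()
  sel <- all_ca_selection(x)
  part <- partition_rigid_domains(x, x, sel)
  expect_length(part$domains, 1L)
  expect_equal(nrow(part$domains[[1]]), 120L)
  expect_equal(nrow(part$unassigned), 0L)
  rep <- hinge_report(x, x, part)
  expect_equal(rep$domains[[1]]$screw$angle_deg, 0)
})

test_that("a noise-free two-body 20-degree hinge is recovered exactly", {
  pair <- two_block_pair(angle = 20, noise_sigma = 0)
  sel <- all_ca_selection(pair$x)
  part <- partition_rigid_domains(pair$x, pair$y, sel)
  expect_length(part$domains, 2L)
  expect_lte(nrow(part$unassigned), 2L)
  got <- lapply(part$domains, function(d) sort(d$resno))
  expect_true(any(vapply(got, identical, TRUE, 1:60)))
  expect_true(any(vapply(got, identical, TRUE, 61:120)))

  rep <- hinge_report(pair$x, pair$y, part)
  # moving block first (sorted by angle); reference block reports ~0
  s <- rep$domains[[1]]$screw
  expect_equal(sort(rep$domains[[1]]$residues$resno), 61:120)
  expect_equal(s$angle_deg, 20, tolerance = 0.1)
  # axis within 1 degree of the planted z axis (sign-free)
  expect_gt(abs(s$axis[3]), cos(1 * pi / 180))
  # pivot within 0.5 A of the planted axis line (x = y = 0)
  expect_lt(sqrt(sum(s$pivot[1:2]^2)), 0.5)
  expect_lt(rep$domains[[2]]$screw$angle_deg, 0.1)
  # the reported screw reconstructs the moving block's coordinates in the
  # reference-aligned frame
  ri <- rep$domains[[which.min(vapply(rep$domains, function(d) d$screw$angle_deg,
                                      numeric(1)))]]$residues$index
  mi <- rep$domains[[1]]$residues$index
  X <- pair$x$xyz[sel$indices, ]; Y <- pair$y$xyz[sel$indices, ]
  YA <- apply_superposition(Y, kabsch_fit(Y[ri, ], X[ri, ]))
  rebuilt <- apply_superposition(X[mi, ],
                                 screw_matrix(s$angle_deg, s$axis, s$pivot, s$pitch))
  expect_lt(max(abs(rebuilt - YA[mi, ])), 1e-6)
})

test_that("partitioning stays accurate under coordinate noise", {
  correct <- total <- 0
  for (seed in 1:20) {
    pair <- two_block_pair(angle = 20, noise_sigma = 0.3, seed = seed)
    part <- partition_rigid_domains(pair$x, pair$y, all_ca_selection(pair$x))
    for (d in part$domains) {
      block <- if (mean(d$resno <= 60) > 0.5) 1:60 else 61:120
      correct <- correct + sum(d$resno %in% block)
    }
    total <- total + 120
  }
  expect_gte(correct / total, 0.95)
})

test_that("multi-body constructions recover every planted screw", {
  # three rigid bodies: one fixed, two rotated by known angles about
  # distinct axes; recovered domain count and angles must match
  a <- build_toy_chain(40, 9, c(-20, 0, 0))
  b <- build_toy_chain(40, 9, c(20, 0, 0)); b$atoms$resno <- 41:80
  c3 <- build_toy_chain(40, 9, c(0, 30, 0)); c3$atoms$resno <- 81:120
  x <- structure3d(rbind(a$atoms, b$atoms, c3$atoms), rbind(a$xyz, b$xyz, c3$xyz))
  pair <- generate_rigid_pair(x, list(
    list(chain = "A", residues = 41:80, angle_deg = 18, axis = c(0, 0, 1),
         pivot = c(5, 0, 0)),
    list(chain = "A", residues = 81:120, angle_deg = 6, axis = c(0, 0, 1),
         pivot = c(0, 6, 0))))
  sel <- all_ca_selection(x)
  part <- partition_rigid_domains(pair$x, pair$y, sel)
  expect_length(part$domains, 3L)
  rep <- hinge_report(pair$x, pair$y, part)
  angles <- vapply(rep$domains, function(d) d$screw$angle_deg, numeric(1))
  # ranked by angle: 18, 6, ~0
  expect_equal(angles[1], 18, tolerance = 0.1)
  expect_equal(angles[2], 6, tolerance = 0.1)
  expect_lt(angles[3], 0.1)
  expect_equal(sort(rep$domains[[1]]$residues$resno), 41:80)
  expect_equal(sort(rep$domains[[2]]$residues$resno), 81:120)
})

test_that("partition is invariant to global rigid transforms", {
  pair <- two_block_pair(angle = 15, noise_sigma = 0.1, seed = 4)
  sel <- all_ca_selection(pair$x)
  base <- partition_rigid_domains(pair$x, pair$y, sel)
  set.seed(10)
  y2 <- pair$y
  y2$xyz <- y2$xyz %*% t(random_rotation()) +
    matrix(c(40, -7, 13), nrow(y2$xyz), 3, byrow = TRUE)
  moved <- partition_rigid_domains(pair$x, y2, sel)
  expect_equal(lapply(moved$domains, `[[`, "resno"),
               lapply(base$domains, `[[`, "resno"))
  expect_equal(moved$mean_displacement, base$mean_displacement, tolerance = 1e-9)
})

test_that("mode-extreme hinge analysis finds the planted rotating core", {
  g <- opening_run()
  tr <- subsample(g$trajectory, 30)
  m <- fit_pca(tr, all_ca_selection(toy_dimer()))
  rep <- analyse_mode_extremes(tr, m, 1)
  top <- rep$domains[[1]]
  # the largest-angle domain is the planted moving block: chain B core
  expect_equal(unique(top$residues$chain), "B")
  truth_res <- g$truth$moving_residues$resno
  overlap <- mean(top$residues$resno %in% truth_res)
  expect_gt(overlap, 0.9)
  # recovered rotation close to the planted schedule span across the
  # extreme frames (linear schedule: angle proportional to time)
  t_max <- max(g$trajectory$times)
  planted <- abs(diff(unname(20 * rep$times / t_max)))
  expect_lt(abs(top$screw$angle_deg - planted), 1)
  # axis parallel to the planted z hinge
  expect_gt(abs(top$screw$axis[3]), cos(5 * pi / 180))
})

test_that("a zero-variance trajectory degrades to one rigid domain", {
  d <- toy_dimer()
  nf <- 3
  tr <- trajectory3d(d, array(rep(d$xyz, each = nf), c(nf, nrow(d$xyz), 3)))
  m <- fit_pca(tr, all_ca_selection(d))
  rep <- analyse_mode_extremes(tr, m, 1)
  expect_length(rep$domains, 1L)
  expect_lt(rep$domains[[1]]$screw$angle_deg, 1e-2)
})
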