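test_that("kink translations sample the stated hemisphere Gaussian", {
  set.seed(1)
  v <- sample_kink_translation(move_set(), 20000L)
  r <- sqrt(rowSums(v^2))
  expect_true(all(v[, 3L] >= 0))
  expect_lt(abs(mean(r) - 7.2), 0.02)
  expect_lt(abs(sd(r) - 0.6), 0.02)
  # radii are draw-for-draw Gaussian (Kolmogorov-Smirnov at alpha 0.01)
  ks <- suppressWarnings(stats::ks.test(r, "pnorm", 7.2, 0.6))
  expect_gt(ks$p.value, 0.01)
  # direction uniform over the hemisphere: z/r is uniform on [0, 1]
  ksu <- stats::ks.test(v[, 3L] / r, "punif")
  expect_gt(ksu$p.value, 0.01)
})

test_that("kink rotations stay inside the permitted quadrants", {
  h <- ideal_helix(30)
  sp <- kink_spec(c(1, 12), c(13, 16), c(17, 30), 17)
  fr <- tmhrebuild:::kink_frame(h, sp)
  m_dir <- tmhrebuild:::outward_m_dir(h, sp)
  set.seed(2)
  B <- cbind(fr$x, fr$y, fr$z)
  for (k in 1:1000) {
    R <- sample_kink_rotation(fr, m_dir)
    new_dir <- as.vector(R %*% m_dir)
    loc <- as.vector(crossprod(B, new_dir))
    expect_gte(loc[1L], -1e-9)   # +x component
    expect_gte(loc[3L], -1e-9)   # +z component
  }
  expect_equal(sample_kink_rotation(fr, m_dir, amplitude = 0), diag(3L))

  # geometric consequence: the moved m N-terminus projects onto the
  # semicircle away from the reference CB
  set.seed(3)
  for (k in 1:50) {
    R <- sample_kink_rotation(fr, m_dir)
    hk <- apply_rigid_transform(h, 1, 12, R = R, pivot = h$CA[12, ])
    p <- hk$CA[1, ] - h$CB[17, ]
    p_perp <- p - sum(p * fr$z) * fr$z
    expect_gte(sum(p_perp * fr$x), -1e-6)
  }
  bad <- fr; bad$x <- fr$x + 0.2
  expect_error(sample_kink_rotation(bad, m_dir), "orthonormal")
})

test_that("proposals are rigid on the moved fragments", {
  h <- ideal_helix(30)
  h$segment[1:30] <- "TM1"
  sp <- kink_spec(c(1, 12), c(13, 16), c(17, 30), 17)
  set.seed(4)
  d_m0 <- as.matrix(dist(h$CA[1:12, ]))
  d_f0 <- as.matrix(dist(h$CA[17:30, ]))
  for (k in 1:200) {
    prop <- propose_move(h, sp, move_set())
    s <- prop$structure
    expect_equal(as.matrix(dist(s$CA[1:12, ])), d_m0, tolerance = 1e-9)
    expect_equal(as.matrix(dist(s$CA[17:30, ])), d_f0, tolerance = 1e-9)
  }
})

test_that("axial spins of a full turn are identities", {
  h <- ideal_helix(20)
  ax <- fit_helix_axis(h$CA)
  spun <- apply_rigid_transform(
    h, 1, 20, R = tmhrebuild:::rot_axis_angle(ax$direction, 360),
    pivot = ax$origin)
  expect_equal(spun$CA, h$CA, tolerance = 1e-6)
})

test_that("coarse energy terms behave at their limits", {
  h1 <- ideal_helix(12, start = c(0, 0, 0))
  h2 <- ideal_helix(12, start = c(10, 0, 0), resno = 16:27)
  pair <- tmh_structure(
    resno = c(h1$resno, h2$resno), aa = c(h1$aa, h2$aa),
    N = rbind(h1$N, h2$N), CA = rbind(h1$CA, h2$CA),
    C = rbind(h1$C, h2$C), O = rbind(h1$O, h2$O),
    CB = rbind(h1$CB, h2$CB), validate = FALSE)
  e_apart <- coarse_energy(pair)
  expect_equal(e_apart$clash, 0)

  h2c <- ideal_helix(12, start = c(0.5, 0, 0), resno = 16:27)
  clashpair <- pair
  clashpair$CA[13:24, ] <- h2c$CA; clashpair$CB[13:24, ] <- h2c$CB
  expect_gt(coarse_energy(clashpair)$clash, 0)

  # start restraint vanishes at the start pose
  e0 <- coarse_energy(pair, start = pair, anchors = c(1L, 20L))
  expect_equal(e0$restraint, 0)

  # membrane term fires only outside the slab
  mem <- apply_rigid_transform(pair, 1, 27, t = c(0, 0, -8))
  mem$segment[] <- "TM1"
  expect_equal(coarse_energy(mem)$membrane, 0)
  shifted <- apply_rigid_transform(mem, 1, 27, t = c(0, 0, 30))
  expect_gt(coarse_energy(shifted)$membrane, 0)
})

test_that("Metropolis runs are deterministic and track the best state", {
  setup <- recovery_setup()
  params <- move_set(steps = 60L)
  set.seed(7)
  r1 <- mc_run(setup$template$structure, setup$kink,
               constraints = setup$constraints, params = params)
  set.seed(7)
  r2 <- mc_run(setup$template$structure, setup$kink,
               constraints = setup$constraints, params = params)
  expect_identical(r1$best_structure$CA, r2$best_structure$CA)
  expect_identical(r1$energy, r2$energy)
  expect_lte(r1$best_energy, r1$energy)

  # best can never exceed the start energy
  e_start <- coarse_energy(
    setup$template$structure, constraints = setup$constraints,
    start = setup$template$structure,
    anchors = c(setup$kink$m_range[2L], setup$kink$f_range[1L]),
    skip_rows = setup$kink$bend_range[1L]:setup$kink$bend_range[2L])
  w <- list(clash = 1, cst = 3, restraint = 1, membrane = 0.1)
  e_start_total <- w$clash * e_start$clash + w$cst * e_start$cst +
    w$restraint * e_start$restraint + w$membrane * e_start$membrane
  expect_lte(r1$best_energy, e_start_total + 1e-9)

  # infinite-temperature limit accepts (essentially) everything
  set.seed(8)
  hot <- mc_run(setup$template$structure, setup$kink,
                constraints = setup$constraints,
                params = move_set(steps = 50L, kT_schedule = 1e9))
  expect_gte(hot$accepted / hot$proposed, 0.99)

  # trajectory log records every step
  set.seed(9)
  tr <- mc_run(setup$template$structure, setup$kink,
               constraints = setup$constraints,
               params = move_set(steps = 10L), log_trajectory = TRUE)
  expect_equal(nrow(tr$trajectory), 10L)
  expect_true(all(tr$trajectory$move_kind %in%
                    c("kink", "f_spin", "m_spin", "whole_unit")))
})

test_that("move-set parameters are validated", {
  expect_error(move_set(restraint_radius = 0.5), "restraint_radius")
  expect_error(move_set(steps = 0), "steps")
  expect_silent(move_set(steps = 5000L, restraint_radius = 1.5))
})
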