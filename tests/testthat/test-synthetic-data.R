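test_that("uniform sphere samples have uniform cos(polar angle)", {
  u <- sample_uniform_sphere(4000, radius = 1, seed = 21)
  expect_equal(sqrt(rowSums(u^2)), rep(1, 4000), tolerance = 1e-9)
  ks <- suppressWarnings(stats::ks.test(u[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # azimuthal angle uniform as well
  ks2 <- suppressWarnings(stats::ks.test(atan2(u[, 2], u[, 1]),
                                         "punif", -pi, pi))
  expect_gt(ks2$p.value, 0.01)
})

test_that("generators are pure functions of their seed", {
  expect_identical(sample_uniform_sphere(50, seed = 5),
                   sample_uniform_sphere(50, seed = 5))
  expect_false(identical(sample_uniform_sphere(50, seed = 5),
                         sample_uniform_sphere(50, seed = 6)))
  r1 <- shell_mc_simulate(mc_params(n_steps = 100, n_equil = 50, seed = 9))
  r2 <- shell_mc_simulate(mc_params(n_steps = 100, n_equil = 50, seed = 9))
  expect_identical(r1$final, r2$final)
  # the caller's RNG stream is not disturbed
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(sample_uniform_sphere(10, seed = 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("Platonic shells reproduce the exact angle sets", {
  t4 <- pair_angles_deg(platonic_shell(4))
  expect_equal(t4, rep(109.4712206, 6), tolerance = 1e-6)
  t6 <- sort(pair_angles_deg(platonic_shell(6)))
  expect_equal(t6, c(rep(90, 12), rep(180, 3)), tolerance = 1e-6)
  t12 <- sort(unique(round(pair_angles_deg(platonic_shell(12)), 4)))
  expect_equal(t12, round(c(63.43495, 116.56505, 180), 4), tolerance = 1e-4)
  expect_error(platonic_shell(5), "4, 6, 8, 12|supported")
  # radius scaling
  expect_equal(sqrt(rowSums(platonic_shell(6, radius = 2.5)^2)),
               rep(2.5, 6), tolerance = 1e-9)
})

test_that("MC energy bookkeeping matches a from-scratch recomputation", {
  p <- mc_params(n_shell = 8, ion_charge = 1.5, n_steps = 400,
                 n_equil = 200, seed = 31)
  run <- shell_mc_simulate(p)
  e_scratch <- mc_total_energy(run$final$pos, run$final$axis, p)
  expect_lt(abs(run$final$energy - e_scratch), 1e-6)
  expect_lt(abs(run$final$energy - e_scratch) /
              max(1, abs(e_scratch)), 1e-9)
})

test_that("MC acceptance is tuned into a sane band", {
  run <- shell_mc_simulate(mc_params(n_steps = 800, n_equil = 600, seed = 5))
  expect_gt(run$acceptance_rate, 0.15)
  expect_lt(run$acceptance_rate, 0.75)
})

test_that("uncharged ion gives no net dipole alignment, charge orders it", {
  base <- function(q, seed) mc_params(n_shell = 6, ion_charge = q,
                                      n_steps = 1500, n_equil = 500,
                                      seed = seed)
  c0 <- mean(sapply(1:3, function(s)
    mc_cos_theta(shell_mc_simulate(base(0, s)))$mean))
  c1 <- mean(sapply(1:3, function(s)
    mc_cos_theta(shell_mc_simulate(base(1, s)))$mean))
  c2 <- mean(sapply(1:3, function(s)
    mc_cos_theta(shell_mc_simulate(base(2.5, s)))$mean))
  expect_lt(abs(c0), 0.08)       # symmetry: no preferred orientation
  expect_gt(c1, c0 + 0.1)        # cation aligns dipoles outward
  expect_gt(c2, c1)              # stronger charge, stronger alignment
  expect_gt(c2, 0.8)
})

test_that("charge jump relaxes the mean orientation upward over sweeps", {
  p <- mc_params(n_shell = 6, n_steps = 300, n_equil = 300, seed = 17)
  cj <- charge_jump_protocol(p, q_before = 0.17, q_after = 1.7,
                             n_replicas = 6)
  expect_equal(dim(cj$cos_theta), c(6L, 300L))
  expect_equal(cj$n_replicas, 6L)
  early <- mean(cj$cos_theta_mean[1:5])
  late <- mean(cj$cos_theta_mean[251:300])
  expect_gt(late, early + 0.05)
  # null jump: no systematic drift
  cj0 <- charge_jump_protocol(p, q_before = 1, q_after = 1, n_replicas = 6)
  d0 <- mean(cj0$cos_theta_mean[251:300]) - mean(cj0$cos_theta_mean[1:5])
  expect_lt(abs(d0), 0.1)
  expect_error(charge_jump_protocol(p, 1, 2, n_replicas = 0), "n_replicas")
})

test_that("Brownian walk increments have the prescribed variance", {
  D <- 0.3; dt <- 0.2
  tr <- brownian_walk(D, dt, n_steps = 200, n_particles = 30, seed = 8)
  expect_equal(length(tr), 201L)
  expect_equal(tr$dt, dt)
  inc <- c()
  for (k in 2:201)
    inc <- c(inc, tr$frames[[k]]$waters$pos - tr$frames[[k - 1]]$waters$pos)
  expect_equal(var(inc), 2 * D * dt, tolerance = 0.05)
  expect_equal(mean(inc), 0, tolerance = 0.01)
  # tracer ion present and stationary
  expect_equal(tr$frames[[1]]$ions$label, "TRC")
  expect_identical(tr$frames[[1]]$ions, tr$frames[[201]]$ions)
})

test_that("stretched occupancy reproduces the analytic decay exactly", {
  tg <- seq(0, 50, by = 0.5)
  s <- stretched_occupancy(10, 0.8, tg)
  expect_equal(s$P, exp(-(tg / 10)^0.8), tolerance = 1e-12)
  expect_equal(s$P[tg == 10], exp(-1), tolerance = 1e-12)
  sn <- stretched_occupancy(10, 0.8, tg, noise_sd = 0.02, seed = 3)
  expect_equal(sn$P[1], 1)                  # P(0) pinned
  expect_true(all(sn$P >= 0 & sn$P <= 1))   # clipped
  expect_error(stretched_occupancy(-1, 0.8, tg), "tau")
  expect_error(stretched_occupancy(10, 2.5, tg), "beta")
})

test_that("toy water box packs the requested count with O-O exclusion", {
  fr <- toy_water_box(20, box(14), seed = 2)
  expect_equal(n_waters(fr), 20L)
  ox <- water_oxygens(fr)
  md <- water_model()
  dmin <- Inf
  for (i in 1:19) for (j in (i + 1):20)
    dmin <- min(dmin, sqrt(sum(min_image_displacement(ox[i, ], ox[j, ],
                                                      fr$box)^2)))
  expect_gte(dmin, 2.2)
  # rigid geometry holds for every packed water
  d1 <- sqrt(rowSums((fr$waters$H1 - fr$waters$O)^2))
  expect_equal(d1, rep(md$r_oh, 20), tolerance = 1e-9)
})

test_that("motifs are inserted verbatim and packing failure is detected", {
  dim2 <- hbond_dimer(r_oo = 2.9, origin = c(3, 3, 3))
  fr <- toy_water_box(8, box(12), seed = 4, motifs = list(dim2))
  expect_equal(n_waters(fr), 8L)
  expect_equal(fr$waters$O[1:2, ], dim2$O, ignore_attr = TRUE)
  expect_equal(fr$waters$H1[1:2, ], dim2$H1, ignore_attr = TRUE)
  # an impossible density cannot be packed
  expect_error(toy_water_box(600, box(8), seed = 1, max_tries = 50),
               "packing failed")
})

test_that("hbond_dimer satisfies the geometric criterion by construction", {
  w <- hbond_dimer(r_oo = 2.9, angle_deg = 12)
  # donor O at origin, acceptor O on the x axis at r_oo
  expect_equal(as.numeric(w$O[1, ]), c(0, 0, 0))
  expect_equal(as.numeric(w$O[2, ]), c(2.9, 0, 0))
  md <- water_model()
  # H-O..O angle at the donor equals the requested perturbation
  oh <- w$H1[1, ] - w$O[1, ]
  oo <- w$O[2, ] - w$O[1, ]
  ang <- acos(sum(oh * oo) / sqrt(sum(oh^2) * sum(oo^2))) * 180 / pi
  expect_equal(ang, 12, tolerance = 1e-6)
  expect_equal(sqrt(sum(oh^2)), md$r_oh, tolerance = 1e-9)
})
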