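test_that("Lennard-Jones has its minimum -epsilon at 2^(1/6) sigma", {
  bx <- box(100)
  p <- pair_params(epsilon = 0.65, sigma = 3.0)
  a <- sites(c(0, 0, 0), charge = 0)
  at <- function(r) pair_potential(a, sites(c(r, 0, 0), charge = 0), p, bx)
  expect_equal(at(2^(1 / 6) * 3.0), -0.65, tolerance = 1e-12)
  expect_equal(at(3.0), 0, tolerance = 1e-12)
  expect_gt(at(2.5), 0)
  expect_lt(at(3.2), 0)
  # numeric minimum sits at the analytic location
  rs <- seq(3.2, 3.6, by = 1e-4)
  expect_equal(rs[which.min(sapply(rs, at))], 2^(1 / 6) * 3.0,
               tolerance = 1e-3)
})

test_that("unit charges 1 A apart give the Coulomb constant", {
  bx <- box(100)
  a <- sites(c(0, 0, 0), charge = 1)
  b <- sites(c(1, 0, 0), charge = 1)
  expect_equal(pair_potential(a, b, pair_params(0, 1), bx), 1389.35458,
               tolerance = 1e-5)
  b2 <- sites(c(2, 0, 0), charge = -1)
  expect_equal(pair_potential(a, b2, pair_params(0, 1), bx),
               -1389.35458 / 2, tolerance = 1e-5)
  expect_error(pair_potential(a, sites(c(0, 0, 0), charge = 1),
                              pair_params(0, 1), bx), "zero separation")
})

test_that("the ideal dimer is attractive and matches direct summation", {
  w <- hbond_dimer(r_oo = 3.0)
  g1 <- hydrashell:::water_site_group(w, 1)
  g2 <- hydrashell:::water_site_group(w, 2)
  prm <- water_pair_params()
  e <- pair_potential(g1, g2, prm, box(100))
  expect_lt(e, 0)
  expect_lt(e, -10)   # a proper hydrogen bond, not marginal attraction
  e_direct <- direct_pair_energy(g1, g2, prm$epsilon, prm$sigma)
  expect_equal(e, e_direct, tolerance = 1e-9)
})

test_that("pair energy is symmetric and translation invariant", {
  w <- hbond_dimer(r_oo = 2.9, origin = c(4, 4, 4))
  g1 <- hydrashell:::water_site_group(w, 1)
  g2 <- hydrashell:::water_site_group(w, 2)
  prm <- water_pair_params()
  bx <- box(60)
  expect_equal(pair_potential(g1, g2, prm, bx),
               pair_potential(g2, g1, prm, bx), tolerance = 1e-12)
  shift <- c(11.3, -6.2, 20.9)
  mv <- function(g) { g$x <- g$x + shift[1]; g$y <- g$y + shift[2]
                      g$z <- g$z + shift[3]; g }
  expect_equal(pair_potential(mv(g1), mv(g2), prm, bx),
               pair_potential(g1, g2, prm, bx), tolerance = 1e-9)
})

test_that("pair energy respects the minimum image across the boundary", {
  bx <- box(10)
  a <- sites(c(0.5, 5, 5), charge = 1)
  b <- sites(c(9.5, 5, 5), charge = 1)   # 1 A via the boundary
  expect_equal(pair_potential(a, b, pair_params(0, 1), bx), 1389.35458,
               tolerance = 1e-5)
})

test_that("radial dipoles 90 degrees apart repel with the closed form", {
  bx <- box(100)
  R <- 3
  p1 <- c(R, 0, 0); p2 <- c(0, R, 0)
  a1 <- c(1, 0, 0); a2 <- c(0, 1, 0)    # outward radial orientations
  e <- hydrashell:::dipole_pair_energy(p1, a1, p2, a2, 0.48, bx)
  # closed form: ke p^2 (a1.a2 - 3 (a1.u)(a2.u)) / r^3 with
  # u = (p2 - p1)/r, r = sqrt(2) R: a1.a2 = 0, a1.u = -1/sqrt(2),
  # a2.u = 1/sqrt(2)  ->  +3/2 ke p^2 / r^3
  r <- sqrt(2) * R
  e_ref <- 1389.35458 * 0.48^2 * (0 - 3 * (-1 / sqrt(2)) * (1 / sqrt(2))) / r^3
  expect_equal(e, e_ref, tolerance = 1e-9)
  expect_gt(e, 0)
  # head-to-tail collinear dipoles attract with -2 ke p^2 / r^3
  e_ht <- hydrashell:::dipole_pair_energy(c(0, 0, 0), c(1, 0, 0),
                                          c(2.5, 0, 0), c(1, 0, 0), 0.48, bx)
  expect_equal(e_ht, -2 * 1389.35458 * 0.48^2 / 2.5^3, tolerance = 1e-9)
})

test_that("shell pair energy averages over gated shell pairs", {
  L <- 40
  ctr <- matrix(L / 2, 6, 3)
  pts <- platonic_shell(6, radius = 2.3) + ctr   # neighbours at 3.25 A
  fr <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"),
              waters = point_dipoles(pts, platonic_shell(6)),
              box = box(L), wrap = FALSE)
  es <- shell_pair_energy(fr, shell = 3, gate = 3.5)
  # 12 orthogonal neighbour pairs pass the 3.5 A gate; 3 antipodal do not
  expect_equal(es$n_pairs, 12L)
  r <- sqrt(2) * 2.3
  e_ref <- 1389.35458 * 0.48^2 * 1.5 / r^3
  expect_equal(es$E_w_w, e_ref, tolerance = 1e-9)
  # single shell water: flagged no-pair result rather than an error
  fr1 <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"),
               waters = point_dipoles(pts[1, , drop = FALSE],
                                      matrix(c(1, 0, 0), 1, 3)),
               box = box(L), wrap = FALSE)
  es1 <- shell_pair_energy(fr1, shell = 3)
  expect_true(is.na(es1$E_w_w))
  expect_equal(es1$n_pairs, 0L)
})

test_that("ion-dipole energy matches the closed form to 1e-6", {
  L <- 40
  d <- 2.6
  q <- 1.3
  prm <- pair_params(0.65, 2.76)
  pos <- matrix(c(L / 2 + d, L / 2, L / 2), 1, 3)
  fr <- frame(0, ions = sites(rep(L / 2, 3), q, "ION"),
              waters = point_dipoles(pos, matrix(c(1, 0, 0), 1, 3)),
              box = box(L), wrap = FALSE)
  ev <- ion_water_energy(fr, shell = 3, params = prm)
  sr6 <- (2.76 / d)^6
  e_ref <- 4 * 0.65 * (sr6^2 - sr6) - 1389.35458 * q * 0.48 / d^2
  expect_lt(abs(ev$mean_signed - e_ref), 1e-6)
  expect_equal(ev$dE_ion_water, abs(e_ref), tolerance = 1e-9)
  # flipping the dipole flips the sign of the Coulomb part
  fr2 <- frame(0, ions = sites(rep(L / 2, 3), q, "ION"),
               waters = point_dipoles(pos, matrix(c(-1, 0, 0), 1, 3)),
               box = box(L), wrap = FALSE)
  ev2 <- ion_water_energy(fr2, shell = 3, params = prm)
  lj <- 4 * 0.65 * (sr6^2 - sr6)
  expect_equal(ev2$mean_signed - lj, -(ev$mean_signed - lj),
               tolerance = 1e-9)
})

test_that("pure charge-dipole interaction scales as 1 / d^2", {
  L <- 60
  prm <- pair_params(0, 2.76)   # no LJ: isolate the Coulomb part
  ds <- seq(2.2, 6, by = 0.2)
  es <- sapply(ds, function(d) {
    pos <- matrix(c(L / 2 + d, L / 2, L / 2), 1, 3)
    fr <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"),
                waters = point_dipoles(pos, matrix(c(1, 0, 0), 1, 3)),
                box = box(L), wrap = FALSE)
    ion_water_energy(fr, shell = 10, params = prm)$mean_signed
  })
  fit <- lm(log(-es) ~ log(ds))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 1e-9)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("bulk hydrogen-bond energy averages bonded pairs with a band", {
  fr <- toy_water_box(26, box(9.2), seed = 19)
  hb <- detect_hbonds(fr)
  expect_gt(nrow(hb), 2)
  res <- hbond_energy_bulk(fr)
  # brute force: unique unordered bonded pairs, direct site-site sums
  key <- unique(data.frame(a = pmin(hb$donor, hb$acceptor),
                           b = pmax(hb$donor, hb$acceptor)))
  prm <- water_pair_params()
  es <- sapply(seq_len(nrow(key)), function(k)
    pair_potential(hydrashell:::water_site_group(fr$waters, key$a[k]),
                   hydrashell:::water_site_group(fr$waters, key$b[k]),
                   prm, fr$box))
  expect_equal(res$n_bonds, nrow(key))
  expect_equal(res$E_hbond, mean(es), tolerance = 1e-9)
  expect_equal(res$band, sqrt(mean((es - mean(es))^2)), tolerance = 1e-9)
  # a box with no close contacts has no bonds and says so
  far <- toy_water_box(4, box(30), seed = 23, min_oo = 6)
  expect_error(hbond_energy_bulk(far), "no hydrogen bonds")
})
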