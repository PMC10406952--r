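test_that("ideal-gas configurations give g(r) near 1", {
  set.seed(41)
  L <- 20
  frames <- lapply(1:80, function(k) {
    pos <- matrix(runif(3 * 150, 0, L), 150, 3)
    frame((k - 1) * 1.0, ions = sites(c(L / 2, L / 2, L / 2), 0, "ION"),
          waters = point_dipoles(pos, matrix(1, 150, 3)),
          box = box(L), wrap = FALSE)
  })
  prof <- compute_rdf(trajectory(frames), bin_width = 0.25)
  sel <- prof$r > 3 & prof$r < 9
  expect_lt(abs(mean(prof$g[sel]) - 1), 0.05)
  expect_lt(max(abs(prof$g[sel] - 1)), 0.4)
})

test_that("binned counts match a brute-force histogram", {
  set.seed(42)
  L <- 12
  pos <- matrix(runif(3 * 60, 0, L), 60, 3)
  fr <- frame(0, ions = sites(c(6, 6, 6), 0, "ION"),
              waters = point_dipoles(pos, matrix(1, 60, 3)),
              box = box(L), wrap = FALSE)
  prof <- compute_rdf(fr, bin_width = 0.3)
  d <- sqrt(rowSums(
    hydrashell:::to_xyz(min_image_displacement(c(6, 6, 6), pos,
                                               fr$box))^2))
  manual <- as.integer(table(factor(
    floor(d[d < max(prof$r) + 0.15] / 0.3) + 1L,
    levels = seq_along(prof$r))))
  expect_equal(as.integer(prof$counts), manual)
})

test_that("a single occupied bin reproduces the analytic g value", {
  L <- 30
  r0 <- 3.1
  pts <- platonic_shell(6, radius = r0) + matrix(L / 2, 6, 3)
  fr <- frame(0, ions = sites(rep(L / 2, 3), 0, "ION"),
              waters = point_dipoles(pts, matrix(1, 6, 3)),
              box = box(L), wrap = FALSE)
  prof <- compute_rdf(fr, bin_width = 0.2)
  i <- which(prof$counts > 0)
  expect_length(i, 1L)
  rho <- 6 / L^3
  # normalization uses the exact spherical shell volume of the bin
  vol <- 4 * pi / 3 * ((prof$r[i] + 0.1)^3 - (prof$r[i] - 0.1)^3)
  expect_equal(prof$g[i], 6 / (vol * rho), tolerance = 1e-9)
  expect_equal(prof$rho, rho, tolerance = 1e-12)
})

test_that("locate_shell finds d, r1 and n on a constructed profile", {
  r <- seq(0.05, 8, by = 0.1)
  g <- 1 + 2.5 * exp(-(r - 2.8)^2 / 0.08) - 0.9 * exp(-(r - 3.6)^2 / 0.1)
  g[r < 2] <- 0
  prof <- make_profile(r, g)
  sh <- locate_shell(prof)
  expect_equal(sh$d, 2.8, tolerance = 0.03)
  expect_equal(sh$r1, 3.6, tolerance = 0.05)
  expect_s3_class(sh, "shell_assignment")
})

test_that("locate_shell errors on flat and monotone profiles", {
  r <- seq(0.05, 8, by = 0.1)
  expect_error(locate_shell(make_profile(r, rep(1, length(r)))),
               "peak|maximum|flat")
  expect_error(locate_shell(make_profile(r, 0.2 * r)),
               "peak|maximum|minimum")
})

test_that("locate_shell takes the first of two peaks", {
  r <- seq(0.05, 10, by = 0.1)
  g <- 1 + 2 * exp(-(r - 2.6)^2 / 0.05) + 3 * exp(-(r - 5)^2 / 0.05) -
    0.8 * exp(-(r - 3.4)^2 / 0.08)
  g[r < 1.8] <- 0
  sh <- locate_shell(make_profile(r, g))
  expect_equal(sh$d, 2.6, tolerance = 0.03)
  expect_lt(sh$r1, 4.2)
})

test_that("coordination number is the frame-averaged direct count", {
  L <- 30
  # 5 inside r1, 3 outside, every frame
  inner <- platonic_shell(4, radius = 2.9) + matrix(L / 2, 4, 3)
  inner <- rbind(inner, c(L / 2 + 3.0, L / 2, L / 2))
  outer <- platonic_shell(6, radius = 5.5)[1:3, ] + matrix(L / 2, 3, 3)
  pts <- rbind(inner, outer)
  frames <- lapply(1:4, function(k)
    frame(k - 1, ions = sites(rep(L / 2, 3), 0, "ION"),
          waters = point_dipoles(pts, matrix(1, 8, 3)),
          box = box(L), wrap = FALSE))
  tr <- trajectory(frames)
  prof <- compute_rdf(tr, bin_width = 0.2)
  sh <- locate_shell(prof, traj = tr)
  expect_equal(sh$n, 5, tolerance = 1e-9)
  # counting integral agrees with the direct count within 2 percent
  i1 <- max(which(prof$r <= sh$r1))
  expect_lt(abs(prof$running_n_integral[i1] - sh$n) / sh$n, 0.02)
})

test_that("translational order t vanishes for g = 1 and halves correctly", {
  r <- seq(0.01, 12, by = 0.01)
  prof1 <- make_profile(r, rep(1, length(r)), rho = 0.03)
  expect_equal(translational_order(prof1), 0, tolerance = 1e-6)
  # |g - 1| = 0.5 on the whole range: t = 0.5 (constant integrand)
  prof2 <- make_profile(r, rep(1.5, length(r)), rho = 0.03)
  t2 <- translational_order(prof2)
  expect_equal(t2, 0.5, tolerance = 0.01)
})

test_that("translational order matches direct quadrature on a known g", {
  rho <- 0.0334
  s <- rho^(1 / 3)
  xi_c <- 2.843
  r <- seq(0.005, xi_c / s + 1, by = 0.005)
  g <- 1 + exp(-r) * sin(2 * r)
  prof <- make_profile(r, g, rho = rho)
  xi <- seq(1e-6, xi_c, length.out = 200001)
  gx <- stats::approx(r * s, g, xout = xi, rule = 2)$y
  t_ref <- sum((abs(gx - 1)[-1] + abs(gx - 1)[-length(gx)]) / 2 *
                 diff(xi)) / xi_c
  expect_equal(translational_order(prof), t_ref, tolerance = 1e-3)
})

test_that("rdf is invariant to rigid translation of the whole system", {
  set.seed(43)
  L <- 16
  pos <- matrix(runif(3 * 40, 0, L), 40, 3)
  shift <- c(3.7, -2.2, 8.9)
  mk <- function(p, ctr) frame(0, ions = sites(ctr, 0, "ION"),
                               waters = point_dipoles(p, matrix(1, 40, 3)),
                               box = box(L), wrap = TRUE)
  p1 <- compute_rdf(mk(pos, c(8, 8, 8)), bin_width = 0.25)
  p2 <- compute_rdf(mk(pos + matrix(shift, 40, 3, byrow = TRUE),
                       c(8, 8, 8) + shift), bin_width = 0.25)
  expect_equal(p1$g, p2$g, tolerance = 1e-9)
})

test_that("dipolar profile reports cos(theta) against the outward radial", {
  L <- 30
  pts <- platonic_shell(6, radius = 3) + matrix(L / 2, 6, 3)
  out_ax <- platonic_shell(6)          # outward radial axes
  fr_out <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"),
                  waters = point_dipoles(pts, out_ax),
                  box = box(L), wrap = FALSE)
  fr_in <- frame(0, ions = sites(rep(L / 2, 3), 1, "ION"),
                 waters = point_dipoles(pts, -out_ax),
                 box = box(L), wrap = FALSE)
  d_out <- dipolar_profile(fr_out, bin_width = 0.5)
  d_in <- dipolar_profile(fr_in, bin_width = 0.5)
  i <- which(d_out$counts > 0)
  expect_equal(d_out$cos_theta[i], 1, tolerance = 1e-9)
  expect_equal(d_in$cos_theta[i], -1, tolerance = 1e-9)
})
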