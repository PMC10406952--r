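# Shared fixtures and brute-force oracles for the test suite.

ke <- 1389.35458        # Coulomb constant, kJ A / (mol e^2)

# brute-force minimum-image displacement: minimize over all 27 images
brute_image_disp <- function(a, b, L, reach = 1) {
  best <- NULL
  best_n <- Inf
  img <- -reach:reach
  for (i in img) for (j in img) for (k in img) {
    d <- b - a + L * c(i, j, k)
    nn <- sum(d^2)
    if (nn < best_n) { best_n <- nn; best <- d }
  }
  best
}

# build a point-dipole trajectory with one ion fixed at the box centre and
# explicit per-frame particle positions (list of n x 3 matrices)
make_dipole_traj <- function(pos_list, L = 50, dt = 1, axes = NULL,
                             ion_charge = 0) {
  ctr <- c(L, L, L) / 2
  frames <- lapply(seq_along(pos_list), function(k) {
    pos <- pos_list[[k]]
    ax <- if (is.null(axes)) {
      u <- pos - matrix(ctr, nrow(pos), 3, byrow = TRUE)
      u / sqrt(rowSums(u^2))
    } else axes[[k]]
    frame(time = (k - 1) * dt,
          ions = {
            s <- sites(ctr, charge = ion_charge, label = "ION")
            s
          },
          waters = point_dipoles(pos, ax),
          box = box(L), wrap = FALSE)
  })
  trajectory(frames, dt = dt)
}

# forge a radial_profile object from an analytic g(r)
make_profile <- function(r, g, rho = 0.0334, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- r[2] - r[1]
  shell_vol <- 4 * pi * r^2 * bin_width
  counts <- round(g * shell_vol * rho * 100)
  run_n <- cumsum(g * shell_vol * rho)
  structure(list(r = r, g = g, running_n = run_n,
                 running_n_integral = run_n, rho = rho,
                 bin_width = bin_width, counts = counts, n_obs = 100L),
            class = "radial_profile")
}

# forge an angular_profile from an analytic g(phi) on [0, pi]
make_angular_profile <- function(phi, g, n = 6, R = 3) {
  structure(list(phi_deg = phi * 180 / pi, phi = phi, g = g,
                 P = g * sin(phi) / 2, n = n, R = R, kernel = 0,
                 n_pairs = 1000L),
            class = "angular_profile")
}

# all pairwise angles (deg) subtended at the origin by rows of u
pair_angles_deg <- function(u) {
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(u)
  out <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cc <- max(-1, min(1, sum(u[i, ] * u[j, ])))
    out <- c(out, acos(cc) * 180 / pi)
  }
  out
}

# direct site-site LJ + Coulomb sum between two groups, no minimum image
direct_pair_energy <- function(A, B, eps, sig) {
  e <- 0
  lj_a <- if (!is.null(A$lj)) A$lj else rep(TRUE, nrow(A))
  lj_b <- if (!is.null(B$lj)) B$lj else rep(TRUE, nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
              (A$z[i] - B$z[j])^2)
    if (lj_a[i] && lj_b[j] && eps > 0) {
      sr6 <- (sig / r)^6
      e <- e + 4 * eps * (sr6^2 - sr6)
    }
    e <- e + ke * A$charge[i] * B$charge[j] / r
  }
  e
}
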