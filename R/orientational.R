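# Angular order of the hydration shell: geodesic pair distribution g(phi)
# on the shell sphere, bond-orientational entropy, characteristic angle,
# and a Thomson-problem reference solver.

# collect all pair angles (radians) from a list of point matrices, taken
# about `center`
collect_pair_angles <- function(configs, center = c(0, 0, 0)) {
  angles <- c(); radii <- c(); counts <- integer(0)
  for (pts in configs) {
    pts <- to_xyz(pts)
    dv <- pts - matrix(center, nrow(pts), 3, byrow = TRUE)
    r <- sqrt(rowSums(dv^2))
    u <- dv / r
    n <- nrow(u)
    counts <- c(counts, n)
    radii <- c(radii, r)
    if (n >= 2L) {
      cosm <- tcrossprod(u)
      ang <- acos(pmin(pmax(cosm[upper.tri(cosm)], -1), 1))
      angles <- c(angles, ang)
    }
  }
  list(angles = angles, radii = radii, counts = counts)
}

#' Geodesic radial distribution function on the shell sphere
#'
#' Pair-angle distribution of shell members as seen from the ion: the
#' angle phi at the centre between the two centre-to-particle vectors
#' (geodesic arc length l = R phi). The histogram is Gaussian-kernel
#' smoothed (with reflection at 0 and 180 degrees so probability mass is
#' conserved) and normalized by the uniform-sphere expectation
#' sin(phi)/2, so uniform points give g = 1.
#'
#' @param configs A matrix of points, list of per-frame matrices, or a
#'   [trajectory()] (all waters, measured about the first selected ion).
#' @param center Centre point, default the origin (ignored for
#'   trajectories, which use the ion position per frame).
#' @param kernel Gaussian smoothing width in degrees (default 5; 0
#'   disables smoothing and bins the raw histogram).
#' @param bins Number of grid points on [0, 180] degrees (default 721).
#' @param ion Ion index when `configs` is a trajectory.
#' @return List of class `angular_profile`: `phi_deg`, `phi` (radians),
#'   `g`, `P` (density in radians, integrating to 1), `n` (mean shell
#'   occupancy), `R` (mean shell radius, A), `kernel`, `n_pairs`.
#' @export
#' @examples
#' prof <- geodesic_rdf(platonic_shell(6, 2.4))
geodesic_rdf <- function(configs, center = c(0, 0, 0), kernel = 5,
                         bins = 721, ion = 1L) {
  if (inherits(configs, "trajectory") || inherits(configs, "frame")) {
    frames <- as_frames(configs)
    configs <- lapply(frames, function(fr) {
      ctr <- as.numeric(fr$ions[ion, c("x", "y", "z")])
      to_xyz(min_image_displacement(ctr, water_oxygens(fr), fr$box))
    })
    center <- c(0, 0, 0)
  }
  if (is.matrix(configs) || (is.numeric(configs) && length(configs) == 3L))
    configs <- list(to_xyz(configs))
  pa <- collect_pair_angles(configs, center)
  if (!length(pa$angles))
    stop("fewer than 2 shell members in all frames")
  phi <- seq(0, pi, length.out = bins)
  h <- kernel * pi / 180
  if (h > 0) {
    # kernel density with reflection about both endpoints
    P <- numeric(length(phi))
    for (a in pa$angles)
      P <- P + stats::dnorm(phi, a, h) + stats::dnorm(phi, -a, h) +
        stats::dnorm(phi, 2 * pi - a, h)
    P <- P / length(pa$angles)
  } else {
    hist_b <- graphics::hist(pa$angles, breaks = phi, plot = FALSE)
    P <- c(hist_b$density, 0)
  }
  # renormalize on the grid (reflection leaves tiny truncation residue)
  Z <- trapz(phi, P)
  P <- P / Z
  g <- ifelse(sin(phi) > 1e-12, P / (sin(phi) / 2), 0)
  structure(list(phi_deg = phi * 180 / pi, phi = phi, g = g, P = P,
                 n = mean(pa$counts), R = mean(pa$radii),
                 kernel = kernel, n_pairs = length(pa$angles)),
            class = "angular_profile")
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Bond-orientational entropy of an angular profile
#'
#' Two-body excess-entropy functional of the geodesic pair distribution:
#' with the surface density rho_s = n / (4 pi R^2) and the spherical area
#' element 2 pi R^2 sin(phi) dphi, the per-particle entropy (in units of
#' k_B) is
#'
#'   s_phi = -(n/4) Int_0^pi \[g ln g - g + 1\] sin(phi) dphi.
#'
#' This is exactly 0 for uniform angular disorder (g = 1), strictly
#' negative otherwise, and scales linearly with occupancy n at a fixed
#' pattern. `normalization = "literal"` instead uses the planar-looking
#' density n / (pi R^2) with a bare pi prefactor,
#' s = -(n / R^2) Int \[...\] sin(phi) dphi, which differs only by the
#' constant factor 4/R^2. The 0 ln 0 limit is treated as 0.
#'
#' @param profile An `angular_profile` from [geodesic_rdf()].
#' @param normalization `"surface"` (default) or `"literal"`.
#' @return s_phi (unitless, per k_B); non-positive.
#' @export
#' @examples
#' bond_orientational_entropy(geodesic_rdf(platonic_shell(6, 2.4)))
bond_orientational_entropy <- function(profile,
                                       normalization = c("surface",
                                                         "literal")) {
  stopifnot(inherits(profile, "angular_profile"))
  normalization <- match.arg(normalization)
  g <- profile$g
  if (any(g < 0)) stop("negative g values in angular profile")
  glng <- ifelse(g > 0, g * log(g), 0)
  integrand <- (glng - g + 1) * sin(profile$phi)
  I <- trapz(profile$phi, integrand)
  pref <- switch(normalization,
                 surface = profile$n / 4,
                 literal = profile$n / profile$R^2)
  -pref * I
}

#' Characteristic angle of the shell
#'
#' Location (degrees) of the global interior maximum of the pair-angle
#' density P(phi), refined by 3-point parabolic interpolation. A profile
#' without angular structure (g never rising meaningfully above 1) is a
#' degenerate input and raises an error, since the sin(phi) measure alone
#' would otherwise put a spurious mode at 90 degrees.
#'
#' @param profile An `angular_profile`.
#' @param peak_gate Minimum g at the candidate peak (default 1.2).
#' @return phi_ion in degrees.
#' @export
#' @examples
#' characteristic_angle(geodesic_rdf(platonic_shell(4, 2.4)))  # 109.47
characteristic_angle <- function(profile, peak_gate = 1.2) {
  stopifnot(inherits(profile, "angular_profile"))
  P <- profile$P
  m <- length(P)
  i <- which.max(P)
  if (i == 1L || i == m) {
    # boundary mode (e.g. antipodal pairs peaking at 180 degrees); gate on
    # g at the nearest interior bin since g is undefined where sin(phi) = 0
    j <- if (i == 1L) 2L else m - 1L
    if (profile$g[j] < peak_gate)
      stop("no significant angular peak: profile consistent with uniform ",
           "disorder (g at mode = ", round(profile$g[j], 3), ")")
    return(profile$phi_deg[i])
  }
  if (profile$g[i] < peak_gate)
    stop("no significant angular peak: profile consistent with uniform ",
         "disorder (g at mode = ", round(profile$g[i], 3), ")")
  parabolic_vertex(profile$phi_deg, P, i)
}

# Coulomb energy of unit-sphere points
thomson_energy <- function(u) {
  d <- as.matrix(stats::dist(u))
  sum(1 / d[upper.tri(d)])
}

thomson_obj <- function(x, n) {
  X <- matrix(x, n, 3)
  U <- X / sqrt(rowSums(X^2))
  thomson_energy(U)
}

thomson_grad <- function(x, n) {
  X <- matrix(x, n, 3)
  nr <- sqrt(rowSums(X^2))
  U <- X / nr
  G <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    dv <- matrix(U[i, ], n, 3, byrow = TRUE) - U
    dv <- dv[-i, , drop = FALSE]
    dd <- sqrt(rowSums(dv^2))
    gu <- -colSums(dv / dd^3)
    # project through the normalization x -> x/|x|
    G[i, ] <- (gu - sum(gu * U[i, ]) * U[i, ]) / nr[i]
  }
  as.numeric(G)
}

#' Solve the Thomson problem on the unit sphere
#'
#' Minimizes the Coulomb energy sum_(i<j) 1/|x_i - x_j| of n unit charges
#' on the unit sphere by multi-start quasi-Newton (BFGS) minimization with
#' on-the-fly sphere projection; the best of `restarts` random starts is
#' returned. The characteristic angle phi_T is the centre of the
#' smallest-angle cluster of the solution's pair angles (the primary
#' nearest-neighbour angle). No global-optimality guarantee exists for
#' large n; for the shell occupancies of interest (n <= 20) the
#' multi-start heuristic reliably reaches the known optima.
#'
#' @param n Number of charges (>= 2).
#' @param restarts Number of random restarts (default 20).
#' @param seed Integer RNG seed.
#' @param cluster_tol Pair angles within this many degrees of the minimum
#'   count as the primary cluster (default 1).
#' @return List of class `thomson_solution`: `n`, `coordinates` (n x 3
#'   unit vectors), `energy`, `phi_T` (degrees), `grad_norm`,
#'   `restart_energies`.
#' @export
#' @examples
#' thomson_solve(4, restarts = 5, seed = 1)$energy  # 3.67423
thomson_solve <- function(n, restarts = 20, seed = 1, cluster_tol = 1) {
  if (n < 2) stop("n must be >= 2")
  with_seed(seed, {
    best <- NULL
    evals <- numeric(restarts)
    for (r in seq_len(restarts)) {
      x0 <- as.numeric(random_unit_vectors(n))
      opt <- stats::optim(x0, thomson_obj, thomson_grad, n = n,
                          method = "BFGS",
                          control = list(maxit = 2000, reltol = 1e-14))
      evals[r] <- opt$value
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    X <- matrix(best$par, n, 3)
    U <- X / sqrt(rowSums(X^2))
    cosm <- tcrossprod(U)
    ang <- acos(pmin(pmax(cosm[upper.tri(cosm)], -1), 1)) * 180 / pi
    amin <- min(ang)
    phi_T <- mean(ang[ang <= amin + cluster_tol])
    structure(list(n = n, coordinates = U, energy = thomson_energy(U),
                   phi_T = phi_T,
                   grad_norm = sqrt(sum(thomson_grad(as.numeric(U), n)^2)),
                   restart_energies = evals),
              class = "thomson_solution")
  })
}
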