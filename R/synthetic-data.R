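# Synthetic inputs at desk scale: uniform-sphere and Platonic-shell fixtures,
# a Metropolis Monte Carlo simulator of radially tethered point dipoles
# around a central charge, a charge-jump relaxation protocol, Brownian
# walks, stretched-exponential occupancy series, and packed rigid-water
# boxes for hydrogen-bond tests. Every generator is a pure function of its
# seed.

# evaluate expr under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# n random unit vectors (rows)
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# uniformly random 3x3 rotation matrix (via QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Uniform random points on a sphere
#'
#' The null model for angular order: i.i.d. points uniform on the sphere of
#' the given radius, centred at the origin.
#'
#' @param n Number of points (>= 1).
#' @param radius Sphere radius in Angstrom.
#' @param seed Integer RNG seed; same seed, same coordinates.
#' @return n x 3 matrix of coordinates.
#' @export
#' @examples
#' pts <- sample_uniform_sphere(100, 2.4, seed = 1)
sample_uniform_sphere <- function(n, radius = 1, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (radius <= 0) stop("radius must be positive")
  with_seed(seed, random_unit_vectors(n) * radius)
}

#' Vertices of a Platonic solid on a sphere
#'
#' Exact vertex coordinates of the regular tetrahedron (4), octahedron (6),
#' cube (8), icosahedron (12) or dodecahedron (20), scaled to the given
#' circumradius.
#'
#' @param n Vertex count: one of 4, 6, 8, 12, 20.
#' @param radius Circumradius in Angstrom.
#' @return n x 3 matrix of coordinates.
#' @export
#' @examples
#' platonic_shell(4)          # tetrahedron, pair angles acos(-1/3)
platonic_shell <- function(n, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- switch(as.character(n),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
    "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    "8" = (expand_signs(c(1, 1, 1)) / sqrt(3)),
    "12" = {
      m <- rbind(expand_signs_2(c(0, 1, phi)),
                 expand_signs_2(c(1, phi, 0)),
                 expand_signs_2(c(phi, 0, 1)))
      m / sqrt(1 + phi^2)
    },
    "20" = {
      m <- rbind(expand_signs(c(1, 1, 1)),
                 expand_signs_2(c(0, 1 / phi, phi)),
                 expand_signs_2(c(1 / phi, phi, 0)),
                 expand_signs_2(c(phi, 0, 1 / phi)))
      m / sqrt(3)
    },
    stop("platonic_shell supports n in {4, 6, 8, 12, 20}, got ", n))
  v * radius
}

# all 2^k sign combinations over the non-zero components
expand_signs <- function(v) {
  as.matrix(expand.grid(c(-v[1], v[1]), c(-v[2], v[2]), c(-v[3], v[3]),
                        KEEP.OUT.ATTRS = FALSE))
}
# sign combinations over the two non-zero components (one component is 0)
expand_signs_2 <- function(v) {
  nz <- which(v != 0)
  g <- expand.grid(c(-1, 1), c(-1, 1), KEEP.OUT.ATTRS = FALSE)
  m <- matrix(rep(v, each = 4), 4, 3)
  m[, nz[1]] <- m[, nz[1]] * g[, 1]
  m[, nz[2]] <- m[, nz[2]] * g[, 2]
  m
}

#' Parameters of the toy dipole-shell Monte Carlo simulator
#'
#' The simulator samples n point-dipole particles around a fixed central
#' charge with Metropolis moves. Energy terms: Lennard-Jones
#' (ion-particle), charge-dipole, dipole-dipole (point-dipole formulas),
#' and an optional harmonic radial tether that emulates confinement to a
#' thin single-layer shell.
#'
#' @param n_shell Number of shell particles.
#' @param ion_charge Central charge in e.
#' @param dipole_moment Particle dipole moment in e*A (default 0.48,
#'   the bulk moment of the rigid water model).
#' @param lj_sigma,lj_epsilon Ion-particle Lennard-Jones parameters
#'   (A, kJ/mol).
#' @param pp_sigma,pp_epsilon Purely repulsive r^-12 excluded-volume core
#'   between shell particles (A, kJ/mol). Point dipoles carry no intrinsic
#'   excluded volume, and the head-to-tail dipole-dipole attraction
#'   diverges at contact, so a short-range core is required for the model
#'   to have a well-defined equilibrium; at the equilibrium neighbour
#'   spacing its contribution is negligible.
#' @param temperature Temperature in K.
#' @param shell_spring Harmonic radial tether constant in kJ/mol/A^2
#'   (0 disables the tether).
#' @param shell_radius Tether target radius in A; defaults to the
#'   Lennard-Jones minimum 2^(1/6) * lj_sigma.
#' @param n_steps Production sweeps (one sweep = one attempted move per
#'   particle).
#' @param n_equil Equilibration sweeps, during which move scales are tuned
#'   toward 40 percent acceptance and then frozen.
#' @param sample_every Record a frame every this many production sweeps.
#' @param seed Integer RNG seed.
#' @param trans_scale,rot_scale Initial move scales (A, rad).
#' @return A list of class `mc_params`.
#' @export
mc_params <- function(n_shell = 6, ion_charge = 1, dipole_moment = 0.48,
                      lj_sigma = 2.76, lj_epsilon = 0.65,
                      pp_sigma = 2.6, pp_epsilon = 0.65, temperature = 300,
                      shell_spring = 50, shell_radius = 2^(1/6) * lj_sigma,
                      n_steps = 4000, n_equil = 1000, sample_every = 10,
                      seed = 1, trans_scale = 0.25, rot_scale = 0.5) {
  if (n_shell < 1) stop("n_shell must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  if (trans_scale <= 0 || rot_scale <= 0) stop("move scales must be positive")
  structure(list(n_shell = n_shell, ion_charge = ion_charge,
                 dipole_moment = dipole_moment, lj_sigma = lj_sigma,
                 lj_epsilon = lj_epsilon, pp_sigma = pp_sigma,
                 pp_epsilon = pp_epsilon, temperature = temperature,
                 shell_spring = shell_spring, shell_radius = shell_radius,
                 n_steps = n_steps, n_equil = n_equil,
                 sample_every = sample_every, seed = seed,
                 trans_scale = trans_scale, rot_scale = rot_scale),
            class = "mc_params")
}

# one-particle energy: LJ + charge-dipole + tether + dipole-dipole vs others
mc_particle_energy <- function(i, pos, axis, p) {
  ri <- pos[i, ]; r <- sqrt(sum(ri^2))
  if (r == 0) return(Inf)
  sr6 <- (p$lj_sigma / r)^6
  e <- 4 * p$lj_epsilon * (sr6^2 - sr6)
  e <- e - .ke_coulomb * p$ion_charge * p$dipole_moment *
    sum(axis[i, ] * ri) / r^3
  if (p$shell_spring > 0)
    e <- e + 0.5 * p$shell_spring * (r - p$shell_radius)^2
  if (nrow(pos) > 1L) {
    others <- setdiff(seq_len(nrow(pos)), i)
    dv <- pos[others, , drop = FALSE] -
      matrix(ri, length(others), 3, byrow = TRUE)
    d <- sqrt(rowSums(dv^2))
    if (any(d == 0)) return(Inf)
    u <- dv / d
    ai_dot <- drop(u %*% axis[i, ])
    aj_dot <- rowSums(u * axis[others, , drop = FALSE])
    aa <- drop(axis[others, , drop = FALSE] %*% axis[i, ])
    e <- e + sum(.ke_coulomb * p$dipole_moment^2 * (aa - 3 * ai_dot * aj_dot) / d^3)
    e <- e + sum(p$pp_epsilon * (p$pp_sigma / d)^12)
  }
  e
}

#' Total energy of a toy-simulator configuration
#'
#' From-scratch sum of all energy terms of the dipole-shell model:
#' one-body terms (ion-particle Lennard-Jones, charge-dipole, radial
#' tether) plus each dipole-dipole and repulsive-core pair counted once.
#' Used to audit the incremental energy bookkeeping of
#' [shell_mc_simulate()] against an independent recomputation.
#'
#' @param pos n x 3 matrix of particle positions (A), ion at the origin.
#' @param axis n x 3 matrix of unit dipole axes.
#' @param p An [mc_params()] object.
#' @return Total energy in kJ/mol (`Inf` for coincident sites).
#' @export
mc_total_energy <- function(pos, axis, p) {
  n <- nrow(pos)
  r <- sqrt(rowSums(pos^2))
  if (any(r == 0)) return(Inf)
  sr6 <- (p$lj_sigma / r)^6
  e <- sum(4 * p$lj_epsilon * (sr6^2 - sr6)) -
    sum(.ke_coulomb * p$ion_charge * p$dipole_moment *
          rowSums(axis * pos) / r^3)
  if (p$shell_spring > 0)
    e <- e + sum(0.5 * p$shell_spring * (r - p$shell_radius)^2)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      dv <- pos[(i + 1L):n, , drop = FALSE] -
        matrix(pos[i, ], n - i, 3, byrow = TRUE)
      d <- sqrt(rowSums(dv^2))
      if (any(d == 0)) return(Inf)
      u <- dv / d
      ai <- drop(u %*% axis[i, ])
      aj <- rowSums(u * axis[(i + 1L):n, , drop = FALSE])
      aa <- drop(axis[(i + 1L):n, , drop = FALSE] %*% axis[i, ])
      e <- e + sum(.ke_coulomb * p$dipole_moment^2 * (aa - 3 * ai * aj) / d^3) +
        sum(p$pp_epsilon * (p$pp_sigma / d)^12)
    }
  }
  e
}

# rotate unit vector a by angle about a random axis perpendicular to it
rotate_axis <- function(a, angle) {
  perp <- stats::rnorm(3)
  perp <- perp - sum(perp * a) * a
  np <- sqrt(sum(perp^2))
  if (np < 1e-12) return(a)
  perp <- perp / np
  v <- cos(angle) * a + sin(angle) * perp
  v / sqrt(sum(v^2))
}

# advance the chain by n_sweeps; mutable state passed in and returned.
# Moves: translation (45%), small axis rotation (45%), full axis resample
# (10%, untuned, decorrelates stuck orientations). When tune=TRUE the
# translation/rotation scales are nudged toward 40% acceptance every 50
# sweeps. per_sweep(pos, axis, sweep) is called after each sweep if given.
mc_chain <- function(pos, axis, e_tot, p, n_sweeps, trans, rot,
                     tune = FALSE, per_sweep = NULL) {
  n <- nrow(pos)
  kT <- .kB * p$temperature
  acc <- c(t = 0L, r = 0L); att <- c(t = 0L, r = 0L)
  acc_all <- 0L; att_all <- 0L
  for (sweep in seq_len(n_sweeps)) {
    for (m in seq_len(n)) {
      i <- sample.int(n, 1L)
      mv <- stats::runif(1)
      e_old <- mc_particle_energy(i, pos, axis, p)
      if (mv < 0.45) {
        kind <- "t"; old <- pos[i, ]
        pos[i, ] <- old + stats::rnorm(3, sd = trans)
      } else if (mv < 0.9) {
        kind <- "r"; old <- axis[i, ]
        axis[i, ] <- rotate_axis(old, stats::rnorm(1, sd = rot))
      } else {
        kind <- "f"; old <- axis[i, ]
        axis[i, ] <- random_unit_vectors(1)[1, ]
      }
      de <- mc_particle_energy(i, pos, axis, p) - e_old
      ok <- is.finite(de) && (de <= 0 || stats::runif(1) < exp(-de / kT))
      if (ok) {
        e_tot <- e_tot + de
      } else if (kind == "t") pos[i, ] <- old else axis[i, ] <- old
      att_all <- att_all + 1L
      if (ok) acc_all <- acc_all + 1L
      if (tune && kind %in% c("t", "r")) {
        att[kind] <- att[kind] + 1L
        if (ok) acc[kind] <- acc[kind] + 1L
      }
    }
    if (tune && sweep %% 50L == 0L) {
      if (att["t"] > 0) {
        f <- (acc["t"] / att["t"]) / 0.4
        trans <- min(max(trans * max(min(f, 1.5), 0.67), 1e-3),
                     p$shell_radius)
      }
      if (att["r"] > 0) {
        f <- (acc["r"] / att["r"]) / 0.4
        rot <- min(max(rot * max(min(f, 1.5), 0.67), 1e-3), pi)
      }
      acc[] <- 0L; att[] <- 0L
    }
    if (!is.null(per_sweep)) per_sweep(pos, axis, sweep, e_tot)
  }
  list(pos = pos, axis = axis, e_tot = e_tot, trans = trans, rot = rot,
       acceptance = if (att_all > 0) acc_all / att_all else NA_real_)
}

#' Toy Metropolis simulation of a dipolar hydration shell
#'
#' Runs a Metropolis chain for `p$n_shell` point dipoles around a central
#' charge fixed at the origin (see [mc_params()] for the energy model).
#' Translation, small-rotation and orientation-resample moves mix at
#' random; move scales are auto-tuned toward 40 percent acceptance during
#' equilibration and then frozen. Production frames are recorded every
#' `p$sample_every` sweeps.
#'
#' @param p An [mc_params()] object.
#' @return A list of class `mc_run` with elements `trajectory` (frames of
#'   point dipoles plus the central ion, non-periodic box), `energy`
#'   (tracked total energy per recorded frame, kJ/mol), `acceptance_rate`
#'   (production-phase fraction), `final` (list with `pos`, `axis`,
#'   `energy`), and `params`.
#' @export
#' @examples
#' run <- shell_mc_simulate(mc_params(n_shell = 4, n_steps = 200,
#'                                    n_equil = 100, seed = 2))
#' run$acceptance_rate
shell_mc_simulate <- function(p) {
  stopifnot(inherits(p, "mc_params"))
  with_seed(p$seed, {
    n <- p$n_shell
    pos <- random_unit_vectors(n) * p$shell_radius
    axis <- random_unit_vectors(n)
    e_tot <- mc_total_energy(pos, axis, p)
    if (!is.finite(e_tot)) stop("non-finite initial energy (particle overlap)")
    eq <- mc_chain(pos, axis, e_tot, p, p$n_equil,
                   p$trans_scale, p$rot_scale, tune = TRUE)
    L_box <- 4 * p$shell_radius + 20
    ctr <- L_box / 2
    rec <- new.env()
    rec$frames <- list(); rec$energies <- numeric(0); rec$k <- 0L
    keep <- function(pos, axis, sweep, e_tot) {
      if (sweep %% p$sample_every == 0L) {
        rec$k <- rec$k + 1L
        rec$frames[[rec$k]] <-
          frame(time = sweep * 1.0,
                ions = sites(c(ctr, ctr, ctr), charge = p$ion_charge,
                             label = "ION"),
                waters = point_dipoles(pos + ctr, axis, p$dipole_moment),
                box = box(L_box, periodic = FALSE), wrap = FALSE)
        rec$energies[rec$k] <- e_tot
      }
    }
    pr <- mc_chain(eq$pos, eq$axis, eq$e_tot, p, p$n_steps,
                   eq$trans, eq$rot, tune = FALSE, per_sweep = keep)
    structure(list(trajectory = if (rec$k > 0) trajectory(rec$frames) else NULL,
                   energy = rec$energies,
                   acceptance_rate = pr$acceptance,
                   final = list(pos = pr$pos, axis = pr$axis,
                                energy = pr$e_tot),
                   move_scales = c(translation = pr$trans,
                                   rotation = pr$rot),
                   params = p),
              class = "mc_run")
  })
}

#' Mean radial dipole projection of a shell run
#'
#' Average of cos(theta) over particles and recorded frames, theta being
#' the angle between a particle's dipole and the ion-to-particle direction.
#'
#' @param run An `mc_run` from [shell_mc_simulate()], or a single frame.
#' @return List with `mean`, `se` (standard error over frames) and the
#'   per-frame means.
#' @export
mc_cos_theta <- function(run) {
  frames <- if (inherits(run, "mc_run")) run$trajectory$frames else list(run)
  per <- vapply(frames, function(fr) {
    ion <- as.numeric(fr$ions[1, c("x", "y", "z")])
    pos <- water_oxygens(fr)
    dv <- pos - matrix(ion, nrow(pos), 3, byrow = TRUE)
    u <- dv / sqrt(rowSums(dv^2))
    dip <- water_dipole(fr)
    dip <- dip / sqrt(rowSums(dip^2))
    mean(rowSums(u * dip))
  }, numeric(1))
  list(mean = mean(per), se = stats::sd(per) / sqrt(length(per)),
       per_frame = per)
}

#' Charge-jump relaxation protocol
#'
#' Each replica is equilibrated with the central charge at `q_before`, the
#' charge is switched instantaneously to `q_after` at time zero, and the
#' ensemble-averaged radial dipolar order and mean neighbouring-pair
#' dipole-dipole energy are followed sweep by sweep, averaged over
#' replicas.
#'
#' @param p An [mc_params()]; `p$n_steps` sweeps are recorded after the
#'   jump and `p$seed` seeds the replica ensemble.
#' @param q_before,q_after Central charge before/after the jump (e).
#' @param n_replicas Number of independent replicas (>= 1).
#' @param equil_steps Equilibration sweeps at `q_before` per replica.
#' @return A list of class `charge_jump` with `sweep` (time axis),
#'   `cos_theta` (n_replicas x n_steps matrix), `pair_energy` (same
#'   shape, kJ/mol), their replica means `cos_theta_mean`,
#'   `pair_energy_mean`, and the parameters.
#' @export
charge_jump_protocol <- function(p, q_before, q_after, n_replicas = 8,
                                 equil_steps = p$n_equil) {
  stopifnot(inherits(p, "mc_params"))
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  ct <- matrix(NA_real_, n_replicas, p$n_steps)
  pe <- matrix(NA_real_, n_replicas, p$n_steps)
  for (r in seq_len(n_replicas)) {
    pr <- p
    pr$seed <- p$seed + r * 1000L
    # equilibrate at q_before, no production sampling needed
    pr$ion_charge <- q_before
    pr$n_equil <- equil_steps
    pr$n_steps <- 1L
    pr$sample_every <- 1L
    eq <- shell_mc_simulate(pr)
    # continue from the equilibrated state at q_after, frozen move scales
    st <- mc_continue(eq$final, eq$move_scales, p, q_after, p$n_steps,
                      seed = pr$seed + 1L)
    ct[r, ] <- st$cos_theta
    pe[r, ] <- st$pair_energy
  }
  structure(list(sweep = seq_len(p$n_steps), cos_theta = ct, pair_energy = pe,
                 cos_theta_mean = colMeans(ct),
                 pair_energy_mean = colMeans(pe),
                 q_before = q_before, q_after = q_after,
                 n_replicas = n_replicas, params = p),
            class = "charge_jump")
}

# run extra sweeps from a given state, recording per-sweep observables
mc_continue <- function(state, scales, p, ion_charge, n_sweeps, seed) {
  p$ion_charge <- ion_charge
  ct <- numeric(n_sweeps); pe <- numeric(n_sweeps)
  watch <- function(pos, axis, sweep, e_tot) {
    u <- pos / sqrt(rowSums(pos^2))
    ct[sweep] <<- mean(rowSums(u * axis))
    pe[sweep] <<- mean_neighbour_dd_energy(pos, axis, p)
  }
  with_seed(seed, {
    e0 <- mc_total_energy(state$pos, state$axis, p)
    mc_chain(state$pos, state$axis, e0, p, n_sweeps,
             scales[["translation"]], scales[["rotation"]],
             tune = FALSE, per_sweep = watch)
  })
  list(cos_theta = ct, pair_energy = pe)
}

# mean dipole-dipole energy over neighbouring pairs (within 1.6x the
# typical nearest-neighbour arc for the shell occupancy)
mean_neighbour_dd_energy <- function(pos, axis, p) {
  n <- nrow(pos)
  if (n < 2L) return(NA_real_)
  gate <- 1.6 * 2 * p$shell_radius * sin(pi / n)  # generous neighbour gate
  es <- c()
  for (i in seq_len(n - 1L)) {
    dv <- pos[(i + 1L):n, , drop = FALSE] - matrix(pos[i, ], n - i, 3, byrow = TRUE)
    d <- sqrt(rowSums(dv^2))
    keep <- d <= gate
    if (!any(keep)) next
    u <- dv[keep, , drop = FALSE] / d[keep]
    aj <- axis[(i + 1L):n, , drop = FALSE][keep, , drop = FALSE]
    ai_dot <- drop(u %*% axis[i, ])
    aj_dot <- rowSums(u * aj)
    aa <- drop(aj %*% axis[i, ])
    es <- c(es, .ke_coulomb * p$dipole_moment^2 * (aa - 3 * ai_dot * aj_dot) / d[keep]^3)
  }
  if (length(es)) mean(es) else NA_real_
}

#' Brownian walk trajectory
#'
#' Independent Gaussian displacement increments with variance 2 D dt per
#' Cartesian component. Particles start at the box centre (optionally
#' spread uniformly within `start_radius` of it); an uncharged tracer
#' "ion" sits at the centre so shell-conditioned analyses can be exercised.
#'
#' @param D Diffusion coefficient in A^2/ps (>= 0).
#' @param dt Time step in ps (> 0).
#' @param n_steps Number of steps (frames = n_steps + 1).
#' @param n_particles Number of walkers.
#' @param seed Integer RNG seed.
#' @param box_length Box edge (A); default is generous and non-periodic.
#' @param periodic Wrap positions (exercises minimum-image unwrapping).
#' @param start_radius Initial uniform spread around the centre (A).
#' @return A [trajectory()] whose waters are point particles.
#' @export
brownian_walk <- function(D, dt, n_steps, n_particles, seed = NULL,
                          box_length = 1000, periodic = FALSE,
                          start_radius = 0) {
  if (D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  with_seed(seed, {
    ctr <- box_length / 2
    pos <- matrix(ctr, n_particles, 3)
    if (start_radius > 0) {
      u <- random_unit_vectors(n_particles) *
        (stats::runif(n_particles)^(1 / 3) * start_radius)
      pos <- pos + u
    }
    sdd <- sqrt(2 * D * dt)
    bx <- box(box_length, periodic = periodic)
    axis0 <- matrix(rep(c(0, 0, 1), each = n_particles), n_particles, 3)
    frames <- vector("list", n_steps + 1L)
    for (k in 0:n_steps) {
      if (k > 0) pos <- pos + matrix(stats::rnorm(3 * n_particles, sd = sdd),
                                     n_particles, 3)
      frames[[k + 1L]] <- frame(time = k * dt,
                                ions = sites(c(ctr, ctr, ctr), 0, "TRC"),
                                waters = point_dipoles(pos, axis0),
                                box = bx, wrap = periodic)
    }
    trajectory(frames, dt = dt)
  })
}

#' Stretched-exponential occupancy series
#'
#' P(t) = exp(-(t/tau)^beta) with optional i.i.d. Gaussian noise, clipped
#' to [0, 1]; P(0) is pinned to 1.
#'
#' @param tau Relaxation time in ps (> 0).
#' @param beta Stretching exponent in (0, 2].
#' @param t_grid Strictly increasing time grid (ps), starting at 0.
#' @param noise_sd Gaussian noise standard deviation (fraction of 1).
#' @param seed Integer RNG seed.
#' @return A list of class `correlation_series` with `t`, `P`, and the
#'   generating `tau`, `beta`.
#' @export
#' @examples
#' s <- stretched_occupancy(10, 0.8, seq(0, 50, by = 0.5))
#' s$P[s$t == 10]  # exp(-1)
stretched_occupancy <- function(tau, beta, t_grid, noise_sd = 0, seed = NULL) {
  if (tau <= 0) stop("tau must be positive")
  if (beta <= 0 || beta > 2) stop("beta must be in (0, 2]")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  P <- exp(-(t_grid / tau)^beta)
  if (noise_sd > 0)
    P <- with_seed(seed, P + stats::rnorm(length(P), sd = noise_sd))
  P <- pmin(pmax(P, 0), 1)
  P[t_grid == 0] <- 1
  structure(list(t = t_grid, P = P, origins = rep(1L, length(t_grid)),
                 tau = tau, beta = beta),
            class = "correlation_series")
}

# reference rigid water: O at origin, bisector (and dipole) along +z,
# hydrogens in the xz-plane
reference_water <- function(model = water_model()) {
  half <- model$theta_hoh / 2 * pi / 180
  list(O = c(0, 0, 0),
       H1 = c(model$r_oh * sin(half), 0, model$r_oh * cos(half)),
       H2 = c(-model$r_oh * sin(half), 0, model$r_oh * cos(half)),
       M = c(0, 0, model$r_om))
}

# build a water_set by applying rotations (list of 3x3) and translations
# (n x 3) to the reference geometry
place_waters <- function(rotations, translations, model = water_model()) {
  ref <- reference_water(model)
  n <- nrow(translations)
  O <- H1 <- H2 <- M <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Rm <- rotations[[i]]
    O[i, ] <- translations[i, ]
    H1[i, ] <- translations[i, ] + drop(Rm %*% ref$H1)
    H2[i, ] <- translations[i, ] + drop(Rm %*% ref$H2)
    M[i, ] <- translations[i, ] + drop(Rm %*% ref$M)
  }
  water_set(O, H1, H2, M, model = model)
}

#' Random rigid-water box
#'
#' Packs `n_water` rigid waters at random positions and orientations into a
#' periodic cubic box, enforcing a minimum-image O-O separation of 2.2 A
#' with bounded retries. Hand-specified motifs (water sets, e.g. an ideal
#' hydrogen-bonded dimer) are inserted verbatim before random packing.
#'
#' @param n_water Total number of waters including motif waters.
#' @param box A [box()].
#' @param seed Integer RNG seed.
#' @param motifs Optional list of `water_set` objects placed unchanged.
#' @param min_oo Minimum O-O separation during packing (A).
#' @param max_tries Placement retries per water before failing.
#' @param model Water convention, see [water_model()].
#' @return A [frame()] at time 0 with no ions.
#' @export
#' @examples
#' fr <- toy_water_box(10, box(15), seed = 3)
toy_water_box <- function(n_water, box, seed = NULL, motifs = NULL,
                          min_oo = 2.2, max_tries = 2000,
                          model = water_model()) {
  stopifnot(inherits(box, "box"))
  with_seed(seed, {
    O <- matrix(numeric(0), 0, 3)
    sets <- list()
    for (ms in motifs) {
      stopifnot(inherits(ms, "water_set"))
      O <- rbind(O, ms$O)
      sets[[length(sets) + 1L]] <- ms
    }
    n_left <- n_water - nrow(O)
    if (n_left < 0) stop("motifs contain more waters than n_water")
    if (n_left > 0) {
      rots <- vector("list", n_left)
      trs <- matrix(0, n_left, 3)
      for (i in seq_len(n_left)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- stats::runif(3, 0, box$edge_length)
          if (nrow(O) == 0 ||
              min(min_image_dist(matrix(cand, 1), O, box)) >= min_oo) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("water packing failed after ", max_tries, " retries")
        trs[i, ] <- cand
        rots[[i]] <- random_rotation()
        O <- rbind(O, cand)
      }
      sets[[length(sets) + 1L]] <- place_waters(rots, trs, model)
    }
    w <- Reduce(function(a, b) water_set(rbind(a$O, b$O), rbind(a$H1, b$H1),
                                         rbind(a$H2, b$H2),
                                         rbind(a$M, b$M), model = model),
                sets)
    frame(0, ions = NULL, waters = w, box = box, wrap = FALSE)
  })
}

#' Ideal hydrogen-bonded water dimer
#'
#' Donor water with one O-H bond pointing along +x at the acceptor oxygen
#' placed `r_oo` away on the x axis; the acceptor's bisector points along
#' +x, away from the donor, so both acceptor hydrogens face away from the
#' incoming hydrogen and the site-site pair energy is attractive. The
#' geometry satisfies the distance/angle hydrogen-bond criterion exactly
#' (angle 0) unless perturbed via `angle_deg`.
#'
#' @param r_oo Donor-acceptor O-O distance (A).
#' @param angle_deg Rotate the donor so the H-O..O angle equals this value.
#' @param origin Position of the donor oxygen.
#' @param model Water convention.
#' @return A `water_set` with two waters (donor first).
#' @export
hbond_dimer <- function(r_oo = 2.9, angle_deg = 0, origin = c(0, 0, 0),
                        model = water_model()) {
  half <- model$theta_hoh / 2 * pi / 180
  # rotation taking the reference H1 direction (sin h, 0, cos h) to +x,
  # then tilting by angle_deg in the xz-plane
  b <- c(sin(half), 0, cos(half))
  target <- c(cos(angle_deg * pi / 180), 0, sin(angle_deg * pi / 180))
  R1 <- rotation_between(b, target)
  R2 <- rotation_between(c(0, 0, 1), c(1, 0, 0))
  rots <- list(R1, R2)
  trs <- rbind(origin, origin + c(r_oo, 0, 0))
  place_waters(rots, trs, model)
}

# minimal rotation matrix taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
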