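# Pairwise energetics: Lennard-Jones plus Coulomb site-site potential,
# shell water-pair energy E_w-w, ion-water interaction magnitude
# dE_ion-water, and the bulk hydrogen-bond energy with its thermal band.
# Sign convention throughout: attraction negative, repulsion positive.

#' Lennard-Jones / Coulomb pair parameters
#'
#' @param epsilon LJ well depth in kJ/mol (>= 0).
#' @param sigma LJ diameter in A (> 0).
#' @param cutoff Distance cutoff in A for whole-box scans (default Inf;
#'   pair analyses between designated groups apply no truncation).
#' @return List of class `pair_params`.
#' @export
pair_params <- function(epsilon, sigma, cutoff = Inf) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff),
            class = "pair_params")
}

#' Water-water interaction parameters of the rigid water model
#'
#' Oxygen-oxygen Lennard-Jones (sigma 3.1589 A, epsilon 0.7749 kJ/mol)
#' plus the site charges of [water_model()].
#'
#' @return A [pair_params()] object.
#' @export
water_pair_params <- function() {
  md <- water_model()
  pair_params(md$lj_epsilon, md$lj_sigma)
}

#' Site-site pair interaction energy between two groups
#'
#' Sum of the Lennard-Jones term, 4 eps \[(sigma/r)^12 - (sigma/r)^6\],
#' over pairs of LJ-flagged sites, plus the Coulomb term k_e q_i q_j / r
#' over all charged site pairs, with minimum-image distances. Site groups
#' are data frames as built by [sites()]; an optional logical `lj` column
#' marks the LJ centres (absent column = all sites carry LJ).
#'
#' @param A,B Site groups (data frames with x, y, z, charge, optional lj).
#' @param params A [pair_params()].
#' @param box A [box()].
#' @return Interaction energy in kJ/mol.
#' @export
#' @examples
#' a <- sites(c(0, 0, 0), charge = 1)
#' b <- sites(c(1, 0, 0), charge = 1)
#' pair_potential(a, b, pair_params(0, 1), box(100))  # 1389.35 kJ/mol
pair_potential <- function(A, B, params, box) {
  stopifnot(inherits(params, "pair_params"), inherits(box, "box"))
  lj_a <- if (!is.null(A$lj)) A$lj else rep(TRUE, nrow(A))
  lj_b <- if (!is.null(B$lj)) B$lj else rep(TRUE, nrow(B))
  pa <- as.matrix(A[, c("x", "y", "z")])
  pb <- as.matrix(B[, c("x", "y", "z")])
  e <- 0
  for (i in seq_len(nrow(pa))) {
    dv <- to_xyz(min_image_displacement(pa[i, ], pb, box))
    r <- sqrt(rowSums(dv^2))
    if (any(r == 0)) stop("zero separation between interacting sites")
    in_cut <- r <= params$cutoff
    if (params$epsilon > 0 && lj_a[i]) {
      sel <- lj_b & in_cut
      if (any(sel)) {
        sr6 <- (params$sigma / r[sel])^6
        e <- e + sum(4 * params$epsilon * (sr6^2 - sr6))
      }
    }
    if (A$charge[i] != 0) {
      sel <- B$charge != 0 & in_cut
      if (any(sel))
        e <- e + sum(.ke_coulomb * A$charge[i] * B$charge[sel] / r[sel])
    }
  }
  e
}

# site group of water i in a water_set: O is the LJ centre, H/M carry the
# charges
water_site_group <- function(w, i) {
  md <- w$model
  pos <- rbind(w$O[i, ], w$H1[i, ], w$H2[i, ],
               if (!is.null(w$M)) w$M[i, ])
  chg <- c(md$q_o, md$q_h, md$q_h, if (!is.null(w$M)) md$q_m)
  g <- sites(pos, charge = chg,
             label = c("OW", "HW1", "HW2", if (!is.null(w$M)) "MW"))
  g$lj <- c(TRUE, FALSE, FALSE, if (!is.null(w$M)) FALSE)
  g
}

# point-dipole pair energy: k_e p^2 [a.b - 3 (a.r)(b.r)] / r^3
dipole_pair_energy <- function(p1, a1, p2, a2, moment, box) {
  dv <- min_image_displacement(p1, p2, box)
  r <- sqrt(sum(dv^2))
  if (r == 0) stop("zero separation between dipoles")
  u <- dv / r
  .ke_coulomb * moment^2 * (sum(a1 * a2) - 3 * sum(a1 * u) * sum(a2 * u)) / r^3
}

#' Mean shell water-pair interaction energy E_w-w
#'
#' Average interaction energy over neighbouring pairs of first-shell
#' waters (pair gate: O-O distance below `gate`, default 3.5 A, the first
#' minimum of the water-water g(r)), averaged over frames. For
#' explicit-site waters the energy is the full site-site sum under
#' `params`; for point-dipole shells it is the point dipole-dipole
#' energy. The full pair-energy distribution is returned alongside the
#' mean.
#'
#' @param traj A [trajectory()] or frame.
#' @param shell A `shell_assignment` or numeric r1 (A).
#' @param params A [pair_params()] (default [water_pair_params()]);
#'   ignored for point-dipole shells.
#' @param gate Neighbour gate on the O-O distance (A).
#' @param ions Ion indices (default all).
#' @return List of class `energy_summary` with `E_w_w` (kJ/mol),
#'   `energies` (all qualifying pair energies), `n_pairs`.
#' @export
shell_pair_energy <- function(traj, shell, params = water_pair_params(),
                              gate = 3.5, ions = NULL) {
  frames <- as_frames(traj)
  r1 <- if (inherits(shell, "shell_assignment")) shell$r1 else
    as.numeric(shell)
  if (is.null(ions)) ions <- seq_len(nrow(frames[[1]]$ions))
  energies <- numeric(0)
  for (fr in frames) {
    ox <- water_oxygens(fr)
    w <- fr$waters
    for (ionidx in ions) {
      ctr <- as.numeric(fr$ions[ionidx, c("x", "y", "z")])
      dsp <- to_xyz(min_image_displacement(ctr, ox, fr$box))
      members <- which(sqrt(rowSums(dsp^2)) <= r1)
      if (length(members) < 2L) next
      for (ii in seq_along(members)[-length(members)]) {
        for (jj in seq((ii + 1L), length(members))) {
          i <- members[ii]; j <- members[jj]
          doo <- sqrt(sum(min_image_displacement(ox[i, ], ox[j, ],
                                                 fr$box)^2))
          if (doo >= gate) next
          e <- if (inherits(w, "point_dipoles")) {
            dipole_pair_energy(w$pos[i, ], w$axis[i, ],
                               w$pos[j, ], w$axis[j, ], w$moment, fr$box)
          } else {
            pair_potential(water_site_group(w, i), water_site_group(w, j),
                           params, fr$box)
          }
          energies <- c(energies, e)
        }
      }
    }
  }
  if (!length(energies))
    return(structure(list(E_w_w = NA_real_, energies = numeric(0),
                          n_pairs = 0L, flag = "no qualifying shell pairs"),
                     class = "energy_summary"))
  structure(list(E_w_w = mean(energies), energies = energies,
                 n_pairs = length(energies)),
            class = "energy_summary")
}

#' Ion-water interaction energy magnitude dE_ion-water
#'
#' Magnitude of the mean interaction energy between the ion and a single
#' first-shell water (Lennard-Jones on the oxygen plus Coulomb over the
#' water's charged sites; charge-dipole plus Lennard-Jones for
#' point-dipole shells), averaged over shell members, ions and frames.
#' The signed mean and the per-water distribution are also returned.
#'
#' @param traj A [trajectory()] or frame.
#' @param shell A `shell_assignment` or numeric r1 (A).
#' @param params A [pair_params()] for the ion-oxygen Lennard-Jones term.
#' @param ions Ion indices (default all).
#' @param ion_charge Override the ion charges stored in the frames
#'   (useful when frames came from a file format without charges).
#' @return List of class `energy_summary` with `dE_ion_water` (kJ/mol,
#'   magnitude), `mean_signed`, `energies`, `n_obs`.
#' @export
ion_water_energy <- function(traj, shell, params, ions = NULL,
                             ion_charge = NULL) {
  frames <- as_frames(traj)
  r1 <- if (inherits(shell, "shell_assignment")) shell$r1 else
    as.numeric(shell)
  if (is.null(ions)) ions <- seq_len(nrow(frames[[1]]$ions))
  energies <- numeric(0)
  for (fr in frames) {
    ox <- water_oxygens(fr)
    w <- fr$waters
    for (ionidx in ions) {
      q <- ion_charge %||% fr$ions$charge[ionidx]
      ctr <- as.numeric(fr$ions[ionidx, c("x", "y", "z")])
      dsp <- to_xyz(min_image_displacement(ctr, ox, fr$box))
      rr <- sqrt(rowSums(dsp^2))
      members <- which(rr <= r1)
      if (!length(members)) stop("empty hydration shell in a frame")
      for (i in members) {
        e <- if (inherits(w, "point_dipoles")) {
          u <- dsp[i, ] / rr[i]
          sr6 <- (params$sigma / rr[i])^6
          4 * params$epsilon * (sr6^2 - sr6) -
            .ke_coulomb * q * w$moment * sum(w$axis[i, ] * u) / rr[i]^2
        } else {
          ion_g <- sites(ctr, charge = q, label = "ION")
          ion_g$lj <- TRUE
          pair_potential(ion_g, water_site_group(w, i), params, fr$box)
        }
        energies <- c(energies, e)
      }
    }
  }
  structure(list(dE_ion_water = abs(mean(energies)),
                 mean_signed = mean(energies), energies = energies,
                 n_obs = length(energies)),
            class = "energy_summary")
}

#' Bulk hydrogen-bond energy and its thermal band
#'
#' Mean site-site pair energy over all hydrogen-bonded water pairs
#' (Luzar-Chandler detection, duplicate donor/acceptor orderings of the
#' same oxygen pair counted once), with the thermal band reported as one
#' standard deviation of the bonded-pair energy population.
#'
#' @param traj A [trajectory()] or frame of neat explicit-site water.
#' @param params A [pair_params()] (default [water_pair_params()]).
#' @param r_max,angle_max Hydrogen-bond criterion, see [detect_hbonds()].
#' @return List of class `energy_summary` with `E_hbond` (kJ/mol),
#'   `band` (kJ/mol, 1 sd), `energies`, `n_bonds`.
#' @export
hbond_energy_bulk <- function(traj, params = water_pair_params(),
                              r_max = 3.5, angle_max = 30) {
  frames <- as_frames(traj)
  energies <- numeric(0)
  for (fr in frames) {
    hb <- detect_hbonds(fr, r_max = r_max, angle_max = angle_max)
    if (!nrow(hb)) next
    key <- unique(data.frame(a = pmin(hb$donor, hb$acceptor),
                             b = pmax(hb$donor, hb$acceptor)))
    w <- fr$waters
    for (k in seq_len(nrow(key))) {
      energies <- c(energies,
                    pair_potential(water_site_group(w, key$a[k]),
                                   water_site_group(w, key$b[k]),
                                   params, fr$box))
    }
  }
  if (!length(energies)) stop("no hydrogen bonds detected")
  structure(list(E_hbond = mean(energies),
                 band = sqrt(mean((energies - mean(energies))^2)),
                 energies = energies, n_bonds = length(energies)),
            class = "energy_summary")
}
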