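# Machinery for the charge-distance (q-d) plane: scan-grid bookkeeping
# with exact charge neutrality and molality, the susceptibility of an
# observable, the structural transformation line (maximal dn/dq), the
# hydrogen-bond crossover length lambda_HB, and ratio/iso-value contours.

#' Molality of a salt box
#'
#' Moles of salt formula units per kilogram of water, from particle
#' counts: m = n_salt / (n_water * M_w / 1000) with M_w = 18.0153 g/mol.
#'
#' @param n_water Number of water molecules.
#' @param n_salt Number of salt formula units (cations).
#' @return Molality in mol/kg.
#' @export
#' @examples
#' molality(3456, 10)  # 0.16 mol/kg
molality <- function(n_water, n_salt) {
  n_salt / (n_water * 18.0153 / 1000)
}

#' Build a charge/size scan grid with exact charge neutrality
#'
#' Cartesian grid of cation charge levels q = k_q * delta_q and
#' cation-oxygen VDW diameters sigma = sigma_ref + k_sigma * delta_sigma.
#' For each point the smallest integral anion count achieving exact
#' neutrality with the given anion charge is recorded
#' (n_anions * |q_anion| = n_cations * q), along with the box molality.
#'
#' @param sigma_ref Reference cation-oxygen VDW diameter (A).
#' @param delta_sigma Sigma increment (A), default 0.04.
#' @param k_sigma Integer vector of sigma levels.
#' @param delta_q Charge increment (e), default 0.17 (= 0.85/5).
#' @param k_q Integer vector of charge levels (>= 1).
#' @param n_cations Cations per box, default 10.
#' @param anion_charge Anion charge magnitude (e), default 0.85.
#' @param n_waters Waters per box, default 3456.
#' @return Data frame of class `scan_grid`: k_q, k_sigma, q, sigma,
#'   n_cations, n_anions, anion_charge, molality, plus a `measured_d`
#'   column (NA) to be filled after analysis.
#' @export
#' @examples
#' g <- build_scan_grid(2.60, k_sigma = 0, k_q = 1:20)
#' range(g$n_anions)  # 2 40
build_scan_grid <- function(sigma_ref, delta_sigma = 0.04, k_sigma = 0,
                            delta_q = 0.17, k_q = 1:20, n_cations = 10,
                            anion_charge = 0.85, n_waters = 3456) {
  if (delta_q <= 0 || delta_sigma <= 0)
    stop("delta_q and delta_sigma must be positive")
  grid <- expand.grid(k_q = as.integer(k_q), k_sigma = as.integer(k_sigma),
                      KEEP.OUT.ATTRS = FALSE)
  q <- grid$k_q * delta_q
  n_an_exact <- n_cations * q / abs(anion_charge)
  n_an <- round(n_an_exact)
  bad <- abs(n_an - n_an_exact) > 1e-9
  if (any(bad))
    stop("charge neutrality unattainable with integral anion counts at ",
         "q = ", paste(unique(round(q[bad], 4)), collapse = ", "),
         " e and anion charge ", anion_charge, " e")
  out <- data.frame(k_q = grid$k_q, k_sigma = grid$k_sigma, q = q,
                    sigma = sigma_ref + grid$k_sigma * delta_sigma,
                    n_cations = n_cations, n_anions = as.integer(n_an),
                    anion_charge = -abs(anion_charge),
                    molality = molality(n_waters, n_cations),
                    measured_d = NA_real_)
  class(out) <- c("scan_grid", "data.frame")
  out
}

#' Small-fractional-charge refinement scan preset
#'
#' Refinement grid for the low-charge region: charges 0 to `q_max` in
#' steps of `delta_q` (default 0.05 e) at a single sigma, with the anion
#' charge set equal to the cation charge and equal counts, so every point
#' is trivially neutral.
#'
#' @param sigma Cation-oxygen VDW diameter (A), default 2.73.
#' @param delta_q Charge step (e), default 0.05.
#' @param q_max Largest charge (e), default 1.2.
#' @param n_cations Cations (= anions) per box, default 10.
#' @param n_waters Waters per box, default 3456.
#' @return A `scan_grid` data frame.
#' @export
refinement_scan_grid <- function(sigma = 2.73, delta_q = 0.05, q_max = 1.2,
                                 n_cations = 10, n_waters = 3456) {
  k <- 0:round(q_max / delta_q)
  out <- data.frame(k_q = k, k_sigma = 0L, q = k * delta_q, sigma = sigma,
                    n_cations = n_cations, n_anions = n_cations,
                    anion_charge = -k * delta_q,
                    molality = molality(n_waters, n_cations),
                    measured_d = NA_real_)
  class(out) <- c("scan_grid", "data.frame")
  out
}

#' Observable values on the (q, d) lattice
#'
#' @param q Strictly increasing charge axis (e).
#' @param d Strictly increasing distance axis (A).
#' @param values Matrix of dim (length(q), length(d)); NA cells are
#'   masked.
#' @param name Observable name.
#' @return List of class `phase_grid`.
#' @export
phase_grid <- function(q, d, values, name = "observable") {
  if (any(diff(q) <= 0) || any(diff(d) <= 0))
    stop("grid axes must be strictly increasing")
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(q), length(d))))
    stop("values matrix must be length(q) x length(d)")
  structure(list(q = q, d = d, values = values, name = name,
                 mask = is.finite(values)),
            class = "phase_grid")
}

# central finite differences (one-sided at the ends) of y on x; NA-safe
finite_diff <- function(x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    if (is.finite(y[lo]) && is.finite(y[hi]) && hi > lo)
      out[i] <- (y[hi] - y[lo]) / (x[hi] - x[lo])
  }
  out
}

#' Susceptibility of an observable to the ion-water distance
#'
#' chi = d(observable)/d(d) along the d axis at each q, by central finite
#' differences (one-sided at the boundaries). Masked cells propagate NA.
#'
#' @param grid A [phase_grid()] (e.g. coordination number n over (q, d)).
#' @return A `phase_grid` of chi.
#' @export
susceptibility_chi <- function(grid) {
  stopifnot(inherits(grid, "phase_grid"))
  if (length(grid$d) < 3L) stop("need at least 3 d levels")
  chi <- t(apply(grid$values, 1L, function(row) finite_diff(grid$d, row)))
  phase_grid(grid$q, grid$d, chi, name = paste0("chi(", grid$name, ")"))
}

#' Structural transformation line: maximal |dn/dq|
#'
#' For each d, the crossover charge q_c is the location of the maximal
#' magnitude of the finite-difference derivative of the observable
#' (coordination number) with respect to q, refined by a 3-point parabola
#' on |dn/dq|. A d column whose derivative has no interior maximum (flat
#' or strictly linear observable) is flagged with NA.
#'
#' @param grid A [phase_grid()] of n over (q, d).
#' @param smooth Optional 3-point moving-average smoothing of the
#'   derivative before locating the maximum (default FALSE).
#' @return Data frame of class `crossover_line` with columns `d`, `q_c`
#'   (NA where flagged), and `max_deriv`.
#' @export
transformation_line <- function(grid, smooth = FALSE) {
  stopifnot(inherits(grid, "phase_grid"))
  if (length(grid$q) < 3L) stop("need at least 3 q levels")
  out <- data.frame(d = grid$d, q_c = NA_real_, max_deriv = NA_real_)
  for (j in seq_along(grid$d)) {
    dn <- abs(finite_diff(grid$q, grid$values[, j]))
    if (smooth && length(dn) >= 3L)
      dn <- stats::filter(dn, rep(1 / 3, 3), sides = 2)
    ok <- which(is.finite(dn))
    if (length(ok) < 3L) next
    i <- ok[which.max(dn[ok])]
    # require an interior maximum: strictly above at least one neighbour
    # and not an endpoint of the finite part
    if (i <= min(ok) || i >= max(ok)) next
    if (!(dn[i] > dn[i - 1L] || dn[i] > dn[i + 1L])) next
    if (abs(dn[i] - dn[i - 1L]) < 1e-12 && abs(dn[i] - dn[i + 1L]) < 1e-12)
      next  # flat derivative: no unique maximum
    out$q_c[j] <- parabolic_vertex(grid$q, as.numeric(dn), i)
    out$max_deriv[j] <- dn[i]
  }
  class(out) <- c("crossover_line", "data.frame")
  out
}

#' Hydrogen-bond crossover length lambda_HB
#'
#' For each charge level q, the ion-water distance at which the ion-water
#' interaction magnitude equals the bulk hydrogen-bond energy:
#' dE_ion_water(d = lambda_HB(q)) = E_hbond. The root is found by
#' monotone linear interpolation between the bracketing grid cells; band
#' edges are the roots at E_hbond +/- band (the thermal-fluctuation band
#' of the hydrogen-bond energy). Charges with no bracketing sign change
#' are flagged NA.
#'
#' @param dE_grid A [phase_grid()] of dE_ion_water (kJ/mol, magnitude)
#'   over (q, d), monotone in d at each q over the bracketing range.
#' @param E_hbond Bulk hydrogen-bond energy magnitude (kJ/mol).
#' @param band Half-width of the thermal band (kJ/mol, default 0).
#' @return Data frame of class `crossover_line`: `q`, `lambda`,
#'   `lambda_lo`, `lambda_hi`.
#' @export
#' @examples
#' qs <- seq(0.5, 2, by = 0.5); ds <- seq(1.5, 4, by = 0.1)
#' dE <- outer(qs, ds, function(q, d) 50 * q / d)
#' lambda_hb(phase_grid(qs, ds, dE), 20)$lambda  # 2.5 at q = 1
lambda_hb <- function(dE_grid, E_hbond, band = 0) {
  stopifnot(inherits(dE_grid, "phase_grid"))
  root_at <- function(vals, level) {
    ok <- which(is.finite(vals))
    if (length(ok) < 2L) return(NA_real_)
    x <- dE_grid$d[ok]; y <- vals[ok] - level
    s <- which(y[-1] * y[-length(y)] <= 0 &
                 (y[-1] != 0 | y[-length(y)] != 0))
    if (!length(s)) {
      if (any(y == 0)) return(x[which(y == 0)[1]])
      return(NA_real_)
    }
    i <- s[1]
    if (y[i] == 0) return(x[i])
    x[i] + (x[i + 1L] - x[i]) * (-y[i]) / (y[i + 1L] - y[i])
  }
  out <- data.frame(q = dE_grid$q,
                    lambda = vapply(seq_along(dE_grid$q), function(i)
                      root_at(dE_grid$values[i, ], E_hbond), numeric(1)),
                    lambda_lo = vapply(seq_along(dE_grid$q), function(i)
                      root_at(dE_grid$values[i, ], E_hbond + band),
                      numeric(1)),
                    lambda_hi = vapply(seq_along(dE_grid$q), function(i)
                      root_at(dE_grid$values[i, ], E_hbond - band),
                      numeric(1)))
  class(out) <- c("crossover_line", "data.frame")
  out
}

#' Level-set contour of a surface or a ratio of surfaces
#'
#' Marching-squares contour (linear interpolation on grid edges) of
#' gridA / gridB at the given level (gridB may be a scalar or omitted,
#' giving an iso-value contour of gridA). An everywhere one-sided surface
#' yields an empty contour, which is a valid result.
#'
#' @param gridA A [phase_grid()].
#' @param gridB A [phase_grid()] on the same axes, a scalar, or NULL.
#' @param level Contour level (default 1, the crossover condition
#'   A = B).
#' @return A list of class `contour_set`; each element is a data frame
#'   with columns `q`, `d` describing one connected polyline.
#' @export
crossover_contour <- function(gridA, gridB = NULL, level = 1) {
  stopifnot(inherits(gridA, "phase_grid"))
  z <- gridA$values
  if (!is.null(gridB)) {
    if (inherits(gridB, "phase_grid")) {
      if (!isTRUE(all.equal(gridA$q, gridB$q)) ||
          !isTRUE(all.equal(gridA$d, gridB$d)))
        stop("grids must share axes")
      z <- z / gridB$values
    } else {
      z <- z / as.numeric(gridB)
    }
  }
  cl <- grDevices::contourLines(x = gridA$q, y = gridA$d, z = z,
                                levels = level)
  out <- lapply(cl, function(seg) data.frame(q = seg$x, d = seg$y))
  class(out) <- "contour_set"
  out
}
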