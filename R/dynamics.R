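# Kinetic observables: intermittent residence correlation with
# stretched-exponential fits, shell-conditioned mean-squared displacement
# and local diffusion, the Rosenfeld-like entropy scaling, and the
# Jones-Dole viscosity fit.

# shell membership indicator matrix: waters x frames, TRUE when within r1
# of the given ion (minimum image)
membership_matrix <- function(frames, r1, ion = 1L) {
  n_w <- n_waters(frames[[1]])
  M <- matrix(FALSE, n_w, length(frames))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    ctr <- as.numeric(fr$ions[ion, c("x", "y", "z")])
    dsp <- to_xyz(min_image_displacement(ctr, water_oxygens(fr), fr$box))
    M[, k] <- sqrt(rowSums(dsp^2)) <= r1
  }
  M
}

#' Intermittent residence correlation of shell water
#'
#' P(t) = <p(t) p(0)> / <p(0)> with p(t) = 1 when a water lies within r1
#' of the ion at time t (re-entries count as present: the indicator is
#' intermittent, not continuous). Averaged over waters, ions and multiple
#' time origins.
#'
#' @param traj A [trajectory()].
#' @param r1 Shell radius in A (first minimum of g(r)), or a
#'   `shell_assignment`.
#' @param ions Ion indices to average over (default all).
#' @param origin_stride Use every `origin_stride`-th frame as a time
#'   origin (default 1).
#' @param max_lag Largest lag in frames (default half the trajectory).
#' @return A list of class `correlation_series` with `t` (ps), `P`,
#'   `origins` (origin count per lag).
#' @export
residence_correlation <- function(traj, r1, ions = NULL, origin_stride = 1L,
                                  max_lag = NULL) {
  frames <- as_frames(traj)
  Tn <- length(frames)
  if (Tn < 2L) stop("need at least 2 frames")
  if (inherits(r1, "shell_assignment")) r1 <- r1$r1
  if (r1 <= 0) stop("r1 must be positive")
  if (is.null(ions)) ions <- seq_len(nrow(frames[[1]]$ions))
  if (is.null(max_lag)) max_lag <- floor((Tn - 1L) / 2)
  max_lag <- min(max_lag, Tn - 1L)
  dt <- if (inherits(traj, "trajectory")) traj$dt else
    frames[[2]]$time - frames[[1]]$time
  num <- numeric(max_lag + 1L)
  den <- numeric(max_lag + 1L)
  origins <- integer(max_lag + 1L)
  any_occ <- FALSE
  for (ion in ions) {
    M <- membership_matrix(frames, r1, ion)
    if (any(M)) any_occ <- TRUE
    for (lag in 0:max_lag) {
      t0 <- seq(1L, Tn - lag, by = origin_stride)
      num[lag + 1L] <- num[lag + 1L] +
        sum(M[, t0, drop = FALSE] & M[, t0 + lag, drop = FALSE])
      den[lag + 1L] <- den[lag + 1L] + sum(M[, t0, drop = FALSE])
      origins[lag + 1L] <- origins[lag + 1L] + length(t0)
    }
  }
  if (!any_occ) stop("no water ever inside r1 for any selected ion")
  structure(list(t = (0:max_lag) * dt,
                 P = ifelse(den > 0, num / den, NA_real_),
                 origins = origins),
            class = "correlation_series")
}

#' Fit a stretched exponential to a correlation series
#'
#' Nonlinear least squares of P(t) = P0 exp(-(t / tau_res)^beta) on the
#' points with P above `floor`, by Levenberg-Marquardt. Initial guesses:
#' P0 = 1, tau from the 1/e crossing, beta = 1. beta is constrained to
#' (0, 2].
#'
#' @param series A `correlation_series` (from [residence_correlation()] or
#'   [stretched_occupancy()]).
#' @param floor Discard points with P <= floor (default 0.01).
#' @param fix_p0 Fix P0 at 1 instead of fitting it (default FALSE).
#' @return List of class `stretched_exp_fit`: `P0`, `tau_res` (ps),
#'   `beta`, `resid_norm`, `n_points`, `window` (time range used).
#' @export
#' @examples
#' s <- stretched_occupancy(10, 0.8, seq(0, 60, by = 0.5))
#' fit_stretched_exp(s)$tau_res
fit_stretched_exp <- function(series, floor = 0.01, fix_p0 = FALSE) {
  keep <- is.finite(series$P) & series$P > floor
  t <- series$t[keep]; P <- series$P[keep]
  if (sum(keep) < 4L) stop("fewer than 4 points above the fit floor")
  tau0 <- {
    below <- which(P < exp(-1))
    if (length(below)) t[below[1]] else max(t[t > 0], 1)
  }
  if (tau0 <= 0) tau0 <- max(t) / 2
  df <- data.frame(t = t, P = P)
  fit <- if (fix_p0) {
    minpack.lm::nlsLM(P ~ exp(-(t / tau)^beta), data = df,
                      start = list(tau = tau0, beta = 1),
                      lower = c(1e-8, 1e-3), upper = c(Inf, 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(P ~ P0 * exp(-(t / tau)^beta), data = df,
                      start = list(P0 = 1, tau = tau0, beta = 1),
                      lower = c(1e-8, 1e-8, 1e-3), upper = c(2, Inf, 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(P0 = if (fix_p0) 1 else unname(cf["P0"]),
                 tau_res = unname(cf["tau"]), beta = unname(cf["beta"]),
                 resid_norm = sqrt(sum(stats::resid(fit)^2)),
                 n_points = length(t), window = range(t)),
            class = "stretched_exp_fit")
}

# minimum-image unwrapped coordinates: cumulative sum of per-frame
# minimum-image increments (plain differences for non-periodic boxes)
unwrap_positions <- function(frames) {
  n_w <- n_waters(frames[[1]])
  Tn <- length(frames)
  out <- array(0, dim = c(n_w, 3, Tn))
  prev <- water_oxygens(frames[[1]])
  out[, , 1] <- prev
  for (k in 2:Tn) {
    cur <- water_oxygens(frames[[k]])
    inc <- to_xyz(min_image_displacement(prev, cur, frames[[k]]$box))
    out[, , k] <- out[, , k - 1L] + inc
    prev <- cur
  }
  out
}

#' Shell-conditioned mean-squared displacement
#'
#' MSD(t) of the waters that are inside the ion's first shell (within r1)
#' at the time origin, averaged over waters, ions and multiple origins.
#' Displacements are unwrapped by summing minimum-image increments, so
#' periodic wrapping does not fold the walk back.
#'
#' @param traj A [trajectory()].
#' @param shell A `shell_assignment` or numeric r1 (A).
#' @param ions Ion indices (default all).
#' @param origin_stride Frames between origins (default 1).
#' @param max_lag Largest lag in frames (default half the trajectory).
#' @return List of class `msd_series`: `t` (ps), `msd` (A^2),
#'   `n_origins` (observation count per lag).
#' @export
conditioned_msd <- function(traj, shell, ions = NULL, origin_stride = 1L,
                            max_lag = NULL) {
  frames <- as_frames(traj)
  Tn <- length(frames)
  if (Tn < 2L) stop("need at least 2 frames")
  r1 <- if (inherits(shell, "shell_assignment")) shell$r1 else
    as.numeric(shell)
  if (is.null(ions)) ions <- seq_len(nrow(frames[[1]]$ions))
  if (is.null(max_lag)) max_lag <- floor((Tn - 1L) / 2)
  max_lag <- min(max_lag, Tn - 1L)
  dt <- if (inherits(traj, "trajectory")) traj$dt else
    frames[[2]]$time - frames[[1]]$time
  U <- unwrap_positions(frames)
  sums <- numeric(max_lag + 1L)
  cnts <- numeric(max_lag + 1L)
  any_origin <- FALSE
  for (ion in ions) {
    M <- membership_matrix(frames, r1, ion)
    for (t0 in seq(1L, Tn, by = origin_stride)) {
      members <- which(M[, t0])
      if (!length(members)) next
      any_origin <- TRUE
      lmax <- min(max_lag, Tn - t0)
      for (lag in 0:lmax) {
        dx <- U[members, , t0 + lag, drop = FALSE] -
          U[members, , t0, drop = FALSE]
        sums[lag + 1L] <- sums[lag + 1L] + sum(dx^2)
        cnts[lag + 1L] <- cnts[lag + 1L] + length(members)
      }
    }
  }
  if (!any_origin) stop("no origin has any water inside r1")
  structure(list(t = (0:max_lag) * dt,
                 msd = ifelse(cnts > 0, sums / cnts, NA_real_),
                 n_origins = cnts),
            class = "msd_series")
}

#' Local diffusion coefficient from an MSD window
#'
#' Einstein relation MSD = 6 D t, with the least-squares slope taken only
#' over points with `window[1] <= MSD <= window[2]` (default 8-16 A^2):
#' the lower bound keeps the fit in the linear regime, the upper bound
#' keeps the tagged waters local to the ion.
#'
#' @param msd An `msd_series`.
#' @param window MSD window in A^2 (default `c(8, 16)`).
#' @return D_1 in A^2/ps.
#' @export
local_diffusion <- function(msd, window = c(8, 16)) {
  keep <- is.finite(msd$msd) & msd$msd >= window[1] & msd$msd <= window[2]
  if (max(msd$msd, na.rm = TRUE) < window[1])
    stop("MSD never reaches the lower window bound ", window[1], " A^2")
  if (sum(keep) < 2L)
    stop("fewer than 2 MSD points inside the window [",
         window[1], ", ", window[2], "] A^2")
  fit <- stats::lm(y ~ t, data = data.frame(t = msd$t[keep],
                                            y = msd$msd[keep]))
  unname(stats::coef(fit)["t"]) / 6
}

#' Rosenfeld-like fit of residence time against entropy
#'
#' Linear regression of ln(tau_res) on s_phi: tau_res = tau0 exp(alpha
#' s_phi). Because s_phi <= 0 and order slows the kinetics, alpha is
#' expected negative.
#'
#' @param s_phi Bond-orientational entropies (unitless).
#' @param tau Residence times (ps), strictly positive.
#' @return List of class `rosenfeld_fit`: `tau0` (ps), `alpha`,
#'   `r_squared`.
#' @export
#' @examples
#' rosenfeld_fit(c(-1, -2, -3), 2 * exp(-3 * c(-1, -2, -3)))
rosenfeld_fit <- function(s_phi, tau) {
  if (length(s_phi) != length(tau)) stop("s_phi and tau lengths differ")
  if (length(s_phi) < 2L || length(unique(s_phi)) < 2L)
    stop("need at least 2 distinct s_phi points")
  if (any(tau <= 0)) stop("residence times must be positive")
  fit <- stats::lm(log(tau) ~ s_phi)
  cf <- stats::coef(fit)
  structure(list(tau0 = exp(unname(cf[1])), alpha = unname(cf[2]),
                 r_squared = summary(fit)$r.squared),
            class = "rosenfeld_fit")
}

#' Jones-Dole fit of relative viscosity against concentration
#'
#' Linear least squares of eta/eta0 - 1 on the design (sqrt(c), c):
#' eta(c)/eta0 = 1 + A sqrt(c) + B c. B > 0 marks kosmotropic
#' (structure-making) salts, B < 0 chaotropic (structure-breaking) ones.
#'
#' @param conc Salt concentrations in mol/dm^3, positive, at least two
#'   distinct values.
#' @param eta_rel Relative viscosities eta/eta0.
#' @return List of class `jones_dole_fit`: `A`, `B`.
#' @export
#' @examples
#' cc <- c(0.05, 0.1, 0.2, 0.5)
#' jones_dole_fit(cc, 1 + 0.006 * sqrt(cc) + 0.15 * cc)
jones_dole_fit <- function(conc, eta_rel) {
  if (length(conc) != length(eta_rel)) stop("conc and eta_rel lengths differ")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct concentrations")
  X <- cbind(sqrt(conc), conc)
  fit <- stats::lm.fit(X, eta_rel - 1)
  if (fit$rank < 2L) stop("degenerate concentration design")
  structure(list(A = unname(fit$coefficients[1]),
                 B = unname(fit$coefficients[2])),
            class = "jones_dole_fit")
}
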