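# Hydrogen-bond detection under the Luzar-Chandler geometric criterion and
# shell-resolved hydrogen-bond statistics, including bridging waters.

#' Detect hydrogen bonds in a frame
#'
#' Luzar-Chandler criterion: an ordered donor-acceptor water pair is
#' hydrogen bonded when the minimum-image O-O distance is below `r_max`
#' (3.5 A) and the angle between the donor's O-H bond vector and the
#' donor-O to acceptor-O vector is below `angle_max` (30 degrees). Both
#' donor hydrogens are tested; each (donor, acceptor, hydrogen) triple
#' satisfying the criterion yields one bond record.
#'
#' @param fr A [frame()] whose waters carry explicit hydrogen sites.
#' @param r_max O-O distance cut-off in A.
#' @param angle_max H-O..O angle cut-off in degrees.
#' @return A `data.frame` with columns `donor`, `acceptor`, `hydrogen`
#'   (1 or 2), `distance` (A), `angle` (degrees); zero rows if no bonds.
#' @export
#' @examples
#' fr <- frame(0, NULL, hbond_dimer(2.9), box(30), wrap = FALSE)
#' detect_hbonds(fr)
detect_hbonds <- function(fr, r_max = 3.5, angle_max = 30) {
  stopifnot(inherits(fr, "frame"))
  w <- fr$waters
  if (!inherits(w, "water_set") || is.null(w$H1))
    stop("hydrogen-bond detection needs explicit-site waters with hydrogens")
  n <- nrow(w$O)
  out <- list()
  if (n >= 2L) {
    dmat <- min_image_dist(w$O, w$O, fr$box)
    diag(dmat) <- Inf
    cand <- which(dmat < r_max, arr.ind = TRUE)  # ordered (donor, acceptor)
    if (nrow(cand)) {
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        oo <- min_image_displacement(w$O[i, ], w$O[j, ], fr$box)
        oo_u <- oo / sqrt(sum(oo^2))
        for (h in 1:2) {
          hv <- (if (h == 1) w$H1 else w$H2)[i, ] - w$O[i, ]
          ang <- acos(pmin(pmax(sum(hv * oo_u) / sqrt(sum(hv^2)), -1), 1)) *
            180 / pi
          if (ang < angle_max)
            out[[length(out) + 1L]] <-
              data.frame(donor = i, acceptor = j, hydrogen = h,
                         distance = dmat[i, j], angle = ang)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(donor = integer(0), acceptor = integer(0),
                  hydrogen = integer(0), distance = numeric(0),
                  angle = numeric(0))
}

#' Shell-resolved hydrogen-bond statistics
#'
#' `N_HW_HW` is the mean number of hydrogen bonds per hydrated (first
#' shell) water whose partner lies in the same shell, counting donated and
#' accepted bonds alike, averaged over shell waters, ions and frames. A
#' bridging water is a non-shell water at ion distance in
#' (r1, second_limit] hydrogen-bonded (either role) to at least two
#' distinct first-shell waters; the mean bridging count is reported per
#' ion and, for reference, per shell water.
#'
#' @param traj A [trajectory()] or frame with explicit-site waters.
#' @param shell A `shell_assignment` from [locate_shell()] (with
#'   membership), or a numeric `r1` to compute membership on the fly.
#' @param second_limit Outer radius for bridging candidates (A); defaults
#'   to `r1 + 1.5`.
#' @param ions Ion centre indices (default all).
#' @param r_max,angle_max Hydrogen-bond criterion, see [detect_hbonds()].
#' @return List of class `shell_hbond_stats`: `N_HW_HW`,
#'   `bridging_per_ion`, `bridging_per_shell_water`, `n_frames`.
#' @export
shell_hbond_stats <- function(traj, shell, second_limit = NULL, ions = NULL,
                              r_max = 3.5, angle_max = 30) {
  frames <- as_frames(traj)
  r1 <- if (inherits(shell, "shell_assignment")) shell$r1 else as.numeric(shell)
  if (is.null(second_limit)) second_limit <- r1 + 1.5
  if (is.null(ions)) ions <- seq_len(nrow(frames[[1]]$ions))
  per_water_counts <- numeric(0)
  bridging <- numeric(0)
  for (fr in frames) {
    hb <- detect_hbonds(fr, r_max = r_max, angle_max = angle_max)
    ox <- water_oxygens(fr)
    for (i in ions) {
      ctr <- as.numeric(fr$ions[i, c("x", "y", "z")])
      dsp <- to_xyz(min_image_displacement(ctr, ox, fr$box))
      rr <- sqrt(rowSums(dsp^2))
      members <- which(rr <= r1)
      if (!length(members)) stop("empty hydration shell in a frame")
      in_shell <- hb$donor %in% members & hb$acceptor %in% members
      cnt <- vapply(members, function(m)
        sum(hb$donor[in_shell] == m) + sum(hb$acceptor[in_shell] == m),
        numeric(1))
      per_water_counts <- c(per_water_counts, cnt)
      outer_cand <- which(rr > r1 & rr <= second_limit)
      nb <- 0L
      for (o in outer_cand) {
        partners <- unique(c(hb$acceptor[hb$donor == o],
                             hb$donor[hb$acceptor == o]))
        if (sum(partners %in% members) >= 2L) nb <- nb + 1L
      }
      bridging <- c(bridging, nb)
    }
  }
  structure(list(N_HW_HW = mean(per_water_counts),
                 bridging_per_ion = mean(bridging),
                 bridging_per_shell_water =
                   sum(bridging) / length(per_water_counts),
                 n_frames = length(frames)),
            class = "shell_hbond_stats")
}
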