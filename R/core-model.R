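# Domain containers: periodic box, site groups, rigid waters, frames,
# trajectories. All coordinates in Angstrom, times in ps, charges in e.

#' Periodic cubic simulation box
#'
#' @param edge_length Box edge in Angstrom; must be positive.
#' @param periodic Logical; whether minimum-image wrapping applies.
#' @return An object of class `box`.
#' @export
#' @examples
#' b <- box(20)
box <- function(edge_length, periodic = TRUE) {
  if (!is.numeric(edge_length) || length(edge_length) != 1L ||
      !is.finite(edge_length) || edge_length <= 0)
    stop("box edge_length must be a single positive finite number")
  structure(list(edge_length = as.numeric(edge_length),
                 periodic = isTRUE(periodic)),
            class = "box")
}

#' Charged interaction sites
#'
#' A site group is a plain data frame with columns `x`, `y`, `z` (A),
#' `charge` (e) and `label`. Single ions, ion lists and arbitrary charge
#' groups (e.g. the charged sites of one water) are all site groups.
#'
#' @param position Numeric matrix (n x 3) or length-3 vector of coordinates.
#' @param charge Charges in e, recycled to the number of sites.
#' @param label Species labels, recycled.
#' @return A `data.frame` with columns x, y, z, charge, label.
#' @export
#' @examples
#' ion <- sites(c(0, 0, 0), charge = 1, label = "NA")
sites <- function(position, charge = 0, label = "X") {
  m <- to_xyz(position)
  if (any(!is.finite(m))) stop("site coordinates must be finite")
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
             charge = rep_len(as.numeric(charge), nrow(m)),
             label = rep_len(as.character(label), nrow(m)),
             stringsAsFactors = FALSE)
}

# coerce vector/matrix input to an n x 3 numeric matrix
to_xyz <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("expected a length-3 coordinate vector")
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Rigid explicit-site water set
#'
#' Holds n rigid waters as parallel coordinate matrices: oxygen, two
#' hydrogens and (optionally) the bisector charge site M. The rigid
#' geometry (O-H distance, H-O-H angle) is validated against `model` to
#' 1e-6 A.
#'
#' @param O,H1,H2 n x 3 coordinate matrices (A).
#' @param M Optional n x 3 matrix for the 4-site charge position.
#' @param model Geometry/charge convention, see [water_model()].
#' @param check Validate rigid geometry (default TRUE).
#' @return An object of class `water_set`.
#' @export
water_set <- function(O, H1, H2, M = NULL, model = water_model(), check = TRUE) {
  O <- to_xyz(O); H1 <- to_xyz(H1); H2 <- to_xyz(H2)
  if (!is.null(M)) M <- to_xyz(M)
  n <- nrow(O)
  if (nrow(H1) != n || nrow(H2) != n || (!is.null(M) && nrow(M) != n))
    stop("water site matrices must have matching row counts")
  w <- structure(list(O = O, H1 = H1, H2 = H2, M = M, model = model),
                 class = "water_set")
  if (check && n > 0L) {
    d1 <- sqrt(rowSums((H1 - O)^2)); d2 <- sqrt(rowSums((H2 - O)^2))
    if (max(abs(c(d1, d2) - model$r_oh)) > 1e-6)
      stop("O-H distances deviate from the rigid geometry by more than 1e-6 A")
  }
  w
}

#' Number of waters in a water set or frame
#' @param w A `water_set`, `point_dipoles` or `frame`.
#' @return Integer count.
#' @export
n_waters <- function(w) {
  if (inherits(w, "frame")) w <- w$waters
  if (is.null(w)) return(0L)
  nrow(w$O %||% w$pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Point-dipole particle set
#'
#' Reduced water representation used by the toy shell simulator: a position
#' plus a unit dipole axis and a common dipole moment.
#'
#' @param pos n x 3 positions (A).
#' @param axis n x 3 unit dipole directions (renormalized on input).
#' @param moment Dipole moment in e*A (default 0.48 e*A, about 2.305 D,
#'   the bulk moment of the rigid water model).
#' @return An object of class `point_dipoles`.
#' @export
point_dipoles <- function(pos, axis, moment = 0.48) {
  pos <- to_xyz(pos); axis <- to_xyz(axis)
  if (nrow(pos) != nrow(axis)) stop("pos and axis must have matching rows")
  nrm <- sqrt(rowSums(axis^2))
  if (any(nrm == 0)) stop("dipole axes must be non-zero")
  structure(list(pos = pos, axis = axis / nrm, moment = as.numeric(moment)),
            class = "point_dipoles")
}

#' Oxygen (or particle) positions of a water representation
#' @param w A `water_set`, `point_dipoles` or `frame`.
#' @return n x 3 matrix of positions.
#' @export
water_oxygens <- function(w) {
  if (inherits(w, "frame")) w <- w$waters
  if (is.null(w)) return(matrix(numeric(0), 0, 3))
  if (inherits(w, "point_dipoles")) w$pos else w$O
}

#' Water dipole vectors
#'
#' Charge-weighted first moment of each water about its oxygen,
#' p = sum_i q_i (r_i - r_O). For point-dipole sets this is moment * axis.
#'
#' @param w A `water_set`, `point_dipoles` or `frame`.
#' @return n x 3 matrix of dipole vectors in e*A.
#' @export
#' @examples
#' w <- toy_water_box(3, box(18), seed = 1)$waters
#' water_dipole(w)
water_dipole <- function(w) {
  if (inherits(w, "frame")) w <- w$waters
  if (inherits(w, "point_dipoles")) return(w$axis * w$moment)
  if (!inherits(w, "water_set")) stop("waters must carry dipole information")
  if (is.null(w$H1) || is.null(w$H2)) stop("water set lacks hydrogen sites")
  md <- w$model
  p <- md$q_h * (w$H1 - w$O) + md$q_h * (w$H2 - w$O)
  if (!is.null(w$M)) p <- p + md$q_m * (w$M - w$O)
  p
}

#' Single configuration of ions and waters in a box
#'
#' @param time Frame time in ps.
#' @param ions Site group (see [sites()]) or NULL.
#' @param waters A `water_set`, `point_dipoles` or NULL.
#' @param box A [box()].
#' @param wrap Wrap all positions into `[0, L)` for periodic boxes
#'   (default TRUE).
#' @return An object of class `frame`.
#' @export
frame <- function(time, ions, waters, box, wrap = TRUE) {
  stopifnot(inherits(box, "box"))
  fr <- structure(list(time = as.numeric(time), ions = ions,
                       waters = waters, box = box),
                  class = "frame")
  if (wrap && box$periodic) fr <- wrap_frame(fr)
  fr
}

#' Wrap coordinates into the primary cell
#'
#' Positions are reduced modulo the edge length into `[0, L)`. Waters are
#' wrapped molecule-wise on the oxygen so rigid geometry is never broken.
#'
#' @param fr A `frame`.
#' @return The wrapped frame.
#' @export
wrap_frame <- function(fr) {
  L <- fr$box$edge_length
  if (!fr$box$periodic) return(fr)
  wrapm <- function(m) m - floor(m / L) * L
  if (!is.null(fr$ions)) {
    m <- wrapm(as.matrix(fr$ions[, c("x", "y", "z")]))
    fr$ions$x <- m[, 1]; fr$ions$y <- m[, 2]; fr$ions$z <- m[, 3]
  }
  w <- fr$waters
  if (inherits(w, "point_dipoles")) {
    w$pos <- wrapm(w$pos)
  } else if (inherits(w, "water_set")) {
    shift <- wrapm(w$O) - w$O
    w$O <- w$O + shift; w$H1 <- w$H1 + shift; w$H2 <- w$H2 + shift
    if (!is.null(w$M)) w$M <- w$M + shift
  }
  fr$waters <- w
  fr
}

#' Ordered, uniformly spaced sequence of frames
#'
#' @param frames List of [frame()] objects with strictly increasing,
#'   uniformly spaced times.
#' @param dt Frame spacing in ps; inferred from the times when omitted.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, dt = NULL) {
  if (length(frames) == 0L) stop("trajectory needs at least one frame")
  tt <- vapply(frames, function(f) f$time, numeric(1))
  if (length(tt) > 1L) {
    d <- diff(tt)
    if (any(d <= 0)) stop("frame times must be strictly increasing")
    if (max(d) - min(d) > 1e-6 * max(d, 1))
      stop("frame times must be uniformly spaced")
    if (is.null(dt)) dt <- d[1]
  } else if (is.null(dt)) dt <- 0
  structure(list(frames = frames, dt = dt), class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
print.trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("trajectory: %d frames, dt = %g ps, box L = %g A, %d ions, %d waters\n",
              length(x$frames), x$dt, f1$box$edge_length,
              if (is.null(f1$ions)) 0L else nrow(f1$ions), n_waters(f1)))
  invisible(x)
}

#' Minimum-image displacement in a periodic cubic box
#'
#' Returns the displacement b - a with each Cartesian component reduced to
#' the nearest periodic image, i.e. into `[-L/2, L/2)`. Accepts single
#' vectors or n x 3 matrices (recycled against each other row-wise).
#' For non-periodic boxes the plain difference is returned.
#'
#' @param a,b Length-3 vectors or n x 3 matrices (A).
#' @param box A [box()].
#' @return Displacement matrix/vector of the same shape as the broadcast
#'   inputs.
#' @export
#' @examples
#' min_image_displacement(c(1, 0, 0), c(9, 0, 0), box(10))  # (-2, 0, 0)
min_image_displacement <- function(a, b, box) {
  stopifnot(inherits(box, "box"))
  a <- to_xyz(a); b <- to_xyz(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  d <- b - a
  if (box$periodic) {
    L <- box$edge_length
    d <- d - round(d / L) * L
    # round() maps exactly +L/2 to +L/2; fold onto [-L/2, L/2)
    d[d >= L / 2] <- d[d >= L / 2] - L
  }
  if (n == 1L) drop(d) else d
}

# pairwise minimum-image distances between rows of a (n x 3) and b (m x 3)
min_image_dist <- function(a, b, box) {
  a <- to_xyz(a); b <- to_xyz(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    d <- min_image_displacement(a[i, ], b, box)
    d <- to_xyz(d)
    out[i, ] <- sqrt(rowSums(d^2))
  }
  out
}
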