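# Plain-text trajectory I/O: Gromacs GRO (fixed columns, nm) and a
# multi-frame XYZ dialect whose comment line carries "box=<L> t=<time>"
# key-value pairs. Velocities in GRO files are ignored; point-dipole
# particle sets round-trip through XYZ only (three extra dipole columns).

#' Read a trajectory from a GRO or multi-frame XYZ file
#'
#' GRO files follow the fixed-column Gromacs convention (coordinates in nm,
#' converted to Angstrom on read); concatenated frames are supported, with
#' the frame time taken from a `t=` token on the title line. The XYZ
#' dialect stores one frame per block, coordinates in Angstrom, and a
#' comment line of `key=value` pairs (`box`, `t`, optionally `periodic=0`).
#' Waters are reconstructed by grouping consecutive `OW`/`HW1`/`HW2`
#' (/`MW`) atoms; `DP` records with six coordinate columns are read as
#' point dipoles; any other atom is an ion site (charge unknown from either
#' format, stored as 0).
#'
#' @param path File to read.
#' @param dialect `"gro"` or `"xyz"`.
#' @param model Water convention for reconstructed waters, see
#'   [water_model()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, dialect = c("gro", "xyz"),
                            model = water_model()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  frames <- switch(dialect,
                   gro = parse_gro(lines, model),
                   xyz = parse_xyz(lines, model))
  trajectory(frames)
}

#' Write a trajectory to a GRO or multi-frame XYZ file
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @param dialect `"gro"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("gro", "xyz")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(traj, "trajectory"))
  out <- unlist(lapply(traj$frames, function(fr)
    switch(dialect, gro = format_gro(fr), xyz = format_xyz(fr))))
  writeLines(out, path)
  invisible(path)
}

# ---- record <-> frame assembly -------------------------------------------

# records: data.frame(name, x, y, z [, mx, my, mz]) in Angstrom
records_to_frame <- function(rec, time, bx, model) {
  if (!is.null(rec$mx) && any(!is.na(rec$mx))) {
    dp <- rec[!is.na(rec$mx), , drop = FALSE]
    mom <- sqrt(dp$mx^2 + dp$my^2 + dp$mz^2)
    w <- point_dipoles(cbind(dp$x, dp$y, dp$z), cbind(dp$mx, dp$my, dp$mz),
                       moment = if (nrow(dp)) mom[1] else 0.48)
    ion <- rec[is.na(rec$mx), , drop = FALSE]
  } else {
    is_wat <- rec$name %in% c("OW", "HW1", "HW2", "MW")
    wat <- rec[is_wat, , drop = FALSE]
    ion <- rec[!is_wat, , drop = FALSE]
    w <- NULL
    if (nrow(wat)) {
      o_idx <- which(wat$name == "OW")
      grab <- function(nm) {
        idx <- vapply(o_idx, function(i) {
          j <- which(wat$name[seq(i, min(i + 3, nrow(wat)))] == nm)
          if (!length(j)) stop("malformed water group: missing ", nm)
          i + j[1] - 1L
        }, integer(1))
        as.matrix(wat[idx, c("x", "y", "z")])
      }
      has_m <- any(wat$name == "MW")
      w <- water_set(as.matrix(wat[o_idx, c("x", "y", "z")]),
                     grab("HW1"), grab("HW2"),
                     M = if (has_m) grab("MW") else NULL,
                     model = model, check = FALSE)
    }
  }
  ions <- if (nrow(ion)) sites(as.matrix(ion[, c("x", "y", "z")]),
                               charge = 0, label = ion$name) else NULL
  frame(time, ions, w, bx, wrap = FALSE)
}

frame_to_records <- function(fr) {
  rec <- NULL
  if (!is.null(fr$ions) && nrow(fr$ions))
    rec <- data.frame(name = fr$ions$label, x = fr$ions$x, y = fr$ions$y,
                      z = fr$ions$z, stringsAsFactors = FALSE)
  w <- fr$waters
  if (inherits(w, "point_dipoles")) {
    m <- w$axis * w$moment
    dp <- data.frame(name = "DP", x = w$pos[, 1], y = w$pos[, 2],
                     z = w$pos[, 3], mx = m[, 1], my = m[, 2], mz = m[, 3],
                     stringsAsFactors = FALSE)
    if (!is.null(rec)) { rec[c("mx", "my", "mz")] <- NA_real_ }
    rec <- rbind(rec, dp)
  } else if (inherits(w, "water_set")) {
    n <- nrow(w$O)
    names_per <- c("OW", "HW1", "HW2", if (!is.null(w$M)) "MW")
    per <- length(names_per)
    coords <- matrix(0, n * per, 3)
    for (i in seq_len(n)) {
      blk <- rbind(w$O[i, ], w$H1[i, ], w$H2[i, ],
                   if (!is.null(w$M)) w$M[i, ])
      coords[(i - 1L) * per + seq_len(per), ] <- blk
    }
    wrec <- data.frame(name = rep(names_per, n), x = coords[, 1],
                       y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE)
    if (!is.null(rec) && !is.null(rec$mx)) wrec[c("mx", "my", "mz")] <- NA_real_
    rec <- rbind(rec, wrec)
  }
  if (is.null(rec)) stop("frame has neither ions nor waters to write")
  rec
}

# ---- GRO ------------------------------------------------------------------

format_gro <- function(fr) {
  rec <- frame_to_records(fr)
  if (!is.null(rec$mx)) stop("point-dipole trajectories require the xyz dialect")
  n <- nrow(rec)
  # residue bookkeeping: OW opens a new SOL residue, others are 1-atom residues
  resname <- ifelse(rec$name %in% c("OW", "HW1", "HW2", "MW"), "SOL", rec$name)
  new_res <- resname != "SOL" | rec$name == "OW"
  resid <- cumsum(new_res)
  lines <- sprintf("%5d%-5s%5s%5d%8.4f%8.4f%8.4f",
                   resid %% 100000L, substr(resname, 1, 5),
                   substr(rec$name, 1, 5), seq_len(n) %% 100000L,
                   rec$x / 10, rec$y / 10, rec$z / 10)
  L <- fr$box$edge_length / 10
  c(sprintf("hydrashell frame t= %.6f", fr$time),
    sprintf("%5d", n), lines, sprintf("%10.5f%10.5f%10.5f", L, L, L))
}

parse_gro <- function(lines, model) {
  frames <- list(); i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file: missing atom count")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0) stop("malformed GRO atom-count line: ", lines[i + 1L])
    if (i + 1L + nat + 1L > length(lines))
      stop("malformed GRO file: expected ", nat, " atom lines plus a box line")
    atom_lines <- lines[i + 1L + seq_len(nat)]
    name <- trimws(substr(atom_lines, 11, 15))
    rest <- lapply(strsplit(trimws(substr(atom_lines, 21, 1000L)), "\\s+"),
                   as.numeric)
    if (any(vapply(rest, length, integer(1)) < 3L) ||
        any(vapply(rest, function(v) any(is.na(v[1:3])), logical(1))))
      stop("malformed GRO atom line: could not parse three coordinates")
    xyz <- do.call(rbind, lapply(rest, `[`, 1:3)) * 10  # nm -> A
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                                 "\\s+")[[1]]))
    if (length(boxv) < 3L || any(is.na(boxv[1:3])))
      stop("malformed GRO box line")
    if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-12))
      stop("non-cubic (triclinic) GRO box is not supported")
    if (max(boxv[1:3]) - min(boxv[1:3]) > 1e-9)
      stop("non-cubic GRO box: edges differ")
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2L) as.numeric(tm[2]) else k * 1.0
    rec <- data.frame(name = name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
    k <- k + 1L
    frames[[k]] <- records_to_frame(rec, time, box(boxv[1] * 10), model)
    i <- i + nat + 3L
  }
  if (!length(frames)) stop("no frames found in GRO file")
  frames
}

# ---- XYZ ------------------------------------------------------------------

format_xyz <- function(fr) {
  rec <- frame_to_records(fr)
  per <- if (!is.null(fr$box$periodic) && !fr$box$periodic) " periodic=0" else ""
  body <- if (!is.null(rec$mx)) {
    ifelse(is.na(rec$mx),
           sprintf("%-4s %14.6f %14.6f %14.6f", rec$name, rec$x, rec$y, rec$z),
           sprintf("%-4s %14.6f %14.6f %14.6f %14.8f %14.8f %14.8f",
                   rec$name, rec$x, rec$y, rec$z, rec$mx, rec$my, rec$mz))
  } else {
    sprintf("%-4s %14.6f %14.6f %14.6f", rec$name, rec$x, rec$y, rec$z)
  }
  c(sprintf("%d", nrow(rec)),
    sprintf("box=%.6f t=%.6f%s", fr$box$edge_length, fr$time, per), body)
}

parse_xyz <- function(lines, model) {
  frames <- list(); i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) stop("malformed XYZ atom-count line: ", lines[i])
    if (i + 1L + nat > length(lines))
      stop("malformed XYZ file: expected ", nat, " atom lines")
    comment <- lines[i + 1L]
    kv <- parse_keyvals(comment)
    if (is.na(kv[["box"]])) stop("XYZ comment line lacks a box=<L> entry")
    bx <- box(kv[["box"]], periodic = is.na(kv[["periodic"]]) ||
                kv[["periodic"]] != 0)
    time <- if (!is.na(kv[["t"]])) kv[["t"]] else k * 1.0
    toks <- strsplit(trimws(lines[i + 1L + seq_len(nat)]), "\\s+")
    nf <- vapply(toks, length, integer(1))
    if (any(nf < 4L)) stop("malformed XYZ atom line: fewer than 4 fields")
    name <- vapply(toks, `[`, character(1), 1L)
    num <- lapply(toks, function(v) suppressWarnings(as.numeric(v[-1])))
    if (any(vapply(num, function(v) any(is.na(v[1:3])), logical(1))))
      stop("malformed XYZ coordinates")
    rec <- data.frame(name = name,
                      x = vapply(num, `[`, numeric(1), 1L),
                      y = vapply(num, `[`, numeric(1), 2L),
                      z = vapply(num, `[`, numeric(1), 3L),
                      stringsAsFactors = FALSE)
    if (any(nf >= 7L)) {
      rec$mx <- rec$my <- rec$mz <- NA_real_
      j <- which(nf >= 7L)
      rec$mx[j] <- vapply(num[j], `[`, numeric(1), 4L)
      rec$my[j] <- vapply(num[j], `[`, numeric(1), 5L)
      rec$mz[j] <- vapply(num[j], `[`, numeric(1), 6L)
    }
    k <- k + 1L
    frames[[k]] <- records_to_frame(rec, time, bx, model)
    i <- i + nat + 2L
  }
  if (!length(frames)) stop("no frames found in XYZ file")
  frames
}

parse_keyvals <- function(s) {
  out <- c(box = NA_real_, t = NA_real_, periodic = NA_real_)
  m <- regmatches(s, gregexpr("([A-Za-z_]+)=([-0-9.eE+]+)", s))[[1]]
  for (tok in m) {
    p <- strsplit(tok, "=")[[1]]
    if (p[1] %in% names(out)) out[p[1]] <- as.numeric(p[2])
  }
  out
}
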