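# TrajectoryWindow: static atom table + long tibble of per-frame coordinates
# (and optional velocities), with box and timestep. The substrate of every
# ensemble average.

#' Construct a trajectory window
#'
#' @param atoms an `ha_structure` (or its atom tibble) describing the
#'   topology: names, groups, charges, masses. Coordinates in `atoms` are
#'   ignored in favor of `frames`.
#' @param frames long tibble with columns `frame` (1-based integer), `atom`,
#'   `x`, `y`, `z` (angstrom) and optionally `vx`, `vy`, `vz` (angstrom/ps).
#' @param box numeric 3-vector, angstrom. Defaults to the box of `atoms`.
#' @param dt time between frames, ps.
#' @return object of class `ha_trajectory`: list with elements `atoms`,
#'   `frames`, `box`, `dt`, `n_frames`.
#' @export
trajectory_window <- function(atoms, frames, box = NULL, dt = 1) {
  box <- box %||% attr(atoms, "box")
  frames <- as_tibble(frames)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(frames))) {
    abort("frames needs columns frame, atom, x, y, z", class = "ha_format_error")
  }
  at <- as_tibble(atoms)
  n_at <- nrow(at)
  counts <- table(frames$frame)
  if (length(unique(as.integer(counts))) > 1 || any(counts != n_at)) {
    bad <- names(counts)[counts != n_at][1]
    abort(paste0("frame ", bad %||% "?", ": atom count does not match topology (",
                 n_at, " atoms expected)"), class = "ha_format_error")
  }
  obj <- list(atoms = at, frames = frames, box = as.numeric(box),
              dt = dt, n_frames = length(counts))
  class(obj) <- "ha_trajectory"
  attr(obj, "box") <- obj$box
  obj
}

#' @export
print.ha_trajectory <- function(x, ...) {
  cat(sprintf("<ha_trajectory> %d frames x %d atoms, dt = %g ps, box %.1f x %.1f x %.1f A%s\n",
              x$n_frames, nrow(x$atoms), x$dt, x$box[1], x$box[2], x$box[3],
              if (has_velocities(x)) ", velocities" else ""))
  invisible(x)
}

has_velocities <- function(window) {
  all(c("vx", "vy", "vz") %in% names(window$frames))
}

#' Wrap a single structure as a one-frame trajectory
#'
#' Every ensemble-average analysis takes an `ha_trajectory`; this lifts one
#' configuration (with velocities when present as `vx`,`vy`,`vz` columns)
#' into a single-frame window.
#'
#' @param structure an `ha_structure`.
#' @param dt nominal timestep, ps.
#' @return an `ha_trajectory` with one frame.
#' @export
as_trajectory <- function(structure, dt = 1) {
  fr <- tibble(frame = 1L, atom = structure$atom,
               x = structure$x, y = structure$y, z = structure$z)
  if (all(c("vx", "vy", "vz") %in% names(structure))) {
    fr$vx <- structure$vx; fr$vy <- structure$vy; fr$vz <- structure$vz
  }
  trajectory_window(structure, fr, box = ha_box(structure), dt = dt)
}

# coordinates of frame i as n x 3 matrix ordered by atom id
frame_coords <- function(window, i) {
  fr <- window$frames[window$frames$frame == i, ]
  fr <- fr[order(fr$atom), ]
  as.matrix(fr[, c("x", "y", "z")])
}

# velocities of all frames for a set of atom ids: list of (n_frames x 3k) matrix
# columns grouped per atom (vx1, vy1, vz1, vx2, ...)
velocity_matrix <- function(window, atom_ids) {
  if (!has_velocities(window)) {
    abort("trajectory has no velocities", class = "ha_capability_error")
  }
  fr <- window$frames[window$frames$atom %in% atom_ids, ]
  fr <- fr[order(fr$frame, fr$atom), ]
  n_at <- length(atom_ids)
  n_fr <- nrow(fr) / n_at
  v <- array(NA_real_, dim = c(n_at, 3, n_fr))
  v[, 1, ] <- fr$vx; v[, 2, ] <- fr$vy; v[, 3, ] <- fr$vz
  # -> n_fr x (3 * n_at) with per-atom (vx, vy, vz) triplets contiguous
  t(matrix(aperm(v, c(2, 1, 3)), nrow = 3 * n_at, ncol = n_fr))
}

frame_indices <- function(window) sort(unique(window$frames$frame))

#' Unwrap z coordinates across periodic images
#'
#' With periodic boundary conditions along the helix axis the raw z
#' coordinate jumps by the box length when an atom crosses the boundary.
#' This rebuilds a continuous per-atom z across frames from minimum-image
#' increments, leaving x and y untouched.
#'
#' @param window an `ha_trajectory`.
#' @return an `ha_trajectory` with continuous `z`.
#' @export
unwrap_z <- function(window) {
  Lz <- window$box[3]
  fr <- window$frames %>% arrange(.data$atom, .data$frame)
  z <- fr$z
  atom <- fr$atom
  dz <- c(0, diff(z))
  newatom <- c(TRUE, diff(atom) != 0)
  dz[newatom] <- 0
  step <- min_image(dz, Lz)
  if (any(abs(step[!newatom]) > Lz / 2 - 1e-9)) {
    flagged <- unique(atom[!newatom & abs(step) > Lz / 2 - 1e-9])
    warn(paste0("ambiguous z displacement > Lz/2 for atoms: ",
                paste(head(flagged, 10), collapse = ", ")),
         class = "ha_unwrap_ambiguity")
  }
  base <- z[newatom][cumsum(newatom)]
  zun <- base + ave(step, atom, FUN = cumsum)
  fr$z <- zun
  out <- window
  out$frames <- fr %>% arrange(.data$frame, .data$atom)
  out
}
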