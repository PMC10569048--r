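# Geometry helpers shared by every analysis module. Boxes are orthorhombic,
# given as c(Lx, Ly, Lz) in angstrom; minimum-image convention throughout.

# wrap displacement components to (-L/2, L/2]
min_image <- function(d, L) d - L * round(d / L)

# minimum-image displacement matrix between an n x 3 and an m x 3 coordinate set;
# returns n x m distance matrix
min_image_dist <- function(a, b, box) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx * dx + dy * dy + dz * dz)
}

# wrap coordinates into [0, L)
wrap_box <- function(xyz, box) {
  xyz <- as_coord_matrix(xyz)
  for (k in 1:3) xyz[, k] <- xyz[, k] - box[k] * floor(xyz[, k] / box[k])
  xyz
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  matrix(x, ncol = 3)
}

# wrap angle to [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)

# signed wrapped angular difference in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Fit a helix axis by principal-component regression
#'
#' Least-squares straight line through a set of points (typically the
#' phosphate positions of one duplex): the centroid plus the leading
#' principal direction. Used to define the "center of the helix" for
#' cylindrical profiles and the per-frame interhelical distance. The
#' direction is oriented along +z.
#'
#' @param xyz numeric matrix (n x 3) or data frame with `x`,`y`,`z`, angstrom.
#' @return list with `origin` (centroid, 3-vector) and `direction`
#'   (unit 3-vector, positive z component).
#' @export
fit_axis <- function(xyz) {
  xyz <- as_coord_matrix(xyz)
  if (nrow(xyz) < 2) abort("axis fit needs at least 2 points", class = "ha_geometry_error")
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  sv <- svd(cc, nu = 0, nv = 3)
  dir <- sv$v[, 1]
  if (dir[3] < 0) dir <- -dir
  if (abs(dir[3]) < 1e-12) dir[3] <- 0
  list(origin = ctr, direction = dir / sqrt(sum(dir^2)))
}

# perpendicular distance of points to an axis (list from fit_axis)
axis_distance <- function(xyz, axis) {
  xyz <- as_coord_matrix(xyz)
  rel <- sweep(xyz, 2, axis$origin)
  proj <- rel %*% axis$direction
  perp <- rel - proj %*% t(axis$direction)
  sqrt(rowSums(perp^2))
}

# azimuth of points about a z-aligned axis, measured CCW from +x, in [0, 2*pi)
axis_azimuth <- function(xyz, axis) {
  xyz <- as_coord_matrix(xyz)
  rel <- sweep(xyz, 2, axis$origin)
  wrap_angle(atan2(rel[, 2], rel[, 1]))
}
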