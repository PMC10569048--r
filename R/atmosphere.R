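# Ion-atmosphere analyses: time-averaged 3D number/charge density fields,
# cylindrical concentration profiles c(lambda), excess condensed counterions,
# surface-shell charges, RDF and surface distribution functions.

# minimum distance of each point to any reference atom (minimum image),
# chunked to bound memory
surface_distance <- function(points, ref, box, chunk = 2048L) {
  points <- as_coord_matrix(points); ref <- as_coord_matrix(ref)
  n <- nrow(points)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    d <- min_image_dist(points[i:j, , drop = FALSE], ref, box)
    out[i:j] <- apply(d, 1, min)
    i <- j + 1L
  }
  out
}

.positions_of_group <- function(window, group_name) {
  ids <- select_group(window$atoms, group_name)
  fr <- window$frames[window$frames$atom %in% ids, c("frame", "atom", "x", "y", "z")]
  list(ids = ids, frames = fr)
}

#' Time-averaged 3D number density field
#'
#' Average count of a species per voxel divided by the voxel volume, over all
#' frames, on a regular grid spanning the box. The field integrates back to
#' the mean particle count of the species (conservation).
#'
#' @param window an `ha_trajectory`.
#' @param species group name (see [select_group()]), e.g. `"ion:Mg"`.
#' @param spacing voxel edge, angstrom (default 1.0).
#' @return object of class `ha_field`: list with `origin`, `spacing`,
#'   `values` (count/angstrom^3), `box`, `species`, `n_frames`, `kind`.
#' @export
number_density <- function(window, species, spacing = 1.0) {
  .density_field(window, species, spacing, weights = NULL, kind = "number")
}

#' Time-averaged 3D charge density field
#'
#' Like [number_density()] but each particle contributes its partial charge;
#' values are e/angstrom^3.
#'
#' @inheritParams number_density
#' @param species group name, or `"all"` for every charged atom.
#' @export
charge_density <- function(window, species = "all", spacing = 1.0) {
  .density_field(window, species, spacing, weights = "charge", kind = "charge")
}

.density_field <- function(window, species, spacing, weights, kind) {
  if (spacing <= 0) abort("spacing must be positive", class = "ha_domain_error")
  box <- window$box
  ids <- if (identical(species, "all")) window$atoms$atom else select_group(window$atoms, species)
  fr <- window$frames[window$frames$atom %in% ids, ]
  if (nrow(fr) == 0) abort("empty selection", class = "ha_empty_selection")
  dims <- pmax(1L, as.integer(round(box / spacing)))
  sp <- box / dims  # adjust spacing so the grid tiles the box exactly
  if (max(abs(sp - spacing)) > 0.05 * spacing) {
    warn("voxel spacing adjusted to tile the box exactly", class = "ha_grid_adjusted")
  }
  xyz <- wrap_box(as.matrix(fr[, c("x", "y", "z")]), box)
  ix <- pmin(dims[1] - 1L, floor(xyz[, 1] / sp[1]))
  iy <- pmin(dims[2] - 1L, floor(xyz[, 2] / sp[2]))
  iz <- pmin(dims[3] - 1L, floor(xyz[, 3] / sp[3]))
  lin <- 1L + ix + dims[1] * (iy + dims[2] * iz)
  w <- if (is.null(weights)) rep(1, nrow(fr)) else {
    window$atoms$charge[match(fr$atom, window$atoms$atom)]
  }
  acc <- numeric(prod(dims))
  tab <- rowsum(w, lin)
  acc[as.integer(rownames(tab))] <- tab[, 1]
  nf <- window$n_frames
  vox <- prod(sp)
  values <- array(acc / (nf * vox), dim = dims)
  structure(list(origin = c(0, 0, 0), spacing = mean(sp), spacing3 = sp,
                 values = values, box = box, species = species,
                 n_frames = nf, kind = kind),
            class = "ha_field")
}

#' @export
print.ha_field <- function(x, ...) {
  cat(sprintf("<ha_field:%s> %s grid %s, spacing %.3g A, integral %.6g\n",
              x$kind, x$species, paste(dim(x$values), collapse = "x"),
              x$spacing, field_integral(x)))
  invisible(x)
}

#' Integral of a density field over the box
#'
#' Sum of voxel values times voxel volume; for a number density this equals
#' the mean particle count of the species.
#'
#' @param field an `ha_field`.
#' @return scalar.
#' @export
field_integral <- function(field) {
  sum(field$values) * prod(field$spacing3 %||% rep(field$spacing, 3))
}

# per-frame least-squares helix axis from a group (default restrained helix
# phosphates); returns list of axis objects keyed by frame
.frame_axes <- function(window, axis_group = "helix1") {
  ids <- intersect(select_group(window$atoms, axis_group),
                   select_group(window$atoms, "phosphate_backbone", require_atoms = FALSE))
  if (length(ids) == 0) ids <- select_group(window$atoms, axis_group)
  lapply(frame_indices(window), function(i) {
    fr <- window$frames[window$frames$frame == i & window$frames$atom %in% ids, ]
    fit_axis(as.matrix(fr[, c("x", "y", "z")]))
  })
}

#' Cylindrical concentration profile c(lambda)
#'
#' Transforms particle positions to cylindrical shells around the helix axis
#' (least-squares fit through the restrained helix's phosphates, per frame)
#' and reports the species concentration in mol/L per shell, normalized by
#' the exact shell volume pi (lambda_out^2 - lambda_in^2) L.
#'
#' @param window an `ha_trajectory`.
#' @param species group name of the tracked species.
#' @param bin_width shell width, angstrom (default 0.5).
#' @param lambda_max outermost radius, angstrom; defaults to half the
#'   smallest xy box edge.
#' @param axis_group group whose phosphates define the axis (default
#'   `"helix1"`); or pass a fixed axis via `axis`.
#' @param axis optional fixed axis (list with `origin`, `direction`).
#' @return tibble of class `ha_profile` with columns `lambda_lo`,
#'   `lambda_hi`, `lambda` (midpoint), `concentration` (mol/L) and
#'   `mean_count`; attributes record kind, axial length and frames used.
#' @export
cylindrical_concentration <- function(window, species, bin_width = 0.5,
                                      lambda_max = NULL, axis_group = "helix1",
                                      axis = NULL) {
  box <- window$box
  lmax <- lambda_max %||% (min(box[1:2]) / 2)
  if (lmax > min(box[1:2]) / 2 + 1e-9) {
    abort("lambda_max exceeds half the smallest xy box edge", class = "ha_range_error")
  }
  sel <- .positions_of_group(window, species)
  axes <- if (is.null(axis)) .frame_axes(window, axis_group) else NULL
  fr_ids <- frame_indices(window)
  edges <- seq(0, lmax, by = bin_width)
  if (edges[length(edges)] < lmax) edges <- c(edges, lmax)
  counts <- numeric(length(edges) - 1)
  for (k in seq_along(fr_ids)) {
    fr <- sel$frames[sel$frames$frame == fr_ids[k], ]
    ax <- if (is.null(axis)) axes[[k]] else axis
    lam <- axis_distance(as.matrix(fr[, c("x", "y", "z")]), ax)
    # fold xy-periodic images so every particle gets its minimum-image radius
    h <- graphics::hist(lam[lam <= lmax], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  nf <- length(fr_ids)
  L <- box[3]
  shellvol <- pi * (edges[-1]^2 - edges[-length(edges)]^2) * L
  mean_count <- counts / nf
  conc <- mean_count / shellvol * .INV_A3_TO_MOLL
  out <- tibble(lambda_lo = edges[-length(edges)], lambda_hi = edges[-1],
                lambda = (edges[-1] + edges[-length(edges)]) / 2,
                concentration = conc, mean_count = mean_count)
  structure(out, class = c("ha_profile", class(out)),
            kind = "cylindrical_concentration", species = species,
            L = L, n_frames = nf, units = "mol/L")
}

#' Excess condensed counterions up to radius R
#'
#' Cumulative number of ions above bulk within a cylinder of radius `R`:
#' the shell integral of `c(lambda) - c_bulk` scaled by Avogadro's number
#' and the axial length L.
#'
#' @param profile an `ha_profile` from [cylindrical_concentration()].
#' @param c_bulk bulk concentration, mol/L; by default estimated as the mean
#'   over the outermost 20 percent of bins.
#' @param L axial length, angstrom; defaults to the profile's.
#' @param R cutoff radius, angstrom (may be a vector).
#' @return tibble with columns `R` and `excess` (counts).
#' @export
excess_ions <- function(profile, c_bulk = NULL, L = attr(profile, "L"), R) {
  if (is.null(c_bulk)) {
    n <- nrow(profile)
    tailbins <- profile$concentration[seq.int(ceiling(0.8 * n) + 1, n)]
    c_bulk <- mean(tailbins)
  }
  if (c_bulk < 0) abort("c_bulk must be >= 0", class = "ha_domain_error")
  lmax <- max(profile$lambda_hi)
  if (any(R > lmax + 1e-9)) {
    abort("R beyond the last profile bin", class = "ha_range_error")
  }
  dens_excess <- (profile$concentration - c_bulk) / .INV_A3_TO_MOLL  # per A^3
  vapply_R <- vapply(R, function(r) {
    hi <- pmin(profile$lambda_hi, r)
    lo <- pmin(profile$lambda_lo, r)
    sum(dens_excess * pi * (hi^2 - lo^2) * L)
  }, numeric(1))
  tibble(R = R, excess = vapply_R)
}

#' Surface-shell excess charge per species
#'
#' Time-averaged signed charge of each mobile species within surface shells
#' of the DNA (distance to the nearest DNA atom, minimum image), typically
#' the hydration (R1 = 3.5 A), tight-binding (R2 = 6 A) and Debye
#' (R3 = 10 A) layers.
#'
#' @param window an `ha_trajectory`.
#' @param shells named numeric vector of increasing shell radii, angstrom.
#' @param species character vector of group names; defaults to every
#'   `ion:*` group present.
#' @return tibble of class `ha_shell_charge`: columns `shell`, `R`,
#'   `species`, `charge` (e, time-averaged), plus a `"total"` species row
#'   per shell. Attribute `dna_charge` records the fixed DNA charge.
#' @export
excess_charge_by_shell <- function(window, shells = c(R1 = 3.5, R2 = 6.0, R3 = 10.0),
                                   species = NULL) {
  if (is.unsorted(shells, strictly = TRUE)) {
    abort("shell radii must be strictly increasing", class = "ha_domain_error")
  }
  at <- window$atoms
  dna_ids <- at$atom[!is.na(at$helix)]
  if (length(dna_ids) == 0) abort("no DNA atoms in topology", class = "ha_empty_reference")
  species <- species %||% sort(unique(at$group[grepl("^ion:", at$group)]))
  if (length(species) == 0) abort("no ion species present", class = "ha_empty_selection")
  box <- window$box
  fr_ids <- frame_indices(window)
  acc <- matrix(0, length(shells), length(species),
                dimnames = list(names(shells), species))
  for (i in fr_ids) {
    fr <- window$frames[window$frames$frame == i, ]
    fr <- fr[order(fr$atom), ]
    xyz <- as.matrix(fr[, c("x", "y", "z")])
    ref <- xyz[match(dna_ids, fr$atom), , drop = FALSE]
    for (s in species) {
      ids <- select_group(at, s)
      pts <- xyz[match(ids, fr$atom), , drop = FALSE]
      q <- at$charge[match(ids, at$atom)]
      dist <- surface_distance(pts, ref, box)
      for (k in seq_along(shells)) {
        acc[k, s] <- acc[k, s] + sum(q[dist <= shells[k]])
      }
    }
  }
  acc <- acc / length(fr_ids)
  out <- as_tibble(as.data.frame.table(acc, responseName = "charge")) %>%
    rename(shell = "Var1", species = "Var2") %>%
    mutate(shell = as.character(.data$shell), species = as.character(.data$species),
           R = shells[.data$shell]) %>%
    select("shell", "R", "species", "charge")
  totals <- out %>% group_by(.data$shell, .data$R) %>%
    summarise(species = "total", charge = sum(.data$charge), .groups = "drop") %>%
    select("shell", "R", "species", "charge")
  res <- bind_rows(out, totals) %>% arrange(.data$R)
  structure(res, class = c("ha_shell_charge", class(res)),
            dna_charge = sum(at$charge[!is.na(at$helix)]),
            n_frames = length(fr_ids))
}

#' Radial distribution function
#'
#' Pair correlation g(r) between a reference group and a target species,
#' normalized by the ideal-gas expectation at the target's box density
#' (exact spherical shell volumes).
#'
#' @param window an `ha_trajectory`.
#' @param ref_group,target_group group names.
#' @param bin_width bin width, angstrom (default 0.5).
#' @param r_max maximum distance; defaults to half the smallest box edge.
#' @return tibble of class `ha_profile` (kind `"rdf"`) with `r`, `g`,
#'   `mean_count`.
#' @export
rdf <- function(window, ref_group, target_group, bin_width = 0.5, r_max = NULL) {
  box <- window$box
  if (any(box <= 0)) abort("zero box volume", class = "ha_geometry_error")
  r_max <- r_max %||% (min(box) / 2)
  ref <- .positions_of_group(window, ref_group)
  tgt <- .positions_of_group(window, target_group)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  fr_ids <- frame_indices(window)
  for (i in fr_ids) {
    rp <- ref$frames[ref$frames$frame == i, ]
    tp <- tgt$frames[tgt$frames$frame == i, ]
    d <- min_image_dist(as.matrix(rp[, c("x", "y", "z")]),
                        as.matrix(tp[, c("x", "y", "z")]), box)
    same <- outer(rp$atom, tp$atom, "==")
    dd <- d[!same & d <= r_max]
    counts <- counts + graphics::hist(dd, breaks = edges, plot = FALSE)$counts
  }
  nf <- length(fr_ids)
  n_ref <- length(ref$ids)
  rho <- length(tgt$ids) / prod(box)
  vshell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * n_ref * rho * vshell)
  out <- tibble(r_lo = edges[-length(edges)], r_hi = edges[-1],
                r = (edges[-1] + edges[-length(edges)]) / 2,
                g = g, mean_count = counts / (nf * n_ref))
  structure(out, class = c("ha_profile", class(out)), kind = "rdf",
            species = target_group, rho = rho, n_frames = nf, units = "1")
}

#' Surface distribution function
#'
#' Distribution of target particles versus distance to the nearest atom of a
#' reference group ("distance from the DNA surface"), normalized by
#' Monte-Carlo-estimated accessible shell volumes so that a uniform gas
#' gives 1 at all distances.
#'
#' @inheritParams rdf
#' @param mc_samples Monte Carlo points for the shell-volume estimate
#'   (default 1e6).
#' @param mc_seed RNG seed for the volume estimate.
#' @param mc_tol maximum tolerated relative error of any occupied bin's
#'   volume estimate (default 0.25).
#' @return tibble of class `ha_profile` (kind `"sdf"`) with `r`, `g`,
#'   `shell_volume`.
#' @export
sdf <- function(window, ref_group, target_group, bin_width = 0.5, r_max = NULL,
                mc_samples = 1e6, mc_seed = 1L, mc_tol = 0.25) {
  box <- window$box
  r_max <- r_max %||% (min(box) / 2)
  ref <- .positions_of_group(window, ref_group)
  tgt <- .positions_of_group(window, target_group)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  fr_ids <- frame_indices(window)
  for (i in fr_ids) {
    rp <- as.matrix(ref$frames[ref$frames$frame == i, c("x", "y", "z")])
    tp <- as.matrix(tgt$frames[tgt$frames$frame == i, c("x", "y", "z")])
    dist <- surface_distance(tp, rp, box)
    counts <- counts + graphics::hist(dist[dist <= r_max], breaks = edges, plot = FALSE)$counts
  }
  # accessible shell volumes by seeded Monte Carlo against the first frame's
  # reference positions (reference assumed rigid across the window)
  rp0 <- as.matrix(ref$frames[ref$frames$frame == fr_ids[1], c("x", "y", "z")])
  mc_counts <- with_seed(mc_seed, {
    m <- as.integer(mc_samples)
    acc <- numeric(nb)
    done <- 0L
    while (done < m) {
      k <- min(m - done, 50000L)
      pts <- cbind(runif(k) * box[1], runif(k) * box[2], runif(k) * box[3])
      dmc <- surface_distance(pts, rp0, box)
      acc <- acc + graphics::hist(dmc[dmc <= r_max], breaks = edges, plot = FALSE)$counts
      done <- done + k
    }
    acc
  })
  frac <- mc_counts / mc_samples
  occupied <- counts > 0
  relerr <- ifelse(mc_counts > 0, sqrt(pmax(1 - frac, 0) / mc_counts), Inf)
  if (any(occupied & relerr > mc_tol)) {
    abort("Monte-Carlo shell-volume estimate too noisy for occupied bins; increase mc_samples",
          class = "ha_resolution_error")
  }
  vshell <- frac * prod(box)
  nf <- length(fr_ids)
  rho <- length(tgt$ids) / prod(box)
  g <- ifelse(vshell > 0, counts / (nf * rho) / vshell, NA_real_)
  out <- tibble(r_lo = edges[-nb - 1], r_hi = edges[-1],
                r = (edges[-1] + edges[-nb - 1]) / 2,
                g = g, mean_count = counts / nf, shell_volume = vshell)
  structure(out, class = c("ha_profile", class(out)), kind = "sdf",
            species = target_group, rho = rho, n_frames = nf, units = "1")
}
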