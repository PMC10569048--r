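# Synthetic ground-truth generators: idealized B-form duplex pairs (reduced
# phosphate + groove-marker representation), ion and water placements with
# known distributions, and Maxwell-Boltzmann velocities. These define the
# study conditions every analysis stage is validated against.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Idealized duplex geometry specification
#'
#' Parameters of the reduced B-form helix model used by the fixture builder:
#' each base pair contributes one phosphate pseudo-atom per strand (charge
#' -1 e) on a cylinder of radius `backbone_radius`, plus one major-groove and
#' one minor-groove marker pseudo-atom. The two strands of a duplex sit at
#' the same z, offset in azimuth by `groove_phase`, which sets the unequal
#' major/minor groove widths of B-DNA.
#'
#' @param n_bp number of base pairs (>= 1).
#' @param rise axial rise per base pair, angstrom (default 3.4).
#' @param twist helical twist per base pair, degrees (default 36).
#' @param backbone_radius phosphate cylinder radius, angstrom (default 8.9).
#' @param groove_phase strand-strand azimuthal offset, degrees (default 154;
#'   the minor groove spans this angle).
#' @param axis_origin base point of the helix-1 axis (angstrom) or NULL to
#'   center the pair in the box.
#' @param azimuth0 azimuth of the first strand-1 phosphate, radians.
#' @return list of class `helix_spec`.
#' @export
helix_spec <- function(n_bp = 20L, rise = 3.4, twist = 36, backbone_radius = 8.9,
                       groove_phase = 154, axis_origin = NULL, azimuth0 = 0) {
  if (n_bp < 1) abort("n_bp must be >= 1", class = "ha_domain_error")
  if (rise <= 0) abort("rise must be positive", class = "ha_domain_error")
  if (twist <= 0 || twist > 180) abort("twist must be in (0, 180] degrees", class = "ha_domain_error")
  structure(list(n_bp = as.integer(n_bp), rise = rise, twist = twist,
                 backbone_radius = backbone_radius, groove_phase = groove_phase,
                 axis_origin = axis_origin, azimuth0 = azimuth0),
            class = "helix_spec")
}

# pseudo-atom site table for one helix at a given axis (x,y) and own-axis rotation
.build_helix <- function(spec, axis_xy, rotation, helix_id, z0 = 0) {
  k <- seq_len(spec$n_bp) - 1L
  tw <- spec$twist * pi / 180
  gp <- spec$groove_phase * pi / 180
  phi1 <- spec$azimuth0 + rotation + k * tw
  phi2 <- phi1 + gp
  z <- z0 + k * spec$rise
  r <- spec$backbone_radius
  # groove markers: minor groove bisects the strand offset, major the complement
  phi_min <- phi1 + gp / 2
  phi_maj <- phi1 + gp / 2 + pi
  rg <- r - 2.0
  site <- function(phi, radius, nm, grp, q, m) {
    tibble(name = nm, resname = "DNA", resid = k + 1L, helix = helix_id,
           group = grp, bp = k + 1L,
           x = axis_xy[1] + radius * cos(phi), y = axis_xy[2] + radius * sin(phi),
           z = z, charge = q, mass = m)
  }
  bind_rows(
    site(phi1, r, "P", "phosphate", -1, 94.97) %>% mutate(strand = 1L),
    site(phi2, r, "P", "phosphate", -1, 94.97) %>% mutate(strand = 2L),
    site(phi_maj, rg, "GM", "major_groove", 0, 12.0) %>% mutate(strand = NA_integer_),
    site(phi_min, rg, "Gm", "minor_groove", 0, 12.0) %>% mutate(strand = NA_integer_)
  )
}

#' Build a parallel duplex pair
#'
#' Constructs two idealized duplexes with long axes parallel to +z: helix 1
#' (the restrained reference) at the spec's axis origin with fixed azimuth,
#' helix 2 displaced by `separation` in the xy-plane (along +x) and rotated
#' by `theta` about its own axis. Every phosphate carries charge -1 e.
#'
#' @param spec a [helix_spec()].
#' @param separation interhelical axis-to-axis distance, nm.
#' @param theta azimuthal rotation of helix 2 about its own axis, radians.
#' @param box orthorhombic box edge lengths, angstrom.
#' @param periodic if TRUE, require the box z-extent to be an integer
#'   multiple of the helical repeat (for seamless z-periodic continuation).
#' @return an [labeled_structure()] with groups `phosphate`, `major_groove`,
#'   `minor_groove` and helix labels 1/2; extra columns `bp` and `strand`
#'   record construction provenance.
#' @export
build_duplex_pair <- function(spec, separation, theta = 0, box, periodic = FALSE) {
  sep_A <- separation * 10
  if (sep_A < 2 * spec$backbone_radius) {
    abort(sprintf("helices overlap: separation %.1f A < 2 x backbone radius %.1f A",
                  sep_A, spec$backbone_radius), class = "ha_degenerate_geometry")
  }
  box <- as.numeric(box)
  if (periodic) {
    repeat_len <- spec$rise * 360 / spec$twist
    if (abs(box[3] / repeat_len - round(box[3] / repeat_len)) > 1e-8) {
      abort("box z-extent is not an integer multiple of the helical repeat",
            class = "ha_geometry_error")
    }
  }
  origin <- spec$axis_origin %||%
    c(box[1] / 2 - sep_A / 2, box[2] / 2, 0)
  ax1 <- origin[1:2]
  ax2 <- ax1 + c(sep_A, 0)
  rmax <- spec$backbone_radius
  for (ax in list(ax1, ax2)) {
    if (ax[1] - rmax < 0 || ax[1] + rmax > box[1] ||
        ax[2] - rmax < 0 || ax[2] + rmax > box[2]) {
      abort("box too small for the requested geometry", class = "ha_geometry_error")
    }
  }
  if ((spec$n_bp - 1) * spec$rise > box[3]) {
    abort("box too short in z for the helix", class = "ha_geometry_error")
  }
  z_base <- if (length(origin) >= 3) origin[3] else 0
  atoms <- bind_rows(
    .build_helix(spec, ax1, rotation = 0, helix_id = 1L, z0 = z_base),
    .build_helix(spec, ax2, rotation = theta, helix_id = 2L, z0 = z_base)
  )
  atoms$atom <- seq_len(nrow(atoms))
  st <- labeled_structure(atoms[, c(.structure_cols, "bp", "strand")], box)
  attr(st, "helix_spec") <- spec
  attr(st, "construction") <- list(separation = separation, theta = wrap_angle(theta),
                                   axis1 = ax1, axis2 = ax2)
  st
}

#' Recover interhelical distance and azimuthal rotation from coordinates
#'
#' Fits the axis of each helix through its phosphates (least squares), takes
#' the interhelical distance `d` as the xy-distance between the fitted axes,
#' and estimates `theta` as the circular mean over helix-2 phosphates of the
#' offset between their observed azimuth and the azimuth they would have at
#' theta = 0 under the construction spec.
#'
#' @param x an `ha_structure` built by [build_duplex_pair()] (or coordinates
#'   carrying the same `bp`/`strand`/`helix` columns).
#' @param spec the [helix_spec()]; defaults to the one stored on `x`.
#' @return list with `d` (nm) and `theta` (radians in `[0, 2pi)`).
#' @export
estimate_d_theta <- function(x, spec = attr(x, "helix_spec")) {
  at <- as_tibble(x)
  if (is.null(spec)) abort("no helix_spec available", class = "ha_domain_error")
  ph1 <- at[at$group == "phosphate" & at$helix == 1L, ]
  ph2 <- at[at$group == "phosphate" & at$helix == 2L, ]
  if (nrow(ph1) == 0 || nrow(ph2) == 0) {
    abort("phosphates of both helices are required", class = "ha_empty_selection")
  }
  a1 <- fit_axis(ph1); a2 <- fit_axis(ph2)
  d <- sqrt(sum((a1$origin[1:2] - a2$origin[1:2])^2)) / 10
  tw <- spec$twist * pi / 180
  gp <- spec$groove_phase * pi / 180
  phi_ref <- spec$azimuth0 + (ph2$bp - 1L) * tw + ifelse(ph2$strand == 2L, gp, 0)
  phi_obs <- axis_azimuth(ph2, a2)
  dphi <- phi_obs - phi_ref
  theta <- wrap_angle(atan2(mean(sin(dphi)), mean(cos(dphi))))
  list(d = d, theta = theta)
}

#' Place ions around a structure
#'
#' Two placement modes with known ground truth. `uniform_bulk`: the ion
#' count is drawn as Poisson(concentration x box volume x N_A) and positions
#' are uniform in the box excluding a hard core around existing atoms.
#' `helical_groove_chain`: `count` ions at isotropic Gaussian displacements
#' (sd `chain_sigma`) from helical guide curves running along each duplex at
#' `guide_offset` angstrom radially outside the phosphate helix of strand 1,
#' emulating the continuous chains of condensed-cation density seen along
#' the grooves.
#'
#' @param structure an `ha_structure`.
#' @param species ion species label, e.g. "Mg", "Na", "Cl".
#' @param valence integer charge in e.
#' @param mode `"uniform_bulk"` or `"helical_groove_chain"`.
#' @param concentration mol/L (uniform mode).
#' @param chain_sigma Gaussian spread, angstrom (groove mode).
#' @param count ions per guide curve (groove mode).
#' @param guide_offset radial offset of the guide curve from the backbone
#'   cylinder, angstrom (groove mode, default 3).
#' @param hard_core exclusion radius around existing atoms, angstrom
#'   (uniform mode, default 2.5).
#' @param seed RNG seed.
#' @param mass ion mass, amu (defaults from a small internal table).
#' @return the structure with ion atoms appended (group `ion:<species>`);
#'   attribute `placement` records the generation parameters.
#' @export
place_ions <- function(structure, species, valence, mode = c("uniform_bulk", "helical_groove_chain"),
                       concentration = NULL, chain_sigma = NULL, count = NULL,
                       guide_offset = 3.0, hard_core = 2.5, seed = 1L, mass = NULL) {
  mode <- match.arg(mode)
  box <- ha_box(structure)
  masses <- c(Mg = 24.305, Na = 22.990, K = 39.098, Cl = 35.453, SPM = 202.34)
  mass <- mass %||% unname(masses[species]) %||% 30
  if (is.na(mass)) mass <- 30
  disp <- NULL
  pos <- with_seed(seed, {
    if (mode == "uniform_bulk") {
      if (is.null(concentration) || concentration < 0) {
        abort("uniform_bulk mode requires concentration >= 0 mol/L", class = "ha_domain_error")
      }
      lambda <- concentration / .INV_A3_TO_MOLL * prod(box)
      n <- rpois(1, lambda)
      .place_uniform(n, structure, box, hard_core)
    } else {
      if (is.null(count) || is.null(chain_sigma) || chain_sigma <= 0) {
        abort("helical_groove_chain mode requires count and chain_sigma > 0",
              class = "ha_domain_error")
      }
      g <- .place_groove(structure, count, chain_sigma, guide_offset)
      disp <- g$disp
      g$pos
    }
  })
  n <- nrow(pos)
  if (n == 0) {
    out <- structure
  } else {
    ions <- tibble(name = species, resname = "ION", resid = seq_len(n),
                   helix = NA_integer_, group = paste0("ion:", species),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   charge = as.numeric(valence), mass = mass)
    out <- append_atoms(structure, ions)
  }
  attr(out, "helix_spec") <- attr(structure, "helix_spec")
  attr(out, "construction") <- attr(structure, "construction")
  attr(out, "placement") <- c(attr(structure, "placement"),
    list(list(species = species, valence = valence, mode = mode, n_placed = n,
              concentration = concentration, chain_sigma = chain_sigma,
              count = count, guide_offset = guide_offset, seed = seed,
              displacements = disp)))
  out
}

.place_uniform <- function(n, structure, box, hard_core) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  existing <- structure_coords(structure)
  out <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 1000L * max(n, 1L)
  while (placed < n) {
    if (tries >= max_tries) {
      abort("could not place ions after bounded retries (box too crowded?)",
            class = "ha_packing_error")
    }
    m <- min(n - placed, 256L)
    cand <- cbind(runif(m) * box[1], runif(m) * box[2], runif(m) * box[3])
    ok <- if (nrow(existing) > 0) {
      apply(min_image_dist(cand, existing, box), 1, min) > hard_core
    } else rep(TRUE, m)
    k <- sum(ok)
    if (k > 0) {
      out[placed + seq_len(k), ] <- cand[ok, , drop = FALSE]
      placed <- placed + k
    }
    tries <- tries + m
  }
  out
}

.place_groove <- function(structure, count, chain_sigma, guide_offset) {
  spec <- attr(structure, "helix_spec")
  cons <- attr(structure, "construction")
  if (is.null(spec) || is.null(cons)) {
    abort("groove placement needs a structure built by build_duplex_pair",
          class = "ha_domain_error")
  }
  zmax <- (spec$n_bp - 1) * spec$rise
  tw <- spec$twist * pi / 180 / spec$rise  # rad per angstrom of z
  rg <- spec$backbone_radius + guide_offset
  res <- list()
  dis <- list()
  for (h in 1:2) {
    ax <- if (h == 1) cons$axis1 else cons$axis2
    rot <- if (h == 1) 0 else cons$theta
    zz <- runif(count) * zmax
    phi <- spec$azimuth0 + rot + tw * zz
    guide <- cbind(ax[1] + rg * cos(phi), ax[2] + rg * sin(phi), zz)
    disp <- matrix(rnorm(3 * count, sd = chain_sigma), ncol = 3)
    res[[h]] <- guide + disp
    dis[[h]] <- disp
  }
  list(pos = do.call(rbind, res), disp = do.call(rbind, dis))
}

#' Place water molecules uniformly in the box
#'
#' Rigid 3-site waters (O-H 0.9572 angstrom, H-O-H 104.52 degrees, TIP3P-like
#' partial charges) at uniform random positions and orientations, excluding a
#' hard core around existing atoms.
#'
#' @inheritParams place_ions
#' @param count number of water molecules.
#' @return structure with water atoms appended (group `water`, names O/H1/H2).
#' @export
place_waters <- function(structure, count, hard_core = 2.4, seed = 1L) {
  box <- ha_box(structure)
  oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  o_pos <- with_seed(seed, .place_uniform(count, structure, box, hard_core))
  if (count == 0) return(structure)
  rot <- with_seed(seed + 1L, {
    # uniform random rotations via normalized quaternions
    q <- matrix(rnorm(4 * count), ncol = 4)
    q / sqrt(rowSums(q^2))
  })
  h1_loc <- c(oh * sin(half), 0, oh * cos(half))
  h2_loc <- c(-oh * sin(half), 0, oh * cos(half))
  rotate <- function(v, q) {
    # rotate fixed vector v by each quaternion row
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
    t(vapply(seq_along(w), function(i) {
      R <- matrix(c(
        1 - 2 * (y[i]^2 + z[i]^2), 2 * (x[i] * y[i] - w[i] * z[i]), 2 * (x[i] * z[i] + w[i] * y[i]),
        2 * (x[i] * y[i] + w[i] * z[i]), 1 - 2 * (x[i]^2 + z[i]^2), 2 * (y[i] * z[i] - w[i] * x[i]),
        2 * (x[i] * z[i] - w[i] * y[i]), 2 * (y[i] * z[i] + w[i] * x[i]), 1 - 2 * (x[i]^2 + y[i]^2)),
        3, 3, byrow = TRUE)
      as.numeric(R %*% v)
    }, numeric(3)))
  }
  h1 <- o_pos + rotate(h1_loc, rot)
  h2 <- o_pos + rotate(h2_loc, rot)
  waters <- bind_rows(
    tibble(name = "O", x = o_pos[, 1], y = o_pos[, 2], z = o_pos[, 3],
           charge = -0.834, mass = 15.9994, resid = seq_len(count)),
    tibble(name = "H1", x = h1[, 1], y = h1[, 2], z = h1[, 3],
           charge = 0.417, mass = 1.008, resid = seq_len(count)),
    tibble(name = "H2", x = h2[, 1], y = h2[, 2], z = h2[, 3],
           charge = 0.417, mass = 1.008, resid = seq_len(count))
  ) %>%
    mutate(resname = "HOH", helix = NA_integer_, group = "water") %>%
    arrange(.data$resid, .data$name)
  out <- append_atoms(structure, waters)
  attr(out, "helix_spec") <- attr(structure, "helix_spec")
  attr(out, "construction") <- attr(structure, "construction")
  attr(out, "placement") <- attr(structure, "placement")
  out
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian velocity component is drawn from Normal(0, kT/m); the net
#' momentum is then removed by subtracting the center-of-mass velocity.
#'
#' @param structure an `ha_structure` with positive masses.
#' @param temperature kelvin (> 0; exactly 0 gives zero velocities).
#' @param seed RNG seed.
#' @param remove_com subtract the center-of-mass velocity (default TRUE).
#' @return single-frame `ha_trajectory` with velocities (angstrom/ps).
#' @export
sample_velocities <- function(structure, temperature, seed = 1L, remove_com = TRUE) {
  if (temperature < 0) abort("temperature must be >= 0", class = "ha_domain_error")
  m <- structure$mass
  if (any(m <= 0)) abort("all masses must be positive", class = "ha_domain_error")
  n <- nrow(structure)
  v <- if (temperature == 0) matrix(0, n, 3) else with_seed(seed, {
    sd <- sqrt(.kT_internal(temperature) / m)
    matrix(rnorm(3 * n, sd = rep(sd, 3)), n, 3)
  })
  if (remove_com && n > 0 && temperature > 0) {
    vcom <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, vcom)
  }
  st <- as_tibble(structure)
  st$vx <- v[, 1]; st$vy <- v[, 2]; st$vz <- v[, 3]
  st <- labeled_structure(st, ha_box(structure))
  as_trajectory(st)
}
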