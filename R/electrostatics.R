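# Shell-restricted Coulomb electrostatics: potential from the charge content
# of a 10-A surface shell around each helix, and the stored interhelical
# energy U_d (shell-to-shell cross Coulomb energy) along the condensation
# path. Vacuum Coulomb constant by default; no Ewald/periodic images (the
# shell restriction embodies the Debye-screened, real-space picture).

#' Shell charge distributions around each helix
#'
#' Assigns every charged mobile particle (ions, water sites) within
#' `thickness` of a helix surface to its nearest helix (by surface distance;
#' exact ties are excluded and logged) and returns the two charge groups,
#' optionally including the helix's own atomic charges.
#'
#' @param structure an `ha_structure` (one frame).
#' @param thickness shell thickness, angstrom (default 10, the Debye length
#'   at the study's salt condition).
#' @param include_dna include the DNA's own charges in each group (default
#'   TRUE).
#' @return list with elements `shell1`, `shell2`: tibbles of `x`, `y`, `z`,
#'   `charge`; attribute `n_ties` counts excluded ambiguous particles.
#' @export
shell_charges <- function(structure, thickness = 10, include_dna = TRUE) {
  at <- as_tibble(structure)
  box <- ha_box(structure)
  h1 <- at[!is.na(at$helix) & at$helix == 1L, ]
  h2 <- at[!is.na(at$helix) & at$helix == 2L, ]
  if (nrow(h1) == 0 || nrow(h2) == 0) {
    abort("both helices must be present", class = "ha_empty_reference")
  }
  mobile <- at[is.na(at$helix) & at$charge != 0, ]
  n_ties <- 0L
  sh <- list(tibble(x = numeric(0), y = numeric(0), z = numeric(0), charge = numeric(0)),
             tibble(x = numeric(0), y = numeric(0), z = numeric(0), charge = numeric(0)))
  if (nrow(mobile) > 0) {
    d1 <- surface_distance(mobile, h1, box)
    d2 <- surface_distance(mobile, h2, box)
    tie <- abs(d1 - d2) < 1e-12 & pmin(d1, d2) <= thickness
    n_ties <- sum(tie)
    if (n_ties > 0) {
      inform(sprintf("%d particles equidistant from both helices excluded from shells", n_ties))
    }
    in1 <- !tie & d1 <= thickness & d1 < d2
    in2 <- !tie & d2 <= thickness & d2 < d1
    sh[[1]] <- mobile[in1, c("x", "y", "z", "charge")]
    sh[[2]] <- mobile[in2, c("x", "y", "z", "charge")]
  }
  if (include_dna) {
    sh[[1]] <- bind_rows(h1[, c("x", "y", "z", "charge")], sh[[1]])
    sh[[2]] <- bind_rows(h2[, c("x", "y", "z", "charge")], sh[[2]])
  }
  structure(list(shell1 = sh[[1]], shell2 = sh[[2]]),
            n_ties = n_ties, thickness = thickness, class = "ha_shells")
}

#' Electrostatic potential of a shell charge distribution
#'
#' Direct Coulomb sum `ke * sum_i q_i / |r - r_i|` over the members of one
#' shell distribution, in kJ/mol per unit probe charge. Vacuum Coulomb
#' constant; an optional relative permittivity scales it down.
#'
#' @param points n x 3 matrix (or data frame with x,y,z), angstrom.
#' @param distribution tibble with `x`, `y`, `z`, `charge` (one element of
#'   [shell_charges()]).
#' @param epsilon_r relative permittivity (default 1).
#' @param min_dist singularity guard: evaluation closer than this to a
#'   source is an error (default 0.1 angstrom).
#' @return numeric vector of potentials, kJ/mol/e.
#' @export
potential_at <- function(points, distribution, epsilon_r = 1, min_dist = 0.1) {
  pts <- as_coord_matrix(points)
  src <- as_coord_matrix(distribution)
  q <- distribution$charge
  dx <- outer(pts[, 1], src[, 1], "-")
  dy <- outer(pts[, 2], src[, 2], "-")
  dz <- outer(pts[, 3], src[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(r < min_dist)) {
    bad <- which(apply(r < min_dist, 1, any))
    abort(paste0("evaluation point(s) within ", min_dist, " A of a source charge: ",
                 paste(head(bad, 10), collapse = ", ")), class = "ha_singularity_error")
  }
  as.numeric((.KE_COUL / epsilon_r) * ((1 / r) %*% q))
}

#' Stored interhelical electrostatic energy of one frame
#'
#' Cross-interaction Coulomb energy between the two helix charge groups
#' (helix plus its surface shell): `sum_{i in shell2} q_i Phi_shell1(r_i)`.
#' Interhelical cross terms only; no self energy. Symmetric in the two
#' shells (Newton's third law).
#'
#' @param shells an `ha_shells` object from [shell_charges()], or a
#'   structure (then shells are built with `...` passed on).
#' @param epsilon_r relative permittivity (default 1).
#' @param ... passed to [shell_charges()] when `shells` is a structure.
#' @return energy in kJ/mol.
#' @export
stored_energy <- function(shells, epsilon_r = 1, ...) {
  if (inherits(shells, "ha_structure")) shells <- shell_charges(shells, ...)
  s1 <- shells$shell1; s2 <- shells$shell2
  if (nrow(s1) == 0 || nrow(s2) == 0) {
    abort("both shells must be non-empty", class = "ha_empty_selection")
  }
  phi <- potential_at(s2, s1, epsilon_r = epsilon_r)
  sum(s2$charge * phi)
}

#' Stored energy along the condensation path
#'
#' Bins frames by interhelical distance and reports the per-bin
#' time-averaged stored energy, as the change relative to the largest-d bin
#' (the free state).
#'
#' @param windows a list of single-frame `ha_structure`s (a condensation
#'   path), each carrying its construction `d`, or a list of
#'   `list(structure, d)` pairs.
#' @param d_bin bin width in d, nm (default 0.05 nm = 0.5 angstrom).
#' @param thickness shell thickness, angstrom.
#' @param include_dna include DNA charges (default TRUE).
#' @param epsilon_r relative permittivity.
#' @return tibble of class `ha_energy_profile` with `d` (bin center, nm),
#'   `U` (kJ/mol), `dU` (relative to largest-d bin), `n_frames`.
#' @export
energy_vs_distance <- function(windows, d_bin = 0.05, thickness = 10,
                               include_dna = TRUE, epsilon_r = 1) {
  recs <- purrr::map_dfr(windows, function(w) {
    st <- if (inherits(w, "ha_structure")) w else w$structure
    d <- if (inherits(w, "ha_structure")) {
      cons <- attr(w, "construction")
      if (!is.null(cons)) cons$separation else estimate_d_theta(w)$d
    } else w$d
    U <- stored_energy(shell_charges(st, thickness = thickness,
                                     include_dna = include_dna),
                       epsilon_r = epsilon_r)
    tibble(d = d, U = U)
  })
  recs$bin <- round(recs$d / d_bin)
  prof <- recs %>% group_by(.data$bin) %>%
    summarise(d = mean(.data$d), U = mean(.data$U), n_frames = n(), .groups = "drop") %>%
    arrange(.data$d) %>% select(-"bin")
  prof$dU <- prof$U - prof$U[nrow(prof)]
  structure(prof, class = c("ha_energy_profile", class(prof)),
            thickness = thickness, include_dna = include_dna)
}
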