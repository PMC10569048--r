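# Hydration-structure metrics: tetrahedral order parameter of water (binned
# into cylindrical shells from the helix axis), bound-water counts in the
# hydration layer R1, and geometric hydrogen-bond counts.

#' Tetrahedral order parameter from explicit neighbor directions
#'
#' Computes `S_g = (3/32) * sum_{j<k} (cos Psi_jk + 1/3)^2` over the six
#' angle pairs of four neighbor bonds subtended at a central atom. 0 for a
#' perfect tetrahedron; bounded in [0, 1] by the 3/32 normalization; 1/4 on
#' average for isotropic random neighbor directions.
#'
#' @param central n x 3 matrix of central positions.
#' @param neighbors n x 4 x 3 array of the four neighbor positions per
#'   central atom.
#' @return numeric vector of S_g values.
#' @export
tetrahedral_sg <- function(central, neighbors) {
  central <- as_coord_matrix(central)
  n <- nrow(central)
  b <- lapply(1:4, function(j) {
    v <- matrix(neighbors[, j, ], nrow = n) - central
    v / sqrt(rowSums(v^2))
  })
  sg <- numeric(n)
  for (j in 1:3) for (k in (j + 1):4) {
    cosjk <- pmin(1, pmax(-1, rowSums(b[[j]] * b[[k]])))
    sg <- sg + (cosjk + 1 / 3)^2
  }
  3 / 32 * sg
}

#' Tetrahedral order parameter of water, binned from the helix axis
#'
#' For each water oxygen, finds its 4 nearest water oxygens (minimum image;
#' regardless of distance, with a cutoff that only triggers the skip rule)
#' and computes S_g; per-water values are averaged into cylindrical shells
#' of `bin_width` around the helix axis.
#'
#' @param window an `ha_trajectory` containing waters.
#' @param bin_width cylindrical bin, angstrom (default 0.5).
#' @param cutoff neighbor-search cutoff, angstrom (default 5); waters with
#'   fewer than 4 neighbors inside it are skipped and counted.
#' @param lambda_max outermost shell; default half the smallest xy box edge.
#' @param axis_group axis definition as in [cylindrical_concentration()];
#'   `NULL` (no DNA present) bins from the box center.
#' @return list with `per_water` (tibble: frame, molecule, lambda, sg) and
#'   `profile` (`ha_profile` of mean S_g vs lambda), plus `n_skipped`.
#' @export
tetrahedral_order <- function(window, bin_width = 0.5, cutoff = 5.0,
                              lambda_max = NULL, axis_group = "helix1") {
  box <- window$box
  ow <- .positions_of_group(window, "water_O")
  if (length(ow$ids) < 5) {
    abort("need at least 5 waters (4 neighbors each)", class = "ha_domain_error")
  }
  has_dna <- any(!is.na(window$atoms$helix))
  axes <- if (has_dna && !is.null(axis_group)) .frame_axes(window, axis_group) else NULL
  lmax <- lambda_max %||% (min(box[1:2]) / 2)
  fr_ids <- frame_indices(window)
  per <- list()
  n_skipped <- 0L
  for (fi in seq_along(fr_ids)) {
    fr <- ow$frames[ow$frames$frame == fr_ids[fi], ]
    xyz <- as.matrix(fr[, c("x", "y", "z")])
    n <- nrow(xyz)
    dm <- min_image_dist(xyz, xyz, box)
    diag(dm) <- Inf
    nb_idx <- t(apply(dm, 1, function(row) order(row)[1:4]))
    nb_ok <- dm[cbind(rep(seq_len(n), 4), as.integer(nb_idx))] <= cutoff
    ok <- rowSums(matrix(nb_ok, n, 4)) == 4
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    ctr <- xyz[ok, , drop = FALSE]
    nbr <- array(NA_real_, c(sum(ok), 4, 3))
    sel <- nb_idx[ok, , drop = FALSE]
    for (j in 1:4) {
      raw <- xyz[sel[, j], , drop = FALSE]
      # neighbor at its minimum-image position relative to the central atom
      for (k in 1:3) raw[, k] <- ctr[, k] + min_image(raw[, k] - ctr[, k], box[k])
      nbr[, j, ] <- raw
    }
    sg <- tetrahedral_sg(ctr, nbr)
    lam <- if (!is.null(axes)) {
      axis_distance(ctr, axes[[fi]])
    } else {
      sqrt((ctr[, 1] - box[1] / 2)^2 + (ctr[, 2] - box[2] / 2)^2)
    }
    per[[fi]] <- tibble(frame = fr_ids[fi], molecule = fr$atom[ok],
                        lambda = lam, sg = sg)
  }
  per <- bind_rows(per)
  edges <- seq(0, lmax, by = bin_width)
  if (edges[length(edges)] < lmax) edges <- c(edges, lmax)
  idx <- findInterval(per$lambda, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(edges) - 1
  means <- rep(NA_real_, length(edges) - 1)
  counts <- rep(0L, length(edges) - 1)
  if (any(keep)) {
    agg <- rowsum(per$sg[keep], idx[keep])
    cts <- rowsum(rep(1L, sum(keep)), idx[keep])
    means[as.integer(rownames(agg))] <- agg[, 1] / cts[, 1]
    counts[as.integer(rownames(cts))] <- cts[, 1]
  }
  prof <- tibble(lambda_lo = edges[-length(edges)], lambda_hi = edges[-1],
                 lambda = (edges[-1] + edges[-length(edges)]) / 2,
                 sg = means, n = counts)
  prof <- structure(prof, class = c("ha_profile", class(prof)),
                    kind = "tetrahedral", units = "1",
                    n_frames = length(fr_ids))
  list(per_water = per, profile = prof, n_skipped = n_skipped)
}

#' Bound waters in the hydration layer
#'
#' Time-averaged number of water oxygens whose distance to the nearest DNA
#' atom is at most `R1`.
#'
#' @param window an `ha_trajectory`.
#' @param R1 hydration shell radius, angstrom (default 3.5).
#' @return scalar mean count.
#' @export
bound_waters <- function(window, R1 = 3.5) {
  at <- window$atoms
  dna_ids <- at$atom[!is.na(at$helix)]
  if (length(dna_ids) == 0) abort("no DNA atoms", class = "ha_empty_reference")
  ow_ids <- select_group(window$atoms, "water_O", require_atoms = FALSE)
  if (length(ow_ids) == 0) return(0)
  ow <- .positions_of_group(window, "water_O")
  fr_ids <- frame_indices(window)
  total <- 0
  for (i in fr_ids) {
    fr <- window$frames[window$frames$frame == i, ]
    ref <- as.matrix(fr[match(dna_ids, fr$atom), c("x", "y", "z")])
    pts <- as.matrix(ow$frames[ow$frames$frame == i, c("x", "y", "z")])
    if (nrow(pts) == 0) next
    total <- total + sum(surface_distance(pts, ref, window$box) <= R1)
  }
  total / length(fr_ids)
}

#' Geometric hydrogen-bond count within the hydration layer
#'
#' Counts donor-acceptor pairs (water-water and water-DNA) among atoms whose
#' oxygen/acceptor sits within `R1` of the DNA surface (or among all waters
#' when no DNA is present), using the geometric criterion: donor-acceptor
#' distance <= `d_cut` and donor-H...acceptor angle >= `angle_cut`.
#'
#' @param window an `ha_trajectory` with explicit water hydrogens.
#' @param R1 region radius from the DNA surface, angstrom; `Inf` counts the
#'   whole box.
#' @param d_cut donor-acceptor distance cutoff, angstrom (default 3.5).
#' @param angle_cut D-H...A angle cutoff, degrees (default 150).
#' @param dna_acceptors group name of DNA acceptor sites (default
#'   phosphates).
#' @return scalar time-averaged H-bond count.
#' @export
hydrogen_bonds <- function(window, R1 = Inf, d_cut = 3.5, angle_cut = 150,
                           dna_acceptors = "phosphate_backbone") {
  at <- window$atoms
  o_ids <- select_group(at, "water_O")
  h_ids <- select_group(at, "water_H", require_atoms = FALSE)
  if (length(h_ids) == 0) {
    abort(paste("waters have no hydrogens; use the oxygen-distance fallback",
                "(d_cut on O...O) by calling with explicit-H fixtures"),
          class = "ha_capability_error")
  }
  dna_ids <- if (any(!is.na(at$helix))) {
    select_group(at, dna_acceptors, require_atoms = FALSE)
  } else integer(0)
  # map water O -> its two H by resid
  wat <- at[at$group == "water", ]
  fr_ids <- frame_indices(window)
  box <- window$box
  cosmin <- cos(angle_cut * pi / 180)  # angle >= cut <=> cos(angle) <= cos(cut)
  total <- 0
  for (i in fr_ids) {
    fr <- window$frames[window$frames$frame == i, ]
    pos <- function(ids) as.matrix(fr[match(ids, fr$atom), c("x", "y", "z")])
    o_xyz <- pos(o_ids)
    dna_xyz <- if (length(dna_ids) > 0) pos(dna_ids) else NULL
    inR <- if (is.finite(R1) && !is.null(dna_xyz)) {
      surface_distance(o_xyz, dna_xyz, box) <= R1
    } else rep(TRUE, length(o_ids))
    o_in <- o_ids[inR]
    if (length(o_in) < 1) next
    # acceptors: in-region water O + DNA acceptor sites within R1 region
    acc_ids <- o_in
    acc_xyz <- o_xyz[inR, , drop = FALSE]
    if (!is.null(dna_xyz) && is.finite(R1)) {
      acc_ids <- c(acc_ids, dna_ids)
      acc_xyz <- rbind(acc_xyz, dna_xyz)
    }
    # donors: the two H of each in-region water
    don_res <- wat$resid[match(o_in, wat$atom)]
    hh <- wat[wat$resid %in% don_res & wat$name != "O", ]
    h_xyz <- pos(hh$atom)
    d_o_ids <- o_in[match(hh$resid, don_res)]
    d_o_xyz <- o_xyz[match(d_o_ids, o_ids), , drop = FALSE]
    # donor O to acceptor distances
    dd <- min_image_dist(d_o_xyz, acc_xyz, box)
    self <- outer(d_o_ids, acc_ids, "==")
    cand <- which(dd <= d_cut & !self, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    nb <- 0L
    for (r in seq_len(nrow(cand))) {
      di <- cand[r, 1]; ai <- cand[r, 2]
      oh <- min_image(h_xyz[di, ] - d_o_xyz[di, ], box)
      ha <- min_image(acc_xyz[ai, ] - h_xyz[di, ], box)
      # angle at H between O-H and H...A: D-H...A angle
      cosang <- -sum(oh * ha) / sqrt(sum(oh^2) * sum(ha^2))
      # cos of D-H...A: vectors H->D and H->A
      if (cosang <= cosmin) nb <- nb + 1L
    }
    total <- total + nb
  }
  total / length(fr_ids)
}
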