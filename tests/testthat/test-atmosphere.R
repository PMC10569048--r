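# Ion-atmosphere densities, cylindrical profiles, excess charge, RDF/SDF.

ion_structure <- function(xyz, box, species = "Mg", valence = 2) {
  bare_structure(xyz, box, charge = valence, mass = 24.3,
                 group = paste0("ion:", species), name = species)
}

test_that("number density averages counts per voxel and conserves particles", {
  box <- c(10, 10, 10)
  st <- ion_structure(c(2.5, 3.5, 4.5), box)   # voxel center at spacing 1
  w <- as_trajectory(st)
  f <- number_density(w, "ion:Mg", spacing = 1)
  expect_equal(max(f$values), 1)               # 1 / spacing^3
  expect_equal(sum(f$values > 0), 1)
  expect_equal(field_integral(f), 1, tolerance = 1e-9)

  # two frames, ion in voxel A then voxel B -> 0.5 each
  w2 <- window_from_coords(st, list(matrix(c(2.5, 3.5, 4.5), 1),
                                    matrix(c(7.5, 7.5, 7.5), 1)))
  f2 <- number_density(w2, "ion:Mg")
  expect_equal(sort(f2$values[f2$values > 0]), c(0.5, 0.5))
  expect_equal(field_integral(f2), 1, tolerance = 1e-9)
  expect_error(number_density(w, "ion:Na"), class = "ha_empty_selection")
})

test_that("uniform placements give Poisson voxel statistics and exact conservation", {
  box <- c(20, 20, 20)
  n_ions <- 500; n_frames <- 40
  set.seed(31)
  st <- ion_structure(matrix(runif(3 * n_ions) * 20, ncol = 3), box)
  coords <- lapply(seq_len(n_frames), function(i) matrix(runif(3 * n_ions) * 20, ncol = 3))
  w <- window_from_coords(st, coords)
  f <- number_density(w, "ion:Mg", spacing = 2)
  expect_equal(field_integral(f), n_ions, tolerance = 1e-6)
  # dispersion of per-voxel counts ~ Poisson (index of dispersion ~ 1)
  counts <- f$values * 8 * n_frames
  disp <- var(as.numeric(counts)) / mean(counts)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / length(counts)) + 0.05)
})

test_that("cylindrical profile is flat for a uniform gas and exact for a delta shell", {
  box <- c(60, 60, 40)
  axis <- list(origin = c(30, 30, 0), direction = c(0, 0, 1))
  # uniform gas inside the analysis cylinder
  n <- 4000
  set.seed(5)
  r <- 25 * sqrt(runif(n)); phi <- runif(n) * 2 * pi
  xyz <- cbind(30 + r * cos(phi), 30 + r * sin(phi), runif(n) * 40)
  st <- ion_structure(xyz, box)
  w <- as_trajectory(st)
  prof <- cylindrical_concentration(w, "ion:Mg", bin_width = 2.5,
                                    lambda_max = 25, axis = axis)
  c0 <- n / (pi * 25^2 * 40) * ha_constants()$invA3_to_molL
  counts <- prof$mean_count
  sigma_c <- prof$concentration / sqrt(pmax(counts, 1))
  expect_true(all(abs(prof$concentration - c0) < 3.5 * sigma_c))
  # conservation: integrating the profile back returns the ion count
  back <- sum(prof$concentration / ha_constants()$invA3_to_molL *
                pi * (prof$lambda_hi^2 - prof$lambda_lo^2) * 40)
  expect_equal(back, n, tolerance = 1e-6)

  # delta shell at lambda = 10: single occupied bin, hand-computable value
  m <- 200
  phi <- seq(0, 2 * pi, length.out = m + 1)[1:m]
  xyz <- cbind(30 + 10 * cos(phi), 30 + 10 * sin(phi), runif(m) * 40)
  wd <- as_trajectory(ion_structure(xyz, box))
  pd <- cylindrical_concentration(wd, "ion:Mg", bin_width = 0.5,
                                  lambda_max = 20, axis = axis)
  occ <- which(pd$mean_count > 0)
  expect_length(occ, 1)
  shellvol <- pi * (pd$lambda_hi[occ]^2 - pd$lambda_lo[occ]^2) * 40
  expect_equal(pd$concentration[occ],
               m / shellvol * ha_constants()$invA3_to_molL, tolerance = 1e-12)
  expect_error(cylindrical_concentration(wd, "ion:Mg", lambda_max = 40, axis = axis),
               class = "ha_range_error")
})

test_that("excess-ion integral is zero at bulk, matches quadrature on a step profile", {
  skip_if_not_installed("pracma")
  mk_prof <- function(conc, edges = seq(0, 25, 0.5)) {
    structure(tibble::tibble(lambda_lo = head(edges, -1), lambda_hi = edges[-1],
                             lambda = (head(edges, -1) + edges[-1]) / 2,
                             concentration = conc),
              L = 68, class = c("ha_profile", "tbl_df", "tbl", "data.frame"))
  }
  flat <- mk_prof(rep(0.1, 50))
  ex <- excess_ions(flat, c_bulk = 0.1, R = c(5, 10, 20))
  expect_equal(ex$excess, c(0, 0, 0), tolerance = 1e-12)

  # step: c = 2 c_bulk inside 10 A, c_bulk beyond; c_bulk = 0.1 M, L = 68 A
  prof <- mk_prof(ifelse(seq(0.25, 24.75, 0.5) < 10, 0.2, 0.1))
  got <- excess_ions(prof, c_bulk = 0.1, R = 20)$excess
  cexc <- function(l) ifelse(l < 10, 0.1, 0) / helixatmos::ha_constants()$invA3_to_molL
  oracle <- pracma::quadgk(function(l) cexc(l) * 2 * pi * l * 68, 0, 20)
  expect_equal(got, oracle, tolerance = 5e-3)
  # analytic value: NA * c_bulk * pi * 10^2 * 68 * 1e-27
  expect_equal(got, 6.02214076e23 * 0.1e-27 * pi * 100 * 68, tolerance = 5e-3)

  # monotone non-decreasing when c >= c_bulk everywhere
  inc <- excess_ions(prof, c_bulk = 0.1, R = seq(1, 25, 1))$excess
  expect_true(all(diff(inc) >= -1e-12))
  expect_error(excess_ions(prof, c_bulk = 0.1, R = 30), class = "ha_range_error")
})

test_that("surface-shell charges bracket correctly and respect electroneutrality", {
  st <- small_pair(n_bp = 10, box = c(118, 118, 68))
  # one +2 ion at surface distance ~5 A: inside R2 and R3, outside R1
  ph <- dplyr::filter(st, group == "phosphate", helix == 1, bp == 5, strand == 1)
  ax <- attr(st, "construction")$axis1
  u <- c(ph$x - ax[1], ph$y - ax[2], 0); u <- u / sqrt(sum(u^2))
  ion_pos <- c(ph$x, ph$y, ph$z) + 5 * u
  sti <- bare_structure(ion_pos, ha_box(st), charge = 2, mass = 24.3,
                        group = "ion:Mg", name = "Mg")
  combined <- labeled_structure(dplyr::bind_rows(
    dplyr::select(tibble::as_tibble(st), dplyr::all_of(helixatmos:::.structure_cols)),
    dplyr::mutate(tibble::as_tibble(sti), atom = max(st$atom) + 1)), ha_box(st))
  sc <- excess_charge_by_shell(as_trajectory(combined))
  tot <- function(s) sc$charge[sc$shell == s & sc$species == "total"]
  expect_equal(tot("R1"), 0)
  expect_equal(tot("R2"), 2)
  expect_equal(tot("R3"), 2)

  # neutral box: 40 phosphates (-40 e) + 20 Mg2+, shells grown to the box
  stn <- place_ions(st, "Mg", 2, "uniform_bulk", concentration = 0, seed = 1)
  stn <- place_ions(st, "Mg", 2, "helical_groove_chain", chain_sigma = 2,
                    count = 10, seed = 2)   # 10 per helix -> 20 ions, +40 e
  scn <- excess_charge_by_shell(as_trajectory(stn),
                                shells = c(all = 300))
  expect_equal(scn$charge[scn$species == "total"] + attr(scn, "dna_charge"), 0,
               tolerance = 1e-9)

  # 20 Mg2+ constructed inside 6 A -> R2 cation charge exactly +40 e
  ph_all <- dplyr::filter(st, group == "phosphate", helix == 1, strand == 1)
  pos <- purrr::map(1:20, function(k) {
    p <- dplyr::filter(st, group == "phosphate")[k, ]
    axk <- if (p$helix == 1) attr(st, "construction")$axis1 else attr(st, "construction")$axis2
    uu <- c(p$x - axk[1], p$y - axk[2], 0); uu <- uu / sqrt(sum(uu^2))
    c(p$x, p$y, p$z) + 4 * uu
  })
  ions <- bare_structure(do.call(rbind, pos), ha_box(st), charge = 2,
                         mass = 24.3, group = "ion:Mg", name = "Mg")
  comb <- labeled_structure(dplyr::bind_rows(
    dplyr::select(tibble::as_tibble(st), dplyr::all_of(helixatmos:::.structure_cols)),
    dplyr::mutate(tibble::as_tibble(ions), atom = max(st$atom) + dplyr::row_number())),
    ha_box(st))
  sc2 <- excess_charge_by_shell(as_trajectory(comb))
  expect_equal(sc2$charge[sc2$shell == "R2" & sc2$species == "total"], 40)
})

test_that("RDF is 1 for an ideal gas and peaks at constructed separations", {
  box <- c(40, 40, 40)
  set.seed(11)
  ref <- bare_structure(c(20, 20, 20), box, group = "probe")
  n <- 2000; n_frames <- 25
  gas <- ion_structure(matrix(runif(3 * n) * 40, ncol = 3), box)
  both <- labeled_structure(dplyr::bind_rows(
    tibble::as_tibble(ref),
    dplyr::mutate(tibble::as_tibble(gas), atom = atom + 1L)), box)
  coords <- lapply(1:n_frames, function(i) {
    rbind(c(20, 20, 20), matrix(runif(3 * n) * 40, ncol = 3))
  })
  w <- window_from_coords(both, coords)
  g <- rdf(w, "probe", "ion:Mg", bin_width = 1)
  rho <- n / prod(box)
  expsd <- 1 / sqrt(pmax(rho * 4 / 3 * pi * (g$r_hi^3 - g$r_lo^3) * n_frames, 1))
  expect_true(all(abs(g$g - 1) < 4 * expsd))
  # two atoms 5 A apart, one frame -> single occupied bin at 5 A
  pair <- labeled_structure(dplyr::bind_rows(
    tibble::as_tibble(bare_structure(c(10, 10, 10), box, group = "probe")),
    dplyr::mutate(tibble::as_tibble(ion_structure(c(15, 10, 10), box)), atom = 2L)), box)
  g2 <- rdf(as_trajectory(pair), "probe", "ion:Mg", bin_width = 0.5)
  expect_equal(g2$r[g2$mean_count > 0], 5.25, tolerance = 0.26)
  expect_equal(sum(g2$mean_count > 0), 1)
})

test_that("SDF normalizes a uniform gas to 1 and matches RDF for point references", {
  box <- c(40, 40, 40)
  set.seed(13)
  n <- 1500; n_frames <- 30
  ref <- bare_structure(c(20, 20, 20), box, group = "probe")
  gas <- ion_structure(matrix(runif(3 * n) * 40, ncol = 3), box)
  both <- labeled_structure(dplyr::bind_rows(
    tibble::as_tibble(ref),
    dplyr::mutate(tibble::as_tibble(gas), atom = atom + 1L)), box)
  coords <- lapply(1:n_frames, function(i) {
    rbind(c(20, 20, 20), matrix(runif(3 * n) * 40, ncol = 3))
  })
  w <- window_from_coords(both, coords)
  s <- sdf(w, "probe", "ion:Mg", bin_width = 1, mc_samples = 2e5, mc_seed = 4)
  g <- rdf(w, "probe", "ion:Mg", bin_width = 1)
  rho <- n / prod(box)
  expsd <- 1 / sqrt(pmax(rho * s$shell_volume * n_frames, 1))
  ok <- s$shell_volume > 50
  expect_true(all(abs(s$g[ok] - 1) < 4 * expsd[ok]))
  # point reference: SDF equals RDF within the counting noise
  expect_equal(s$g[ok], g$g[ok], tolerance = 0.15)

  # groove-chain fixture: ions Gaussian (sigma = 1) around a curve 3 A
  # outside a dense reference helix -> modal bin at 3 +- 0.5 A
  zz <- seq(0, 40, by = 0.25)
  curve <- cbind(20 + 8.9 * cos(0.2 * zz), 20 + 8.9 * sin(0.2 * zz), zz)
  refs <- bare_structure(curve, box, group = "probe")
  set.seed(17)
  ni <- 3000
  zi <- runif(ni) * 40
  guide <- cbind(20 + 11.9 * cos(0.2 * zi), 20 + 11.9 * sin(0.2 * zi), zi)
  ions <- ion_structure(guide + matrix(rnorm(3 * ni), ncol = 3), box)
  comb <- labeled_structure(dplyr::bind_rows(
    tibble::as_tibble(refs),
    dplyr::mutate(tibble::as_tibble(ions), atom = atom + nrow(refs))), box)
  sg <- sdf(as_trajectory(comb), "probe", "ion:Mg", bin_width = 0.5,
            r_max = 10, mc_samples = 2e5, mc_seed = 5)
  modal <- sg$r[which.max(sg$mean_count)]
  expect_lt(abs(modal - 3), 0.51)
})
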