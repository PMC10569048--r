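# Ground-truth generators: duplex geometry, ion/water placement, velocities.

test_that("duplex construction reproduces the requested helical geometry", {
  spec <- helix_spec(n_bp = 20, rise = 3.4, twist = 36)
  st <- build_duplex_pair(spec, separation = 2.8, theta = 0, box = c(118, 118, 68))

  ph1 <- dplyr::filter(st, group == "phosphate", helix == 1, strand == 1) %>%
    dplyr::arrange(bp)
  # consecutive strand-1 phosphates differ by exactly 36 deg and 3.4 A
  ax <- attr(st, "construction")$axis1
  phi <- atan2(ph1$y - ax[2], ph1$x - ax[1])
  dphi <- diff(phi) %% (2 * pi)
  expect_equal(dphi, rep(36 * pi / 180, 19), tolerance = 1e-9)
  expect_equal(diff(ph1$z), rep(3.4, 19), tolerance = 1e-12)
  # helix repeats after 10 bp (360/36)
  expect_equal(sin(phi[11]), sin(phi[1]), tolerance = 1e-9)
  expect_equal(cos(phi[11]), cos(phi[1]), tolerance = 1e-9)
  # every phosphate carries -1 e
  expect_true(all(st$charge[st$group == "phosphate"] == -1))
  # strand 2 phosphate k sits at the same z, offset by groove_phase
  ph2 <- dplyr::filter(st, group == "phosphate", helix == 1, strand == 2) %>%
    dplyr::arrange(bp)
  expect_equal(ph2$z, ph1$z)
  phi2 <- atan2(ph2$y - ax[2], ph2$x - ax[1])
  expect_equal((phi2 - phi) %% (2 * pi), rep(154 * pi / 180, 20), tolerance = 1e-9)
})

test_that("single base pair gives one phosphate per strand at z = 0", {
  st <- build_duplex_pair(helix_spec(n_bp = 1), separation = 2.8, theta = 0,
                          box = c(100, 100, 20))
  ph <- dplyr::filter(st, group == "phosphate", helix == 1)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$z, c(0, 0))
})

test_that("interhelical distance and rotation are recovered from coordinates", {
  spec <- helix_spec(n_bp = 20)
  st <- build_duplex_pair(spec, separation = 2.8, theta = 0.25,
                          box = c(118, 118, 68))
  # centroid-to-centroid xy distance of the two fitted axes = 28.0 A
  est <- estimate_d_theta(st)
  expect_equal(est$d, 2.8, tolerance = 1e-9)
  expect_equal(est$theta, 0.25, tolerance = 1e-9)
  # property: recovery across a grid of built geometries
  for (d in c(2.4, 3.2, 4.0)) for (th in c(0, 1.7, 5.9)) {
    e <- estimate_d_theta(build_duplex_pair(spec, d, th, c(118, 118, 68)))
    expect_equal(e$d, d, tolerance = 1e-9)
    circ_err <- abs(((e$theta - th + pi) %% (2 * pi)) - pi)
    expect_lt(circ_err, 1e-9)
  }
})

test_that("degenerate and infeasible geometries are rejected", {
  spec <- helix_spec(n_bp = 10)
  expect_error(build_duplex_pair(spec, separation = 1.0, theta = 0,
                                 box = c(118, 118, 68)),
               class = "ha_degenerate_geometry")
  expect_error(build_duplex_pair(spec, separation = 2.8, theta = 0,
                                 box = c(40, 40, 68)),
               class = "ha_geometry_error")
  # periodic continuation requires commensurate box (repeat = 34 A)
  expect_error(build_duplex_pair(spec, separation = 2.8, theta = 0,
                                 box = c(118, 118, 60), periodic = TRUE),
               class = "ha_geometry_error")
  expect_s3_class(build_duplex_pair(spec, separation = 2.8, theta = 0,
                                    box = c(118, 118, 68), periodic = TRUE),
                  "ha_structure")
  expect_error(helix_spec(n_bp = 0), class = "ha_domain_error")
  expect_error(helix_spec(twist = 200), class = "ha_domain_error")
})

test_that("uniform ion placement draws Poisson counts at c V N_A", {
  st <- small_pair()
  # zero concentration -> zero ions
  st0 <- place_ions(st, "Mg", 2, "uniform_bulk", concentration = 0, seed = 1)
  expect_equal(nrow(st0), nrow(st))
  # 0.05 mol/L in the 11.8 x 11.8 x 6.8 nm^3 study box: mean c V N_A ~ 28.5
  box <- c(118, 118, 68)
  lam <- 0.05 * prod(box) * ha_constants()$NA_mol * 1e-27
  counts <- vapply(1:1000, function(s) {
    sti <- place_ions(st, "Mg", 2, "uniform_bulk", concentration = 0.05, seed = s)
    sum(sti$group == "ion:Mg")
  }, numeric(1))
  se <- sqrt(lam / 1000)  # Poisson
  expect_lt(abs(mean(counts) - lam), 3 * se)
})

test_that("groove-chain placement reproduces its generating distribution", {
  st <- small_pair()
  # sigma -> 0: ions exactly on the guide helix (radius backbone + offset)
  stg <- place_ions(st, "Mg", 2, "helical_groove_chain", chain_sigma = 1e-12,
                    count = 50, guide_offset = 3, seed = 2)
  ions <- dplyr::filter(stg, group == "ion:Mg")
  ax1 <- attr(st, "construction")$axis1
  ax2 <- attr(st, "construction")$axis2
  r1 <- sqrt((ions$x - ax1[1])^2 + (ions$y - ax1[2])^2)
  r2 <- sqrt((ions$x - ax2[1])^2 + (ions$y - ax2[2])^2)
  expect_equal(sort(pmin(r1, r2)), rep(8.9 + 3, 100), tolerance = 1e-6)
  # moment test at n = 1e4: displacement components are Normal(0, sigma)
  stn <- place_ions(st, "Mg", 2, "helical_groove_chain", chain_sigma = 1.5,
                    count = 5000, seed = 3)
  disp <- attr(stn, "placement")[[1]]$displacements
  n <- length(disp)
  expect_lt(abs(mean(disp)), 3 * 1.5 / sqrt(n))
  expect_lt(abs(sd(disp) - 1.5), 3 * 1.5 / sqrt(2 * n))
})

test_that("Maxwell-Boltzmann velocities satisfy equipartition with zero net momentum", {
  st <- bare_structure(matrix(runif(3e4) * 50, ncol = 3), box = c(50, 50, 50),
                       mass = 24.3)
  # T = 0 -> all zero
  w0 <- sample_velocities(st, 0)
  expect_true(all(w0$frames$vx == 0 & w0$frames$vy == 0 & w0$frames$vz == 0))
  # equipartition at 300 K, N = 1e4
  w <- sample_velocities(st, 300, seed = 7)
  v2 <- w$frames$vx^2 + w$frames$vy^2 + w$frames$vz^2
  ke_per_dof <- mean(24.3 * v2 / 2) / 3 * 0.01     # kJ/mol
  kT2 <- ha_constants()$kB * 300 / 2
  se <- kT2 * sqrt(2 / (3 * nrow(st)))
  expect_lt(abs(ke_per_dof - kT2), 3 * se)
  # net momentum removed
  p <- c(sum(24.3 * w$frames$vx), sum(24.3 * w$frames$vy), sum(24.3 * w$frames$vz))
  expect_lt(max(abs(p)) / sum(24.3 * abs(w$frames$vx)), 1e-12)
  expect_error(sample_velocities(st, -10), class = "ha_domain_error")
})

test_that("generation is deterministic under a fixed seed", {
  st <- small_pair()
  a <- place_ions(st, "Mg", 2, "uniform_bulk", concentration = 0.05, seed = 42)
  b <- place_ions(st, "Mg", 2, "uniform_bulk", concentration = 0.05, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  va <- sample_velocities(st, 300, seed = 9)
  vb <- sample_velocities(st, 300, seed = 9)
  expect_identical(va$frames, vb$frames)
  wa <- place_waters(st, 50, seed = 5)
  wb <- place_waters(st, 50, seed = 5)
  expect_identical(as.data.frame(wa), as.data.frame(wb))
})
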