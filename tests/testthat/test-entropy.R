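# Density of states, 2PT partition, QHO/hard-sphere entropies, quasi-harmonic
# macromolecule terms, entropy-change reports.

R_GAS <- 8.314462618

qho_closed <- function(nu, temperature = 300) {
  k <- ha_constants()
  x <- k$h * nu / (k$kB * temperature)
  R_GAS * (x / (exp(x) - 1) - log(1 - exp(-x)))
}

# oscillator velocity track with equipartition amplitude (<KE> = kT/2)
osc_track <- function(nu0, n = 16384, dt = 0.01, m = 24.3, temperature = 300,
                      phase = 0) {
  kT <- ha_constants()$kB * temperature * 100
  w0 <- 2 * pi * nu0
  A <- sqrt(2 * kT / m) / w0
  A * w0 * cos(w0 * (0:(n - 1)) * dt + phase)
}

dos_obj <- function(freq, dos, n_particles, volume, mass, temperature = 300) {
  structure(tibble::tibble(freq = freq, trans = dos),
            n_particles = n_particles, volume = volume, mass = mass,
            temperature = temperature,
            class = c("ha_dos", "tbl_df", "tbl", "data.frame"))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

test_that("DoS of a harmonic oscillator is a unit peak at its frequency", {
  v <- matrix(osc_track(10), ncol = 1)
  d <- dos_from_velocities(v, 24.3, 0.01, 300, correlation_length = 10)
  expect_equal(trapz(d$freq, d$dos), 1, tolerance = 0.02)   # 1 dof
  expect_equal(d$freq[which.max(d$dos)], 10)
  # frequency off the study point still integrates to its dof
  v2 <- matrix(osc_track(17.3), ncol = 1)
  d2 <- dos_from_velocities(v2, 24.3, 0.01, 300, correlation_length = 10)
  expect_equal(trapz(d2$freq, d2$dos), 1, tolerance = 0.02)
})

test_that("a free particle concentrates all spectral weight at zero frequency", {
  v <- matrix(rep(1.7, 4096), ncol = 1)
  d <- dos_from_velocities(v, 40, 0.01, 300)
  expect_equal(d$freq[which.max(d$dos)], 0)
  expect_gt(d$dos[1] * (d$freq[2] - d$freq[1]) / trapz(d$freq, d$dos), 0.5)
})

test_that("Maxwell-Boltzmann gas: dof sum rule and Green-Kubo zero-frequency value", {
  # Langevin (OU) velocities: D = kT/(m gamma), s0 = 12 N m D / kT = 12 N / gamma
  N <- 500; m <- 40; gam <- 0.05; dt <- 0.02; n <- 16384
  kT <- ha_constants()$kB * 300 * 100
  v <- ou_velocities(n, 3 * N, dt, gam, sqrt(kT / m), seed = 2)
  d <- dos_from_velocities(v, rep(m, 3 * N), dt, 300, correlation_length = 120)
  expect_equal(trapz(d$freq, d$dos), 3 * N, tolerance = 0.01)
  # Green-Kubo D from the same trajectory's VACF
  ac <- helixatmos:::.acf_columns(v, 6000)
  vacf1 <- rowMeans(ac)                    # per-dof VACF
  D_gk <- sum(vacf1 * dt) - vacf1[1] * dt / 2
  expect_equal(d$dos[1], 12 * N * m * D_gk / kT, tolerance = 0.02)
  expect_equal(D_gk, kT / (m * gam), tolerance = 0.05)
})

test_that("fluidicity hits the solid and gas limits", {
  # pure solid: s0 = 0 -> f = 0, gas identically zero
  v <- matrix(osc_track(10), ncol = 1)
  d <- dos_from_velocities(v, 24.3, 0.01, 300, correlation_length = 10)
  dd <- dos_obj(d$freq, replace(d$dos, 1, 0), 1, 1e6, 24.3)
  p0 <- two_phase_partition(dd)
  expect_equal(p0$fluidicity, 0)
  expect_true(all(p0$gas == 0))
  # partition components sum back to the input DoS (pre-clipping)
  ddo <- dos_obj(d$freq, d$dos, 1, 1e6, 24.3)
  po <- two_phase_partition(ddo)
  expect_equal(po$gas + (po$total - po$gas), po$total, tolerance = 1e-12)

  # dilute OU gas: f = 1 within 0.02
  N <- 500; m <- 40; gam <- 0.05; dt <- 0.02
  kT <- ha_constants()$kB * 300 * 100
  v <- ou_velocities(16384, 3 * N, dt, gam, sqrt(kT / m), seed = 3)
  dg <- dos_from_velocities(v, rep(m, 3 * N), dt, 300, correlation_length = 120)
  pg <- two_phase_partition(dos_obj(dg$freq, dg$dos, N, 1e6, m))
  expect_equal(pg$fluidicity, 1, tolerance = 0.02)
  # gas component carries 3 N f degrees of freedom
  expect_equal(trapz(pg$freq, pg$gas), 3 * N * pg$fluidicity, tolerance = 0.01)
})

test_that("2PT entropy matches closed forms in both limits", {
  # solid limit: QHO entropy at the oscillator frequency, within 1%
  for (nu0 in c(6, 10)) {
    v <- matrix(osc_track(nu0), ncol = 1)
    d <- dos_from_velocities(v, 24.3, 0.01, 300, correlation_length = 10)
    S <- entropy_from_dos(two_phase_partition(dos_obj(d$freq, d$dos, 1, 1e6, 24.3)),
                          "translation")
    expect_equal(as.numeric(S), qho_closed(nu0), tolerance = 0.01)
  }
  # frozen mode: entropy -> 0 as nu0 grows
  v45 <- matrix(osc_track(45), ncol = 1)
  d45 <- dos_from_velocities(v45, 24.3, 0.01, 300, correlation_length = 10)
  S45 <- entropy_from_dos(two_phase_partition(dos_obj(d45$freq, d45$dos, 1, 1e6, 24.3)),
                          "translation")
  expect_lt(as.numeric(S45), 0.06)

  # gas limit: hard-sphere closed form at the fixture's (T, rho, m) within 3%
  N <- 500; m <- 40; gam <- 0.05; dt <- 0.02; V <- 1e6
  kT <- ha_constants()$kB * 300 * 100
  v <- ou_velocities(16384, 3 * N, dt, gam, sqrt(kT / m), seed = 4)
  dg <- dos_from_velocities(v, rep(m, 3 * N), dt, 300, correlation_length = 120)
  Sg <- entropy_from_dos(two_phase_partition(dos_obj(dg$freq, dg$dos, N, V, m)),
                         "translation")
  S_hs <- R_GAS * N * helixatmos:::hs_entropy_per_particle(m, 300, V, N, 0)
  expect_equal(as.numeric(Sg), S_hs, tolerance = 0.03)
})

test_that("rigid-molecule decomposition conserves degrees of freedom", {
  box <- c(40, 40, 40)
  st <- place_waters(bare_structure(matrix(20, 1, 3), box, group = "seed_atom"),
                     count = 60, seed = 8)
  st <- labeled_structure(dplyr::filter(tibble::as_tibble(st), group == "water"), box)
  n_frames <- 600
  frames <- dplyr::bind_rows(lapply(seq_len(n_frames), function(i) {
    tr <- sample_velocities(st, 300, seed = 100 + i, remove_com = FALSE)
    f <- tr$frames; f$frame <- i; f
  }))
  w <- trajectory_window(st, frames, dt = 0.02)
  d <- compute_dos(w, "water", "rigid_molecule", temperature = 300,
                   correlation_length = 2)
  n_at <- 180
  expect_equal(trapz(d$freq, d$total), 3 * n_at, tolerance = 0.02)
  expect_equal(trapz(d$freq, d$trans), 3 * 60, tolerance = 0.03)
  expect_equal(trapz(d$freq, d$rot), 3 * 60, tolerance = 0.03)
  # components sum to the total within the vib clipping
  expect_equal(trapz(d$freq, d$trans + d$rot + d$vib),
               trapz(d$freq, d$total), tolerance = 0.03)
  expect_error(compute_dos(window_from_coords(st, list(structure_coords(st))),
                           "water", temperature = 300),
               class = "ha_capability_error")
})

test_that("quasi-harmonic macromolecule terms match the analytic tether", {
  spec <- helix_spec(n_bp = 10)
  st <- build_duplex_pair(spec, 2.8, 0, c(118, 118, 68))
  h1 <- labeled_structure(dplyr::filter(tibble::as_tibble(st), helix == 1),
                          ha_box(st))
  M <- sum(h1$mass)
  kT <- ha_constants()$kB * 300 * 100
  nu_target <- 4                       # 1/ps
  k_spring <- M * (2 * pi * nu_target)^2
  sigma <- sqrt(kT / k_spring)
  base <- structure_coords(h1)
  set.seed(41)
  coords <- lapply(1:2500, function(i) sweep(base, 2, rnorm(3, sd = sigma), "+"))
  w <- window_from_coords(h1, coords)
  mm <- mcc_macromolecule_entropy(w, "helix1", temperature = 300)
  S_trans <- mm$S[mm$component == "transvib"]
  expect_equal(S_trans, 3 * qho_closed(nu_target), tolerance = 0.02)
  expect_equal(mm$S[mm$component == "rovib"], 0, tolerance = 1e-6)

  # frozen helix: zero entropy
  w0 <- window_from_coords(h1, rep(list(base), 20))
  m0 <- mcc_macromolecule_entropy(w0, "helix1")
  expect_equal(m0$S[m0$component == "total"], 0, tolerance = 1e-9)

  # invariance under a global rotation of the whole trajectory
  ang <- 0.9
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  coords_r <- lapply(coords[1:800], function(m) m %*% t(Rz))
  mr <- mcc_macromolecule_entropy(window_from_coords(h1, coords_r), "helix1")
  mu <- mcc_macromolecule_entropy(window_from_coords(h1, coords[1:800]), "helix1")
  expect_equal(mr$S, mu$S, tolerance = 1e-6)
})

test_that("entropy-change reports recover closed-form differences and additivity", {
  box <- c(60, 60, 60)
  mk_state <- function(nu0, n_ions = 30, n = 4000, dt = 0.01) {
    st <- bare_structure(matrix(runif(3 * n_ions, 10, 50), ncol = 3), box,
                         charge = 2, mass = 24.3, group = "ion:Mg", name = "Mg")
    kT <- ha_constants()$kB * 300 * 100
    w0 <- 2 * pi * nu0
    A <- sqrt(2 * kT / 24.3) / w0
    set.seed(77)
    phases <- matrix(runif(3 * n_ions) * 2 * pi, ncol = 3)
    tt <- (0:(n - 1)) * dt
    frames <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(frame = i, atom = st$atom,
                     x = st$x, y = st$y, z = st$z,
                     vx = A * w0 * cos(w0 * tt[i] + phases[, 1]),
                     vy = A * w0 * cos(w0 * tt[i] + phases[, 2]),
                     vz = A * w0 * cos(w0 * tt[i] + phases[, 3]))
    }))
    trajectory_window(st, frames, dt = dt)
  }
  bound <- mk_state(10)   # condensed-state ions stiffer
  free <- mk_state(5)
  expect_warning(rep_tbl <- entropy_change_report(bound, free, temperature = 300,
                                                  blocks = 5,
                                                  correlation_length = 4),
                 class = "ha_partial_report")
  cation <- rep_tbl[rep_tbl$component == "cation", ]
  expected <- -300 * (qho_closed(10) - qho_closed(5)) * 3 * 30 / 1000
  expect_equal(cation$minus_T_dS, expected, tolerance = 0.02)
  expect_false(rep_tbl$available[rep_tbl$component == "water"])

  # identical states -> zero change, and the total row is the component sum
  expect_warning(rep0 <- entropy_change_report(bound, bound, 300, blocks = 4))
  expect_equal(rep0$minus_T_dS[rep0$component == "cation"], 0, tolerance = 1e-9)
  expect_equal(rep0$minus_T_dS[rep0$component == "total"],
               sum(rep0$minus_T_dS[rep0$available & rep0$component != "total"]),
               tolerance = 1e-9)
})
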