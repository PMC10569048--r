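# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly on one core.

# bare structure from coordinate rows (no DNA), for low-level tests
bare_structure <- function(xyz, box, charge = 0, mass = 1, group = "probe",
                           name = "X", helix = NA_integer_) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  labeled_structure(tibble::tibble(
    atom = seq_len(n), name = rep_len(name, n), resname = "FIX",
    resid = seq_len(n), helix = rep_len(helix, n), group = rep_len(group, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), mass = rep_len(mass, n)), box)
}

# multi-frame window from a list of coordinate matrices over one structure
window_from_coords <- function(structure, coord_list, dt = 1) {
  frames <- dplyr::bind_rows(lapply(seq_along(coord_list), function(i) {
    m <- coord_list[[i]]
    tibble::tibble(frame = i, atom = structure$atom,
                   x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  trajectory_window(structure, frames, box = ha_box(structure), dt = dt)
}

# standard small duplex-pair fixture (study geometry, reduced size)
small_pair <- function(separation = 2.8, theta = 0.25, n_bp = 20,
                       box = c(118, 118, 68)) {
  build_duplex_pair(helix_spec(n_bp = n_bp), separation = separation,
                    theta = theta, box = box)
}

# dense charged rod along z as a bead chain: length L, total charge Q
bead_rod <- function(x, y, L, Q, n_beads, box, helix = NA_integer_,
                     group = "rod") {
  z <- (seq_len(n_beads) - 0.5) * L / n_beads
  bare_structure(cbind(rep(x, n_beads), rep(y, n_beads), z), box,
                 charge = Q / n_beads, mass = 95, group = group,
                 name = "P", helix = helix)
}

# closed form for the Coulomb energy of two parallel uniform line charges
# (charges Q1, Q2 spread over length L, axis separation a), kJ/mol
line_charge_energy <- function(Q1, Q2, L, a) {
  ke <- ha_constants()$ke
  lam2 <- Q1 * Q2 / L^2
  ke * lam2 * 2 * (L * asinh(L / a) - sqrt(a^2 + L^2) + a)
}

frame_coords_for_test <- function(window, i) helixatmos:::frame_coords(window, i)

# Ornstein-Uhlenbeck velocity trajectory: exact discretization, one column
# per dof; sd = sqrt(kT/m), relaxation time 1/gamma
ou_velocities <- function(n_steps, n_dof, dt, gamma, sd, seed = 1) {
  set.seed(seed)
  a <- exp(-gamma * dt)
  b <- sd * sqrt(1 - a^2)
  v <- matrix(0, n_steps, n_dof)
  v[1, ] <- rnorm(n_dof, sd = sd)
  for (t in 2:n_steps) v[t, ] <- a * v[t - 1, ] + b * rnorm(n_dof)
  v
}
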