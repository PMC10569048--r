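# broom-style tidiers for the package's result objects.

#' @describeIn reconstruct_fes tidy a free-energy surface into a long tibble
#' @param x an `ha_fes`.
#' @param ... unused.
#' @export
tidy.ha_fes <- function(x, ...) export_polar(x)

#' @describeIn reconstruct_fes one-row summary: grid size, depth, minima
#' @export
glance.ha_fes <- function(x, ...) {
  mins <- locate_minima(x)
  tibble(n_d = length(x$d), n_theta = length(x$theta),
         depth = max(x$F), n_minima = nrow(mins),
         d_min = if (nrow(mins) > 0) mins$d[1] else NA_real_,
         theta_min = if (nrow(mins) > 0) mins$theta[1] else NA_real_,
         bias_factor = x$bias_factor, temperature = x$temperature)
}

#' @describeIn number_density tidy a 3D field into voxel rows
#' @param x an `ha_field`.
#' @param ... unused.
#' @export
tidy.ha_field <- function(x, ...) {
  dims <- dim(x$values)
  sp <- x$spacing3 %||% rep(x$spacing, 3)
  xs <- x$origin[1] + (rep(seq_len(dims[1]), times = dims[2] * dims[3]) - 0.5) * sp[1]
  ys <- x$origin[2] + (rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]) - 0.5) * sp[2]
  zs <- x$origin[3] + (rep(seq_len(dims[3]), each = dims[1] * dims[2]) - 0.5) * sp[3]
  vals <- as.numeric(x$values)
  tibble(x = xs, y = ys, z = zs, value = vals)
}

#' @describeIn number_density one-row field summary (integral = mean count)
#' @export
glance.ha_field <- function(x, ...) {
  tibble(kind = x$kind, species = x$species, spacing = x$spacing,
         integral = field_integral(x), n_frames = x$n_frames,
         max_value = max(x$values))
}

#' @describeIn two_phase_partition tidy the partition into a long tibble
#' @param x an `ha_2pt`.
#' @param ... unused.
#' @export
tidy.ha_2pt <- function(x, ...) {
  tibble(freq = rep(x$freq, 3),
         component = rep(c("total", "gas", "solid"), each = length(x$freq)),
         dos = c(x$total, x$gas, x$solid))
}

#' @describeIn two_phase_partition one-row summary (fluidicity, dof split)
#' @export
glance.ha_2pt <- function(x, ...) {
  tibble(fluidicity = x$fluidicity, Delta = x$Delta, s0 = x$s0, y = x$y,
         dof_gas = trapz(x$freq, x$gas), dof_total = trapz(x$freq, x$total),
         clipped_dof = x$clipped_dof)
}

#' @describeIn run_langevin_wtmd tidy a run: the CV trajectory
#' @param x an `ha_wtmd_run`.
#' @param ... unused.
#' @export
tidy.ha_wtmd_run <- function(x, ...) x$cv

#' @describeIn run_langevin_wtmd one-row run summary
#' @export
glance.ha_wtmd_run <- function(x, ...) {
  tibble(n_steps_recorded = nrow(x$cv), n_hills = nrow(x$hills),
         final_height = if (nrow(x$hills) > 0) tail(x$hills$height, 1) else NA_real_,
         bias_factor = if (nrow(x$hills) > 0) x$hills$biasf[1] else NA_real_)
}

#' @describeIn convergence_diagnostics tidy diagnostics: block dF estimates
#' @param x an `ha_convergence`.
#' @param ... unused.
#' @export
tidy.ha_convergence <- function(x, ...) x$block_delta_f

#' @describeIn convergence_diagnostics one-row convergence summary
#' @export
glance.ha_convergence <- function(x, ...) {
  tibble(converged = x$converged, delta_f_spread = x$delta_f_spread,
         first_block_height = if (length(x$block_heights) > 0) x$block_heights[1] else NA_real_,
         final_block_height = if (length(x$block_heights) > 0) tail(x$block_heights, 1) else NA_real_)
}
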