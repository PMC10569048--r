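# Well-tempered metadynamics free-energy reconstruction on the (d, theta)
# plane: F = -(gamma/(gamma-1)) * V_bias with theta-periodic Gaussians,
# 1D projection, minima location, state free-energy differences, and
# convergence diagnostics (hill-height decay + block analysis).

#' Reconstruct a 2D free-energy surface from deposited hills
#'
#' Sums the recorded Gaussians into the bias potential (theta treated
#' periodically through wrapped angular differences) and converts to the
#' free energy via the well-tempered identity
#' `F = -(gamma/(gamma-1)) V_bias`, shifted so `min F = 0`.
#'
#' @param hills a [hill_series()].
#' @param d_grid grid over the distance CV, nm (default `seq(2.2, 4.2,
#'   0.02)`; must cover all hill centers).
#' @param theta_grid periodic grid over the azimuthal CV, radians (default
#'   2-degree spacing over `[0, 2 pi)`).
#' @param temperature kelvin (metadata; the conversion needs only gamma).
#' @param average_from optional fraction in (0, 1): instead of the final
#'   bias, use the bias averaged over deposition times after this fraction
#'   of the series (the standard time-averaged well-tempered estimator,
#'   which suppresses the late-time oscillation of the instantaneous bias).
#'   `NULL` (default) reconstructs from the plain hill sum.
#' @return object of class `ha_fes`: list with `d`, `theta`, `F` (matrix
#'   d x theta, kJ/mol, min 0), `V_bias`, `bias_factor`, `temperature`.
#' @export
reconstruct_fes <- function(hills, d_grid = seq(2.2, 4.2, by = 0.02),
                            theta_grid = seq(0, 2 * pi - pi / 90, by = pi / 90),
                            temperature = 300, average_from = NULL) {
  nh <- nrow(hills)
  V <- matrix(0, length(d_grid), length(theta_grid))
  gamma <- if (nh > 0) hills$biasf[1] else Inf
  if (nh > 0) {
    if (any(hills$cv1 < min(d_grid)) || any(hills$cv1 > max(d_grid))) {
      bad <- which(hills$cv1 < min(d_grid) | hills$cv1 > max(d_grid))[1]
      abort(sprintf("hill %d center (d = %.3f) outside the d grid", bad, hills$cv1[bad]),
            class = "ha_range_error")
    }
    w <- rep(1, nh)
    if (!is.null(average_from)) {
      # hill i enters the checkpoint average with weight = fraction of
      # checkpoints in the window whose cumulative bias includes it
      win <- if (length(average_from) == 2) {
        as.integer(average_from)
      } else {
        c(max(1L, ceiling(average_from * nh)), nh)
      }
      K <- win[2] - win[1] + 1L
      w <- pmax(0L, win[2] - pmax(seq_len(nh), win[1]) + 1L) / K
    }
    # V = Ed diag(w h) Ed_theta^T in one BLAS product
    Ed <- exp(-outer(d_grid, hills$cv1, "-")^2 /
                matrix(2 * hills$sigma1^2, length(d_grid), nh, byrow = TRUE))
    dth <- angle_diff(outer(theta_grid, hills$cv2, "-"), 0)
    Et <- exp(-dth^2 / matrix(2 * hills$sigma2^2, length(theta_grid), nh, byrow = TRUE))
    V <- sweep(Ed, 2, w * hills$height, "*") %*% t(Et)
  }
  pref <- if (is.finite(gamma)) gamma / (gamma - 1) else 1
  F <- -pref * V
  F <- F - min(F)
  structure(list(d = d_grid, theta = theta_grid, F = F, V_bias = V,
                 bias_factor = gamma, temperature = temperature),
            class = "ha_fes")
}

#' @export
print.ha_fes <- function(x, ...) {
  cat(sprintf("<ha_fes> %d x %d grid, d in [%.2f, %.2f] nm, depth %.2f kJ/mol, gamma = %g\n",
              length(x$d), length(x$theta), min(x$d), max(x$d), max(x$F),
              x$bias_factor))
  invisible(x)
}

#' Project a free-energy surface onto the distance axis
#'
#' Boltzmann-weighted marginalization over theta:
#' `F(d) = -kT log integral exp(-F(d, theta)/kT) dtheta`, re-shifted to
#' min 0.
#'
#' @param fes an `ha_fes`.
#' @param temperature kelvin; defaults to the surface's.
#' @return tibble of class `ha_fes_profile` with `d` (nm) and `F` (kJ/mol).
#' @export
project_1d <- function(fes, temperature = fes$temperature) {
  kT <- .kB * temperature
  dth <- 2 * pi / length(fes$theta)
  # log-sum-exp across each row for numerical safety
  Fd <- apply(fes$F, 1, function(row) {
    m <- min(row)
    -kT * (log(sum(exp(-(row - m) / kT)) * dth) - m / kT)
  })
  Fd <- Fd - min(Fd)
  out <- tibble(d = fes$d, F = Fd)
  structure(out, class = c("ha_fes_profile", class(out)),
            temperature = temperature)
}

#' Locate free-energy minima
#'
#' Finds grid-local minima (theta-periodic neighborhoods), refines each by a
#' quadratic fit in both directions, and orders them by depth. Minima with a
#' prominence (barrier to a deeper neighbor along the grid) below
#' `min_prominence` are dropped.
#'
#' @param fes an `ha_fes`.
#' @param min_prominence kJ/mol (default 0.5).
#' @return tibble with `d`, `theta`, `F` ordered by increasing F; zero rows
#'   for a flat surface.
#' @export
locate_minima <- function(fes, min_prominence = 0.5) {
  F <- fes$F
  nd <- nrow(F); nt <- ncol(F)
  if (max(F) - min(F) < 1e-12) {
    return(tibble(d = numeric(0), theta = numeric(0), F = numeric(0)))
  }
  wrap_j <- function(j) (j - 1L) %% nt + 1L
  res <- list()
  for (i in seq_len(nd)) for (j in seq_len(nt)) {
    ii <- max(1L, i - 1L):min(nd, i + 1L)
    jj <- wrap_j((j - 1L):(j + 1L))
    if (F[i, j] <= min(F[ii, jj]) && sum(F[ii, jj] == F[i, j]) == 1) {
      res[[length(res) + 1L]] <- c(i, j)
    }
  }
  if (length(res) == 0) {
    return(tibble(d = numeric(0), theta = numeric(0), F = numeric(0)))
  }
  refine <- function(i, j) {
    # quadratic sub-grid refinement along each axis independently
    dd <- fes$d[i]; th <- fes$theta[j]
    f0 <- F[i, j]
    if (i > 1 && i < nd) {
      a <- F[i - 1, j]; b <- F[i + 1, j]
      den <- a - 2 * f0 + b
      if (den > 1e-12) dd <- dd + 0.5 * (a - b) / den * (fes$d[2] - fes$d[1])
    }
    jm <- wrap_j(j - 1L); jp <- wrap_j(j + 1L)
    a <- F[i, jm]; b <- F[i, jp]
    den <- a - 2 * f0 + b
    dth <- 2 * pi / nt
    if (den > 1e-12) th <- th + 0.5 * (a - b) / den * dth
    c(dd, wrap_angle(th), f0)
  }
  m <- t(vapply(res, function(ij) refine(ij[1], ij[2]), numeric(3)))
  out <- tibble(d = m[, 1], theta = m[, 2], F = m[, 3]) %>% arrange(.data$F)
  # prominence: barrier toward the global minimum must exceed the threshold
  keep <- vapply(seq_len(nrow(out)), function(k) {
    k == 1 || (ridge_barrier(fes, out[k, ], out[1, ]) - out$F[k]) >= min_prominence
  }, logical(1))
  out[keep, ]
}

# crude barrier estimate between two minima: max of F along the straight
# grid path in d at the shallower minimum's theta
ridge_barrier <- function(fes, from, to) {
  i1 <- which.min(abs(fes$d - from$d)); i2 <- which.min(abs(fes$d - to$d))
  j <- which.min(abs(angle_diff(fes$theta, from$theta)))
  max(fes$F[min(i1, i2):max(i1, i2), j])
}

#' Free-energy difference between two interhelical distances
#'
#' `dF = F(d_bound) - F(d_free)` with linear interpolation between grid
#' points, optionally scaled per base pair and to longer DNA (the per-bp
#' free energy is additive along the axis, so
#' `dF_total(N_bp) = dF_per_bp * N_bp`).
#'
#' @param profile an `ha_fes_profile` from [project_1d()] (or any tibble
#'   with `d`, `F`).
#' @param d_bound,d_free state distances, nm (defaults 2.8 and 4.0, the
#'   condensed and free states).
#' @param n_bp base pairs represented by the profile (for the per-bp value).
#' @param scale_to_bp optional base-pair counts to extrapolate to.
#' @return list with `delta_f` (kJ/mol), `per_bp` (kJ/mol/bp, when `n_bp`
#'   given), and `scaled` (tibble over `scale_to_bp`).
#' @export
delta_f <- function(profile, d_bound = 2.8, d_free = 4.0, n_bp = NULL,
                    scale_to_bp = NULL) {
  rng <- range(profile$d)
  if (d_bound < rng[1] || d_bound > rng[2] || d_free < rng[1] || d_free > rng[2]) {
    abort("state distance outside the profile range", class = "ha_range_error")
  }
  fb <- approx(profile$d, profile$F, xout = d_bound)$y
  ff <- approx(profile$d, profile$F, xout = d_free)$y
  df <- fb - ff
  per_bp <- if (!is.null(n_bp)) df / n_bp else NULL
  scaled <- if (!is.null(scale_to_bp) && !is.null(per_bp)) {
    tibble(n_bp = scale_to_bp, delta_f = per_bp * scale_to_bp)
  } else NULL
  list(delta_f = df, per_bp = per_bp, scaled = scaled)
}

#' Convergence diagnostics for a well-tempered run
#'
#' Tracks the decay of deposited hill heights and the spread of the
#' bound/free free-energy difference across non-overlapping hill blocks.
#' Each block's surface is reconstructed from that window's deposition
#' alone: once a well-tempered run has converged, hills are laid down
#' uniformly over the visited region, so the per-block differences collapse
#' toward zero and their spread measures the residual sampling error.
#'
#' @param hills a [hill_series()].
#' @param blocks number of blocks (default 4, >= 2).
#' @param d_bound,d_free state distances for the block dF series, nm.
#' @param asymptote_fraction flag converged when the final block's mean
#'   height is below this fraction of the first block's (default 0.2).
#' @param ... grids passed to [reconstruct_fes()].
#' @return object of class `ha_convergence`: list with `height_series`,
#'   `block_delta_f` (tibble block, delta_f), `delta_f_spread`, `converged`.
#' @export
convergence_diagnostics <- function(hills, blocks = 4, d_bound = 2.8,
                                    d_free = 4.0, asymptote_fraction = 0.2,
                                    ...) {
  nh <- nrow(hills)
  if (blocks < 2) abort("need at least 2 blocks", class = "ha_domain_error")
  if (nh < 2 * blocks) {
    warn("too few hills for a stable block analysis; diagnostics degraded",
         class = "ha_degraded_diagnostics")
  }
  idx <- if (nh > 0) cut(seq_len(nh), breaks = blocks, labels = FALSE) else integer(0)
  block_df <- purrr::map_dfr(seq_len(blocks), function(b) {
    sel <- if (nh > 0) which(idx == b) else integer(0)
    if (length(sel) == 0) return(tibble(block = b, delta_f = NA_real_))
    f <- reconstruct_fes(hill_series(hills[sel, ]), ...)
    p <- project_1d(f)
    dfv <- tryCatch(delta_f(p, d_bound, d_free)$delta_f, error = function(e) NA_real_)
    tibble(block = b, delta_f = dfv)
  })
  hmean <- if (nh > 0) {
    vapply(split(hills$height, idx), mean, numeric(1))
  } else numeric(0)
  converged <- length(hmean) >= 2 && is.finite(hmean[1]) && hmean[1] > 0 &&
    (hmean[length(hmean)] < asymptote_fraction * hmean[1])
  structure(list(
    height_series = tibble(time = hills$time, height = hills$height),
    block_heights = hmean,
    block_delta_f = block_df,
    delta_f_spread = if (all(is.finite(block_df$delta_f))) {
      max(block_df$delta_f) - min(block_df$delta_f)
    } else NA_real_,
    converged = converged
  ), class = "ha_convergence")
}

#' Free-energy recovery benchmark on the toy double well
#'
#' End-to-end validation harness: runs well-tempered Langevin sampling on
#' the analytic double-well potential (wells at 2.8 and 4.0 nm), rebuilds
#' the surface from the deposited hills with the time-averaged estimator,
#' and compares the theta-projected profile against the exact marginal
#' `F(d) = -kT log integral exp(-F_true(d,theta)/kT) dtheta`. Run
#' parameters are fixed study conditions chosen so the sampler converges:
#' 4e6 overdamped steps of 0.01 ps, hills every 200 steps, initial height
#' 0.8 kJ/mol, widths (0.08 nm, 0.6 rad), bias factor 8.
#'
#' @param seed RNG seed for the sampler.
#' @param steps integration steps (default 4e6).
#' @param potential the ground-truth [toy_potential_2d()].
#' @return list: `max_error` (max |F_rec - F_true| over the sampled core
#'   d in [2.5, 4.3] nm after mean alignment, kJ/mol), `delta_f_error`,
#'   `delta_f`, `delta_f_true`, `barrier` (kJ/mol), `fes`, `profile`,
#'   `hills`.
#' @export
fes_recovery_benchmark <- function(seed = 1, steps = 4e6,
                                   potential = toy_potential_2d()) {
  kT <- .kB * potential$temperature
  d_grid <- seq(potential$d_domain[1], potential$d_domain[2], by = 0.02)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  f_true <- vapply(d_grid, function(d) {
    -kT * log(mean(exp(-potential$value(d, th) / kT)) * 2 * pi)
  }, numeric(1))
  f_true <- f_true - min(f_true)
  run <- run_langevin_wtmd(potential, steps = steps, dt = 0.01, friction = 50,
                           hill_stride = 200, hill_height0 = 0.8,
                           hill_widths = c(0.08, 0.6), bias_factor = 8,
                           seed = seed)
  fes <- reconstruct_fes(run$hills, d_grid = d_grid,
                         temperature = potential$temperature,
                         average_from = 0.3)
  prof <- project_1d(fes)
  core <- d_grid >= 2.5 & d_grid <= 4.3
  err <- (prof$F[core] - mean(prof$F[core])) - (f_true[core] - mean(f_true[core]))
  df_rec <- delta_f(prof, 2.8, 4.0)$delta_f
  df_true <- delta_f(tibble(d = d_grid, F = f_true), 2.8, 4.0)$delta_f
  list(max_error = max(abs(err)), delta_f_error = df_rec - df_true,
       delta_f = df_rec, delta_f_true = df_true,
       barrier = potential$params$barrier, fes = fes, profile = prof,
       hills = run$hills)
}

#' Export a free-energy surface as a polar-chart table
#'
#' Long-format table with the interhelical distance as radius and theta as
#' angle, suitable for polar heat maps.
#'
#' @param fes an `ha_fes`.
#' @return tibble with `d` (radius, nm), `theta` (rad), `F` (kJ/mol).
#' @export
export_polar <- function(fes) {
  tibble(d = rep(fes$d, times = length(fes$theta)),
         theta = rep(fes$theta, each = length(fes$d)),
         F = as.numeric(fes$F))
}
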