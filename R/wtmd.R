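# Toy collective-variable sampler: overdamped Langevin dynamics on an
# analytic 2D potential F(d, theta) with well-tempered metadynamics hill
# deposition. Provides ground truth for the free-energy reconstruction.

#' Analytic 2D toy potential over (d, theta)
#'
#' Ground-truth free-energy surfaces for validating the metadynamics
#' machinery. `"double_well"` is a quartic double well in the interhelical
#' distance d (wells at `d1`, `d2`, barrier height `barrier`, depth
#' asymmetry `tilt`: the d-profile is `barrier*(u^2-1)^2 + tilt*u` with u
#' mapping d1 -> -1 and d2 -> +1, so positive `tilt` deepens the d1 --
#' condensed -- well) plus a
#' cosine well in the azimuthal angle (`coupling * (1 - cos(theta -
#' theta0))`), periodic in theta with period 2 pi. `"single_well"` is a
#' harmonic basin, useful for Boltzmann-sampling checks.
#'
#' @param form `"double_well"` or `"single_well"`.
#' @param d1,d2 well positions, nm.
#' @param barrier quartic barrier height at the midpoint, kJ/mol.
#' @param tilt linear asymmetry, kJ/mol; the well free-energy difference
#'   F(d1) - F(d2) is approximately `-2 * tilt`.
#' @param coupling amplitude of the theta well, kJ/mol.
#' @param theta0 theta well position, radians.
#' @param kappa harmonic stiffness for `"single_well"`, kJ/mol/nm^2.
#' @param temperature kelvin.
#' @param d_domain declared d domain, nm (dynamics outside it is an error).
#' @return object of class `ha_potential`: list with `value(d, theta)`,
#'   `grad(d, theta)` (2-vector function), `d_domain`, `temperature`,
#'   `params`.
#' @export
toy_potential_2d <- function(form = c("double_well", "single_well"),
                             d1 = 2.8, d2 = 4.0, barrier = 6, tilt = 1.5,
                             coupling = 1.0, theta0 = 0.25, kappa = 40,
                             temperature = 300, d_domain = c(2.0, 4.8)) {
  form <- match.arg(form)
  half <- (d2 - d1) / 2
  mid <- (d1 + d2) / 2
  if (form == "double_well") {
    value <- function(d, theta) {
      u <- (d - mid) / half
      barrier * (u^2 - 1)^2 + tilt * u + coupling * (1 - cos(theta - theta0))
    }
    grad <- function(d, theta) {
      u <- (d - mid) / half
      c(d = (4 * barrier * u * (u^2 - 1) + tilt) / half,
        theta = coupling * sin(theta - theta0))
    }
  } else {
    value <- function(d, theta) {
      0.5 * kappa * (d - mid)^2 + coupling * (1 - cos(theta - theta0))
    }
    grad <- function(d, theta) {
      c(d = kappa * (d - mid), theta = coupling * sin(theta - theta0))
    }
  }
  structure(list(form = form, value = value, grad = grad,
                 d_domain = d_domain, temperature = temperature,
                 params = list(d1 = d1, d2 = d2, barrier = barrier, tilt = tilt,
                               coupling = coupling, theta0 = theta0, kappa = kappa)),
            class = "ha_potential")
}

# bias grid bookkeeping: value + both gradient components on a (d, theta) grid
.new_bias_grid <- function(d_domain, n_d = 121, n_theta = 64) {
  d <- seq(d_domain[1], d_domain[2], length.out = n_d)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[1:n_theta]
  list(d = d, theta = theta, dd = d[2] - d[1], dth = theta[2] - theta[1],
       V = matrix(0, n_d, n_theta), Gd = matrix(0, n_d, n_theta),
       Gt = matrix(0, n_d, n_theta))
}

.add_hill_to_grid <- function(g, cd, ct, sd, st, h) {
  ed <- exp(-(g$d - cd)^2 / (2 * sd^2))
  dth <- angle_diff(g$theta, ct)
  et <- exp(-dth^2 / (2 * st^2))
  gauss <- h * outer(ed, et)
  g$V <- g$V + gauss
  g$Gd <- g$Gd - gauss * outer((g$d - cd) / sd^2, rep(1, length(g$theta)))
  g$Gt <- g$Gt - gauss * outer(rep(1, length(g$d)), dth / st^2)
  g
}

# bilinear interpolation of V, Gd, Gt at a point (theta wraps)
.interp_bias <- function(g, d, theta) {
  nd <- length(g$d); nt <- length(g$theta)
  fd <- (d - g$d[1]) / g$dd
  i <- floor(fd); wi <- fd - i
  i <- min(max(i, 0), nd - 2)
  ft <- wrap_angle(theta) / g$dth
  j <- floor(ft) %% nt; wj <- ft - floor(ft)
  i1 <- i + 1L; i2 <- i + 2L
  j1 <- j + 1L; j2 <- (j + 1L) %% nt + 1L
  bl <- function(M) {
    (1 - wi) * ((1 - wj) * M[i1, j1] + wj * M[i1, j2]) +
      wi * ((1 - wj) * M[i2, j1] + wj * M[i2, j2])
  }
  c(V = bl(g$V), Gd = bl(g$Gd), Gt = bl(g$Gt))
}

#' Run overdamped Langevin dynamics with well-tempered hill deposition
#'
#' Integrates `dx = -grad(F + V_bias)/friction dt + sqrt(2 kT dt/friction) xi`
#' on the (d, theta) plane of an analytic [toy_potential_2d()], wrapping theta
#' periodically. Every `hill_stride` steps a Gaussian hill is deposited with
#' the well-tempered height rescaling
#' `h = hill_height0 * exp(-V_bias(x) / (kB T (bias_factor - 1)))`.
#' With `hill_height0 = 0` this is plain Langevin sampling of the potential.
#'
#' @param potential a [toy_potential_2d()].
#' @param steps number of integration steps.
#' @param dt time step, ps.
#' @param friction friction coefficient, kJ/mol ps / nm^2 (and per rad^2 for
#'   theta; both CVs share the friction).
#' @param hill_stride deposit a hill every this many steps.
#' @param hill_height0 initial hill height, kJ/mol (default 1.0).
#' @param hill_widths Gaussian sigmas `c(sigma_d, sigma_theta)` in (nm, rad).
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @param seed RNG seed.
#' @param x0 starting point `c(d, theta)`; defaults to the first well.
#' @param record_stride store the CV position every this many steps.
#' @return list of class `ha_wtmd_run`: `cv` (tibble time, d, theta),
#'   `hills` (a [hill_series()]), `potential`, and the bias grid.
#' @export
run_langevin_wtmd <- function(potential, steps, dt = 0.01, friction = 1.0,
                              hill_stride = 500, hill_height0 = 1.0,
                              hill_widths = c(0.05, 0.25), bias_factor = 10,
                              seed = 1L, x0 = NULL, record_stride = 10L) {
  if (bias_factor <= 1) abort("bias_factor must be > 1", class = "ha_domain_error")
  kT <- .kB * potential$temperature
  dom <- potential$d_domain
  x <- x0 %||% c(potential$params$d1, potential$params$theta0)
  g <- .new_bias_grid(dom)
  depositing <- hill_height0 > 0
  n_rec <- floor(steps / record_stride)
  rec <- matrix(NA_real_, n_rec, 3)
  hills <- list()
  noise_sd <- sqrt(2 * kT * dt / friction)
  with_seed(seed, {
    xi <- NULL
    chunk <- 10000L
    for (step in seq_len(steps)) {
      k <- (step - 1L) %% chunk + 1L
      if (k == 1L) xi <- matrix(rnorm(2 * min(chunk, steps - step + 1L), sd = noise_sd), ncol = 2)
      gr <- unname(potential$grad(x[1], x[2]))
      if (depositing && length(hills) > 0) {
        b <- .interp_bias(g, x[1], x[2])
        gr <- gr + c(b[["Gd"]], b[["Gt"]])
      }
      x <- x - gr * dt / friction + xi[k, ]
      x[2] <- wrap_angle(x[2])
      if (x[1] < dom[1] || x[1] > dom[2]) {
        abort(sprintf("trajectory left the declared d domain at step %d (d = %.3f nm)",
                      step, x[1]), class = "ha_domain_violation")
      }
      if (depositing && step %% hill_stride == 0) {
        vb <- if (length(hills) > 0) .interp_bias(g, x[1], x[2])[["V"]] else 0
        h <- hill_height0 * exp(-vb / (kT * (bias_factor - 1)))
        g <- .add_hill_to_grid(g, x[1], x[2], hill_widths[1], hill_widths[2], h)
        hills[[length(hills) + 1L]] <- c(step * dt, x[1], x[2],
                                         hill_widths[1], hill_widths[2], h)
      }
      if (step %% record_stride == 0) {
        rec[step %/% record_stride, ] <- c(step * dt, x[1], x[2])
      }
    }
  })
  hills_tbl <- if (length(hills) > 0) {
    m <- do.call(rbind, hills)
    hill_series(tibble(time = m[, 1], cv1 = m[, 2], cv2 = m[, 3],
                       sigma1 = m[, 4], sigma2 = m[, 5], height = m[, 6],
                       biasf = bias_factor))
  } else {
    hill_series(tibble(time = numeric(0), cv1 = numeric(0), cv2 = numeric(0),
                       sigma1 = numeric(0), sigma2 = numeric(0),
                       height = numeric(0), biasf = numeric(0)))
  }
  structure(list(cv = tibble(time = rec[, 1], d = rec[, 2], theta = rec[, 3]),
                 hills = hills_tbl, potential = potential, bias_grid = g),
            class = "ha_wtmd_run")
}
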