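# Free-energy surface reconstruction, projection, minima, dF, diagnostics.

mk_hills <- function(time, cv1, cv2, h, s1 = 0.08, s2 = 0.5, biasf = 8) {
  hill_series(tibble::tibble(time = time, cv1 = cv1, cv2 = cv2,
                             sigma1 = s1, sigma2 = s2, height = h,
                             biasf = biasf))
}

test_that("single-hill algebra and theta periodicity hold exactly", {
  empty <- mk_hills(numeric(0), numeric(0), numeric(0), numeric(0))
  f0 <- reconstruct_fes(empty)
  expect_true(all(f0$F == 0))

  h <- mk_hills(1, 3.0, 0.5, h = 2, biasf = 10)
  fes <- reconstruct_fes(h, d_grid = seq(2.2, 4.2, 0.01))
  # unique minimum at the hill center, depth gamma/(gamma-1) * height
  idx <- which(fes$F == 0, arr.ind = TRUE)
  expect_equal(nrow(idx), 1)
  expect_equal(fes$d[idx[1]], 3.0, tolerance = 1e-9)
  expect_lt(abs(fes$theta[idx[2]] - 0.5), pi / 180 + 1e-12)  # half a grid cell
  expect_true(all(fes$F >= 0))
  expect_equal(max(fes$F), 10 / 9 * 2, tolerance = 1e-3)
  # periodic image: the slice equals the wrapped-Gaussian closed form
  h2 <- mk_hills(1, 3.0, 0.05, h = 2)
  f2 <- reconstruct_fes(h2, d_grid = seq(2.2, 4.2, 0.01))
  slice <- f2$F[which(f2$d == 3.0), ]
  v <- 2 * exp(-helixatmos:::angle_diff(f2$theta, 0.05)^2 / (2 * 0.5^2))
  expect_equal(slice, 8 / 7 * (max(v) - v), tolerance = 1e-9)
  # hill outside the grid is a range error naming the record
  bad <- mk_hills(1, 5.0, 0.5, h = 1)
  expect_error(reconstruct_fes(bad), class = "ha_range_error")
})

test_that("reconstruction is additive and order-invariant", {
  set.seed(55)
  n <- 40
  h_all <- mk_hills(1:n, runif(n, 2.4, 4.0), runif(n, 0, 2 * pi),
                    runif(n, 0.2, 1))
  perm <- sample(n)
  h_perm <- hill_series(dplyr::mutate(as.data.frame(h_all)[perm, ],
                                      time = sort(time[perm])))
  f1 <- reconstruct_fes(h_all)
  f2 <- reconstruct_fes(h_perm)
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
  # V_bias is the plain hill sum
  va <- reconstruct_fes(mk_hills(1, 3.0, 1.0, 0.7))$V_bias +
    reconstruct_fes(mk_hills(1, 3.4, 2.0, 0.4))$V_bias
  vb <- reconstruct_fes(mk_hills(1:2, c(3.0, 3.4), c(1.0, 2.0), c(0.7, 0.4)))$V_bias
  expect_equal(va, vb, tolerance = 1e-12)
})

test_that("1D projection respects separability and theta-independence", {
  kT <- ha_constants()$kB * 300
  d_grid <- seq(2.2, 4.2, 0.02)
  theta_grid <- seq(0, 2 * pi, length.out = 121)[-121]
  U <- 3 * (d_grid - 3.1)^2
  W <- 1.2 * (1 - cos(theta_grid - 0.8))
  fes <- structure(list(d = d_grid, theta = theta_grid,
                        F = outer(U, W, "+"), V_bias = NULL,
                        bias_factor = 8, temperature = 300),
                   class = "ha_fes")
  prof <- project_1d(fes)
  # separable surface: F(d) - U(d) constant to 1e-6
  diffs <- prof$F - (U - min(U))
  expect_lt(max(diffs) - min(diffs), 1e-6)
  # theta-independent surface: projection equals any slice up to a constant
  fes2 <- structure(list(d = d_grid, theta = theta_grid,
                         F = matrix(U, length(d_grid), length(theta_grid)),
                         V_bias = NULL, bias_factor = 8, temperature = 300),
                    class = "ha_fes")
  p2 <- project_1d(fes2)
  expect_equal(p2$F, U - min(U), tolerance = 1e-9)
})

test_that("minima are located with sub-grid refinement on an analytic surface", {
  d_grid <- seq(2.2, 4.2, 0.02)
  theta_grid <- seq(0, 2 * pi, length.out = 181)[-181]
  well <- function(d, th, d0, th0, depth, wd = 0.15, wt = 0.5) {
    -depth * exp(-(d - d0)^2 / (2 * wd^2)) *
      exp(-helixatmos:::angle_diff(th, th0)^2 / (2 * wt^2))
  }
  F <- outer(d_grid, theta_grid, function(d, th) {
    8 + well(d, th, 2.77, 0.25, 8) + well(d, th, 4.01, 2.51, 6)
  })
  fes <- structure(list(d = d_grid, theta = theta_grid, F = F - min(F),
                        V_bias = NULL, bias_factor = 8, temperature = 300),
                   class = "ha_fes")
  mins <- locate_minima(fes)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$d, c(2.77, 4.01), tolerance = 0.011)   # half a grid cell
  expect_equal(mins$theta, c(0.25, 2.51), tolerance = 0.02)
  expect_equal(mins$F[1], 0)
  # flat surface: no minima
  flat <- fes; flat$F <- matrix(0, length(d_grid), length(theta_grid))
  expect_equal(nrow(locate_minima(flat)), 0)
  # gauge property: shifting the theta origin shifts reported minima equally
  shift <- 31  # grid cells
  fes_s <- fes; fes_s$F <- fes$F[, c((shift + 1):ncol(F), 1:shift)]
  mins_s <- locate_minima(fes_s)
  dtheta <- helixatmos:::angle_diff(mins$theta, mins_s$theta)
  expect_equal(dtheta, rep(shift * 2 * pi / 180, 2), tolerance = 1e-6)
})

test_that("state free-energy differences interpolate and scale per base pair", {
  prof <- tibble::tibble(d = seq(2.2, 4.2, 0.02), F = 0)
  expect_equal(delta_f(prof)$delta_f, 0)
  # the -0.15 kJ/mol/bp worked example: 300 and 500 bp give 45 and 75 kJ/mol
  prof2 <- tibble::tibble(d = c(2.2, 2.8, 4.0, 4.2), F = c(4, 0, 3, 3.1))
  dfv <- delta_f(prof2, 2.8, 4.0, n_bp = 20, scale_to_bp = c(300, 500))
  per_bp <- -0.15
  expect_equal(dfv$delta_f, -3)
  expect_equal(dfv$per_bp, per_bp)
  expect_equal(dfv$scaled$delta_f, c(-45, -75))
  expect_equal(abs(per_bp * c(300, 500)), c(45, 75))
  expect_error(delta_f(prof2, 2.0, 4.0), class = "ha_range_error")
})

test_that("convergence diagnostics flag decay and block agreement", {
  # constant heights (gamma -> infinity behavior): flag false
  n <- 80
  const <- mk_hills(1:n, runif(n, 2.6, 4.0), runif(n, 0, 2 * pi), rep(1, n))
  cd <- convergence_diagnostics(const, blocks = 4)
  expect_false(cd$converged)
  # decaying heights: flag true
  dec <- mk_hills(1:n, rep(seq(2.6, 4.0, length.out = 20), 4),
                  rep(seq(0.1, 6.2, length.out = 20), 4),
                  1 * 0.93^(1:n))
  cdd <- convergence_diagnostics(dec, blocks = 4, asymptote_fraction = 0.2)
  expect_true(cdd$converged)
  # identical hill blocks: zero dF spread
  base <- tibble::tibble(cv1 = seq(2.5, 4.1, length.out = 25),
                         cv2 = seq(0.2, 6, length.out = 25),
                         sigma1 = 0.1, sigma2 = 0.6,
                         height = 0.5, biasf = 8)
  twice <- hill_series(dplyr::mutate(dplyr::bind_rows(base, base),
                                     time = dplyr::row_number()))
  cd2 <- convergence_diagnostics(twice, blocks = 2)
  expect_equal(cd2$delta_f_spread, 0, tolerance = 1e-9)
  expect_warning(convergence_diagnostics(mk_hills(1:3, c(3, 3.2, 3.4),
                                                  c(1, 2, 3), c(1, 1, 1)),
                                         blocks = 2),
                 class = "ha_degraded_diagnostics")
})

test_that("polar export round-trips grid values", {
  h <- mk_hills(1:3, c(2.8, 3.2, 3.8), c(0.3, 2, 4), c(1, 0.7, 0.4))
  fes <- reconstruct_fes(h)
  tab <- export_polar(fes)
  expect_equal(nrow(tab), length(fes$d) * length(fes$theta))
  expect_true(!is.unsorted(tab$d[tab$theta == tab$theta[1]]))
  set.seed(3)
  for (k in sample(nrow(tab), 3)) {
    i <- which(fes$d == tab$d[k]); j <- which(fes$theta == tab$theta[k])
    expect_equal(tab$F[k], fes$F[i, j])
  }
  expect_equal(tidy(fes), tab)
})

test_that("a short tempered run recovers the double-well topology", {
  # scaled-down sampling: coarse bound on the recovery error; the converged
  # study-length run is exercised by the acceptance suite
  bench <- fes_recovery_benchmark(seed = 101, steps = 3e5)
  expect_lt(bench$max_error, 0.35 * bench$barrier)
  expect_lt(abs(bench$delta_f_error), 0.25 * bench$barrier)
  mins <- locate_minima(bench$fes, min_prominence = 1.5)
  expect_gte(nrow(mins), 2)
  expect_equal(sort(head(mins$d, 2)), c(2.8, 4.0), tolerance = 0.08)
  # well-tempered identity: heights fall as the bias fills the wells
  q <- split(bench$hills$height, cut(seq_len(nrow(bench$hills)), 4))
  expect_lt(mean(q[[4]]), mean(q[[1]]))
})
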