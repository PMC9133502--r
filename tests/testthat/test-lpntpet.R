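test_that("gamma-variate response has the closed-form values and shape", {
  expect_equal(gamma_variate_h(20, 20, 25, 1), 0)       # h(t_d) = 0
  expect_equal(gamma_variate_h(25, 20, 25, 1), 1)       # h(t_p) = 1
  expect_equal(gamma_variate_h(30, 20, 25, 1), 2 * exp(-1))
  expect_true(all(gamma_variate_h(seq(0, 20, 0.5), 20, 25, 2) == 0))
  h <- gamma_variate_h(seq(0, 60, 0.01), 20, 25, 1.5)
  expect_equal(max(h), 1, tolerance = 1e-6)
  # unimodal: increases to the peak then decreases
  expect_equal(sum(diff(sign(diff(h[h > 0]))) != 0), 1L)
  expect_error(gamma_variate_h(1, 25, 20, 1), "t_p > t_d")
  expect_error(gamma_variate_h(1, 20, 25, 0), "alpha")
})

test_that("default basis grid has exactly 2394 shapes with the stated ranges", {
  g <- basis_grid()
  expect_equal(nrow(g), 2394L)
  expect_equal(sort(unique(g$t_d)), seq(10, 40, 1.5))
  expect_equal(sort(unique(g$alpha)), seq(0.5, 3, 0.5))
  expect_true(all(g$t_p > g$t_d))
  expect_true(all(g$t_p <= 53.5))
  # brute-force combinatorial enumeration oracle
  n_pairs <- sum(sapply(seq(10, 40, 1.5), function(td)
    length(seq(td + 1.5, 53.5, 1.5))))
  expect_equal(n_pairs * 6, 2394L)
  # dropping one alpha removes exactly one sixth
  expect_equal(nrow(basis_grid(alphas = seq(0.5, 2.5, 0.5))), 1995L)
})

test_that("basis library integrates C_T against each response shape", {
  tacs <- default_frame_tacs()
  lib <- build_basis_library(tacs$active)
  expect_equal(ncol(lib$B), 2394L)
  expect_true(all(lib$B[1, ] >= 0))
  expect_true(all(diff(lib$B[, 100]) >= -1e-12))   # non-decreasing columns
  # independent oracle on one column: dense trapezoid on a fine interpolation
  i <- 1200L
  g <- lib$grid[i, ]
  t0 <- c(0, tacs$active$time_min)
  v0 <- c(0, tacs$active$value)
  w <- v0 * gamma_variate_h(t0, g$t_d, g$t_p, g$alpha)
  oracle <- cumsum(c(0, diff(t0) * (w[-length(w)] + w[-1]) / 2))[-1]
  expect_equal(as.vector(lib$B[, i]), oracle, tolerance = 1e-12)
  zero <- tacs$active
  zero$value <- zero$value * 0
  expect_true(all(build_basis_library(zero)$B == 0))
  expect_error(basis_grid(t_d_min = 50, t_d_max = 40), "by")
})

test_that("exhaustive NNLS fit matches a per-basis Lawson-Hanson oracle", {
  skip_if_not_installed("pracma")
  tacs <- default_frame_tacs()
  grid <- basis_grid()[c(400, 1200, 2000), ]
  y <- tacs$active$value
  t <- tacs$active$time_min
  cr <- tacs$C_R$value
  cum <- function(v) {
    v0 <- c(0, v); t0 <- c(0, t)
    cumsum(diff(t0) * (v0[-length(v0)] + v0[-1]) / 2)
  }
  X0 <- cbind(cr, cum(cr), -cum(y))
  lib <- build_basis_library(tacs$active, grid)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    sol <- pracma::lsqnonneg(cbind(X0, -lib$B[, i]), y)
    if (is.null(best) || sol$resid.norm < best$sse - 1e-12)
      best <- list(i = i, sse = sol$resid.norm, theta = sol$x)
  }
  fit <- fit_lpntpet(tacs$active, tacs$C_R, grid)
  expect_equal(fit$basis_index, best$i)
  expect_equal(fit$sse, best$sse, tolerance = 1e-8)
  expect_equal(c(fit$R1, fit$k2, fit$k2a, fit$gamma), as.vector(best$theta),
               tolerance = 1e-6)
})

test_that("noise-free on-grid data are recovered exactly", {
  tacs <- default_frame_tacs()
  kin <- kinetic_params(R1 = 0.9, k2 = 0.3, k2a = 0.05)
  act <- activation_shape(gamma = 0.02, t_d = 20.5, t_p = 26.5, alpha = 1)
  ct <- ongrid_tac(kin, act, tacs$C_R)
  fit <- fit_lpntpet(ct, tacs$C_R)
  expect_lt(fit$sse, 1e-10)
  expect_equal(c(fit$t_d, fit$t_p, fit$alpha), c(20.5, 26.5, 1))
  expect_equal(c(fit$R1, fit$k2, fit$k2a, fit$gamma),
               c(0.9, 0.3, 0.05, 0.02), tolerance = 1e-6)
})

test_that("fitted SSE is the global minimum over all bases", {
  tacs <- default_frame_tacs()
  grid <- basis_grid()[seq(1, 2394, by = 97), ]
  set.seed(42)
  noisy <- tacs$active
  noisy$value <- pmax(noisy$value + rnorm(47, 0, 0.2), 0)
  fit <- fit_lpntpet(noisy, tacs$C_R, grid)
  lib <- build_basis_library(noisy, grid)
  t <- noisy$time_min
  cum <- function(v) {
    v0 <- c(0, v); t0 <- c(0, t)
    cumsum(diff(t0) * (v0[-length(v0)] + v0[-1]) / 2)
  }
  X0 <- cbind(tacs$C_R$value, cum(tacs$C_R$value), -cum(noisy$value))
  for (i in seq_len(nrow(grid))) {
    sol <- petkern:::nnls_enum(cbind(X0, -lib$B[, i]), noisy$value)
    expect_gte(sol$sse, fit$sse - 1e-9)
  }
})

test_that("free sign mode reduces to per-basis ordinary least squares", {
  tacs <- default_frame_tacs()
  grid <- basis_grid()[c(100, 900, 1500), ]
  fit <- fit_lpntpet(tacs$active, tacs$C_R, grid, sign_mode = "free")
  lib <- build_basis_library(tacs$active, grid)
  t <- tacs$active$time_min
  cum <- function(v) {
    v0 <- c(0, v); t0 <- c(0, t)
    cumsum(diff(t0) * (v0[-length(v0)] + v0[-1]) / 2)
  }
  X0 <- cbind(tacs$C_R$value, cum(tacs$C_R$value), -cum(tacs$active$value))
  sses <- sapply(seq_len(nrow(grid)), function(i) {
    X <- cbind(X0, -lib$B[, i])
    sum(stats::lm.fit(X, tacs$active$value)$residuals^2)
  })
  expect_equal(fit$sse, min(sses), tolerance = 1e-9)
  expect_equal(fit$basis_index, which.min(sses))
})

test_that("ARP identity holds and matches printed-value arithmetic", {
  fit <- list(gamma = 0.182, k2a = 0.109, t_d = 16, t_p = 37, alpha = 1)
  arp <- compute_arp(fit, time_min = c(10, 16, 37, 50))
  expect_equal(arp$arp_pct[arp$time_min == 37], 100 * 0.182 / 0.109)
  expect_equal(arp$arp_pct[arp$time_min <= 16], c(0, 0))
  zero <- compute_arp(list(gamma = 0, k2a = 0.05, t_d = 20, t_p = 25, alpha = 1))
  expect_true(all(zero$arp_pct == 0))
  expect_error(compute_arp(list(gamma = 1, k2a = 0, t_d = 1, t_p = 2, alpha = 1)),
               "k2a")
})

test_that("tidy and glance summarize a fit", {
  tacs <- default_frame_tacs()
  fit <- fit_lpntpet(tacs$active, tacs$C_R, basis_grid()[seq(1, 2394, 40), ])
  td <- generics::tidy(fit)
  expect_equal(td$term, c("R1", "k2", "k2a", "gamma", "t_d", "t_p", "alpha"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_frames, 47L)
})

test_that("parametric maps recover region-wise truth on noise-free images", {
  fr <- make_framing(list(c(4, 300), c(4, 600)))
  cr <- reference_tac(dt_s = 5)
  crf <- frame_activity(cr, fr)
  kin <- kinetic_params()
  grid <- basis_grid()[seq(1, 2394, by = 12), ]
  act_tac <- frame_activity(simulate_ntpet_tac(kin, activation_shape(), cr), fr)
  rest_tac <- frame_activity(simulate_ntpet_tac(kin, NULL, cr), fr)
  img <- array(0, dim = c(4, 4, nrow(fr)))
  act_mask <- matrix(FALSE, 4, 4); act_mask[1:2, ] <- TRUE
  for (f in seq_len(nrow(fr))) {
    img[1:2, , f] <- act_tac$value[f]
    img[3:4, , f] <- rest_tac$value[f]
  }
  attr(img, "framing") <- fr
  maps <- fit_parametric_maps(img, crf, matrix(TRUE, 4, 4), grid)
  expect_true(all(maps$gamma[act_mask] > 0.01))
  expect_true(all(maps$gamma[!act_mask] < maps$gamma[act_mask][1] / 2))
  # spatially constant within each region
  expect_equal(stats::sd(maps$gamma[act_mask]), 0)
  expect_equal(stats::sd(maps$t_d[act_mask]), 0)
  # single-pixel mask consistency with the regional fit
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  m1 <- fit_parametric_maps(img, crf, one, grid)
  f1 <- fit_lpntpet(act_tac, crf, grid)
  expect_equal(m1$gamma[1, 1], f1$gamma)
  expect_equal(m1$t_d[1, 1], f1$t_d)
  # zero TACs are flagged
  img0 <- img; img0[4, 4, ] <- 0
  zm <- matrix(FALSE, 4, 4); zm[4, 4] <- TRUE
  m0 <- fit_parametric_maps(img0, crf, zm, grid)
  expect_true(m0$zero_tac[4, 4])
  expect_equal(m0$gamma[4, 4], 0)
  expect_error(fit_parametric_maps(img, crf, matrix(FALSE, 4, 4), grid), "empty")
})
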