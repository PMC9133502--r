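small_cfg <- function(...) {
  experiment_config(budgets = 2e6, n_realizations = 2, arms = c("ifr"),
                    n_iter = 15, seed = 7, ...)
}

test_that("simulation experiment produces per-arm summaries and is deterministic", {
  s <- tiny_setup()
  grid <- basis_grid()[seq(1, 2394, by = 20), ]
  r1 <- run_simulation_experiment(small_cfg(), s, grid)
  expect_setequal(unique(r1$summary$arm), "ifr")
  expect_setequal(unique(r1$summary$param), c("k2a", "gamma", "t_d", "t_p"))
  expect_equal(nrow(r1$summary), 4L)   # one arm x four parameters
  expect_equal(nrow(r1$regional), 2 * 2)  # 2 realizations x 2 regions
  expect_true(all(r1$summary$cov_pct >= 0, na.rm = TRUE))
  r2 <- run_simulation_experiment(small_cfg(), s, grid)
  expect_equal(r1$regional, r2$regional)
  expect_equal(r1$summary, r2$summary)
  # every seed recorded in the manifest table
  expect_equal(nrow(r1$seeds), 2L)
  expect_equal(r1$seeds$seed, c(7 + 1000 + 1, 7 + 1000 + 2))
})

test_that("noise-free images give zero COV across repeated fits", {
  s <- tiny_setup()
  grid <- basis_grid()[seq(1, 2394, by = 40), ]
  eng <- basis_engine(s$framing$mid_min, grid)
  # two "realizations" of the noise-free arm are identical by construction
  f1 <- petkern:::fit_region_params(s$truth_dc, s, grid = grid, engine = eng)
  f2 <- petkern:::fit_region_params(s$truth_dc, s, grid = grid, engine = eng)
  long <- tibble::tibble(arm = "noisefree", param = "gamma",
                         value = c(f1$gamma[1], f2$gamma[1]))
  nf <- tibble::tibble(param = "gamma", noisefree = f1$gamma[1])
  sm <- summarize_cov_bias(long, nf)
  expect_equal(sm$cov_pct, 0)
  expect_equal(sm$diff_pct, 0)
})

test_that("COV and bias follow their definitions", {
  long <- tibble::tibble(arm = "a", param = "gamma", value = c(1, 3))
  nf <- tibble::tibble(param = "gamma", noisefree = 2)
  sm <- summarize_cov_bias(long, nf)
  expect_equal(sm$mean, 2)
  expect_equal(sm$cov_pct, 100 * sqrt(2) / 2, tolerance = 1e-12)  # 70.71%
  expect_equal(sm$diff_pct, 0)
  sm0 <- summarize_cov_bias(
    tibble::tibble(arm = "a", param = "gamma", value = c(0.05, 0.05, 0.05)),
    tibble::tibble(param = "gamma", noisefree = 0.05))
  expect_equal(sm0$cov_pct, 0)
  expect_equal(sm0$diff_pct, 0)
  # undefined difference for zero noise-free value
  smna <- summarize_cov_bias(long, tibble::tibble(param = "gamma", noisefree = 0))
  expect_true(is.na(smna$diff_pct))
  expect_error(summarize_cov_bias(long[1, ], nf), ">= 2")
})

test_that("paired test matches the textbook formula and flags degeneracies", {
  rest <- c(0.1, 0.2, 0.3)
  active <- c(0.3, 0.5, 0.4)
  res <- paired_activation_test(rest, active)
  d <- active - rest
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  p_manual <- 2 * stats::pt(abs(t_manual), df = 2, lower.tail = FALSE)
  expect_equal(res$difference, 0.2)
  expect_equal(res$t, t_manual)
  expect_equal(res$p, p_manual)
  shift <- paired_activation_test(1:10 / 10, 1:10 / 10 + 1)
  expect_equal(shift$difference, 1)
  expect_true(shift$zero_variance)
  expect_true(is.na(shift$p))
  same <- paired_activation_test(1:5, 1:5)
  expect_equal(same$difference, 0)
})

test_that("experiment scale factor shrinks realizations and iterations", {
  cfg <- experiment_config(scale = 0.1)
  expect_equal(cfg$n_realizations, 3L)
  expect_equal(cfg$n_iter, 30L)
  expect_equal(cfg$n_realizations_sweep, 1L)
  full <- experiment_config()
  expect_equal(full$budgets, c(1e7, 4e7, 8e7))
  expect_equal(full$n_realizations, 30L)
  expect_equal(full$activation_levels, c(120, 140, 160, 180, 200))
  expect_equal(full$n_realizations_sweep, 10L)
  expect_equal(full$sweep_budget, 4e7)
  expect_equal(full$n_iter, 300L)
  expect_error(experiment_config(arms = character(0)), "arm")
})

test_that("outputs directory contains tables, manifest and log", {
  s <- tiny_setup()
  grid <- basis_grid()[seq(1, 2394, by = 40), ]
  res <- run_simulation_experiment(small_cfg(), s, grid)
  dir <- withr::local_tempdir()
  write_outputs(res, file.path(dir, "run1"))
  files <- list.files(file.path(dir, "run1"))
  expect_true(all(c("summary_regional.csv", "fits_regional.csv",
                    "fits_noisefree.csv", "manifest.json", "run.log") %in% files))
  man <- jsonlite::read_json(file.path(dir, "run1", "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seeds$seed, res$seeds$seed)
  back <- read.csv(file.path(dir, "run1", "fits_regional.csv"))
  expect_equal(nrow(back), nrow(res$regional))
})

test_that("checkpointed runs resume to identical results", {
  s <- tiny_setup()
  grid <- basis_grid()[seq(1, 2394, by = 40), ]
  ckpt <- withr::local_tempdir()
  cfg <- small_cfg(checkpoint_dir = ckpt)
  r1 <- run_simulation_experiment(cfg, s, grid)
  expect_gt(length(list.files(ckpt)), 0)
  r2 <- run_simulation_experiment(cfg, s, grid)   # reads the checkpoints
  expect_equal(r1$regional, r2$regional)
})

test_that("activation sweep collects paired ratios per level", {
  s <- tiny_setup()
  grid <- basis_grid()[seq(1, 2394, by = 40), ]
  cfg <- experiment_config(budgets = 2e6, n_realizations = 2,
                           n_realizations_sweep = 2, sweep_budget = 2e6,
                           activation_levels = c(140, 200), arms = "ifr",
                           n_iter = 15, seed = 11)
  sw <- run_activation_sweep(cfg, s, grid)
  expect_setequal(unique(sw$ratios$level), c(140, 200))
  expect_equal(nrow(sw$tests), 2L)  # one arm x two levels
  expect_true(all(c("difference", "p") %in% names(sw$tests)))
  expect_equal(nrow(sw$ratios), 2 * 2 * 2)  # levels x realizations x regions
})
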