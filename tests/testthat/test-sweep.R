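# Parameter sweeps, discontinuity detection, phase maps

test_that("sweeps are deterministic and cache-transparent", {
  p <- preset_params("fig4", N_A = 3)
  kin <- kinetic_params(log_zeta = -12)
  grid <- seq(-13, -12, by = 0.25)
  s1 <- sweep_micelle(p, kin, "log_zeta", grid, cache = TRUE)
  s2 <- sweep_micelle(p, kin, "log_zeta", grid, cache = TRUE)
  s3 <- sweep_micelle(p, kin, "log_zeta", grid, cache = FALSE)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_equal(s1$alpha_star, s3$alpha_star, tolerance = 1e-12)
  expect_equal(s1$n_star, s3$n_star, tolerance = 1e-9)
  expect_named(
    s1, c("log_zeta", "n_star", "alpha_star", "F_n_star", "eff_F_min",
          "r_c", "r_A", "r_C", "phase", "note")
  )
})

test_that("sweep grids must be monotone and bad cells do not abort", {
  p <- preset_params("fig4", N_A = 3)
  kin <- kinetic_params(log_zeta = -12)
  expect_error(sweep_micelle(p, kin, "log_zeta", c(-12, -14, -13)),
               "monotone")
})

test_that("alpha decreases and n grows with the transcription rate", {
  p <- preset_params("fig4", N_A = 3)
  kin <- kinetic_params(log_zeta = -12)
  sw <- sweep_micelle(p, kin, "log_zeta", seq(-14, -9, by = 0.5))
  stable <- sw$n_star >= 2
  expect_true(all(diff(sw$alpha_star[stable]) <= 1e-8))
  expect_true(all(diff(sw$n_star[stable]) >= -1e-8))
})

test_that("discontinuity detection separates first-order jumps from steep
           continuous crossovers", {
  kin <- kinetic_params(log_zeta = -12)
  grid <- seq(-16, -6, by = 0.1)
  # constant curve: nothing to detect
  p1 <- preset_params("fig4", N_A = 1)
  sw1 <- sweep_micelle(p1, kin, "log_zeta", grid)
  expect_false(detect_discontinuity(sw1)$is_discontinuous)
  # N_A = 3 < critical: continuous decrease
  sw3 <- sweep_micelle(preset_params("fig4", N_A = 3), kin, "log_zeta", grid)
  d3 <- detect_discontinuity(sw3)
  expect_false(d3$is_discontinuous)
  # N_A = 10 > critical: all-A-shell to all-A-core jump
  sw10 <- sweep_micelle(preset_params("fig4", N_A = 10), kin, "log_zeta", grid)
  d10 <- detect_discontinuity(sw10)
  expect_true(d10$is_discontinuous)
  expect_gt(d10$jump, 0.9)
  expect_true(d10$location > -7 && d10$location < -6)
  # the unrefined grid criterion agrees well above the critical point
  expect_true(detect_discontinuity(sw10, refine = FALSE)$is_discontinuous)
})

test_that("alpha continuity scale separates N_A = 1 from N_A = 10", {
  kin <- kinetic_params(log_zeta = -12)
  grid <- seq(-16, -6, by = 0.1)
  sw1 <- sweep_micelle(preset_params("fig4", N_A = 1), kin, "log_zeta", grid)
  st <- sw1$n_star >= 2
  expect_lt(max(abs(diff(sw1$alpha_star[st]))), 0.05)
  sw10 <- sweep_micelle(preset_params("fig4", N_A = 10), kin, "log_zeta", grid)
  st10 <- sw10$n_star >= 2
  a <- sw10$alpha_star[st10]
  i <- which.max(abs(diff(a)))
  expect_gte(a[i], 0.95)
  expect_lte(a[i + 1], 0.05)
})

test_that("block-length trends: n* and r_C shrink with N_A, alpha grows as
           N_B shrinks", {
  kin <- preset_kinetics("fig6")
  p6 <- preset_params("fig6", N_A = 1)
  swA <- sweep_micelle(p6, kin, "N_A", seq(1, 4, by = 0.75))
  expect_true(all(diff(swA$n_star) < 0))
  expect_true(all(diff(swA$r_C) < 0))
  p7 <- preset_params("fig7", N_A = 8, N_B = 40)
  swB <- sweep_micelle(p7, kin, "N_B", seq(25, 40, by = 2.5))
  stable <- swB$n_star >= 2
  expect_true(all(diff(swB$alpha_star[stable]) <= 1e-8)) # alpha rises as N_B falls
  expect_true(all(diff(swB$r_C[stable]) >= -1e-8))       # r_C falls as N_B falls
})

test_that("phase map reproduces the rate-diagram topology", {
  p <- preset_params("fig5", N_A = 1)
  kin <- kinetic_params(log_zeta = -12)
  map <- phase_map(p, kin, NA_grid = c(3, 10), x_variable = "log_zeta",
                   x_grid = seq(-16, -6, by = 0.5))
  expect_true(all(!is.na(map$phase)))
  expect_true(all(map$phase %in% c("all_A_shell", "mixed", "all_A_core",
                                   "unstable")))
  # unstable band at very low transcription rate for every N_A
  low <- dplyr::filter(map, log_zeta == -16)
  expect_true(all(low$phase == "unstable"))
  # above the critical length: direct shell -> core, no mixed cells
  col10 <- dplyr::filter(map, N_A == 10)
  expect_false(any(col10$phase == "mixed"))
  expect_true(any(col10$phase == "all_A_shell"))
  expect_true(any(col10$phase == "all_A_core"))
  # below the critical length: a contiguous mixed band
  col3 <- dplyr::filter(map, N_A == 3)
  mixed_idx <- which(col3$phase == "mixed")
  expect_gt(length(mixed_idx), 0)
  expect_true(all(diff(mixed_idx) == 1))
})

test_that("phase boundaries lie between differing labels", {
  p <- preset_params("fig5", N_A = 1)
  kin <- kinetic_params(log_zeta = -12)
  map <- phase_map(p, kin, NA_grid = c(8, 10), x_variable = "log_zeta",
                   x_grid = seq(-10, -6, by = 1))
  b <- phase_boundaries(map)
  expect_true(all(c("x", "N_A", "from", "to") %in% names(b)))
  expect_true(all(b$from != b$to))
})

test_that("critical_NA validates its bracket", {
  p <- preset_params("fig4", N_A = 5)
  kin <- kinetic_params(log_zeta = -12)
  expect_error(
    critical_NA(p, kin, "log_zeta", bracket = c(7, 8),
                grid = seq(-10, -6, by = 0.5)),
    "bracket"
  )
})

test_that("autoplot methods return ggplot objects", {
  p <- preset_params("fig4", N_A = 3)
  kin <- kinetic_params(log_zeta = -12)
  sw <- sweep_micelle(p, kin, "log_zeta", seq(-12.5, -12, by = 0.25))
  expect_s3_class(autoplot(sw), "ggplot")
  d <- size_distribution(p, kin, n_max = 400)
  expect_s3_class(autoplot(d), "ggplot")
  map <- phase_map(p, kin, NA_grid = c(3, 10), x_variable = "log_zeta",
                   x_grid = c(-12.5, -12))
  expect_s3_class(autoplot(map), "ggplot")
  expect_s3_class(plot_alpha_landscape(p, n = c(10, 50)), "ggplot")
})
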