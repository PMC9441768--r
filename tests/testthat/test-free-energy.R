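# Free-energy functional and micelle geometry

test_that("core volume fractions follow the packing closed form", {
  p <- preset_params("fig4", N_A = 10)
  vf <- volume_fractions(tibble::tibble(n = 5, alpha = c(1, 0, 0.5)), p)
  expect_equal(vf$phi_A, c(0, 10 / 50, 5 / 45))
  expect_equal(vf$phi_B, c(1, 40 / 50, 40 / 45))

  p8 <- preset_params("fig4", N_A = 8)
  vf8 <- volume_fractions(tibble::tibble(n = 3, alpha = 0.5), p8)
  expect_equal(vf8$phi_A, 4 / 44)
  # exact complementarity across random states
  set.seed(11)
  st <- tibble::tibble(n = runif(50, 1, 500), alpha = runif(50))
  vfr <- volume_fractions(st, p)
  expect_equal(vfr$phi_A + vfr$phi_B, rep(1, 50))
})

test_that("core radius matches the packing condition and n^(1/3) scaling", {
  p <- preset_params("fig4", N_A = 8)
  r1 <- core_radius(tibble::tibble(n = 1, alpha = 1), p)$r_c
  expect_equal(r1, (3 * 40 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(r1, 2.121568835894, tolerance = 1e-10)
  r8 <- core_radius(tibble::tibble(n = 8, alpha = 1), p)$r_c
  expect_equal(r8, 2 * r1, tolerance = 1e-12)
  # N_A = 0 limit equals the all-A-shell core
  p0 <- preset_params("fig4", N_A = 0)
  expect_equal(core_radius(tibble::tibble(n = 1, alpha = 0), p0)$r_c, r1)
})

test_that("surface partition f_A = alpha/(1+alpha) with its endpoints", {
  expect_equal(shell_fraction(c(0, 0.5, 1)), c(0, 1 / 3, 1 / 2))
  a <- seq(0, 1, by = 0.01)
  expect_true(all(diff(shell_fraction(a)) > 0))
  expect_error(shell_fraction(1.5), "alpha")
})

test_that("brush heights: closed form, N_A = 0, continuity at alpha = 0", {
  p <- preset_params("fig4", N_A = 8)
  bh <- brush_heights(tibble::tibble(n = 1, alpha = 1), p)
  expect_equal(bh$h_C, 4.923340635293, tolerance = 1e-10)
  p0 <- preset_params("fig4", N_A = 0)
  expect_equal(brush_heights(tibble::tibble(n = 1, alpha = 0.5), p0)$h_A, 0)
  # removable singularity: alpha -> 0 limit equals the alpha = 0 value
  h <- brush_heights(tibble::tibble(n = 10, alpha = c(0, 1e-12)), p)
  expect_equal(h$h_A[1], h$h_A[2], tolerance = 1e-9)
  expect_gt(h$h_A[1], 0)
})

test_that("free-energy terms have the stated signs, limits and additivity", {
  p <- preset_params("fig4", N_A = 8)
  set.seed(7)
  st <- tibble::tibble(n = runif(40, 1, 300), alpha = runif(40))
  fe <- free_energy(st, p)
  expect_true(all(fe$f_stretch >= 0 & fe$f_AB >= 0 & fe$f_surface >= 0 &
                    fe$f_shell_A >= 0 & fe$f_shell_C >= 0))
  expect_true(all(fe$f_mix <= 0))
  expect_equal(
    fe$total,
    fe$f_stretch + fe$f_AB + fe$f_surface + fe$f_shell_A + fe$f_shell_C +
      fe$f_mix,
    tolerance = 1e-12
  )

  # alpha = 1: no A in the core, no A-B interaction energy
  expect_equal(free_energy(tibble::tibble(n = 20, alpha = 1), p)$f_AB, 0)
  # closed form of f_AB at alpha = 0
  fe0 <- free_energy(tibble::tibble(n = 10, alpha = 0), p)
  expect_equal(fe0$f_AB, 10 * (8 * 40) / 48, tolerance = 1e-12)
  # surface term at n = 1, alpha = 1
  fe1 <- free_energy(tibble::tibble(n = 1, alpha = 1), p)
  expect_equal(fe1$f_surface, 28.280958404403, tolerance = 1e-10)
  # chi_B = 0 kills the surface term
  pB0 <- micelle_params(N_A = 8, N_B = 40, N_C = 15, chi_B = 1e-12,
                        chi_AB = 1)
  expect_lt(free_energy(tibble::tibble(n = 5, alpha = 0.5), pB0)$f_surface,
            1e-9)
})

test_that("shell terms vanish in their dilute limits", {
  p <- preset_params("fig4", N_A = 8)
  expect_equal(free_energy(tibble::tibble(n = 15, alpha = 0), p)$f_shell_A, 0)
  pC <- micelle_params(N_A = 8, N_B = 40, N_C = 1e-9, chi_B = 0.5, chi_AB = 1)
  expect_lt(free_energy(tibble::tibble(n = 15, alpha = 1), pC)$f_shell_C, 1e-8)
})

test_that("mixing entropy: convention at the endpoints and symmetry", {
  p <- preset_params("fig4", N_A = 8)
  fm <- function(n, a) free_energy(tibble::tibble(n = n, alpha = a), p)$f_mix
  expect_equal(fm(10, 0.5), -10 * log(2))
  expect_equal(fm(5, 1), 0)
  expect_equal(fm(5, 0), 0)
  expect_equal(fm(7, 0.3), fm(7, 0.7), tolerance = 1e-12)
  a <- seq(0.05, 0.95, by = 0.05)
  expect_equal(a[which.min(fm(1, a))], 0.5)
})

test_that("exact power laws in n at fixed alpha", {
  p <- preset_params("fig4", N_A = 8)
  n <- c(2, 20, 200)
  fe <- free_energy(tibble::tibble(n = n, alpha = 0.5), p)
  slope <- function(y) diff(log(y)) / diff(log(n))
  expect_equal(slope(fe$f_stretch), rep(5 / 3, 2), tolerance = 1e-10)
  expect_equal(slope(fe$f_surface), rep(2 / 3, 2), tolerance = 1e-10)
  expect_equal(slope(fe$f_AB), rep(1, 2), tolerance = 1e-10)
})

test_that("stretching scales as N_B^(-1/3) for short A blocks", {
  slope_NB <- function(NB1, NB2) {
    f <- function(NB) {
      p <- micelle_params(N_A = 0, N_B = NB, N_C = 15, chi_B = 0.5,
                          chi_AB = 1)
      free_energy(tibble::tibble(n = 50, alpha = 1), p)$f_stretch
    }
    (log(f(NB2)) - log(f(NB1))) / (log(NB2) - log(NB1))
  }
  expect_equal(slope_NB(30, 60), -1 / 3, tolerance = 1e-6)
})

test_that("all terms are continuous in alpha, including alpha -> 0", {
  p <- preset_params("fig4", N_A = 8)
  a <- c(0, 1e-10, 1e-6, seq(0.01, 1, by = 0.01))
  fe <- free_energy(tibble::tibble(n = 30, alpha = a), p)
  for (col in c("f_stretch", "f_AB", "f_surface", "f_shell_A", "f_shell_C",
                "f_mix", "total")) {
    expect_true(all(abs(diff(fe[[col]])) < 5), label = paste(col, "continuous"))
  }
  expect_lt(abs(fe$f_shell_A[2] - fe$f_shell_A[1]), 1e-6)
})

test_that("every quantity matches the independent transcription oracle", {
  set.seed(42)
  for (i in 1:100) {
    p <- micelle_params(
      N_A = runif(1, 0.5, 15), N_B = runif(1, 10, 60),
      N_C = runif(1, 5, 25), chi_B = runif(1, 0.1, 2),
      chi_AB = runif(1, 0, 3), v_A = runif(1, 0.5, 2),
      v_C = runif(1, 0.5, 2), C_s = runif(1, 0.5, 3)
    )
    n <- runif(1, 1, 1000)
    alpha <- sample(c(0, 1, runif(3)), 1)
    o <- oracle_terms(n, alpha, p)
    fe <- free_energy(tibble::tibble(n = n, alpha = alpha), p)
    for (col in c("f_stretch", "f_AB", "f_surface", "f_shell_A",
                  "f_shell_C", "f_mix", "total")) {
      expect_equal(fe[[col]], unname(o[col]), tolerance = 1e-12,
                   label = sprintf("%s (draw %d)", col, i))
    }
    g <- micelle_geometry(tibble::tibble(n = n, alpha = alpha), p)
    expect_equal(g$r_c, unname(o["rc"]), tolerance = 1e-12)
    expect_equal(g$r_A, unname(o["rA"]), tolerance = 1e-12)
    expect_equal(g$r_C, unname(o["rC"]), tolerance = 1e-12)
  }
})

test_that("shell radii: limits, closed form, monotonicity in N_A", {
  p <- preset_params("fig4", N_A = 8)
  g <- shell_radii(tibble::tibble(n = 1, alpha = 1), p)
  expect_equal(g$r_C, 5.483411050409, tolerance = 1e-10)
  expect_true(all(g$r_A >= g$r_c & g$r_C >= g$r_c))
  # h_A = 0 (via N_A = 0) collapses r_A onto r_c
  p0 <- preset_params("fig4", N_A = 0)
  g0 <- shell_radii(tibble::tibble(n = 10, alpha = 0.5), p0)
  expect_equal(g0$r_A, g0$r_c)
  # r_A grows with N_A at fixed (n, alpha)
  rA <- vapply(c(2, 5, 8), function(na) {
    shell_radii(tibble::tibble(n = 10, alpha = 0.7),
                preset_params("fig4", N_A = na))$r_A
  }, 0)
  expect_true(all(diff(rA) > 0))
})

test_that("invalid states and degenerate cores are rejected", {
  p <- preset_params("fig4", N_A = 8)
  expect_error(free_energy(tibble::tibble(n = 0.5, alpha = 0.5), p), "n")
  expect_error(free_energy(tibble::tibble(n = 2, alpha = 1.2), p), "alpha")
  expect_error(micelle_params(N_A = 8, N_B = -1, N_C = 15, chi_B = 0.5,
                              chi_AB = 1), "N_B")
})
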