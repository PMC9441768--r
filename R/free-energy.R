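#' @keywords internal
#' @noRd
.check_states <- function(states) {
  if (!is.data.frame(states) || !all(c("n", "alpha") %in% names(states))) {
    stop("`states` must be a data frame with columns `n` and `alpha`")
  }
  if (any(states$n < 1)) stop("aggregation number `n` must be >= 1")
  if (any(states$alpha < 0 | states$alpha > 1)) {
    stop("shell fraction `alpha` must lie in [0, 1]")
  }
  invisible(states)
}

# Core volume per Vc = n b^3 (N_B + (1 - alpha) N_A); degenerate when the
# core would be empty.
.core_units <- function(alpha, p) {
  Nbar <- p$N_B + (1 - alpha) * p$N_A
  if (any(Nbar <= 0)) stop("degenerate core: N_B + (1 - alpha) N_A must be > 0")
  Nbar
}

#' Core volume fractions of A and B units
#'
#' The core is packed with the B blocks of all `n` copolymers plus the
#' `(1 - alpha)` fraction of A blocks that are not in the shell, so
#' `phi_A = (1 - alpha) N_A / (N_B + (1 - alpha) N_A)` and
#' `phi_B = 1 - phi_A`.
#'
#' @param states Data frame with columns `n` (aggregation number, >= 1) and
#'   `alpha` (shell fraction of A blocks, in `[0, 1]`).
#' @param params A [micelle_params()] object.
#' @return The input as a tibble with columns `phi_A` and `phi_B` appended.
#' @examples
#' p <- preset_params("fig4", N_A = 10)
#' volume_fractions(tibble::tibble(n = 5, alpha = 0), p)
#' @export
volume_fractions <- function(states, params) {
  .check_states(states)
  Nbar <- .core_units(states$alpha, params)
  tibble::as_tibble(states) |>
    dplyr::mutate(
      phi_A = (1 - .data$alpha) * params$N_A / Nbar,
      phi_B = params$N_B / Nbar
    )
}

#' Core radius
#'
#' From the packing condition `(4 pi / 3) r_c^3 = n b^3 (N_B + (1-alpha) N_A)`,
#' so `r_c` scales exactly as `n^(1/3)`.
#'
#' @inheritParams volume_fractions
#' @return The input as a tibble with column `r_c` (units of `b`) appended.
#' @export
core_radius <- function(states, params) {
  .check_states(states)
  tibble::as_tibble(states) |>
    dplyr::mutate(
      r_c = (3 * .data$n * .core_units(.data$alpha, params) / (4 * pi))^(1 / 3)
    )
}

#' Fraction of the core surface occupied by A domains
#'
#' Equating the osmotic pressures of the A and C shell domains gives
#' `f_A = alpha / (1 + alpha)`, which runs from 0 (no A in the shell) to
#' 1/2 (all A in the shell).
#'
#' @param alpha Numeric vector of shell fractions in `[0, 1]`.
#' @return Numeric vector `f_A` in `[0, 1/2]`.
#' @examples
#' shell_fraction(c(0, 0.5, 1))
#' @export
shell_fraction <- function(alpha) {
  stopifnot("alpha must lie in [0, 1]" = all(alpha >= 0 & alpha <= 1))
  alpha / (1 + alpha)
}

#' Planar-limit brush heights of the A and C shell domains
#'
#' Daoud-Cotton heights of the shell brushes in the flat-surface limit.
#' The A-domain height uses the algebraic identity `alpha / f_A = 1 + alpha`
#' so that the `alpha -> 0` limit is finite and continuous (the grafting
#' density of A arms inside their own domains stays finite as the domains
#' shrink).
#'
#' @inheritParams volume_fractions
#' @return The input as a tibble with columns `r_c`, `f_A`, `h_A`, `h_C`
#'   appended (lengths in units of `b`).
#' @export
brush_heights <- function(states, params) {
  core_radius(states, params) |>
    dplyr::mutate(
      f_A = shell_fraction(.data$alpha),
      h_A = params$N_A *
        (params$v_A * .data$n * (1 + .data$alpha) / (4 * pi * .data$r_c^2))^(1 / 3),
      h_C = params$N_C *
        (params$v_C * .data$n / (4 * pi * (1 - .data$f_A) * .data$r_c^2))^(1 / 3)
    )
}

#' Distances from the paraspeckle centre to the tops of the A and C domains
#'
#' Curvature-corrected Daoud-Cotton radii
#' `r_X = r_c (1 + (5/3) h_X / r_c)^(3/5)`; both reduce to `r_c` when the
#' corresponding brush vanishes.
#'
#' @inheritParams volume_fractions
#' @return The input as a tibble with columns `r_c`, `f_A`, `h_A`, `h_C`,
#'   `r_A`, `r_C` appended.
#' @export
shell_radii <- function(states, params) {
  brush_heights(states, params) |>
    dplyr::mutate(
      r_A = .data$r_c * (1 + (5 / 3) * .data$h_A / .data$r_c)^(3 / 5),
      r_C = .data$r_c * (1 + (5 / 3) * .data$h_C / .data$r_c)^(3 / 5)
    )
}

#' Full micelle geometry
#'
#' Convenience wrapper returning core radius, surface partition, brush
#' heights, shell radii and core volume fractions in one tibble.
#'
#' @inheritParams volume_fractions
#' @return A tibble with columns `n`, `alpha`, `r_c`, `f_A`, `h_A`, `h_C`,
#'   `r_A`, `r_C`, `phi_A`, `phi_B`.
#' @examples
#' p <- preset_params("fig4", N_A = 8)
#' micelle_geometry(tibble::tibble(n = 20, alpha = 1), p)
#' @export
micelle_geometry <- function(states, params) {
  shell_radii(states, params) |>
    dplyr::mutate(
      phi_A = (1 - .data$alpha) * params$N_A / .core_units(.data$alpha, params),
      phi_B = params$N_B / .core_units(.data$alpha, params)
    )
}

# ---- fast scalar/vector kernel --------------------------------------------
#
# .fe_terms() is the single transcription of the free-energy functional used
# everywhere (the tibble API below and the minimisers). Vectorised over
# `n` and `alpha` (recycled). Reduced units b = 1, kBT = 1.
#
# Core stretching: the alpha-population of B blocks has both junctions at
# the core surface (A in the shell), i.e. two arms of length N_B/2, giving
# the weight 4 alpha / N_B^2; the (1-alpha)-population drags its A block
# into the core as a single arm of length N_A + N_B:
#   F_str = (3/2) lambda_s r_c^5 [ 4 alpha / N_B^2 + (1-alpha)/(N_A+N_B)^2 ]
# A-B interactions: chi_AB phi_A phi_B V_c.
# Surface: 4 pi chi_B r_c^2.
# Shell (Daoud-Cotton, A and C in segregated domains, no A-C cross term):
#   F_X = (3/5) (arms)^(3/2) (4 pi f_X)^(-1/2) C_s log(1 + (5/3) h_X / r_c)
# Mixing entropy of A blocks between core and shell:
#   F_mix = n (alpha log alpha + (1-alpha) log(1-alpha)), x log x := 0 at 0.
.fe_terms <- function(n, alpha, p) {
  Nbar <- p$N_B + (1 - alpha) * p$N_A
  Vc <- n * Nbar
  rc2 <- (3 * Vc / (4 * pi))^(2 / 3)
  rc <- sqrt(rc2)

  f_stretch <- 1.5 * p$lambda_s * rc2^2 * rc *
    (4 * alpha / p$N_B^2 + (1 - alpha) / (p$N_A + p$N_B)^2)
  f_AB <- p$chi_AB * ((1 - alpha) * p$N_A / Nbar) * (p$N_B / Nbar) * Vc
  f_surface <- 4 * pi * p$chi_B * rc2

  fA <- alpha / (1 + alpha)
  h_A <- p$N_A * (p$v_A * n * (1 + alpha) / (4 * pi * rc2))^(1 / 3)
  h_C <- p$N_C * (p$v_C * n / (4 * pi * (1 - fA) * rc2))^(1 / 3)
  f_shell_A <- ifelse(
    alpha > 0,
    0.6 * (n * alpha)^1.5 * p$C_s * log1p((5 / 3) * h_A / rc) /
      sqrt(4 * pi * fA),
    0
  )
  f_shell_C <- 0.6 * n^1.5 * p$C_s * log1p((5 / 3) * h_C / rc) /
    sqrt(4 * pi * (1 - fA))

  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  f_mix <- n * (xlx(alpha) + xlx(1 - alpha))

  list(
    f_stretch = f_stretch, f_AB = f_AB, f_surface = f_surface,
    f_shell_A = f_shell_A, f_shell_C = f_shell_C, f_mix = f_mix,
    total = f_stretch + f_AB + f_surface + f_shell_A + f_shell_C + f_mix
  )
}

# total only; hot path of the minimisers
.fe_total <- function(n, alpha, p) .fe_terms(n, alpha, p)$total

#' Free energy of a paraspeckle micelle, term by term
#'
#' Evaluates the micelle free energy `F_n(alpha)` of a spherical
#' paraspeckle of `n` copolymers with a fraction `alpha` of A blocks in the
#' shell, decomposed into core stretching, A-B interaction, surface,
#' A-shell, C-shell and mixing-entropy terms. Energies are in units of
#' `kBT`, lengths in units of the Kuhn length `b`.
#'
#' @inheritParams volume_fractions
#' @return The input as a tibble with columns `f_stretch`, `f_AB`,
#'   `f_surface`, `f_shell_A`, `f_shell_C`, `f_mix` and `total` appended.
#' @examples
#' p <- preset_params("fig4", N_A = 8)
#' free_energy(tibble::tibble(n = 20, alpha = c(0, 0.5, 1)), p)
#' @export
free_energy <- function(states, params) {
  .check_states(states)
  stopifnot(inherits(params, "micelle_params"))
  terms <- .fe_terms(states$n, states$alpha, params)
  dplyr::bind_cols(tibble::as_tibble(states), tibble::as_tibble(terms))
}
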