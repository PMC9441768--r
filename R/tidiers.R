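# broom-style tidiers for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted paraspeckle equilibrium
#'
#' One row per free-energy term of the micelle at the optimum
#' `(n*, alpha*)`, in kBT.
#'
#' @param x A `micelle_fit` from [optimal_micelle()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `energy`.
#' @export
tidy.micelle_fit <- function(x, ...) {
  fe <- free_energy(tibble::tibble(n = x$n_star, alpha = x$alpha_star),
                    x$params)
  fe |>
    dplyr::select(dplyr::all_of(c("f_stretch", "f_AB", "f_surface",
                                  "f_shell_A", "f_shell_C", "f_mix",
                                  "total"))) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "term", values_to = "energy")
}

#' One-row summary of a fitted paraspeckle equilibrium
#'
#' @param x A `micelle_fit` from [optimal_micelle()].
#' @param ... Unused.
#' @return A one-row tibble: `n_star`, `alpha_star`, `F_n_star`,
#'   `eff_F_min`, `phase`, `r_c`, `r_A`, `r_C`, `log_zeta`, `phi_p`.
#' @export
glance.micelle_fit <- function(x, ...) {
  tibble::tibble(
    n_star = x$n_star, alpha_star = x$alpha_star,
    F_n_star = x$F_n_star, eff_F_min = x$eff_F_min,
    phase = x$phase,
    r_c = x$geometry$r_c, r_A = x$geometry$r_A, r_C = x$geometry$r_C,
    log_zeta = x$kinetics$log_zeta, phi_p = x$kinetics$phi_p
  )
}
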