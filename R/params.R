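#' Model parameters for the triblock-copolymer micelle
#'
#' Constructs the static parameter set of the paraspeckle micelle model in
#' reduced units (`b = 1` Kuhn length, `kBT = 1`). The NEAT1_2
#' ribonucleoprotein complex is coarse-grained as an ABC triblock copolymer:
#' the 5' terminal region (A block, `N_A` units), the associative middle
#' region (B block, `N_B` units) and the 3' terminal region (C block, `N_C`
#' units).
#'
#' @param N_A Length of the A block in Kuhn units (>= 0; 0 is the deletion
#'   limit of the 5' terminal region).
#' @param N_B Length of the associative B block in Kuhn units (> 0).
#' @param N_C Length of the C block in Kuhn units (> 0).
#' @param chi_B Surface interaction parameter (> 0): free-energy penalty per
#'   unit area for B units exposed at the core surface.
#' @param chi_AB A-B interaction parameter (>= 0): repulsion between A and B
#'   units mixed in the core.
#' @param v_A,v_C Excluded volumes of A and C units in units of `b^3` (> 0).
#' @param C_s Numerical constant of the Daoud-Cotton shell free energy
#'   (order unity, > 0).
#' @param lambda_s Geometrical factor of the core stretching free energy.
#'   Defaults to `pi^3/30`; overriding it is only meant for sensitivity
#'   studies.
#'
#' @return An object of class `micelle_params`: a named list of validated
#'   parameters with `b = 1` and `kBT = 1` fixed.
#' @examples
#' p <- micelle_params(N_A = 8, N_B = 40, N_C = 15, chi_B = 0.5, chi_AB = 1)
#' p$lambda_s # pi^3/30
#' @seealso [preset_params()] for the parameter sets used in published
#'   figure analogues, [kinetic_params()] for the transcription kinetics.
#' @export
micelle_params <- function(N_A, N_B, N_C, chi_B, chi_AB,
                           v_A = 1, v_C = 1, C_s = 1.5,
                           lambda_s = pi^3 / 30) {
  stopifnot(
    "N_A must be a single number >= 0" = is_num1(N_A) && N_A >= 0,
    "N_B must be a single number > 0" = is_num1(N_B) && N_B > 0,
    "N_C must be a single number > 0" = is_num1(N_C) && N_C > 0,
    "chi_B must be a single number > 0" = is_num1(chi_B) && chi_B > 0,
    "chi_AB must be a single number >= 0" = is_num1(chi_AB) && chi_AB >= 0,
    "v_A must be a single number > 0" = is_num1(v_A) && v_A > 0,
    "v_C must be a single number > 0" = is_num1(v_C) && v_C > 0,
    "C_s must be a single number > 0" = is_num1(C_s) && C_s > 0,
    "lambda_s must be a single positive number" = is_num1(lambda_s) && lambda_s > 0
  )
  structure(
    list(
      N_A = as.numeric(N_A), N_B = as.numeric(N_B), N_C = as.numeric(N_C),
      chi_B = as.numeric(chi_B), chi_AB = as.numeric(chi_AB),
      v_A = as.numeric(v_A), v_C = as.numeric(v_C), C_s = as.numeric(C_s),
      lambda_s = as.numeric(lambda_s), b = 1, kBT = 1
    ),
    class = "micelle_params"
  )
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @export
print.micelle_params <- function(x, ...) {
  cat("<micelle_params> (reduced units: b = 1, kBT = 1)\n")
  cat(sprintf("  blocks : N_A = %g, N_B = %g, N_C = %g\n", x$N_A, x$N_B, x$N_C))
  cat(sprintf("  chi    : chi_B = %g, chi_AB = %g\n", x$chi_B, x$chi_AB))
  cat(sprintf("  shell  : v_A = %g, v_C = %g, C_s = %g\n", x$v_A, x$v_C, x$C_s))
  cat(sprintf("  lambda_s = %.6f\n", x$lambda_s))
  invisible(x)
}

#' Transcription kinetics parameters
#'
#' Parameters coupling the micelle free energy to transcription of the
#' scaffold RNA. The steady state depends on the rate ratio
#' `zeta = k_tx / k_0` (nascent-transcript addition rate over the
#' association rate constant of free transcripts) and on the volume
#' fraction `phi_p` of transcripts free in the nucleoplasm. The default
#' operating limit is `phi_p = 0`: all transcripts are in paraspeckles.
#'
#' @param log_zeta Natural logarithm of `zeta = k_tx/k_0`. Exactly one of
#'   `log_zeta` and `zeta` must be supplied.
#' @param zeta Rate ratio `k_tx/k_0` (> 0).
#' @param phi_p Volume fraction of free transcripts (>= 0, default 0).
#'
#' @return An object of class `kinetic_params` with fields `zeta`,
#'   `log_zeta` and `phi_p`.
#' @examples
#' kinetic_params(log_zeta = -12)
#' @export
kinetic_params <- function(log_zeta = NULL, zeta = NULL, phi_p = 0) {
  if (is.null(zeta) == is.null(log_zeta)) {
    stop("supply exactly one of `log_zeta` and `zeta`")
  }
  if (is.null(zeta)) {
    stopifnot("log_zeta must be a single finite number" = is_num1(log_zeta))
    zeta <- exp(log_zeta)
  } else {
    stopifnot("zeta must be a single number > 0" = is_num1(zeta) && zeta > 0)
    log_zeta <- log(zeta)
  }
  stopifnot(
    "phi_p must be a single number >= 0" = is_num1(phi_p) && phi_p >= 0,
    "phi_p + zeta must be > 0" = phi_p + zeta > 0
  )
  structure(
    list(zeta = zeta, log_zeta = log_zeta, phi_p = phi_p),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> log(zeta) = %g, phi_p = %g\n",
              x$log_zeta, x$phi_p))
  invisible(x)
}

# Caption parameter sets of the published figure analogues. fig4/5/6 share
# one micelle parameter set; fig6/7/8 pin log(zeta) = -12.
.presets <- list(
  fig4 = list(N_B = 40, N_C = 15, chi_B = 0.5, chi_AB = 1, v_A = 1, v_C = 1,
              C_s = 1.5),
  fig5 = list(N_B = 40, N_C = 15, chi_B = 0.5, chi_AB = 1, v_A = 1, v_C = 1,
              C_s = 1.5),
  fig6 = list(N_B = 40, N_C = 15, chi_B = 0.5, chi_AB = 1, v_A = 1, v_C = 1,
              C_s = 1.5, log_zeta = -12),
  fig7 = list(N_C = 15, chi_B = 0.5, chi_AB = 1, v_A = 1, v_C = 1, C_s = 1.5,
              log_zeta = -12),
  fig8 = list(N_C = 15, chi_B = 0.5, chi_AB = 1, v_A = 1, v_C = 1, C_s = 1.5,
              log_zeta = -12)
)

#' Preset parameter registries for the figure analogues
#'
#' Returns the micelle parameters printed in the captions of the published
#' figure analogues (`"fig4"` ... `"fig8"`), with optional overrides.
#' Presets fig4/fig5/fig6 share `N_B = 40`, `N_C = 15`, `chi_B = 0.5`,
#' `chi_AB = 1`, `v_A = v_C = 1`, `C_s = 1.5`; fig7/fig8 leave `N_B` free
#' (it is the swept variable). Overrides win over preset values.
#'
#' @param preset Preset name, one of `"fig4"`, `"fig5"`, `"fig6"`,
#'   `"fig7"`, `"fig8"`.
#' @param ... Named overrides for any [micelle_params()] argument. `N_A`
#'   (and `N_B` for fig7/fig8) must be given since the presets sweep them.
#'
#' @return A `micelle_params` object.
#' @examples
#' preset_params("fig4", N_A = 8)
#' @export
preset_params <- function(preset, ...) {
  preset <- match.arg(preset, names(.presets))
  base <- .presets[[preset]]
  base$log_zeta <- NULL
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == ""))) {
    stop("preset overrides must be named")
  }
  unknown <- setdiff(names(dots), names(formals(micelle_params)))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  args <- utils::modifyList(base, dots)
  do.call(micelle_params, args)
}

#' Preset kinetics (fixed transcription rate) for fig6/fig7/fig8
#'
#' fig6, fig7 and fig8 fix the transcription rate at `log(zeta) = -12`.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [kinetic_params()].
#' @return A `kinetic_params` object, or `NULL` if the preset does not pin
#'   a transcription rate (fig4, fig5 sweep it).
#' @export
preset_kinetics <- function(preset, ...) {
  preset <- match.arg(preset, names(.presets))
  lz <- .presets[[preset]]$log_zeta
  dots <- list(...)
  if (is.null(lz) && !length(dots)) return(NULL)
  args <- utils::modifyList(list(log_zeta = lz), dots)
  do.call(kinetic_params, args)
}
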