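# Master equation for transcript association/dissociation at the
# transcription site, its detailed-balance equilibrium, and relaxation to
# the steady state.

#' Rate parameters of the master equation
#'
#' Time is measured in units of `1/k_0`, the association rate constant of
#' transcripts diffusing in the nucleoplasm; `k_tx` is the rate at which a
#' nascent transcript is added to the paraspeckle during transcription, so
#' the steady state depends only on `zeta = k_tx/k_0` and `phi_p`.
#'
#' @param k0 Association rate constant (> 0, default 1 fixes the time unit).
#' @param ktx Nascent-transcript addition rate (>= 0).
#' @param phi_p Volume fraction of free transcripts (>= 0).
#' @return An object of class `rate_params`.
#' @examples
#' rate_params(ktx = exp(-12))
#' @export
rate_params <- function(k0 = 1, ktx = 0, phi_p = 0) {
  stopifnot(
    "k0 must be a single number > 0" = is_num1(k0) && k0 > 0,
    "ktx must be a single number >= 0" = is_num1(ktx) && ktx >= 0,
    "phi_p must be a single number >= 0" = is_num1(phi_p) && phi_p >= 0
  )
  structure(list(k0 = k0, ktx = ktx, phi_p = phi_p), class = "rate_params")
}

#' Alpha-minimised micelle free energies for a chain of aggregation numbers
#'
#' Precomputes `F_n = min_alpha F_n(alpha)` for integer `n = 1..n_max`.
#' These are the free energies entering both the flux of the master
#' equation and the steady-state effective free energy.
#'
#' @param params A [micelle_params()] object.
#' @param n_max Largest aggregation number (integer >= 2).
#' @return Numeric vector of length `n_max`, `F_n` in kBT.
#' @examples
#' micelle_free_energies(preset_params("fig4", N_A = 3), 10)
#' @export
micelle_free_energies <- function(params, n_max) {
  stopifnot(is_num1(n_max), n_max >= 2)
  vapply(seq_len(n_max), function(n) .min_alpha1(n, params)[["F"]], 0)
}

#' Probability flux of the master equation
#'
#' The flux from size `n` to size `n + 1`:
#' `J_n = k0 phi_p q_n - k0 exp(-(F_n + F_1 - F_{n+1})) (n+1) q_{n+1} + ktx q_n`
#' (energies in kBT). The first term is association of free transcripts,
#' the second spontaneous dissociation, the third addition of a nascent
#' transcript through transcription (no translational-entropy cost).
#'
#' @param q Probability vector over `n = 1..n_max`.
#' @param rates A [rate_params()] object.
#' @param free_energies `F_n` for `n = 1..n_max` (kBT), alpha-minimised,
#'   e.g. from [micelle_free_energies()].
#' @return Numeric vector `J_n` for `n = 1..n_max - 1`.
#' @export
flux <- function(q, rates, free_energies) {
  stopifnot(inherits(rates, "rate_params"),
            length(q) == length(free_energies), length(q) >= 2)
  nmax <- length(q)
  n <- seq_len(nmax - 1L)
  Fn <- free_energies
  expo <- -(Fn[n] + Fn[1] - Fn[n + 1])
  if (!all(is.finite(expo))) stop("non-finite exponent in dissociation rate")
  rates$k0 * rates$phi_p * q[n] -
    rates$k0 * exp(expo) * (n + 1) * q[n + 1] +
    rates$ktx * q[n]
}

#' Right-hand side of the master equation
#'
#' `dq_1/dt = -J_1`, `dq_n/dt = J_{n-1} - J_n`, with the boundary flux
#' `J_{n_max}` forced to zero (reflecting truncation), so total
#' probability is conserved exactly.
#'
#' @inheritParams flux
#' @return Numeric vector `dq/dt` of the same length as `q`.
#' @export
master_rhs <- function(q, rates, free_energies) {
  J <- flux(q, rates, free_energies)
  c(-J[1], J[-length(J)] - J[-1], J[length(J)])
}

# Tridiagonal generator A of dq/dt = A q under reflecting truncation.
.master_matrix <- function(rates, free_energies) {
  nmax <- length(free_energies)
  n <- seq_len(nmax - 1L)
  up <- rates$k0 * (rates$phi_p + rates$ktx / rates$k0) # growth n -> n+1
  down <- rates$k0 *
    exp(-(free_energies[n] + free_energies[1] - free_energies[n + 1])) * (n + 1)
  A <- matrix(0, nmax, nmax)
  A[cbind(n + 1L, n)] <- up
  A[cbind(n, n + 1L)] <- down
  diag(A) <- -c(rep(up, nmax - 1L), 0) - c(0, down)
  A
}

#' Integrate the master equation to a given time
#'
#' Integrates the stiff linear system `dq/dt = A q` with `deSolve`
#' (`lsoda`, analytic Jacobian) from an initial probability vector.
#'
#' @param q0 Initial probabilities over `n = 1..n_max` (non-negative, sum
#'   <= 1).
#' @param rates A [rate_params()] object.
#' @param free_energies `F_n` for `n = 1..n_max` (kBT).
#' @param t_end Final time in units of `1/k0`.
#' @param times Optional vector of output times (defaults to
#'   `c(0, t_end)`).
#' @param rtol,atol Integration tolerances.
#' @return A tibble in long format with columns `t`, `n`, `q`.
#' @examples
#' Fn <- micelle_free_energies(preset_params("fig4", N_A = 3), 20)
#' r <- rate_params(ktx = exp(-12))
#' traj <- evolve(c(1, rep(0, 19)), r, Fn, t_end = 10)
#' @export
evolve <- function(q0, rates, free_energies, t_end, times = NULL,
                   rtol = 1e-8, atol = 1e-12) {
  stopifnot(all(q0 >= 0), sum(q0) <= 1 + 1e-9,
            length(q0) == length(free_energies))
  if (t_end < 0) stop("t_end must be >= 0")
  if (is.null(times)) times <- c(0, t_end)
  if (t_end == 0) {
    return(tibble::tibble(t = 0, n = seq_along(q0), q = q0))
  }
  A <- .master_matrix(rates, free_energies)
  deriv <- function(t, q, parms) list(as.vector(A %*% q))
  jac <- function(t, q, parms) A
  sol <- deSolve::ode(
    y = q0, times = times, func = deriv, parms = NULL,
    jacfunc = jac, jactype = "fullusr", method = "lsoda",
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) stop("master-equation integration failed")
  tot <- rowSums(sol[, -1, drop = FALSE])
  if (any(abs(tot - sum(q0)) > 1e-6)) {
    stop("probability conservation breached during integration")
  }
  tibble::as_tibble(as.data.frame(sol)) |>
    rlang::set_names(c("t", seq_along(q0))) |>
    tidyr::pivot_longer(-"t", names_to = "n", values_to = "q") |>
    dplyr::mutate(n = as.integer(.data$n)) |>
    dplyr::arrange(.data$t, .data$n)
}

#' Equilibrium size distribution without transcription
#'
#' With transcription switched off (`ktx -> 0`) and a reservoir of free
#' transcripts at volume fraction `phi_p > 0`, detailed balance gives
#' `q_n ~ phi_p^(n-1) / n! exp(-(F_n - n F_1))`: this is the unique
#' distribution that makes every flux of the master equation vanish, and
#' the `zeta -> 0` limit of the steady-state distribution.
#'
#' @param free_energies `F_n` for `n = 1..n_max` (kBT), alpha-minimised.
#' @param phi_p Volume fraction of free transcripts (> 0).
#' @param n_max Optional truncation (defaults to the length of
#'   `free_energies`).
#' @return A tibble with columns `n` and `prob` (normalised over the
#'   truncated chain).
#' @examples
#' Fn <- micelle_free_energies(preset_params("fig4", N_A = 3), 20)
#' equilibrium_distribution(Fn, phi_p = 1e-4)
#' @export
equilibrium_distribution <- function(free_energies, phi_p, n_max = NULL) {
  if (!is_num1(phi_p) || phi_p <= 0) stop("phi_p must be a single number > 0")
  if (is.null(n_max)) n_max <- length(free_energies)
  stopifnot(n_max <= length(free_energies))
  n <- seq_len(n_max)
  Fn <- free_energies[n]
  logw <- (n - 1) * log(phi_p) - lgamma(n + 1) - (Fn - n * Fn[1])
  m <- max(logw)
  w <- exp(logw - m)
  tibble::tibble(n = n, prob = w / sum(w))
}

#' Analytic steady-state distribution from the zero-flux recursion
#'
#' Solves `J_n = 0` for all `n` directly:
#' `q_{n+1}/q_n = (phi_p + zeta) exp(F_n + F_1 - F_{n+1}) / (n + 1)`,
#' which is the size distribution `q_n ~ exp(-effF(n))` restricted to the
#' truncated chain. Useful as the reference for [evolve()] long-time
#' limits.
#'
#' @param free_energies `F_n` for `n = 1..n_max` (kBT).
#' @param rates A [rate_params()] object.
#' @return A tibble with columns `n` and `prob`.
#' @export
steady_state_distribution <- function(free_energies, rates) {
  stopifnot(inherits(rates, "rate_params"))
  nmax <- length(free_energies)
  n <- seq_len(nmax - 1L)
  zeta <- rates$ktx / rates$k0
  logratio <- log(rates$phi_p + zeta) +
    (free_energies[n] + free_energies[1] - free_energies[n + 1]) -
    log(n + 1)
  logw <- c(0, cumsum(logratio))
  m <- max(logw)
  w <- exp(logw - m)
  tibble::tibble(n = seq_len(nmax), prob = w / sum(w))
}
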