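# Minimisation of F_n(alpha) over alpha, the steady-state effective free
# energy, and the most probable aggregation number.

# Scalar workhorse: global minimum of F_n(alpha) on [0, 1] at fixed n.
# Dense grid scan localises every candidate well (the landscape is bimodal
# near the first-order transition), then each local basin plus the two
# branch seeds near alpha = 0 and alpha = 1 is refined with Brent.
.min_alpha1 <- function(n, p, grid_n = 201L) {
  a <- seq(0, 1, length.out = grid_n)
  v <- .fe_total(n, a, p)
  if (!all(is.finite(v))) stop("non-finite free energy at n = ", n)
  h <- 1 / (grid_n - 1)
  f <- function(x) .fe_total(n, x, p)

  refine <- function(centre) {
    lo <- max(0, centre - h)
    hi <- min(1, centre + h)
    o <- stats::optimize(f, c(lo, hi), tol = 1e-10)
    # endpoints of the unit interval are legitimate minimisers
    for (e in c(lo, hi)[c(lo == 0, hi == 1)]) {
      if (f(e) < o$objective) o <- list(minimum = e, objective = f(e))
    }
    o
  }

  interior <- which(diff(sign(diff(v))) > 0) + 1L # local minima of the grid
  seeds <- unique(c(a[interior], a[which.min(v)], 0.02, 0.98))
  best <- NULL
  for (s in seeds) {
    o <- refine(s)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  c(alpha = best$minimum, F = best$objective)
}

#' Minimise the micelle free energy over the shell fraction
#'
#' For each aggregation number `n`, finds the global minimiser
#' `alpha* in [0, 1]` of `F_n(alpha)`. A 201-point grid scan localises all
#' wells (the landscape is bimodal near the first-order transition between
#' the all-A-shell and all-A-core states) and each candidate well is
#' refined by Brent minimisation; the lowest branch is returned.
#'
#' @param states Data frame with a column `n` (aggregation numbers, >= 1).
#' @param params A [micelle_params()] object.
#' @return The input as a tibble with columns `alpha_star` and `F_min`
#'   (kBT) appended.
#' @examples
#' p <- preset_params("fig4", N_A = 8)
#' minimize_alpha(tibble::tibble(n = c(1, 20, 50)), p)
#' @export
minimize_alpha <- function(states, params) {
  if (!is.data.frame(states) || !"n" %in% names(states)) {
    stop("`states` must be a data frame with a column `n`")
  }
  if (any(states$n < 1)) stop("aggregation number `n` must be >= 1")
  res <- vapply(states$n, .min_alpha1, c(alpha = 0, F = 0), p = params)
  tibble::as_tibble(states) |>
    dplyr::mutate(alpha_star = unname(res["alpha", ]),
                  F_min = unname(res["F", ]))
}

# Memoised F(n) = min_alpha F_n(alpha); one cache per parameter set.
# The cache is transparent: values are exactly .min_alpha1() results.
.fmin_factory <- function(p, cache = TRUE) {
  env <- new.env(parent = emptyenv())
  function(n) {
    if (!cache) return(.min_alpha1(n, p)[["F"]])
    key <- sprintf("%.15g", n)
    got <- get0(key, envir = env)
    if (is.null(got)) {
      got <- .min_alpha1(n, p)[["F"]]
      assign(key, got, envir = env)
    }
    got
  }
}

#' Steady-state effective free energy of the transcription-coupled micelle
#'
#' The steady-state size distribution of paraspeckles at the transcription
#' site is `q_n ~ exp(-effF(n))` with
#' `effF(n) = F_n - n F_1 - (n - 1) log(phi_p + zeta) + log Gamma(n + 1)`,
#' where `F_n` is the micelle free energy already minimised over the shell
#' fraction `alpha` and `zeta = k_tx/k_0`. `log Gamma(n + 1)` extends
#' `log n!` smoothly to real `n`; `effF(1) = 0` identically.
#'
#' @param states Data frame with a column `n` (>= 1).
#' @param params A [micelle_params()] object.
#' @param kinetics A [kinetic_params()] object.
#' @return The input as a tibble with columns `alpha_star`, `F_min` and
#'   `eff_F` (kBT) appended.
#' @examples
#' p <- preset_params("fig4", N_A = 8)
#' k <- kinetic_params(log_zeta = -12)
#' effective_free_energy(tibble::tibble(n = c(1, 10, 40)), p, k)
#' @export
effective_free_energy <- function(states, params, kinetics) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (kinetics$phi_p + kinetics$zeta <= 0) stop("phi_p + zeta must be > 0")
  out <- minimize_alpha(states, params)
  F1 <- .min_alpha1(1, params)[["F"]]
  lz <- log(kinetics$phi_p + kinetics$zeta)
  dplyr::mutate(
    out,
    eff_F = .data$F_min - .data$n * F1 - (.data$n - 1) * lz + lgamma(.data$n + 1)
  )
}

# Scalar minimiser of effF over continuous n in [1, n_cap]: geometric
# coarse scan (factor 1.3) guards against distant minima, then Brent on
# the bracketing interval.
.optimal_n <- function(p, kin, n_cap = 1e5, fmin = NULL) {
  if (is.null(fmin)) fmin <- .fmin_factory(p)
  F1 <- fmin(1)
  lz <- log(kin$phi_p + kin$zeta)
  eff <- function(n) fmin(n) - n * F1 - (n - 1) * lz + lgamma(n + 1)
  ns <- 1.3^(0:ceiling(log(n_cap) / log(1.3)))
  ns[length(ns)] <- n_cap
  vs <- vapply(ns, eff, 0)
  if (!all(is.finite(vs))) stop("non-finite effective free energy in n scan")
  i <- which.min(vs)
  if (i == length(ns) && vs[i] < vs[1]) {
    stop("no finite minimum of the effective free energy below n_cap = ", n_cap)
  }
  lo <- ns[max(1L, i - 1L)]
  hi <- ns[min(length(ns), i + 1L)]
  o <- stats::optimize(eff, c(lo, hi), tol = 1e-6 * ns[i])
  n_star <- o$minimum
  eff_min <- o$objective
  if (eff(1) <= eff_min) { # boundary minimum: no stable micelle
    n_star <- 1
    eff_min <- eff(1)
  }
  list(n_star = n_star, eff_min = eff_min)
}

#' Classify the micelle state
#'
#' Phase labels for the location of the A blocks: `all_A_shell`
#' (`alpha* >= 1 - delta`), `all_A_core` (`alpha* <= delta`), `mixed`
#' (in between), and `unstable` when no stable micelle forms
#' (`n* < n_unstable`).
#'
#' @param alpha_star Minimising shell fraction(s) in `[0, 1]`.
#' @param n_star Most probable aggregation number(s).
#' @param delta Closeness threshold for "all" (default 0.05).
#' @param n_unstable Aggregation number below which the paraspeckle is
#'   deemed unstable (default 2).
#' @return A factor with levels `all_A_shell`, `mixed`, `all_A_core`,
#'   `unstable`.
#' @examples
#' classify_state(c(0.99, 0.5, 0.01), c(50, 30, 40))
#' @export
classify_state <- function(alpha_star, n_star, delta = 0.05, n_unstable = 2) {
  stopifnot(all(alpha_star >= 0 & alpha_star <= 1))
  lab <- ifelse(
    n_star < n_unstable, "unstable",
    ifelse(alpha_star >= 1 - delta, "all_A_shell",
           ifelse(alpha_star <= delta, "all_A_core", "mixed"))
  )
  factor(lab, levels = c("all_A_shell", "mixed", "all_A_core", "unstable"))
}

#' Most probable paraspeckle under transcription
#'
#' Minimises the effective free energy over the continuous aggregation
#' number `n in [1, n_cap]`, minimises `F_n(alpha)` over the shell fraction
#' at the optimum, and classifies the phase. Returns a fitted-model object
#' with [tidy()] and [glance()] methods.
#'
#' @param params A [micelle_params()] object.
#' @param kinetics A [kinetic_params()] object.
#' @param n_cap Upper bound of the search over `n` (default `1e5`).
#' @param delta,n_unstable Phase-classification thresholds, see
#'   [classify_state()].
#' @return An object of class `micelle_fit` with elements `n_star`,
#'   `alpha_star`, `F_n_star`, `eff_F_min`, `phase`, `geometry` (tibble of
#'   radii at the optimum), plus the inputs.
#' @examples
#' fit <- optimal_micelle(preset_params("fig4", N_A = 8),
#'                        kinetic_params(log_zeta = -12))
#' glance(fit)
#' @export
optimal_micelle <- function(params, kinetics, n_cap = 1e5,
                            delta = 0.05, n_unstable = 2) {
  stopifnot(inherits(params, "micelle_params"),
            inherits(kinetics, "kinetic_params"))
  opt <- .optimal_n(params, kinetics, n_cap = n_cap)
  ma <- .min_alpha1(opt$n_star, params)
  phase <- classify_state(ma[["alpha"]], opt$n_star,
                          delta = delta, n_unstable = n_unstable)
  geom <- micelle_geometry(
    tibble::tibble(n = opt$n_star, alpha = ma[["alpha"]]), params
  )
  structure(
    list(
      n_star = opt$n_star, alpha_star = ma[["alpha"]],
      F_n_star = ma[["F"]], eff_F_min = opt$eff_min,
      phase = as.character(phase), geometry = geom,
      params = params, kinetics = kinetics,
      settings = list(n_cap = n_cap, delta = delta, n_unstable = n_unstable)
    ),
    class = "micelle_fit"
  )
}

#' @export
print.micelle_fit <- function(x, ...) {
  cat("<micelle_fit>\n")
  cat(sprintf("  n* = %.4f, alpha* = %.6f, phase = %s\n",
              x$n_star, x$alpha_star, x$phase))
  cat(sprintf("  F(n*) = %.4f kBT, effF(n*) = %.4f kBT\n",
              x$F_n_star, x$eff_F_min))
  cat(sprintf("  r_c = %.3f b, r_A = %.3f b, r_C = %.3f b\n",
              x$geometry$r_c, x$geometry$r_A, x$geometry$r_C))
  invisible(x)
}

#' Steady-state size distribution of paraspeckles
#'
#' Probabilities `q_n ~ exp(-effF(n))` over integer aggregation numbers
#' `n = 1..n_max`, normalised by log-sum-exp. When `n_max` is `NULL` it is
#' grown automatically until the effective free energy at the boundary
#' exceeds the minimum by at least `tail_gap` kBT, so that the truncated
#' tail mass is negligible.
#'
#' @param params A [micelle_params()] object.
#' @param kinetics A [kinetic_params()] object.
#' @param n_max Truncation (integer), or `NULL` to choose automatically.
#' @param tail_gap Required `effF(n_max) - min effF` margin in kBT
#'   (default 30).
#' @return A tibble with columns `n`, `eff_F` and `prob`, of class
#'   `size_distribution`, with attributes `logZ` (log of the effective
#'   partition function) and `n_max`.
#' @examples
#' d <- size_distribution(preset_params("fig4", N_A = 8),
#'                        kinetic_params(log_zeta = -12))
#' sum(d$prob)
#' @export
size_distribution <- function(params, kinetics, n_max = NULL, tail_gap = 30) {
  fmin <- .fmin_factory(params)
  F1 <- fmin(1)
  lz <- log(kinetics$phi_p + kinetics$zeta)
  eff <- function(n) {
    vapply(n, fmin, 0) - n * F1 - (n - 1) * lz + lgamma(n + 1)
  }
  if (is.null(n_max)) {
    opt <- .optimal_n(params, kinetics, fmin = fmin)
    n_max <- max(10, ceiling(opt$n_star * 1.5))
    while (eff(n_max) - opt$eff_min < tail_gap && n_max < 1e6) {
      n_max <- ceiling(n_max * 1.5)
    }
  }
  n <- seq_len(n_max)
  e <- eff(n)
  if (e[n_max] - min(e) < tail_gap) {
    stop("truncation failure: effF(n_max) - min effF < ", tail_gap,
         " kBT; increase n_max")
  }
  m <- max(-e)
  logZ <- m + log(sum(exp(-e - m)))
  structure(
    tibble::tibble(n = n, eff_F = e, prob = exp(-e - logZ)),
    logZ = logZ, n_max = n_max,
    class = c("size_distribution", class(tibble::tibble()))
  )
}
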