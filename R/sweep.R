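# Parameter sweeps, discontinuity detection, bisection for the critical
# A-block length, and phase maps.

# Solve one (params, kinetics) point; returns a one-row tibble. fmin is an
# optional memoised F(n) shared across a sweep at fixed micelle params.
.solve_point <- function(p, kin, fmin = NULL, n_cap = 1e5,
                         delta = 0.05, n_unstable = 2) {
  opt <- .optimal_n(p, kin, n_cap = n_cap, fmin = fmin)
  ma <- .min_alpha1(opt$n_star, p)
  geom <- micelle_geometry(tibble::tibble(n = opt$n_star, alpha = ma[["alpha"]]), p)
  tibble::tibble(
    n_star = opt$n_star, alpha_star = ma[["alpha"]],
    F_n_star = ma[["F"]], eff_F_min = opt$eff_min,
    r_c = geom$r_c, r_A = geom$r_A, r_C = geom$r_C,
    phase = as.character(classify_state(ma[["alpha"]], opt$n_star,
                                        delta = delta, n_unstable = n_unstable))
  )
}

.sweep_vars <- c("log_zeta", "N_A", "N_B")

# Build (params, kinetics) for one value of the swept variable.
.sweep_point_pars <- function(variable, value, params, kinetics) {
  if (variable == "log_zeta") {
    list(p = params, kin = kinetic_params(log_zeta = value,
                                          phi_p = kinetics$phi_p))
  } else {
    pl <- unclass(params)
    pl[[variable]] <- value
    pl$b <- NULL; pl$kBT <- NULL
    list(p = do.call(micelle_params, pl), kin = kinetics)
  }
}

#' Sweep the equilibrium paraspeckle over a model parameter
#'
#' Solves the nested minimisation (over the shell fraction `alpha` and the
#' aggregation number `n`) at every value of a grid over `log_zeta`
#' (transcription rate), `N_A`, or `N_B`, recording the optimum, the
#' micelle radii and the phase label. Per-point failures are recorded as
#' `NA` rows with the reason in the `note` column rather than aborting the
#' sweep.
#'
#' @param params A [micelle_params()] object (base values; the swept field
#'   is overridden per grid point).
#' @param kinetics A [kinetic_params()] object (ignored field `zeta` when
#'   sweeping `log_zeta`).
#' @param variable One of `"log_zeta"`, `"N_A"`, `"N_B"`.
#' @param grid Strictly monotone numeric grid of values to sweep.
#' @param n_cap,delta,n_unstable Passed to the per-point solver, see
#'   [optimal_micelle()].
#' @param cache Memoise `min_alpha F_n(alpha)` across grid points where the
#'   micelle parameters do not change (only for `log_zeta` sweeps). Results
#'   are identical with the cache disabled.
#' @return A tibble of class `micelle_sweep` with one row per grid value:
#'   the swept variable, `n_star`, `alpha_star`, `F_n_star`, `eff_F_min`,
#'   `r_c`, `r_A`, `r_C`, `phase`, `note`.
#' @examples
#' \donttest{
#' p <- preset_params("fig4", N_A = 3)
#' sweep_micelle(p, kinetic_params(log_zeta = -12), "log_zeta",
#'               grid = seq(-13, -11, by = 0.5))
#' }
#' @export
sweep_micelle <- function(params, kinetics, variable, grid,
                          n_cap = 1e5, delta = 0.05, n_unstable = 2,
                          cache = TRUE) {
  variable <- match.arg(variable, .sweep_vars)
  stopifnot(
    "grid must be strictly monotone" =
      length(grid) >= 1 && (length(grid) == 1 ||
        all(diff(grid) > 0) || all(diff(grid) < 0))
  )
  fmin <- if (variable == "log_zeta") .fmin_factory(params, cache = cache)
  rows <- purrr::map(grid, function(v) {
    pk <- .sweep_point_pars(variable, v, params, kinetics)
    out <- tryCatch(
      .solve_point(pk$p, pk$kin, fmin = fmin, n_cap = n_cap,
                   delta = delta, n_unstable = n_unstable) |>
        dplyr::mutate(note = NA_character_),
      error = function(e) tibble::tibble(
        n_star = NA_real_, alpha_star = NA_real_, F_n_star = NA_real_,
        eff_F_min = NA_real_, r_c = NA_real_, r_A = NA_real_, r_C = NA_real_,
        phase = NA_character_, note = conditionMessage(e)
      )
    )
    dplyr::bind_cols(tibble::tibble("{variable}" := v), out)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("micelle_sweep", class(out))
  attr(out, "variable") <- variable
  attr(out, "params") <- params
  attr(out, "kinetics") <- kinetics
  out
}

# alpha* at one value of the swept variable (used by jump refinement)
.alpha_at <- function(variable, value, params, kinetics, fmin = NULL,
                      n_unstable = 2) {
  pk <- .sweep_point_pars(variable, value, params, kinetics)
  if (variable != "log_zeta") fmin <- NULL
  opt <- .optimal_n(pk$p, pk$kin, fmin = fmin)
  c(alpha = .min_alpha1(opt$n_star, pk$p)[["alpha"]], n = opt$n_star)
}

#' Detect a discontinuity in a swept shell-fraction curve
#'
#' Classifies an `alpha*` curve from [sweep_micelle()] as continuous or
#' discontinuous. A candidate jump is an adjacent-grid change exceeding
#' `threshold` among the stable points (`n* >= n_unstable`); by default the
#' candidate is then refined by bisection on the swept variable down to an
#' interval of width `refine_tol`, and the curve is called discontinuous
#' only if the jump persists (exceeds `persist`) across that interval.
#' The refinement distinguishes a genuine first-order jump from a steep
#' but continuous crossover, which on a coarse grid can exceed
#' `threshold`. With `refine = FALSE` the grid criterion alone decides.
#'
#' @param sweep A `micelle_sweep` tibble (from [sweep_micelle()]).
#' @param threshold Adjacent-grid jump in `alpha*` that triggers a
#'   candidate (default 0.2).
#' @param refine Refine candidate jumps by bisection (default `TRUE`).
#' @param refine_tol Width of the refined interval in the swept variable
#'   (default 1e-6).
#' @param persist Minimum jump across the refined interval for a
#'   discontinuity (default 0.01).
#' @param n_unstable Points with `n* <` this are excluded (no stable
#'   micelle; the onset of stability is not an `alpha` discontinuity).
#' @return A one-row tibble: `is_discontinuous`, `location` (midpoint of
#'   the jump interval, `NA` if continuous), `jump` (limiting jump size).
#' @export
detect_discontinuity <- function(sweep, threshold = 0.2, refine = TRUE,
                                 refine_tol = 1e-6, persist = 0.01,
                                 n_unstable = 2) {
  stopifnot(inherits(sweep, "micelle_sweep"))
  variable <- attr(sweep, "variable")
  params <- attr(sweep, "params")
  kinetics <- attr(sweep, "kinetics")
  ok <- !is.na(sweep$alpha_star) & sweep$n_star >= n_unstable
  a <- sweep$alpha_star[ok]
  x <- sweep[[variable]][ok]
  none <- tibble::tibble(is_discontinuous = FALSE, location = NA_real_,
                         jump = if (length(a) > 1) max(abs(diff(a))) else 0)
  if (length(a) < 2) return(none)
  jumps <- abs(diff(a))
  if (any(is.na(sweep$alpha_star[!is.na(sweep$n_star) &
                                 sweep$n_star >= n_unstable]))) {
    stop("missing alpha values inside the stable region")
  }
  i <- which.max(jumps)
  if (jumps[i] <= threshold) return(none)
  if (!refine) {
    return(tibble::tibble(is_discontinuous = TRUE,
                          location = (x[i] + x[i + 1]) / 2, jump = jumps[i]))
  }
  fmin <- if (variable == "log_zeta") .fmin_factory(params)
  lo <- x[i]; hi <- x[i + 1]
  alo <- a[i]; ahi <- a[i + 1]
  while (abs(hi - lo) > refine_tol) {
    m <- (lo + hi) / 2
    am <- .alpha_at(variable, m, params, kinetics, fmin = fmin)[["alpha"]]
    if (abs(am - alo) > abs(ahi - am)) {
      hi <- m; ahi <- am
    } else {
      lo <- m; alo <- am
    }
  }
  jump <- abs(ahi - alo)
  tibble::tibble(is_discontinuous = jump > persist,
                 location = (lo + hi) / 2, jump = jump)
}

#' Critical A-block length by bisection
#'
#' Finds the A-block length `N_A^c` separating continuous from
#' discontinuous dependence of the shell fraction `alpha*` on the swept
#' variable (`log_zeta` for the transcription-rate diagram, `N_B` for the
#' B-block diagram at fixed transcription rate). Each bisection step runs
#' [sweep_micelle()] at the candidate `N_A` and classifies the curve with
#' [detect_discontinuity()].
#'
#' @param params Base [micelle_params()]; its `N_A` is replaced by the
#'   bisection candidate.
#' @param kinetics A [kinetic_params()] object (fixed rate for `N_B`
#'   sweeps; `phi_p` carried over for `log_zeta` sweeps).
#' @param sweep_variable `"log_zeta"` or `"N_B"`.
#' @param bracket Length-2 bracket on `N_A`; the curve must be continuous
#'   at the lower end and discontinuous at the upper end.
#' @param grid Grid of the swept variable for each classification sweep.
#' @param tol Bisection tolerance on `N_A` (default 5e-4).
#' @param ... Passed to [detect_discontinuity()].
#' @return A one-row tibble with `N_A_c`, `sweep_variable`, `bracket_lo`,
#'   `bracket_hi`, `tol`.
#' @examples
#' \donttest{
#' # transcription-rate sweep; recovers N_A^c near 5.25 (several minutes)
#' critical_NA(preset_params("fig4", N_A = 5), kinetic_params(log_zeta = -12),
#'             "log_zeta", bracket = c(3, 8))
#' }
#' @export
critical_NA <- function(params, kinetics, sweep_variable = c("log_zeta", "N_B"),
                        bracket = c(3, 8),
                        grid = NULL, tol = 5e-4, ...) {
  sweep_variable <- match.arg(sweep_variable)
  if (is.null(grid)) {
    grid <- if (sweep_variable == "log_zeta") seq(-16, -6, by = 0.1)
            else seq(10, 60, by = 0.5)
  }
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  pred <- function(NA_val) {
    pl <- unclass(params)
    pl$N_A <- NA_val
    pl$b <- NULL; pl$kBT <- NULL
    p <- do.call(micelle_params, pl)
    sw <- sweep_micelle(p, kinetics, sweep_variable, grid)
    detect_discontinuity(sw, ...)$is_discontinuous
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (pred(lo) || !pred(hi)) {
    stop("invalid bracket: need a continuous curve at N_A = ", lo,
         " and a discontinuous curve at N_A = ", hi)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
  }
  tibble::tibble(
    N_A_c = (lo + hi) / 2, sweep_variable = sweep_variable,
    bracket_lo = bracket[1], bracket_hi = bracket[2], tol = tol
  )
}

#' Phase map over a two-parameter grid
#'
#' Classifies the paraspeckle state on a grid of `N_A` against either the
#' transcription rate (`log_zeta`, the rate diagram) or the B-block length
#' (`N_B`, the block-length diagram at fixed rate). Per-cell failures are
#' labelled `NA` with the reason in `note`.
#'
#' @param params Base [micelle_params()] (its `N_A`, and `N_B` when swept,
#'   are overridden per cell).
#' @param kinetics A [kinetic_params()] object.
#' @param NA_grid Grid of A-block lengths.
#' @param x_variable `"log_zeta"` or `"N_B"` for the other axis.
#' @param x_grid Grid of the other axis.
#' @param ... Passed to the per-point solver (`delta`, `n_unstable`,
#'   `n_cap`).
#' @return A tibble of class `phase_map` with columns `N_A`, the x
#'   variable, `n_star`, `alpha_star`, `phase`, `note`.
#' @export
phase_map <- function(params, kinetics, NA_grid,
                      x_variable = c("log_zeta", "N_B"), x_grid, ...) {
  x_variable <- match.arg(x_variable)
  rows <- purrr::map(NA_grid, function(na) {
    pl <- unclass(params)
    pl$N_A <- na
    pl$b <- NULL; pl$kBT <- NULL
    p <- do.call(micelle_params, pl)
    sweep_micelle(p, kinetics, x_variable, x_grid, ...) |>
      dplyr::mutate(N_A = na, .before = 1)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::select(dplyr::all_of(c("N_A", x_variable,
                                  "n_star", "alpha_star", "phase", "note")))
  class(out) <- c("phase_map", class(tibble::tibble()))
  attr(out, "x_variable") <- x_variable
  out
}

#' Extract phase-boundary segments from a phase map
#'
#' Marches over the label grid and returns the midpoints of grid edges
#' whose two cells carry different phase labels, one row per boundary
#' edge, tagged with the pair of phases it separates.
#'
#' @param map A `phase_map` tibble.
#' @return A tibble with columns `x`, `N_A`, `from`, `to`.
#' @export
phase_boundaries <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  xv <- attr(map, "x_variable")
  long <- dplyr::arrange(tibble::as_tibble(map), .data$N_A, .data[[xv]])
  edge <- function(df, along) {
    df |>
      dplyr::mutate(
        nxt = dplyr::lead(.data$phase),
        xm = (.data[[along]] + dplyr::lead(.data[[along]])) / 2
      ) |>
      dplyr::filter(!is.na(.data$nxt), .data$phase != .data$nxt)
  }
  horiz <- long |>
    dplyr::group_by(.data$N_A) |>
    edge(xv) |>
    dplyr::ungroup() |>
    dplyr::transmute(x = .data$xm, N_A = .data$N_A,
                     from = .data$phase, to = .data$nxt)
  vert <- long |>
    dplyr::group_by(.data[[xv]]) |>
    edge("N_A") |>
    dplyr::ungroup() |>
    dplyr::transmute(x = .data[[xv]], N_A = .data$xm,
                     from = .data$phase, to = .data$nxt)
  dplyr::bind_rows(horiz, vert)
}
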