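# broom-style tidiers for solver results and fits.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an equilibrium into a one-row tibble
#'
#' @param x An `ess_equilibrium`.
#' @param ... Unused.
#' @return A one-row tibble with the strategies, payoffs, damage fraction
#'   and solver flags.
#' @examples
#' tidy(solve_undamaged(game_env(N = 50), plant_params()))
#' @method tidy ess_equilibrium
#' @export
tidy.ess_equilibrium <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, location = x$location, partials_mode = x$partials_mode,
    N = x$env$N, C = x$env$C,
    u_r = x$u_r, u_s = x$u_s, u_h = x$u_h, phi = x$phi, D = x$D,
    pi_C = x$pi_C, pi_N = x$pi_N, G = x$G, converged = x$converged
  )
}

#' @rdname tidy.ess_equilibrium
#' @method glance ess_equilibrium
#' @export
glance.ess_equilibrium <- function(x, ...) {
  tibble::tibble(converged = x$converged, soc_ok = x$soc_ok,
                 residual = x$residual, iterations = x$iterations)
}

#' Tidy a lnRR trend fit
#'
#' @param x A `trend_fit` from [fit_trend()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`intercept`, `d`).
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "d"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    scope = x$scope
  )
}

#' @rdname tidy.trend_fit
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = x$sigma, nobs = x$n,
                 scope = x$scope)
}

#' Tidy a slope comparison
#'
#' @param x A `slope_comparison` from [compare_slopes()].
#' @param ... Unused.
#' @return A one-row tibble with the slope difference, its standard error,
#'   the chi-squared statistic and p-value.
#' @method tidy slope_comparison
#' @export
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(
    slope_observed = x$slope_observed, slope_expected = x$slope_expected,
    slope_diff = x$slope_diff, std.error = x$se,
    statistic = x$statistic, p.value = x$p_value
  )
}

#' Summary statistics of a sweep table
#'
#' @param x A `herbgame_sweep` from [sweep_fixed()] or [sweep_dynamic()].
#' @param ... Unused.
#' @return A one-row tibble with grid sizes, the convergence count and
#'   (for dynamic sweeps) the mean damage fraction.
#' @method glance herbgame_sweep
#' @export
glance.herbgame_sweep <- function(x, ...) {
  damaged <- dplyr::filter(x, .data$damage_mode != "none")
  tibble::tibble(
    sweep_type = attr(x, "sweep_type"),
    n_N = length(unique(x$N)),
    n_damage = length(unique(x$D)),
    n_converged = sum(damaged$converged),
    n_cells = nrow(damaged),
    mean_D = if (!is.null(attr(x, "mean_D"))) attr(x, "mean_D") else
      mean(damaged$D[damaged$converged])
  )
}
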