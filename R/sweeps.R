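# Nitrogen-gradient sweeps of the game equilibria, and the compensation
# metrics used to compare damaged with undamaged plants.

#' Log response ratio
#'
#' `ln_rr(x_damaged, x_undamaged) = log(x_damaged / x_undamaged)` for any
#' positive tissue mass or fitness. Zero means perfect compensation,
#' negative undercompensation, positive overcompensation.
#'
#' @param value_damaged,value_undamaged Positive masses or fitness values;
#'   vectorized.
#' @return Numeric lnRR.
#' @examples
#' ln_rr(8, 10)       # undercompensation
#' ln_rr(10, 10)      # perfect compensation
#' @export
ln_rr <- function(value_damaged, value_undamaged) {
  if (any(!is.finite(value_damaged)) || any(!is.finite(value_undamaged)) ||
      any(value_damaged <= 0) || any(value_undamaged <= 0)) {
    stop("ln_rr is defined only for positive, finite values")
  }
  log(value_damaged / value_undamaged)
}

#' Proportion of the attacked tissue consumed
#'
#' `D = 1 - exp(-a * u_h)`: the consumed fraction implied by a foraging
#' time. At an interior herbivore optimum this also equals
#' `1 - c_h / (a * u_i*)`.
#'
#' @param eq An `ess_equilibrium`, or a numeric foraging time `u_h`.
#' @param herb A [herbivore_params()] supplying `a`.
#' @return Damage fraction in `[0, 1)`.
#' @examples
#' damage_fraction(1, herbivore_params(a = 0.7))
#' @export
damage_fraction <- function(eq, herb) {
  u_h <- if (inherits(eq, "ess_equilibrium")) eq$u_h else eq
  if (any(is.na(u_h))) return(NA_real_)
  if (any(u_h < 0)) stop("u_h must be non-negative")
  1 - exp(-herb$a * u_h)
}

#' No-compensation floor for lnRR
#'
#' A plant that loses fraction `D` of a tissue and mounts no compensatory
#' response shows `lnRR = log(1 - D)` for that tissue. Observed lnRR above
#' this floor indicates compensatory regrowth.
#'
#' @param D Damage fraction in `[0, 1)`; vectorized.
#' @return `log(1 - D)`.
#' @examples
#' null_floor(c(0, 0.15, 0.60))
#' @export
null_floor <- function(D) {
  if (any(D < 0) || any(D >= 1)) stop("D must lie in [0, 1)")
  log(1 - D)
}

.sweep_row <- function(N, eq, un, damage_mode, herb_a) {
  dead <- !eq$converged || !is.finite(eq$u_r)
  base_ok <- un$converged && is.finite(un$u_r)
  can_lnrr <- !dead && base_ok
  tibble::tibble(
    N = N,
    damage_mode = damage_mode,
    location = eq$location,
    D = eq$D,
    partials_mode = eq$partials_mode,
    u_r = eq$u_r, u_s = eq$u_s, u_h = eq$u_h,
    pi_C = eq$pi_C, pi_N = eq$pi_N, G = eq$G,
    lnRR_fruit = if (can_lnrr) ln_rr(eq$G, un$G) else NA_real_,
    lnRR_shoot = if (can_lnrr) ln_rr(eq$u_s, un$u_s) else NA_real_,
    lnRR_root = if (can_lnrr) ln_rr(eq$u_r, un$u_r) else NA_real_,
    null_floor = null_floor(eq$D),
    converged = eq$converged
  )
}

#' Fixed-damage sweep over nitrogen and damage gradients
#'
#' For each nitrogen availability the undamaged equilibrium is solved once;
#' each damage fraction is then imposed as a fixed consumed fraction of the
#' attacked tissue and the plant's best response solved. Log response
#' ratios for fruit (fitness), shoot and root are computed against the
#' paired undamaged equilibrium at the same nitrogen level, alongside the
#' `log(1 - D)` no-compensation floor. Fully deterministic given inputs.
#'
#' @param plant A [plant_params()].
#' @param env_grid Nitrogen availabilities (gN); default 50 evenly spaced
#'   values on `[5, 100]`.
#' @param damage_grid Damage fractions; default spans `[0, 0.95]`.
#' @param location Attacked tissue, `"shoot"` or `"root"`.
#' @param C Season carbon total (gC).
#' @param partials_mode `"derived"` or `"table2"`.
#' @param herb A [herbivore_params()] used only to report the foraging time
#'   implied by each damage fraction.
#' @param control A [solver_control()].
#' @return A tibble of class `herbgame_sweep`: one row per (N, D) cell,
#'   with strategies, payoffs, lnRR columns (NA on non-converged cells) and
#'   the null floor. D = 0 rows are the undamaged baselines.
#' @examples
#' sw <- sweep_fixed(plant_params(), env_grid = c(20, 50),
#'                   damage_grid = c(0, 0.5), location = "shoot")
#' sw[, c("N", "D", "lnRR_shoot", "null_floor")]
#' @export
sweep_fixed <- function(plant = plant_params(),
                        env_grid = seq(5, 100, length.out = 50),
                        damage_grid = seq(0, 0.95, by = 0.05),
                        location = c("shoot", "root"),
                        C = 5000,
                        partials_mode = c("derived", "table2"),
                        herb = herbivore_params(location = location),
                        control = solver_control()) {
  location <- match.arg(location)
  partials_mode <- match.arg(partials_mode)
  stopifnot(length(env_grid) >= 1, length(damage_grid) >= 1,
            all(damage_grid >= 0), all(damage_grid < 1))
  damage_grid <- sort(unique(c(0, damage_grid)))
  warm_un <- NULL
  rows <- purrr::map(env_grid, function(N) {
    env <- game_env(C = C, N = N)
    un <- solve_undamaged(env, plant, partials_mode, control,
                          warm_start = warm_un)
    if (un$converged) warm_un <<- c(un$u_r, un$u_s)
    warm_d <- if (un$converged) c(un$u_r, un$u_s) else NULL
    purrr::map(damage_grid, function(D) {
      if (D == 0) {
        eq <- un
        eq$location <- location
      } else {
        eq <- solve_fixed_damage(env, plant, D, location, partials_mode,
                                 herb = herb, control = control,
                                 warm_start = warm_d)
        if (eq$converged) warm_d <<- c(eq$u_r, eq$u_s)
      }
      .sweep_row(N, eq, un,
                 damage_mode = if (D == 0) "none" else "fixed", herb$a)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  n_failed <- sum(!rows$converged)
  if (n_failed > 0) {
    rlang::inform(paste0(n_failed, " sweep cell(s) did not converge"))
  }
  class(rows) <- c("herbgame_sweep", class(rows))
  attr(rows, "sweep_type") <- "fixed"
  rows
}

#' Dynamic-herbivore sweep over a nitrogen gradient
#'
#' For each nitrogen availability, solves the coupled plant-herbivore Nash
#' equilibrium ([solve_dynamic()]) and pairs it with the undamaged
#' equilibrium at the same nitrogen level. The realized damage fraction
#' `D = 1 - exp(-a * u_h*)` is co-determined with growth; its unweighted
#' mean over the converged grid cells is attached as the `mean_D`
#' attribute and available via [glance()].
#'
#' @inheritParams sweep_fixed
#' @param herb A [herbivore_params()] with location `"shoot"` or `"root"`.
#' @return A tibble of class `herbgame_sweep` with paired `none` (undamaged)
#'   and `dynamic` rows per N, plus attribute `mean_D`.
#' @examples
#' sw <- sweep_dynamic(plant_params(), herbivore_params(location = "shoot"),
#'                     env_grid = c(20, 50))
#' attr(sw, "mean_D")
#' @export
sweep_dynamic <- function(plant = plant_params(),
                          herb = herbivore_params(location = "shoot"),
                          env_grid = seq(5, 100, length.out = 50),
                          C = 5000,
                          partials_mode = c("derived", "table2"),
                          control = solver_control()) {
  partials_mode <- match.arg(partials_mode)
  stopifnot(herb$location %in% c("shoot", "root"))
  warm <- NULL
  rows <- purrr::map(env_grid, function(N) {
    env <- game_env(C = C, N = N)
    un <- solve_undamaged(env, plant, partials_mode, control,
                          warm_start = warm)
    dyn <- solve_dynamic(env, plant, herb, partials_mode, control,
                         warm_start = if (un$converged) c(un$u_r, un$u_s)
                                      else warm)
    if (un$converged) warm <<- c(un$u_r, un$u_s)
    un$location <- herb$location
    dplyr::bind_rows(
      .sweep_row(N, un, un, damage_mode = "none", herb$a),
      .sweep_row(N, dyn, un, damage_mode = "dynamic", herb$a)
    )
  }) |> purrr::list_rbind()
  dyn_rows <- dplyr::filter(rows, .data$damage_mode == "dynamic")
  n_failed <- sum(!dyn_rows$converged)
  if (n_failed > 0) {
    rlang::inform(paste0(n_failed, " dynamic cell(s) did not converge"))
  }
  class(rows) <- c("herbgame_sweep", class(rows))
  attr(rows, "sweep_type") <- "dynamic"
  attr(rows, "mean_D") <- mean(dyn_rows$D[dyn_rows$converged])
  rows
}
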