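# Equilibrium computation: the herbivore's closed-form best response, the
# plant's numerically solved vector best response, and the coupled Nash
# equilibrium of the full game.
#
# The plant problem has no closed form. Strategies are parameterized in
# log-space (which enforces positivity), and the two first-order conditions
# are solved by a damped Newton iteration with a numeric Jacobian. The FOCs
# are solved in a rescaled form that is numerically benign:
#   alpha * pi_N * dpi_C/du + beta * pi_C * dpi_N/du = 0
# which equals the raw gradient of G divided by the positive factor
# E * pi_C^(alpha-1) * pi_N^(beta-1), so the roots coincide on the live
# branch. Multi-start guards against non-convexity; among converged roots
# with positive payoffs and passing second-order checks, the highest-G root
# is kept.

#' Solver control parameters
#'
#' @param tol Convergence tolerance on each raw gradient component of the
#'   plant fitness at the solution.
#' @param n_starts Number of log-uniform multi-start points (in addition to
#'   an analytic seed at the cost-equals-marginal-gross point).
#' @param start_range Range (g) over which multi-start points are spread
#'   log-uniformly, for both tissues.
#' @param max_iter Newton iteration cap per start.
#' @param damping Step damping for the dynamic best-response iteration.
#' @param dynamic_tol Relative tolerance on strategy change declaring the
#'   dynamic fixed point converged.
#' @param dynamic_max_iter Iteration cap for the dynamic game.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(tol = 1e-10, n_starts = 8,
                           start_range = c(1e-2, 1e3), max_iter = 100,
                           damping = 0.5, dynamic_tol = 1e-8,
                           dynamic_max_iter = 500) {
  stopifnot(tol > 0, n_starts >= 1, length(start_range) == 2,
            start_range[1] > 0, start_range[2] > start_range[1],
            damping > 0, damping <= 1)
  structure(list(tol = tol, n_starts = n_starts, start_range = start_range,
                 max_iter = max_iter, damping = damping,
                 dynamic_tol = dynamic_tol,
                 dynamic_max_iter = dynamic_max_iter),
            class = "solver_control")
}

#' Herbivore's optimal foraging time
#'
#' Closed-form best response of the herbivore to an attacked tissue of mass
#' `u_i`: `u_h* = max(0, (1/a) * log(a * u_i / c_h))`. The interior value
#' zeroes the herbivore's marginal condition `a * u_i * exp(-a * u_h) = c_h`;
#' the clamp at zero encodes that a herbivore never forages at a loss (the
#' unclamped expression is negative when `a * u_i < c_h`).
#'
#' @param u_i Mass of the attacked tissue (g); vectorized.
#' @param herb A [herbivore_params()].
#' @return Optimal foraging time (days).
#' @examples
#' herbivore_best_response(10, herbivore_params())
#' @export
herbivore_best_response <- function(u_i, herb) {
  if (any(u_i < 0)) stop("u_i must be non-negative")
  pmax(0, log(pmax(herb$a * u_i / herb$c_h, .Machine$double.xmin)) / herb$a)
}

# rescaled FOC at log-strategies z = (log u_r, log u_s); NA when dead
.foc <- function(z, env, plant, phi, location, partials_mode) {
  u_r <- exp(z[1])
  u_s <- exp(z[2])
  pc <- env$C * (1 - exp(-plant$Vc * u_s)) - plant$c_cr * u_r -
    plant$c_cs * u_s -
    plant$alpha * switch(location, shoot = u_s, root = u_r, 0) * phi
  pn <- env$N * (1 - exp(-plant$Vn * u_r)) - plant$c_nr * u_r -
    plant$c_ns * u_s -
    plant$beta * switch(location, shoot = u_s, root = u_r, 0) * phi
  if (!is.finite(pc) || !is.finite(pn) || pc <= 0 || pn <= 0) {
    return(c(NA_real_, NA_real_))
  }
  d <- plant_partials(u_r, u_s, env, plant, phi, location, partials_mode)
  c(plant$alpha * pn * d$dC_dur + plant$beta * pc * d$dN_dur,
    plant$alpha * pn * d$dC_dus + plant$beta * pc * d$dN_dus)
}

# damped Newton on the rescaled FOC; returns log-strategies or NULL
.newton <- function(z0, env, plant, phi, location, partials_mode, max_iter) {
  z <- z0
  f <- .foc(z, env, plant, phi, location, partials_mode)
  if (anyNA(f)) return(NULL)
  for (it in seq_len(max_iter)) {
    # relative residual against the magnitudes of the FOC's two terms
    scale <- c(
      plant$alpha * plant$c_cr + plant$beta * plant$c_nr,
      plant$alpha * plant$c_cs + plant$beta * plant$c_ns
    ) * (abs(env$C) + abs(env$N))
    if (max(abs(f) / scale) < 1e-14) break
    h <- 1e-6
    jac <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- z[j] - h
      fp <- .foc(zp, env, plant, phi, location, partials_mode)
      fm <- .foc(zm, env, plant, phi, location, partials_mode)
      if (anyNA(fp) || anyNA(fm)) return(NULL)
      jac[, j] <- (fp - fm) / (2 * h)
    }
    step <- tryCatch(solve(jac, -f), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) return(NULL)
    # line search: halve until the residual decreases
    lambda <- 1
    improved <- FALSE
    for (k in 1:25) {
      zn <- z + lambda * step
      fn <- .foc(zn, env, plant, phi, location, partials_mode)
      if (!anyNA(fn) && max(abs(fn)) < max(abs(f))) {
        z <- zn
        f <- fn
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  z
}

# numerical pure second differences of plant_fitness (relative step 1e-5)
.soc_ok <- function(u_r, u_s, env, plant, phi, location) {
  g <- function(r, s) plant_fitness(r, s, env, plant, phi, location)
  hr <- 1e-5 * max(u_r, 1e-8)
  hs <- 1e-5 * max(u_s, 1e-8)
  d2r <- (g(u_r + hr, u_s) - 2 * g(u_r, u_s) + g(u_r - hr, u_s)) / hr^2
  d2s <- (g(u_r, u_s + hs) - 2 * g(u_r, u_s) + g(u_r, u_s - hs)) / hs^2
  is.finite(d2r) && is.finite(d2s) && d2r < 0 && d2s < 0
}

.start_points <- function(env, plant, control) {
  # analytic seed: marginal gross harvest equals construction cost,
  # currency by currency; a good guess when C is abundant
  seed <- c(
    log(max(log(max(plant$Vn * env$N / plant$c_nr, 1.05)) / plant$Vn, 1e-2)),
    log(max(log(max(plant$Vc * env$C / plant$c_cs, 1.05)) / plant$Vc, 1e-2))
  )
  lo <- log(control$start_range[1])
  hi <- log(control$start_range[2])
  k <- max(2, ceiling(sqrt(control$n_starts)))
  grid <- seq(lo, hi, length.out = k)
  starts <- list(seed)
  for (i in grid) for (j in grid) starts <- c(starts, list(c(i, j)))
  starts[seq_len(min(length(starts), control$n_starts + 1))]
}

.equilibrium <- function(u_r, u_s, u_h, phi, env, plant, location, mode,
                         partials_mode, converged, soc_ok, residual,
                         iterations = NA_integer_) {
  alive <- is.finite(u_r) && is.finite(u_s)
  if (alive) {
    pay <- plant_fitness(u_r, u_s, env, plant, phi, location, detail = TRUE)
  } else {
    pay <- tibble::tibble(pi_C = NA_real_, pi_N = NA_real_, G = 0,
                          alive = FALSE)
  }
  structure(
    list(u_r = u_r, u_s = u_s, u_h = u_h, phi = phi,
         D = if (location == "none") 0 else phi,
         pi_C = pay$pi_C, pi_N = pay$pi_N, G = pay$G,
         converged = converged, soc_ok = soc_ok, residual = residual,
         iterations = iterations, mode = mode, location = location,
         partials_mode = partials_mode, env = env, plant = plant),
    class = "ess_equilibrium"
  )
}

#' Plant's evolutionarily stable growth strategy at a fixed consumed fraction
#'
#' Solves the plant's two first-order conditions for root and shoot
#' production with the consumed fraction `phi` of the attacked tissue held
#' fixed, by damped Newton iteration in log-strategy space with multi-start.
#' Among converged roots with positive net harvests, second-order conditions
#' (numerically negative pure second derivatives of fitness) are required,
#' and the highest-fitness root is returned.
#'
#' If no live root is found the result has `converged = FALSE` and `NA`
#' strategies rather than throwing; sweeps record such cells and move on.
#'
#' @param env A [game_env()].
#' @param plant A [plant_params()].
#' @param phi Consumed fraction of the attacked tissue, in `[0, 1)`.
#' @param location `"shoot"`, `"root"`, or `"none"`.
#' @param partials_mode `"derived"` or `"table2"`; see [plant_gradient()].
#' @param control A [solver_control()].
#' @param warm_start Optional length-2 numeric `c(u_r, u_s)` used as the
#'   first start point (e.g. the solution at a neighbouring grid cell).
#' @return An `ess_equilibrium` object; see [tidy.ess_equilibrium()].
#' @examples
#' eq <- plant_best_response(game_env(N = 50), plant_params())
#' tidy(eq)
#' @export
plant_best_response <- function(env, plant, phi = 0, location = "none",
                                partials_mode = c("derived", "table2"),
                                control = solver_control(),
                                warm_start = NULL) {
  partials_mode <- match.arg(partials_mode)
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  starts <- .start_points(env, plant, control)
  if (!is.null(warm_start) && all(is.finite(warm_start)) &&
      all(warm_start > 0)) {
    starts <- c(list(log(warm_start)), starts)
  }
  best <- NULL
  for (z0 in starts) {
    z <- .newton(z0, env, plant, phi, location, partials_mode,
                 control$max_iter)
    if (is.null(z)) next
    u_r <- exp(z[1])
    u_s <- exp(z[2])
    pay <- plant_fitness(u_r, u_s, env, plant, phi, location, detail = TRUE)
    if (!pay$alive) next
    grad <- plant_gradient(u_r, u_s, env, plant, phi, location, partials_mode)
    res <- max(abs(grad$dG_dur), abs(grad$dG_dus))
    if (res > control$tol) next
    if (is.null(best) || pay$G > best$G) {
      best <- list(u_r = u_r, u_s = u_s, G = pay$G, res = res)
    }
    if (!is.null(warm_start) && !is.null(best)) break  # warm path: trust it
  }
  if (is.null(best)) {
    return(.equilibrium(NA_real_, NA_real_, NA_real_, phi, env, plant,
                        location, mode = if (phi == 0) "none" else "fixed",
                        partials_mode, converged = FALSE, soc_ok = FALSE,
                        residual = NA_real_))
  }
  soc <- .soc_ok(best$u_r, best$u_s, env, plant, phi, location)
  .equilibrium(best$u_r, best$u_s, NA_real_, phi, env, plant, location,
               mode = if (phi == 0) "none" else "fixed", partials_mode,
               converged = soc, soc_ok = soc, residual = best$res)
}

#' Undamaged plant equilibrium
#'
#' Convenience wrapper: [plant_best_response()] with no herbivore
#' (`phi = 0`), with herbivore time and damage recorded as zero.
#'
#' @inheritParams plant_best_response
#' @return An `ess_equilibrium`.
#' @examples
#' solve_undamaged(game_env(N = 50), plant_params())$G
#' @export
solve_undamaged <- function(env, plant,
                            partials_mode = c("derived", "table2"),
                            control = solver_control(), warm_start = NULL) {
  partials_mode <- match.arg(partials_mode)
  eq <- plant_best_response(env, plant, phi = 0, location = "none",
                            partials_mode = partials_mode, control = control,
                            warm_start = warm_start)
  eq$u_h <- 0
  eq
}

#' Plant equilibrium under a fixed damage fraction
#'
#' Holds the herbivore's consumption constant at damage fraction `D` of the
#' attacked tissue (the fixed-damage protocol of the nitrogen-gradient
#' sweeps) and solves the plant's best response. The herbivore foraging time
#' implied by the damage, `u_h = -log(1 - D) / a`, is stored for reporting.
#'
#' @inheritParams plant_best_response
#' @param D Damage fraction in `[0, 1)`; used directly as the consumed
#'   fraction `phi`.
#' @param herb A [herbivore_params()] supplying the encounter rate `a` used
#'   to report the implied foraging time.
#' @return An `ess_equilibrium` with `mode = "fixed"`.
#' @examples
#' solve_fixed_damage(game_env(N = 50), plant_params(), D = 0.5,
#'                    location = "shoot")$u_s
#' @export
solve_fixed_damage <- function(env, plant, D, location = c("shoot", "root"),
                               partials_mode = c("derived", "table2"),
                               herb = herbivore_params(location = location),
                               control = solver_control(),
                               warm_start = NULL) {
  location <- match.arg(location)
  partials_mode <- match.arg(partials_mode)
  if (D < 0 || D >= 1) stop("D must lie in [0, 1)")
  eq <- plant_best_response(env, plant, phi = D, location = location,
                            partials_mode = partials_mode, control = control,
                            warm_start = warm_start)
  eq$u_h <- -log(1 - D) / herb$a
  eq$mode <- "fixed"
  eq
}

#' Coupled plant-herbivore Nash equilibrium
#'
#' Finds a simultaneous equilibrium of the full game: the plant's growth
#' strategy is a best response to the herbivore's foraging time, and the
#' foraging time is the herbivore's best response to the attacked tissue
#' mass. Solved by damped best-response iteration (plant step, then
#' herbivore step), warm-starting each plant solve from the previous
#' iterate. The returned solution is verified against the full three-way
#' stationarity condition: both plant gradient components below `tol` and,
#' when the herbivore is interior, `a * u_i * exp(-a * u_h) - c_h` below
#' `dynamic_tol`.
#'
#' If the herbivore cannot profitably forage at the undamaged optimum the
#' clamp engages and the result equals [solve_undamaged()]. If no live
#' plant best response exists at the equilibrium damage the plant is driven
#' to death; the result is flagged (`converged = FALSE`, `G = 0`).
#'
#' @inheritParams plant_best_response
#' @param herb A [herbivore_params()] with `location` `"shoot"` or `"root"`.
#' @return An `ess_equilibrium` with `mode = "dynamic"` and the herbivore
#'   time in `u_h`.
#' @examples
#' eq <- solve_dynamic(game_env(N = 50), plant_params(),
#'                     herbivore_params(location = "shoot"))
#' c(eq$u_s, eq$D)
#' @export
solve_dynamic <- function(env, plant, herb,
                          partials_mode = c("derived", "table2"),
                          control = solver_control(), warm_start = NULL) {
  partials_mode <- match.arg(partials_mode)
  if (herb$location == "none") {
    return(solve_undamaged(env, plant, partials_mode, control, warm_start))
  }
  location <- herb$location
  eq <- plant_best_response(env, plant, phi = 0, location = "none",
                            partials_mode = partials_mode, control = control,
                            warm_start = warm_start)
  if (!eq$converged) {
    out <- .equilibrium(NA_real_, NA_real_, NA_real_, 0, env, plant,
                        location, "dynamic", partials_mode,
                        converged = FALSE, soc_ok = FALSE,
                        residual = NA_real_)
    return(out)
  }
  u_i <- if (location == "shoot") eq$u_s else eq$u_r
  u_h <- herbivore_best_response(u_i, herb)
  iterations <- 0L
  ok <- FALSE
  for (it in seq_len(control$dynamic_max_iter)) {
    iterations <- it
    phi <- 1 - exp(-herb$a * u_h)
    prev <- c(eq$u_r, eq$u_s)
    eq <- plant_best_response(env, plant, phi = phi, location = location,
                              partials_mode = partials_mode,
                              control = control, warm_start = prev)
    if (!eq$converged) {
      # plant killed at this damage level: dead outcome, flagged
      out <- .equilibrium(NA_real_, NA_real_, u_h, phi, env, plant,
                          location, "dynamic", partials_mode,
                          converged = FALSE, soc_ok = FALSE,
                          residual = NA_real_, iterations = iterations)
      return(out)
    }
    u_i <- if (location == "shoot") eq$u_s else eq$u_r
    u_h_new <- herbivore_best_response(u_i, herb)
    delta <- max(abs(u_h_new - u_h) / (1 + abs(u_h)),
                 abs(c(eq$u_r, eq$u_s) - prev) / (1 + abs(prev)))
    if (delta < control$dynamic_tol) {
      u_h <- u_h_new
      ok <- TRUE
      break
    }
    u_h <- u_h + control$damping * (u_h_new - u_h)
  }
  phi <- 1 - exp(-herb$a * u_h)
  eq <- plant_best_response(env, plant, phi = phi, location = location,
                            partials_mode = partials_mode, control = control,
                            warm_start = c(eq$u_r, eq$u_s))
  u_i <- if (location == "shoot") eq$u_s else eq$u_r
  herb_res <- if (u_h > 0) {
    abs(herb$a * u_i * exp(-herb$a * u_h) - herb$c_h)
  } else 0
  out <- .equilibrium(eq$u_r, eq$u_s, u_h, phi, env, plant, location,
                      "dynamic", partials_mode,
                      converged = ok && eq$converged &&
                        herb_res < control$dynamic_tol,
                      soc_ok = eq$soc_ok,
                      residual = max(eq$residual, herb_res),
                      iterations = iterations)
  out
}

#' Exhaustive grid search for the plant optimum
#'
#' Brute-force evaluation of [plant_fitness()] on a log-spaced strategy
#' grid, followed by one local refinement pass around the best cell. This
#' is a validation oracle for [plant_best_response()] -- slow but
#' assumption-free -- and is used by the test-suite, not by the solvers.
#'
#' @inheritParams plant_best_response
#' @param n_grid Grid resolution per axis (at least 50).
#' @param bounds Length-2 strategy bounds (g) for both axes.
#' @return A list with `u_r`, `u_s`, `G` at the best grid point.
#' @examples
#' grid_oracle(game_env(N = 50), plant_params(), n_grid = 60)
#' @export
grid_oracle <- function(env, plant, phi = 0, location = "none",
                        n_grid = 400, bounds = c(1e-3, 1e4)) {
  stopifnot(n_grid >= 50, all(is.finite(bounds)), bounds[1] > 0)
  eval_grid <- function(ur_vals, us_vals) {
    g <- outer(ur_vals, us_vals, function(r, s) {
      plant_fitness(r, s, env, plant, phi, location)
    })
    idx <- arrayInd(which.max(g), dim(g))
    list(u_r = ur_vals[idx[1]], u_s = us_vals[idx[2]], G = max(g),
         i = idx[1], j = idx[2])
  }
  ur_vals <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  us_vals <- ur_vals
  coarse <- eval_grid(ur_vals, us_vals)
  # refine within +/- 2 cells of the coarse optimum
  span <- function(vals, i) {
    lo <- vals[max(1, i - 2)]
    hi <- vals[min(length(vals), i + 2)]
    exp(seq(log(lo), log(hi), length.out = n_grid))
  }
  fine <- eval_grid(span(ur_vals, coarse$i), span(us_vals, coarse$j))
  fine[c("u_r", "u_s", "G")]
}

#' @export
print.ess_equilibrium <- function(x, ...) {
  cat(sprintf("<ess_equilibrium: %s damage, %s attack, %s partials>\n",
              x$mode, x$location, x$partials_mode))
  if (is.finite(x$u_r)) {
    cat(sprintf("  u_r* = %.6g  u_s* = %.6g  u_h* = %s\n", x$u_r, x$u_s,
                ifelse(is.na(x$u_h), "-", sprintf("%.6g", x$u_h))))
    cat(sprintf("  G = %.6g  pi_C = %.6g  pi_N = %.6g  D = %.4g\n",
                x$G, x$pi_C, x$pi_N, x$D))
  } else {
    cat("  no live solution (plant dead or solver failed)\n")
  }
  cat(sprintf("  converged = %s  soc_ok = %s  residual = %.3g\n",
              x$converged, x$soc_ok, x$residual))
  invisible(x)
}
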