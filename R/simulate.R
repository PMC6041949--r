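# Synthetic randomized-complete-block clipping experiments with known
# ground truth, for end-to-end testing of the analysis pipeline and for
# power / error-rate studies.
#
# Noise is multiplicative log-normal at two levels (block intercept and
# per-plant residual), so the lnRR of generated data is exactly
# truth(d) + Gaussian noise and recovery algebra stays transparent.

#' Specification of a synthetic clipping experiment
#'
#' Describes a randomized complete block design: every block contains one
#' plant per clipping level, including the unclipped control. Treatment
#' effects (the true lnRR curves per tissue) come either from the growth
#' game itself -- fixed-damage equilibria at a chosen nitrogen availability
#' -- or from user-supplied linear lnRR-versus-d slopes.
#'
#' Baseline masses are arbitrary round numbers; every downstream statistic
#' depends only on ratios. Clipping accounting: the clipped mass is
#' `d * total_shoot` (the clipping fraction applied to season-total shoot
#' production, mirroring leaf-by-leaf clipping of a fixed length fraction),
#' and standing mass is the remainder.
#'
#' @param n_blocks Number of blocks (default 18).
#' @param d_levels Clipping fractions; must include 0 (the control).
#' @param baseline Named numeric: control means for `spike`, `shoot`
#'   (total), `root`, in grams.
#' @param block_sd SD of the log-normal multiplicative block intercept
#'   (log scale).
#' @param residual_cv Named numeric per-tissue residual coefficients of
#'   variation (log-scale SD): `fruit`, `shoot`, `root`.
#' @param effects `"model"` for game-linked truth curves, or a named list
#'   `list(fruit =, shoot =, root =)` of linear lnRR-versus-d slopes.
#' @param model_N Nitrogen availability used for model-linked effects
#'   (default 20, a nutrient-limited soil).
#' @param location,partials_mode Passed to [solve_fixed_damage()] for
#'   model-linked effects.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return A list of class `experiment_spec`.
#' @examples
#' experiment_spec(n_blocks = 6, effects = list(fruit = -0.5, shoot = -1,
#'                                              root = -0.3))
#' @export
experiment_spec <- function(n_blocks = 18,
                            d_levels = c(0, 0.15, 0.30, 0.45, 0.60),
                            baseline = c(spike = 2, shoot = 10, root = 5),
                            block_sd = 0.15,
                            residual_cv = c(fruit = 0.10, shoot = 0.10,
                                            root = 0.15),
                            effects = "model",
                            model_N = 20,
                            location = "shoot",
                            partials_mode = "derived",
                            seed = 1L) {
  stopifnot(n_blocks >= 2, 0 %in% d_levels, all(d_levels >= 0),
            all(d_levels < 1), all(baseline > 0), block_sd >= 0,
            all(residual_cv >= 0),
            all(c("spike", "shoot", "root") %in% names(baseline)),
            all(c("fruit", "shoot", "root") %in% names(residual_cv)))
  if (is.list(effects)) {
    stopifnot(all(c("fruit", "shoot", "root") %in% names(effects)))
  } else if (!identical(effects, "model")) {
    stop("effects must be \"model\" or a named list of slopes")
  }
  structure(
    list(n_blocks = as.integer(n_blocks), d_levels = sort(unique(d_levels)),
         baseline = baseline, block_sd = block_sd,
         residual_cv = residual_cv, effects = effects, model_N = model_N,
         location = location, partials_mode = partials_mode,
         seed = as.integer(seed)),
    class = "experiment_spec"
  )
}

#' True lnRR curves of a synthetic experiment
#'
#' Returns the generating per-treatment lnRR values for each tissue --
#' linear `slope * d` curves in parametric mode, or the fixed-damage
#' equilibrium lnRR of the growth game at `model_N` in model-linked mode.
#' Used for parameter-recovery assertions.
#'
#' @param spec An [experiment_spec()].
#' @return A tibble with columns `d`, `lnRR_fruit`, `lnRR_shoot`,
#'   `lnRR_root`.
#' @examples
#' truth_report(experiment_spec(effects = list(fruit = -0.5, shoot = -1,
#'                                             root = -0.3)))
#' @export
truth_report <- function(spec) {
  d <- spec$d_levels
  if (is.list(spec$effects)) {
    return(tibble::tibble(
      d = d,
      lnRR_fruit = spec$effects$fruit * d,
      lnRR_shoot = spec$effects$shoot * d,
      lnRR_root = spec$effects$root * d
    ))
  }
  env <- game_env(N = spec$model_N)
  plant <- plant_params()
  un <- solve_undamaged(env, plant, spec$partials_mode)
  if (!un$converged) stop("undamaged equilibrium failed at model_N")
  warm <- c(un$u_r, un$u_s)
  purrr::map(d, function(dd) {
    if (dd == 0) {
      return(tibble::tibble(d = 0, lnRR_fruit = 0, lnRR_shoot = 0,
                            lnRR_root = 0))
    }
    eq <- solve_fixed_damage(env, plant, dd, spec$location,
                             spec$partials_mode, warm_start = warm)
    if (!eq$converged) stop("fixed-damage equilibrium failed at d = ", dd)
    tibble::tibble(d = dd,
                   lnRR_fruit = ln_rr(eq$G, un$G),
                   lnRR_shoot = ln_rr(eq$u_s, un$u_s),
                   lnRR_root = ln_rr(eq$u_r, un$u_r))
  }) |> purrr::list_rbind()
}

#' Generate a synthetic clipping experiment
#'
#' Draws one multiplicative block intercept per block and one log-normal
#' residual per plant and tissue around `baseline * exp(true lnRR(d))`.
#' The true curves are attached as attribute `"truth"` (also available via
#' [truth_report()]). Identical spec and seed give identical output.
#'
#' @param spec An [experiment_spec()].
#' @param seed Optional override of `spec$seed`.
#' @return A tibble of experiment records with columns `block`, `d`,
#'   `spike_g`, `shoot_standing_g`, `clippings_g`, `root_g`, ready for
#'   [block_ln_rr()].
#' @examples
#' rec <- generate_experiment(experiment_spec(n_blocks = 4))
#' head(rec)
#' @export
generate_experiment <- function(spec, seed = spec$seed) {
  truth <- truth_report(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n_b <- spec$n_blocks
  blocks <- sprintf("B%02d", seq_len(n_b))
  block_int <- stats::rnorm(n_b, 0, spec$block_sd)
  rows <- tidyr::expand_grid(block_i = seq_len(n_b), d = spec$d_levels) |>
    dplyr::left_join(truth, by = "d")
  n <- nrow(rows)
  eps_fruit <- stats::rnorm(n, 0, spec$residual_cv[["fruit"]])
  eps_shoot <- stats::rnorm(n, 0, spec$residual_cv[["shoot"]])
  eps_root <- stats::rnorm(n, 0, spec$residual_cv[["root"]])
  out <- rows |>
    dplyr::mutate(
      block = blocks[.data$block_i],
      spike_g = spec$baseline[["spike"]] *
        exp(.data$lnRR_fruit + block_int[.data$block_i] + eps_fruit),
      total_shoot = spec$baseline[["shoot"]] *
        exp(.data$lnRR_shoot + block_int[.data$block_i] + eps_shoot),
      clippings_g = .data$d * .data$total_shoot,
      shoot_standing_g = .data$total_shoot - .data$clippings_g,
      root_g = spec$baseline[["root"]] *
        exp(.data$lnRR_root + block_int[.data$block_i] + eps_root)
    ) |>
    dplyr::select("block", "d", "spike_g", "shoot_standing_g",
                  "clippings_g", "root_g")
  if (any(out$clippings_g > out$shoot_standing_g + out$clippings_g)) {
    stop("clipping accounting produced clippings exceeding total shoot")
  }
  attr(out, "truth") <- truth
  out
}
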