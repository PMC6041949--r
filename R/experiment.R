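# Analysis of randomized complete block clipping experiments: block-paired
# log response ratios, the ln(1 - d) expected floor, observed-vs-expected
# trend fits, and per-treatment compensation tests.
#
# The experimental design pairs every clipping treatment with the unclipped
# control of its own block, so lnRR already removes the block intercept of
# the control plant. Trend models use a fixed block intercept (equivalent
# to block-demeaning); in this balanced design the treatment-effect
# estimates coincide with those of a block random-intercept model, and the
# shared-control noise in lnRR is exactly a block-level term the intercepts
# absorb.

#' Read clipping-experiment records from a delimited file
#'
#' Expects a header with columns `block`, `d`, `spike_g`,
#' `shoot_standing_g`, `clippings_g`, `root_g`. Comma and tab dialects are
#' auto-detected. Damage may be recorded as a fraction (0.15) or as a
#' percentage (15) -- set `percent = TRUE` for the latter.
#'
#' @param path File path.
#' @param percent If `TRUE`, `d` values are divided by 100 on read.
#' @return A tibble of experiment records.
#' @export
read_experiment <- function(path, percent = FALSE) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  required <- c("block", "d", "spike_g", "shoot_standing_g", "clippings_g",
                "root_g")
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  if (percent) dat$d <- dat$d / 100
  if (any(dat$d < 0 | dat$d >= 1)) {
    stop("d must lie in [0, 1); use percent = TRUE for percent-coded files")
  }
  dat
}

#' Block-paired log response ratios
#'
#' For every treatment plant, computes lnRR for fruit (spike mass), total
#' shoot (standing + clippings, so removed tissue counts as production) and
#' root mass against the unclipped control (`d = 0`) of the same block.
#' Control rows are retained with lnRR 0 (a plant compared with itself), so
#' trend fits see every treatment level. Blocks without a usable control,
#' and plants with non-positive masses, are dropped with a message.
#'
#' @param records A data frame of experiment records with columns `block`,
#'   `d`, `spike_g`, `shoot_standing_g`, `clippings_g`, `root_g` (see
#'   [read_experiment()]).
#' @return A tibble of class `lnrr_table` with columns `block`, `d`,
#'   `lnRR_fruit`, `lnRR_shoot`, `lnRR_root`, `expected_floor`.
#' @examples
#' rec <- generate_experiment(experiment_spec(n_blocks = 4))
#' block_ln_rr(rec)
#' @export
block_ln_rr <- function(records) {
  records <- tibble::as_tibble(records)
  records$total_shoot <- records$shoot_standing_g + records$clippings_g
  usable <- records$spike_g > 0 & records$total_shoot > 0 & records$root_g > 0
  n_bad <- sum(!usable)
  records <- records[usable, , drop = FALSE]
  controls <- dplyr::filter(records, .data$d == 0) |>
    dplyr::select("block", ctrl_spike = "spike_g", ctrl_shoot = "total_shoot",
                  ctrl_root = "root_g")
  if (anyDuplicated(controls$block)) {
    stop("a block has more than one d = 0 control")
  }
  out <- dplyr::inner_join(records, controls, by = "block")
  n_bad <- n_bad + nrow(records) - nrow(out)
  if (nrow(out) == 0) stop("no blocks with a usable d = 0 control")
  if (n_bad > 0) {
    rlang::inform(paste0(n_bad, " record(s) dropped (missing control or ",
                         "non-positive mass)"))
  }
  out <- out |>
    dplyr::mutate(
      lnRR_fruit = ln_rr(.data$spike_g, .data$ctrl_spike),
      lnRR_shoot = ln_rr(.data$total_shoot, .data$ctrl_shoot),
      lnRR_root = ln_rr(.data$root_g, .data$ctrl_root),
      expected_floor = null_floor(.data$d)
    ) |>
    dplyr::select("block", "d", "lnRR_fruit", "lnRR_shoot", "lnRR_root",
                  "expected_floor") |>
    dplyr::arrange(.data$block, .data$d)
  class(out) <- c("lnrr_table", class(out))
  out
}

#' Expected lnRR floor per treatment level
#'
#' The lnRR a plant would show at each clipping fraction if it mounted no
#' compensatory response: `log(1 - d)`.
#'
#' @param d_levels Clipping fractions in `[0, 1)`.
#' @return A tibble with columns `d` and `expected_floor`.
#' @examples
#' expected_floor_series(c(0, 0.15, 0.30, 0.45, 0.60))
#' @export
expected_floor_series <- function(d_levels) {
  tibble::tibble(d = d_levels, expected_floor = null_floor(d_levels))
}

#' Fit a lnRR-versus-damage trend
#'
#' Treats the clipping fraction as a continuous covariate. For
#' `scope = "observed"` the chosen tissue's lnRR is regressed on `d` with a
#' fixed intercept per block (block-demeaning); with a balanced design this
#' reproduces the treatment slope of a block random-intercept model, and
#' correctly absorbs the control-plant noise shared within a block. For
#' `scope = "expected"` the response is the block-invariant floor
#' `log(1 - d)`, so the fit reduces to ordinary least squares on the
#' distinct treatment levels and is fully deterministic.
#'
#' @param table An `lnrr_table` from [block_ln_rr()], or for the expected
#'   scope any data frame with a `d` column.
#' @param scope `"observed"` or `"expected"`.
#' @param tissue Which lnRR to model in the observed scope: `"shoot"`
#'   (default, the directly clipped tissue), `"fruit"`, or `"root"`.
#' @return A `trend_fit` object; see [tidy.trend_fit()].
#' @examples
#' fit_trend(expected_floor_series(c(0, 0.15, 0.3, 0.45, 0.6)), "expected")
#' @export
fit_trend <- function(table, scope = c("observed", "expected"),
                      tissue = c("shoot", "fruit", "root")) {
  scope <- match.arg(scope)
  tissue <- match.arg(tissue)
  d_levels <- sort(unique(c(0, table$d)))
  if (length(d_levels) < 2) stop("need at least 2 distinct damage levels")
  if (scope == "expected") {
    dat <- tibble::tibble(d = d_levels, y = null_floor(d_levels))
    fit <- stats::lm(y ~ d, data = dat)
    co <- summary(fit)$coefficients
    est <- co[, "Estimate"]
    se <- co[, "Std. Error"]
  } else {
    response <- paste0("lnRR_", tissue)
    if (!response %in% names(table)) stop("table lacks column ", response)
    dat <- tibble::tibble(block = factor(table$block), d = table$d,
                          y = table[[response]])
    if (stats::var(dat$y) == 0) {
      # degenerate flat response: slope and intercept are exactly zero
      fit <- stats::lm(y ~ d, data = dat)
    } else {
      fit <- stats::lm(y ~ d + block, data = dat)
    }
    co <- summary(fit)$coefficients
    est <- co[c("(Intercept)", "d"), "Estimate"]
    se <- co[c("(Intercept)", "d"), "Std. Error"]
  }
  structure(
    list(slope = unname(est["d"]), intercept = unname(est["(Intercept)"]),
         slope_se = unname(se["d"]), intercept_se = unname(se["(Intercept)"]),
         scope = scope, tissue = if (scope == "observed") tissue else NA,
         d_levels = d_levels, fit = fit, n = nrow(dat),
         sigma = summary(fit)$sigma),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %s%s>\n", x$scope,
              if (!is.na(x$tissue)) paste0(", lnRR_", x$tissue) else ""))
  cat(sprintf("  slope = %.4f (SE %.4f)   intercept = %.4f (SE %.4f)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Compare observed and expected lnRR slopes
#'
#' Stacks the observed lnRR series with the expected `log(1 - d)` floor
#' (replicated across blocks so the two series share the design) and tests
#' the scope-by-damage interaction in a fixed-block linear model. The
#' interaction estimate is the slope difference
#' `slope(observed) - slope(expected)`; a positive difference (observed
#' slope shallower, i.e. closer to zero) is the compensatory-growth
#' signature. The Wald statistic `(estimate / SE)^2` is referred to a
#' 1-df chi-squared distribution.
#'
#' @param fit_obs An observed-scope [fit_trend()].
#' @param fit_exp An expected-scope [fit_trend()] on the same damage levels.
#' @param table The `lnrr_table` both fits were computed from.
#' @return A `slope_comparison` object with elements `slope_diff`, `se`,
#'   `statistic`, `p_value`, and the two slopes.
#' @examples
#' tab <- block_ln_rr(generate_experiment(experiment_spec(n_blocks = 6)))
#' compare_slopes(fit_trend(tab, "observed"), fit_trend(tab, "expected"), tab)
#' @export
compare_slopes <- function(fit_obs, fit_exp, table) {
  if (fit_obs$scope != "observed" || fit_exp$scope != "expected") {
    stop("expected one observed-scope and one expected-scope fit")
  }
  if (!isTRUE(all.equal(fit_obs$d_levels, fit_exp$d_levels))) {
    stop("the two fits use different damage levels")
  }
  response <- paste0("lnRR_", fit_obs$tissue)
  obs <- tibble::tibble(block = factor(table$block), d = table$d,
                        y = table[[response]], scope = "observed")
  exp_rows <- tidyr::expand_grid(block = unique(obs$block),
                                 d = fit_exp$d_levels) |>
    dplyr::mutate(y = null_floor(.data$d), scope = "expected")
  stacked <- dplyr::bind_rows(obs, exp_rows)
  stacked$scope <- stats::relevel(factor(stacked$scope), ref = "expected")
  fit <- stats::lm(y ~ d * scope + block, data = stacked)
  co <- summary(fit)$coefficients
  term <- "d:scopeobserved"
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  stat <- (est / se)^2
  structure(
    list(slope_diff = unname(est), se = unname(se),
         statistic = unname(stat),
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         slope_observed = fit_obs$slope, slope_expected = fit_exp$slope,
         tissue = fit_obs$tissue, fit = fit),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("<slope_comparison: lnRR_%s>\n", x$tissue))
  cat(sprintf("  observed slope %.4f vs expected %.4f; difference %.4f (SE %.4f)\n",
              x$slope_observed, x$slope_expected, x$slope_diff, x$se))
  cat(sprintf("  chi-squared(1) = %.2f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Per-treatment compensation test
#'
#' For each clipping level, tests whether the block-paired mean lnRR of the
#' chosen tissue differs from zero (one-sample t test on the within-block
#' ratios; the pairing against the block's own control is already inside
#' lnRR). P-values are adjusted for multiplicity across levels (Holm by
#' default). Verdicts: `"full compensation"` when zero is not rejected,
#' `"undercompensation"` when rejected with a negative mean,
#' `"overcompensation"` when rejected with a positive mean.
#'
#' @param table An `lnrr_table` from [block_ln_rr()].
#' @param tissue `"fruit"` (default; equal fitness is the tolerance
#'   criterion), `"shoot"`, or `"root"`.
#' @param alpha Significance level for the verdict.
#' @param adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @return A tibble with one row per positive treatment level: `d`,
#'   `n_blocks`, `mean_lnRR`, `se`, `statistic`, `df`, `p_value`, `p_adj`,
#'   `verdict`.
#' @examples
#' tab <- block_ln_rr(generate_experiment(experiment_spec()))
#' compensation_test(tab)
#' @export
compensation_test <- function(table, tissue = c("fruit", "shoot", "root"),
                              alpha = 0.05, adjust = "holm") {
  tissue <- match.arg(tissue)
  response <- paste0("lnRR_", tissue)
  dat <- dplyr::filter(table, .data$d > 0)
  levels_d <- sort(unique(dat$d))
  rows <- purrr::map(levels_d, function(dd) {
    y <- dat[[response]][dat$d == dd]
    if (length(y) < 2) {
      rlang::warn(paste0("treatment d = ", dd,
                         " has fewer than 2 blocks; skipped"))
      return(NULL)
    }
    if (stats::sd(y) == 0) {
      # degenerate exact data: mean identically equal to the tested value
      tt <- list(statistic = if (mean(y) == 0) 0 else Inf * sign(mean(y)),
                 parameter = length(y) - 1,
                 p.value = if (mean(y) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(y, mu = 0)
    }
    tibble::tibble(d = dd, n_blocks = length(y), mean_lnRR = mean(y),
                   se = stats::sd(y) / sqrt(length(y)),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  }) |> purrr::list_rbind()
  if (nrow(rows) == 0) stop("no treatment level has at least 2 blocks")
  rows$p_adj <- stats::p.adjust(rows$p_value, method = adjust)
  rows$verdict <- dplyr::case_when(
    rows$p_adj >= alpha ~ "full compensation",
    rows$mean_lnRR < 0 ~ "undercompensation",
    TRUE ~ "overcompensation"
  )
  rows
}
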