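make_records <- function(blocks, d_levels, spike, shoot, root) {
  # identical plants everywhere unless masses are functions of (block, d)
  tidyr::expand_grid(block = blocks, d = d_levels) |>
    dplyr::mutate(
      spike_g = spike, clippings_g = d * shoot,
      shoot_standing_g = shoot - .data$clippings_g, root_g = root
    )
}

test_that("block-paired lnRR is zero when treatments equal their control", {
  rec <- make_records(c("B1", "B2"), c(0, 0.15, 0.3), 2, 10, 5)
  tab <- block_ln_rr(rec)
  expect_true(all(tab$lnRR_fruit == 0))
  expect_true(all(tab$lnRR_shoot == 0))
  expect_true(all(tab$lnRR_root == 0))
  expect_equal(tab$expected_floor, log(1 - tab$d), tolerance = 1e-12)
})

test_that("lnRR uses total shoot production and the block's own control", {
  rec <- tibble::tibble(
    block = c("B1", "B1"), d = c(0, 0.3),
    spike_g = c(2, 1), shoot_standing_g = c(10, 5), clippings_g = c(0, 3),
    root_g = c(5, 4)
  )
  tab <- block_ln_rr(rec)
  row <- tab[tab$d == 0.3, ]
  expect_equal(row$lnRR_shoot, log(8 / 10), tolerance = 1e-12)
  expect_equal(row$lnRR_fruit, log(1 / 2), tolerance = 1e-12)
  expect_equal(row$lnRR_root, log(4 / 5), tolerance = 1e-12)
  # exponentiating recovers the raw mass ratio exactly
  expect_equal(exp(row$lnRR_root), 4 / 5, tolerance = 1e-15)
})

test_that("blocks without a usable control are dropped with a message", {
  rec <- dplyr::bind_rows(
    make_records("B1", c(0, 0.3), 2, 10, 5),
    make_records("B2", 0.3, 2, 10, 5)   # no control plant
  )
  expect_message(tab <- block_ln_rr(rec), "dropped")
  expect_identical(unique(tab$block), "B1")
  expect_error(block_ln_rr(make_records("B1", c(0.15, 0.3), 2, 10, 5)),
               "control")
})

test_that("expected floor series decreases over the treatment levels", {
  fs <- expected_floor_series(c(0, 0.15, 0.30, 0.45, 0.60))
  expect_identical(nrow(fs), 5L)
  expect_identical(fs$expected_floor[1], 0)
  expect_equal(fs$expected_floor[3], log(0.70), tolerance = 1e-12)
  expect_true(all(diff(fs$expected_floor) < 0))
})

test_that("the expected-scope trend matches closed-form least squares", {
  d <- c(0, 0.15, 0.30, 0.45, 0.60)
  fit <- fit_trend(expected_floor_series(d), "expected")
  # closed form on the five (d, log(1 - d)) pairs
  y <- log(1 - d)
  slope <- sum((d - mean(d)) * (y - mean(y))) / sum((d - mean(d))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(d), tolerance = 1e-12)
  expect_equal(fit$slope, -1.511933, tolerance = 1e-6)
  expect_equal(fit$intercept, 0.0469156, tolerance = 1e-5)
  # deterministic: block count and noise are irrelevant to this scope
  tab <- block_ln_rr(generate_experiment(experiment_spec(n_blocks = 4)))
  fit2 <- fit_trend(tab, "expected")
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
})

test_that("an identically zero response fits a zero trend", {
  rec <- make_records(c("B1", "B2", "B3"), c(0, 0.15, 0.3), 2, 10, 5)
  tab <- block_ln_rr(rec)
  fit <- fit_trend(tab, "observed", tissue = "root")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
})

test_that("observed trend recovers a known generating slope", {
  spec <- experiment_spec(
    effects = list(fruit = -0.5, shoot = -1.0, root = -0.3), seed = 7
  )
  tab <- block_ln_rr(generate_experiment(spec))
  fit <- fit_trend(tab, "observed", tissue = "shoot")
  ci <- fit$slope + c(-1, 1) * stats::qt(0.975, stats::df.residual(fit$fit)) *
    fit$slope_se
  expect_gte(-1.0, ci[1])
  expect_lte(-1.0, ci[2])
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "d"))
})

test_that("slope comparison detects shallower-than-floor observed trends", {
  spec <- experiment_spec(
    effects = list(fruit = -0.5, shoot = -1.0, root = -0.3), seed = 11
  )
  tab <- block_ln_rr(generate_experiment(spec))
  f_obs <- fit_trend(tab, "observed", tissue = "shoot")
  f_exp <- fit_trend(tab, "expected")
  cmp <- compare_slopes(f_obs, f_exp, tab)
  # truth: -1.0 observed vs -1.5119 floor, difference about +0.512
  expect_equal(cmp$slope_diff, 0.512, tolerance = 0.35)
  expect_gt(cmp$slope_diff, 0)
  expect_lt(cmp$p_value, 0.01)
})

test_that("identical observed and expected series give a null comparison", {
  blocks <- c("B1", "B2", "B3")
  d_levels <- c(0, 0.15, 0.30, 0.45, 0.60)
  rec <- tidyr::expand_grid(block = blocks, d = d_levels) |>
    dplyr::mutate(
      spike_g = 2, shoot_standing_g = 10 * (1 - d) * (1 - d),
      clippings_g = 10 * (1 - d) * d, root_g = 5
    )
  # total shoot = 10 * (1 - d), so observed lnRR is exactly the floor
  tab <- block_ln_rr(rec)
  expect_equal(tab$lnRR_shoot, tab$expected_floor, tolerance = 1e-12)
  cmp <- compare_slopes(fit_trend(tab, "observed"), fit_trend(tab, "expected"),
                        tab)
  expect_equal(cmp$slope_diff, 0, tolerance = 1e-10)
  expect_gt(cmp$p_value, 0.99)
})

test_that("mismatched damage levels are rejected in slope comparison", {
  tab1 <- block_ln_rr(make_records(c("B1", "B2"), c(0, 0.15, 0.3), 2, 10, 5))
  tab2 <- block_ln_rr(make_records(c("B1", "B2"), c(0, 0.2, 0.4), 2, 10, 5))
  expect_error(
    compare_slopes(fit_trend(tab1, "observed"), fit_trend(tab2, "expected"),
                   tab1),
    "different damage levels"
  )
})

test_that("compensation verdicts follow the paired test against zero", {
  # exact zeros: full compensation at every level
  rec <- make_records(paste0("B", 1:4), c(0, 0.15, 0.3), 2, 10, 5)
  ct <- compensation_test(block_ln_rr(rec))
  expect_true(all(ct$verdict == "full compensation"))
  expect_true(all(ct$p_value == 1))

  # strong deficit with tiny variance: rejected at any sensible level
  set.seed(3)
  rec2 <- tidyr::expand_grid(block = paste0("B", 1:6), d = c(0, 0.3)) |>
    dplyr::mutate(
      spike_g = ifelse(d == 0, 2,
                       2 * exp(-1 + stats::rnorm(dplyr::n(), 0, 1e-4))),
      shoot_standing_g = 10 * (1 - d), clippings_g = 10 * d, root_g = 5
    )
  ct2 <- compensation_test(block_ln_rr(rec2))
  expect_identical(ct2$verdict, "undercompensation")
  expect_lt(ct2$p_adj, 1e-6)
})

test_that("single-block treatments are skipped with a warning", {
  rec <- dplyr::bind_rows(
    make_records(c("B1", "B2"), c(0, 0.15), 2, 10, 5),
    make_records("B1", 0.3, 2, 10, 5)
  )
  expect_warning(ct <- compensation_test(block_ln_rr(rec)), "skipped")
  expect_identical(ct$d, 0.15)
})

test_that("lnRR tables plot without error", {
  tab <- block_ln_rr(generate_experiment(experiment_spec(n_blocks = 5)))
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
})
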