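test_that("log response ratio has the standard sign conventions", {
  expect_identical(ln_rr(10, 10), 0)
  expect_equal(ln_rr(5, 10), log(0.5), tolerance = 1e-12)
  expect_gt(ln_rr(11, 10), 0)
  expect_error(ln_rr(0, 10), "positive")
  expect_error(ln_rr(10, -1), "positive")
})

test_that("damage fraction converts foraging time through the encounter rate", {
  herb <- herbivore_params(a = 0.7, c_h = 1)
  expect_identical(damage_fraction(0, herb), 0)
  expect_equal(damage_fraction(1, herb), 1 - exp(-0.7), tolerance = 1e-12)
  # substituting the interior best response gives 1 - c_h / (a * u_i)
  u_h <- herbivore_best_response(10, herb)
  expect_equal(damage_fraction(u_h, herb), 1 - 1 / 7, tolerance = 1e-12)
  eq <- solve_undamaged(game_env(N = 50), plant_params())
  expect_identical(damage_fraction(eq, herb), 0)
})

test_that("the no-compensation floor is log(1 - D)", {
  expect_identical(null_floor(0), 0)
  expect_equal(null_floor(0.15), log(0.85), tolerance = 1e-12)
  expect_equal(null_floor(0.60), log(0.40), tolerance = 1e-12)
  expect_error(null_floor(1), "\\[0, 1\\)")
})

test_that("fixed sweep pairs every damaged cell with its own-N baseline", {
  sw <- sweep_fixed(env_grid = c(20, 60), damage_grid = c(0, 0.3, 0.6),
                    location = "shoot")
  expect_s3_class(sw, "herbgame_sweep")
  expect_identical(nrow(sw), 6L)
  expect_true(all(sw$converged))

  # lnRR recomputed from the table's own strategy columns matches exactly
  for (nn in unique(sw$N)) {
    base <- sw[sw$N == nn & sw$D == 0, ]
    for (dd in c(0.3, 0.6)) {
      row <- sw[sw$N == nn & sw$D == dd, ]
      expect_equal(row$lnRR_shoot, log(row$u_s / base$u_s), tolerance = 1e-12)
      expect_equal(row$lnRR_root, log(row$u_r / base$u_r), tolerance = 1e-12)
      expect_equal(row$lnRR_fruit, log(row$G / base$G), tolerance = 1e-12)
      expect_equal(row$null_floor, log(1 - dd), tolerance = 1e-12)
    }
  }

  # zero-damage rows are perfect-compensation references
  expect_true(all(sw$lnRR_shoot[sw$D == 0] == 0))
})

test_that("fixed-sweep compensation lies between floor and perfection", {
  sw <- sweep_fixed(env_grid = seq(5, 100, length.out = 5),
                    damage_grid = c(0, 0.25, 0.5, 0.75),
                    location = "shoot")
  damaged <- sw[sw$D > 0 & sw$converged, ]
  expect_true(all(damaged$lnRR_shoot >= damaged$null_floor))
  expect_true(all(damaged$lnRR_shoot <= 0))
  expect_true(all(damaged$lnRR_fruit <= 0))
  # fitness declines with damage at every N
  for (nn in unique(sw$N)) {
    g <- sw$G[sw$N == nn][order(sw$D[sw$N == nn])]
    expect_true(all(diff(g) <= 1e-9))
  }
  # tolerance improves with nitrogen at fixed damage
  for (dd in c(0.25, 0.5, 0.75)) {
    f <- abs(damaged$lnRR_fruit[damaged$D == dd])
    expect_true(all(diff(f) <= 1e-9))
  }
})

test_that("cross-tissue responses to damage are an order smaller than own", {
  # the undamaged tissue adjusts only through the shared payoff trade-off:
  # shoots contract slightly under root damage, while roots drift by less
  # than a percent (slightly upward) under shoot damage
  sw_s <- sweep_fixed(env_grid = c(10, 50, 90), damage_grid = c(0, 0.5),
                      location = "shoot")
  dmg_s <- sw_s[sw_s$D > 0, ]
  expect_true(all(abs(dmg_s$lnRR_root) < 0.01))
  expect_true(all(abs(dmg_s$lnRR_root) < abs(dmg_s$lnRR_shoot)))
  sw_r <- sweep_fixed(env_grid = c(10, 50, 90), damage_grid = c(0, 0.5),
                      location = "root")
  dmg_r <- sw_r[sw_r$D > 0, ]
  expect_true(all(dmg_r$lnRR_shoot <= 1e-6))
  expect_true(all(abs(dmg_r$lnRR_shoot) < abs(dmg_r$lnRR_root)))
})

test_that("dynamic sweep pairs equilibria and reports mean damage", {
  sw <- sweep_dynamic(env_grid = c(30, 70),
                      herb = herbivore_params(location = "shoot"))
  expect_identical(nrow(sw), 4L)
  dyn <- sw[sw$damage_mode == "dynamic", ]
  base <- sw[sw$damage_mode == "none", ]
  expect_true(all(dyn$converged))
  expect_equal(dyn$lnRR_shoot, log(dyn$u_s / base$u_s), tolerance = 1e-12)
  expect_true(all(dyn$lnRR_fruit <= 0))
  expect_equal(attr(sw, "mean_D"), mean(dyn$D), tolerance = 1e-12)
  gl <- glance(sw)
  expect_identical(gl$sweep_type, "dynamic")
  expect_equal(gl$mean_D, attr(sw, "mean_D"))
})

test_that("a prohibitively costly herbivore leaves the baseline untouched", {
  sw <- sweep_dynamic(env_grid = c(30, 70),
                      herb = herbivore_params(c_h = 1e6, location = "shoot"))
  dyn <- sw[sw$damage_mode == "dynamic", ]
  expect_true(all(dyn$D == 0))
  expect_true(all(abs(dyn$lnRR_shoot) < 1e-8))
})

test_that("sweep plots assemble without error", {
  sw <- sweep_fixed(env_grid = c(20, 80), damage_grid = c(0, 0.3, 0.6))
  p <- ggplot2::autoplot(sw)
  expect_s3_class(p, "ggplot")
  swd <- sweep_dynamic(env_grid = c(30, 70))
  expect_s3_class(ggplot2::autoplot(swd), "ggplot")
})
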