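test_that("herbivore best response is the closed form with a zero clamp", {
  herb <- herbivore_params(a = 0.7, c_h = 1)
  # boundary: a * u_i = c_h makes the log vanish
  expect_equal(herbivore_best_response(1 / 0.7, herb), 0, tolerance = 1e-12)
  expect_identical(herbivore_best_response(0.5, herb), 0)
  expect_identical(herbivore_best_response(0, herb), 0)
  expect_equal(herbivore_best_response(10, herb), log(7) / 0.7,
               tolerance = 1e-12)
})

test_that("closed-form foraging time maximizes the herbivore payoff", {
  herb <- herbivore_params(a = 0.7, c_h = 1)
  u_star <- herbivore_best_response(10, herb)
  grid <- seq(0, 10, length.out = 20001)
  best_grid <- grid[which.max(herbivore_fitness(grid, 10, herb))]
  expect_equal(u_star, best_grid, tolerance = 1e-3)
  # interior marginal condition zeroed essentially exactly
  expect_lt(abs(0.7 * 10 * exp(-0.7 * u_star) - 1), 1e-12)
})

test_that("plant best response finds the grid-oracle optimum", {
  env <- game_env(C = 5000, N = 50)
  plant <- plant_params()
  eq <- plant_best_response(env, plant)
  expect_true(eq$converged)
  expect_true(eq$soc_ok)
  expect_lt(eq$residual, 1e-8)
  ora <- grid_oracle(env, plant, n_grid = 300)
  expect_equal(eq$G, ora$G, tolerance = 1e-6)
  expect_equal(eq$u_r, ora$u_r, tolerance = 1e-2)
  expect_equal(eq$u_s, ora$u_s, tolerance = 1e-2)
  # the solver is never dominated by a coarse grid
  expect_lte(ora$G, eq$G * (1 + 1e-9))
})

test_that("solver matches the oracle across random instances", {
  set.seed(202)
  n_checked <- 0
  while (n_checked < 5) {
    inst <- draw_instance()
    eq <- plant_best_response(inst$env, inst$plant, inst$phi, inst$location)
    if (!eq$converged) next
    ora <- grid_oracle(inst$env, inst$plant, inst$phi, inst$location,
                       n_grid = 200)
    expect_equal(eq$G, ora$G, tolerance = 1e-3)
    n_checked <- n_checked + 1
  }
})

test_that("undamaged wrapper equals a zero-damage best response", {
  env <- game_env(C = 5000, N = 30)
  plant <- plant_params()
  a <- solve_undamaged(env, plant)
  b <- plant_best_response(env, plant, phi = 0, location = "none")
  expect_identical(a$u_r, b$u_r)
  expect_identical(a$u_s, b$u_s)
  expect_identical(a$u_h, 0)
  expect_identical(a$D, 0)
})

test_that("fitness improves with nitrogen at the optimum", {
  plant <- plant_params()
  g5 <- solve_undamaged(game_env(N = 5), plant)$G
  g100 <- solve_undamaged(game_env(N = 100), plant)$G
  expect_true(g5 > 0)
  expect_gt(g100, g5)
})

test_that("zero fixed damage reduces to the undamaged equilibrium", {
  env <- game_env(C = 5000, N = 40)
  plant <- plant_params()
  un <- solve_undamaged(env, plant)
  fx <- solve_fixed_damage(env, plant, D = 0, location = "shoot")
  expect_equal(fx$u_r, un$u_r, tolerance = 1e-10)
  expect_equal(fx$u_s, un$u_s, tolerance = 1e-10)
  expect_equal(fx$u_h, 0)
})

test_that("fixed shoot damage elicits partial compensation", {
  env <- game_env(C = 5000, N = 50)
  plant <- plant_params()
  un <- solve_undamaged(env, plant)
  fx <- solve_fixed_damage(env, plant, D = 0.5, location = "shoot")
  lnrr <- ln_rr(fx$u_s, un$u_s)
  # between the no-response floor and perfect compensation
  expect_gte(lnrr, log(1 - 0.5))
  expect_lt(lnrr, 0)
  # implied foraging time reported
  expect_equal(fx$u_h, -log(0.5) / 0.7, tolerance = 1e-12)
})

test_that("extreme shoot damage shrinks the shoot strategy", {
  env <- game_env(C = 5000, N = 50)
  plant <- plant_params()
  un <- solve_undamaged(env, plant)
  hi <- solve_fixed_damage(env, plant, D = 0.99, location = "shoot")
  expect_true(hi$converged)
  expect_lt(ln_rr(hi$u_s, un$u_s), 0)
})

test_that("dynamic game clamps to undamaged when foraging cannot pay", {
  env <- game_env(C = 5000, N = 50)
  plant <- plant_params()
  herb <- herbivore_params(a = 0.7, c_h = 1e6, location = "shoot")
  dyn <- solve_dynamic(env, plant, herb)
  un <- solve_undamaged(env, plant)
  expect_equal(dyn$u_h, 0)
  expect_equal(dyn$D, 0, tolerance = 1e-12)
  expect_equal(dyn$u_s, un$u_s, tolerance = 1e-8)
})

test_that("dynamic equilibrium is a mutual best response", {
  env <- game_env(C = 5000, N = 50)
  plant <- plant_params()
  herb <- herbivore_params(location = "shoot")
  dyn <- solve_dynamic(env, plant, herb)
  expect_true(dyn$converged)

  # herbivore cannot gain by deviating on a dense grid
  payoff_h <- herbivore_fitness(seq(0, 20, length.out = 4001), dyn$u_s, herb)
  expect_lte(max(payoff_h),
             herbivore_fitness(dyn$u_h, dyn$u_s, herb) + 1e-6)

  # plant cannot gain by deviating locally around the equilibrium
  mult <- exp(seq(-0.5, 0.5, length.out = 81))
  g_dev <- outer(dyn$u_r * mult, dyn$u_s * mult, function(r, s) {
    plant_fitness(r, s, env, plant, dyn$phi, "shoot")
  })
  expect_lte(max(g_dev), dyn$G * (1 + 1e-8))

  # interior consistency identity D = 1 - c_h / (a * u_i)
  expect_equal(dyn$D, 1 - herb$c_h / (herb$a * dyn$u_s), tolerance = 1e-6)
})

test_that("starvation yields a flagged non-converged result, not an error", {
  eq <- plant_best_response(game_env(C = 5000, N = 1e-3), plant_params())
  expect_false(eq$converged)
  expect_true(is.na(eq$u_r))
  expect_identical(eq$G, 0)
})

test_that("equilibrium tidiers expose strategies and diagnostics", {
  eq <- solve_undamaged(game_env(N = 50), plant_params())
  td <- tidy(eq)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_true(all(c("u_r", "u_s", "G", "converged") %in% names(td)))
  gl <- glance(eq)
  expect_true(gl$converged)
  expect_true(gl$soc_ok)
})
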