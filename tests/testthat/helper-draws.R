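# random but reproducible game instances for property-style tests

draw_instance <- function() {
  plant <- plant_params(
    alpha = runif(1, 0.85, 0.97),
    Vc = runif(1, 0.5, 2), Vn = runif(1, 0.5, 2),
    c_cs = 3 * runif(1, 0.5, 2), c_cr = 1.2 * runif(1, 0.5, 2),
    c_ns = 0.03 * runif(1, 0.5, 2), c_nr = 0.01 * runif(1, 0.5, 2),
    E = runif(1, 0.05, 0.5)
  )
  env <- game_env(C = runif(1, 1000, 10000), N = runif(1, 5, 100))
  location <- sample(c("shoot", "root", "none"), 1)
  phi <- if (location == "none") 0 else runif(1, 0, 0.8)
  list(plant = plant, env = env, phi = phi, location = location)
}

# a live evaluation point for the instance (positive net harvests), found
# by shrinking toward a conservative interior point; NULL if none found
draw_live_point <- function(inst) {
  seed_r <- log(max(inst$plant$Vn * inst$env$N / inst$plant$c_nr, 1.1)) /
    inst$plant$Vn
  seed_s <- log(max(inst$plant$Vc * inst$env$C / inst$plant$c_cs, 1.1)) /
    inst$plant$Vc
  u <- c(seed_r, seed_s) * runif(2, 0.6, 1.2)
  for (k in 1:30) {
    alive <- plant_fitness(u[1], u[2], inst$env, inst$plant, inst$phi,
                           inst$location, detail = TRUE)$alive
    if (alive) return(u)
    u <- u * 0.7
  }
  NULL
}
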