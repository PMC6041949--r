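# Fitness equations of the plant-herbivore foraging game.
#
# The plant's season-total payoff is G = E * pi_C^alpha * pi_N^beta, a
# Cobb-Douglas product of net carbon and net nitrogen harvest. Each net
# harvest is saturating gross uptake minus linear construction costs minus
# the resource content of tissue the herbivore consumes. Consumption enters
# every plant equation only through the consumed fraction
# phi = 1 - exp(-a * u_h), so phi is the canonical damage variable here;
# herbivore time u_h and reported damage D are convertible views of it.

.attacked_mass <- function(u_r, u_s, location) {
  switch(location, shoot = u_s, root = u_r, none = 0 * u_s)
}

.check_strategy <- function(u_r, u_s, phi) {
  if (any(u_r < 0) || any(u_s < 0)) {
    stop("root and shoot production must be non-negative")
  }
  if (any(phi < 0) || any(phi >= 1)) {
    stop("consumed fraction phi must lie in [0, 1)")
  }
}

#' Net seasonal carbon harvest of the plant
#'
#' Gross carbon uptake saturates in shoot mass, `C * (1 - exp(-Vc * u_s))`;
#' construction costs are linear in both tissues; and when the herbivore
#' attacks, the carbon content `alpha` of the consumed tissue mass
#' `u_i * phi` is deducted (`u_i` is the attacked tissue: shoot for a shoot
#' herbivore, root for a root herbivore). The result may be negative when
#' costs exceed harvest.
#'
#' @param u_r,u_s Root and shoot production (g); vectorized.
#' @param env A [game_env()].
#' @param plant A [plant_params()].
#' @param phi Consumed fraction of the attacked tissue, in `[0, 1)`.
#' @param location Attack location: `"shoot"`, `"root"`, or `"none"`.
#' @return Net carbon harvest (gC), same length as the inputs.
#' @examples
#' net_carbon(1, 1, game_env(N = 50), plant_params())
#' @export
net_carbon <- function(u_r, u_s, env, plant, phi = 0, location = "none") {
  .check_strategy(u_r, u_s, phi)
  env$C * (1 - exp(-plant$Vc * u_s)) - plant$c_cr * u_r - plant$c_cs * u_s -
    plant$alpha * .attacked_mass(u_r, u_s, location) * phi
}

#' Net seasonal nitrogen harvest of the plant
#'
#' Mirror of [net_carbon()]: gross uptake saturates in root mass,
#' `N * (1 - exp(-Vn * u_r))`, costs are linear, and the nitrogen content
#' `beta = 1 - alpha` of consumed tissue is deducted. Consumption removes
#' both C and N from the plant regardless of which tissue is attacked.
#'
#' @inheritParams net_carbon
#' @return Net nitrogen harvest (gN).
#' @examples
#' net_nitrogen(1, 1, game_env(N = 50), plant_params())
#' @export
net_nitrogen <- function(u_r, u_s, env, plant, phi = 0, location = "none") {
  .check_strategy(u_r, u_s, phi)
  env$N * (1 - exp(-plant$Vn * u_r)) - plant$c_nr * u_r - plant$c_ns * u_s -
    plant$beta * .attacked_mass(u_r, u_s, location) * phi
}

#' Plant reproductive output
#'
#' `G = E * pi_C^alpha * pi_N^beta` when both net harvests are positive.
#' A plant that cannot cover the construction cost of its own tissues in
#' either currency is treated as dead: the power-product is undefined for
#' non-positive harvests, so fitness is defined as 0 there. This keeps the
#' fitness surface total and lets solvers treat infeasible strategies as
#' simply worthless rather than erroring.
#'
#' @inheritParams net_carbon
#' @param detail If `TRUE`, return a tibble with `pi_C`, `pi_N`, `G`, and
#'   an `alive` flag instead of the bare fitness vector.
#' @return Fitness (numeric), or a tibble when `detail = TRUE`.
#' @examples
#' plant_fitness(5, 7, game_env(N = 50), plant_params())
#' plant_fitness(5, 7, game_env(N = 50), plant_params(), detail = TRUE)
#' @export
plant_fitness <- function(u_r, u_s, env, plant, phi = 0, location = "none",
                          detail = FALSE) {
  pc <- net_carbon(u_r, u_s, env, plant, phi, location)
  pn <- net_nitrogen(u_r, u_s, env, plant, phi, location)
  alive <- pc > 0 & pn > 0
  g <- ifelse(alive, plant$E * pc^plant$alpha * pn^plant$beta, 0)
  if (!detail) return(g)
  tibble::tibble(pi_C = pc, pi_N = pn, G = g, alive = alive)
}

#' Herbivore net harvest
#'
#' The herbivore consumes a saturating fraction of the attacked tissue and
#' pays a linear metabolic cost in foraging time:
#' `u_i * (1 - exp(-a * u_h)) - c_h * u_h`.
#'
#' @param u_h Foraging time (days); non-negative, vectorized.
#' @param u_i Mass of the attacked tissue (g).
#' @param herb A [herbivore_params()].
#' @return Herbivore payoff (g tissue equivalents).
#' @examples
#' herbivore_fitness(1, u_i = 10, herb = herbivore_params())
#' @export
herbivore_fitness <- function(u_h, u_i, herb) {
  if (any(u_h < 0)) stop("foraging time u_h must be non-negative")
  u_i * (1 - exp(-herb$a * u_h)) - herb$c_h * u_h
}

# The four partial derivatives of pi_C and pi_N needed for the plant's
# first-order conditions. partials_mode picks where the consumption term
# appears:
#   "derived": differentiate the net-harvest equations exactly as written,
#     so a shoot herbivore contributes -alpha*phi to dpi_C/du_s AND
#     -beta*phi to dpi_N/du_s (root attack symmetric on u_r).
#   "table2": the consumption term appears only in the partial of the
#     same-currency harvest with respect to the attacked tissue
#     (dpi_C/du_s for shoot attack, dpi_N/du_r for root attack).
plant_partials <- function(u_r, u_s, env, plant, phi = 0, location = "none",
                           partials_mode = c("derived", "table2")) {
  partials_mode <- match.arg(partials_mode)
  d <- list(
    dC_dur = rep(-plant$c_cr, length.out = max(length(u_r), length(u_s))),
    dC_dus = plant$Vc * env$C * exp(-plant$Vc * u_s) - plant$c_cs,
    dN_dur = plant$Vn * env$N * exp(-plant$Vn * u_r) - plant$c_nr,
    dN_dus = rep(-plant$c_ns, length.out = max(length(u_r), length(u_s)))
  )
  if (partials_mode == "derived") {
    if (location == "shoot") {
      d$dC_dus <- d$dC_dus - plant$alpha * phi
      d$dN_dus <- d$dN_dus - plant$beta * phi
    } else if (location == "root") {
      d$dC_dur <- d$dC_dur - plant$alpha * phi
      d$dN_dur <- d$dN_dur - plant$beta * phi
    }
  } else {
    if (location == "shoot") d$dC_dus <- d$dC_dus - plant$alpha * phi
    if (location == "root")  d$dN_dur <- d$dN_dur - plant$beta * phi
  }
  d
}

#' Gradient of plant fitness with respect to its strategy
#'
#' Chain-rule gradient of [plant_fitness()] on the live branch:
#' `dG/du = E * (alpha * pi_C^(alpha-1) * pi_N^beta * dpi_C/du +
#' pi_C^alpha * beta * pi_N^(beta-1) * dpi_N/du)` for `u` in
#' `{u_r, u_s}`. Zeroing both components is the plant's first-order
#' stationarity condition.
#'
#' @section Partials modes:
#' Two published forms of the harvest partials circulate for the damaged
#' plant. `"derived"` (default) differentiates the net-harvest equations
#' directly, so consumption of a tissue depresses the marginal value of
#' that tissue in *both* currencies. `"table2"` keeps the consumption term
#' only in the same-currency partial (C for shoots, N for roots). With
#' `phi = 0` the two modes coincide.
#'
#' @inheritParams net_carbon
#' @param partials_mode `"derived"` or `"table2"`; see Details.
#' @return A tibble with columns `dG_dur` and `dG_dus`.
#' @examples
#' plant_gradient(5, 7, game_env(N = 50), plant_params())
#' @export
plant_gradient <- function(u_r, u_s, env, plant, phi = 0, location = "none",
                           partials_mode = c("derived", "table2")) {
  partials_mode <- match.arg(partials_mode)
  pc <- net_carbon(u_r, u_s, env, plant, phi, location)
  pn <- net_nitrogen(u_r, u_s, env, plant, phi, location)
  if (any(pc <= 0) || any(pn <= 0)) {
    stop("gradient undefined at a dead-plant point (pi_C or pi_N <= 0)")
  }
  d <- plant_partials(u_r, u_s, env, plant, phi, location, partials_mode)
  al <- plant$alpha
  be <- plant$beta
  pref <- plant$E * pc^(al - 1) * pn^(be - 1)
  tibble::tibble(
    dG_dur = pref * (al * pn * d$dC_dur + be * pc * d$dN_dur),
    dG_dus = pref * (al * pn * d$dC_dus + be * pc * d$dN_dus)
  )
}
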