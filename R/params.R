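#' Plant physiological parameters
#'
#' Bundles the constants that define the plant's fitness surface: tissue
#' stoichiometry, resource encounter rates, construction costs, and the
#' conversion of net harvest into reproductive output. The nitrogen fraction
#' of tissue is always `1 - alpha`; it is not independently settable, so the
#' C:N stoichiometry stays consistent across every equation.
#'
#' Defaults are the standard parameterization used throughout the package's
#' worked analyses. Units are abstract "example units" (grams of tissue,
#' gC, gN); only ratios matter to the equilibria.
#'
#' @param alpha Fraction of seed/tissue mass that is carbon, in (0, 1).
#'   The nitrogen fraction `beta = 1 - alpha` is derived.
#' @param Vc Encounter rate between photosynthetic tissue and CO2
#'   (per unit shoot mass).
#' @param Vn Encounter rate between uptake tissue and inorganic nitrogen
#'   (per unit root mass).
#' @param c_cs,c_cr Carbon cost to construct and maintain one unit of shoot
#'   (`c_cs`) or root (`c_cr`) mass.
#' @param c_ns,c_nr Nitrogen cost per unit shoot (`c_ns`) or root (`c_nr`).
#' @param E Conversion factor from the weighted product of net C and N
#'   harvest to reproductive output.
#' @return An object of class `plant_params` (a named list with a derived
#'   `beta` element).
#' @examples
#' plant_params()
#' plant_params(alpha = 0.9, c_cs = 2.5)
#' @export
plant_params <- function(alpha = 0.95, Vc = 1, Vn = 1,
                         c_cs = 3, c_cr = 1.2, c_ns = 0.03, c_nr = 0.01,
                         E = 0.1) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
    Vc > 0, Vn > 0, c_cs > 0, c_cr > 0, c_ns > 0, c_nr > 0, E >= 0
  )
  structure(
    list(alpha = alpha, beta = 1 - alpha, Vc = Vc, Vn = Vn,
         c_cs = c_cs, c_cr = c_cr, c_ns = c_ns, c_nr = c_nr, E = E),
    class = "plant_params"
  )
}

#' Herbivore foraging parameters
#'
#' The herbivore's scalar strategy is time spent foraging; these constants
#' set how foraging time converts to consumption and what it costs.
#'
#' @param a Encounter rate between herbivore and plant tissue (per day);
#'   search efficiency. The consumed fraction of the attacked tissue after
#'   `u_h` time units is `1 - exp(-a * u_h)`.
#' @param c_h Plant-tissue mass required to fuel each unit of foraging time.
#' @param location Which tissue is attacked: `"shoot"`, `"root"`, or
#'   `"none"` (the herbivore-free game, foraging time identically zero).
#' @return An object of class `herbivore_params`.
#' @examples
#' herbivore_params(location = "shoot")
#' @export
herbivore_params <- function(a = 0.7, c_h = 1,
                             location = c("shoot", "root", "none")) {
  location <- match.arg(location)
  stopifnot(is.numeric(a), length(a) == 1, a > 0, c_h > 0)
  structure(list(a = a, c_h = c_h, location = location),
            class = "herbivore_params")
}

#' Seasonal resource environment
#'
#' Season totals of harvestable carbon and nitrogen. Carbon is typically
#' non-limiting at the default; nitrogen is the gradient of interest,
#' ranging over roughly 5-100 gN in the standard sweeps.
#'
#' @param C Maximum carbon available over the season (gC).
#' @param N Maximum nitrogen available over the season (gN).
#' @return An object of class `game_env`.
#' @examples
#' game_env(N = 50)
#' @export
game_env <- function(C = 5000, N = 50) {
  stopifnot(is.numeric(C), length(C) == 1, C > 0,
            is.numeric(N), length(N) == 1, N > 0)
  structure(list(C = C, N = N), class = "game_env")
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params>\n")
  cat(sprintf("  alpha = %g (beta = %g)   Vc = %g   Vn = %g\n",
              x$alpha, x$beta, x$Vc, x$Vn))
  cat(sprintf("  costs: c_cs = %g  c_cr = %g  c_ns = %g  c_nr = %g   E = %g\n",
              x$c_cs, x$c_cr, x$c_ns, x$c_nr, x$E))
  invisible(x)
}

#' @export
print.herbivore_params <- function(x, ...) {
  cat(sprintf("<herbivore_params> a = %g  c_h = %g  location = %s\n",
              x$a, x$c_h, x$location))
  invisible(x)
}

#' @export
print.game_env <- function(x, ...) {
  cat(sprintf("<game_env> C = %g gC  N = %g gN\n", x$C, x$N))
  invisible(x)
}

# flat key set used by the config file round-trip
.param_keys <- c("alpha", "Vc", "Vn", "c_cs", "c_cr", "c_ns", "c_nr", "E",
                 "a", "c_h", "C", "N")

#' Read and write game parameters as a flat YAML config
#'
#' The config file is a flat key-value YAML mapping with exactly the field
#' names of [plant_params()], [herbivore_params()] and [game_env()]
#' (`alpha, Vc, Vn, c_cs, c_cr, c_ns, c_nr, E, a, c_h, C, N`), plus an
#' optional `location`. Keys that are omitted take their defaults; unknown
#' keys are an error so typos cannot silently revert to defaults.
#'
#' @param path File to read from or write to.
#' @return `read_params()` returns a list with elements `plant`, `herb`,
#'   `env`; `write_params()` returns `path` invisibly.
#' @examples
#' cfg <- tempfile(fileext = ".yml")
#' write_params(cfg, plant = plant_params(), herb = herbivore_params(),
#'              env = game_env(N = 20))
#' read_params(cfg)$env$N
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c(.param_keys, "location"))
  if (length(unknown) > 0) {
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  }
  take <- function(fun, keys) {
    do.call(fun, raw[intersect(names(raw), keys)])
  }
  list(
    plant = take(plant_params,
                 c("alpha", "Vc", "Vn", "c_cs", "c_cr", "c_ns", "c_nr", "E")),
    herb  = take(herbivore_params, c("a", "c_h", "location")),
    env   = take(game_env, c("C", "N"))
  )
}

#' @rdname read_params
#' @param plant A [plant_params()] object.
#' @param herb A [herbivore_params()] object.
#' @param env A [game_env()] object.
#' @export
write_params <- function(path, plant = plant_params(),
                         herb = herbivore_params(), env = game_env()) {
  flat <- c(plant[setdiff(names(plant), "beta")],
            herb[c("a", "c_h", "location")],
            env[c("C", "N")])
  yaml::write_yaml(flat, path)
  invisible(path)
}
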