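#' Configuration for the individual-based evolution model
#'
#' Bundles the fixed environment (uptake efficiencies), the founding strategy,
#' and the reproduction settings of the individual-based model. Populations
#' of plants (carrying the `gamma` trait) and fungi (carrying `epsilon`) are
#' paired uniformly at random one-to-one each generation, run a full
#' lifecycle, and reproduce in proportion to fitness; individuals with no
#' growth cannot reproduce.
#'
#' @inheritParams simulate_lifecycle
#' @param population_size Individuals per species (>= 2).
#' @param mutation_sd Standard deviation of the Gaussian mutation applied to
#'   every offspring trait (trait scale).
#' @param generation_cap Maximum number of generations to simulate.
#' @param init_gamma,init_epsilon Founding strategy centre.
#' @param initial_spread Standard deviation of founding variation around the
#'   founding strategy; 0 founds monomorphic populations.
#' @param weight How reproductive weight is derived from a grown individual's
#'   final biomass: the biomass itself (`"biomass"`, default) or the biomass
#'   gained (`"gain"`).
#' @return Object of class `"evolution_config"`.
#' @export
evolution_config <- function(alpha, beta,
                             population_size = 200L,
                             mutation_sd = 0.02,
                             generation_cap = 2000L,
                             init_gamma = 0, init_epsilon = 0,
                             initial_spread = 0,
                             steps = 10L,
                             weight = c("biomass", "gain")) {
  check_uptake(alpha, beta)
  check_strategy(init_gamma, init_epsilon)
  population_size <- as.integer(population_size)
  generation_cap <- as.integer(generation_cap)
  if (is.na(population_size) || population_size < 2L)
    domain_error("population_size must be >= 2")
  if (is.na(generation_cap) || generation_cap < 1L)
    domain_error("generation_cap must be >= 1")
  check_scalar(mutation_sd, "mutation_sd")
  if (mutation_sd < 0) domain_error("mutation_sd must be >= 0")
  check_scalar(initial_spread, "initial_spread")
  if (initial_spread < 0) domain_error("initial_spread must be >= 0")
  structure(list(
    alpha = alpha, beta = beta,
    population_size = population_size,
    mutation_sd = mutation_sd,
    generation_cap = generation_cap,
    init_gamma = init_gamma, init_epsilon = init_epsilon,
    initial_spread = initial_spread,
    steps = as.integer(steps),
    weight = match.arg(weight)),
    class = "evolution_config")
}

#' Found the plant and fungus populations
#'
#' Draws `population_size` traits per species as the founding strategy plus
#' Gaussian variation of sd `initial_spread`, clipped to `[-1, 1]`. Uses the
#' current R random stream.
#'
#' @param config An [evolution_config()].
#' @return List with numeric vectors `plant` (gamma traits) and `fungus`
#'   (epsilon traits).
#' @export
init_populations <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  n <- config$population_size
  list(
    plant = pmin(1, pmax(-1, config$init_gamma +
                           rnorm(n, 0, config$initial_spread))),
    fungus = pmin(1, pmax(-1, config$init_epsilon +
                            rnorm(n, 0, config$initial_spread))))
}

#' Advance the individual-based model by one generation
#'
#' Pairs plants and fungi uniformly at random one-to-one, evaluates each
#' pair's lifecycle, assigns reproductive weights (final biomass, or biomass
#' gain under `weight = "gain"`, and zero for individuals that did not grow),
#' and samples the next generation with replacement proportional to weight,
#' mutating every offspring. A species whose weights are all zero is flagged
#' extinct and produces no offspring.
#'
#' @param plant,fungus Equal-length numeric trait vectors.
#' @inheritParams init_populations
#' @return List with `next_plant` / `next_fungus` (or `NULL` on extinction),
#'   the generation record fields (`mean_gamma`, `mean_epsilon`,
#'   `frac_plants_grew`, `frac_fungi_grew`) and extinction flags.
#' @export
step_generation <- function(plant, fungus, config) {
  stopifnot(inherits(config, "evolution_config"))
  if (length(plant) != length(fungus))
    stop("plant and fungus populations must have equal size")
  .step_generation_cpp(as.numeric(plant), as.numeric(fungus),
                       config$alpha, config$beta, config$steps,
                       config$mutation_sd, config$weight == "gain")
}

#' Run co-evolution of the resource exchange strategy
#'
#' Iterates [step_generation()] from a founding population until one or both
#' species go extinct (all individuals of a species experience no growth in a
#' generation) or the generation cap is reached. Per-generation population
#' mean strategies and growth fractions are recorded; the trajectory is fully
#' reproducible from `seed`.
#'
#' @inheritParams init_populations
#' @param seed Integer seed; `NULL` continues the current random stream.
#' @param engine `"cpp"` runs the whole generation loop compiled (the
#'   production path); `"r"` steps through [step_generation()] from R. The
#'   two consume the random stream identically and give bit-identical
#'   trajectories from the same seed.
#' @return Object of class `"evolution_trajectory"`: a `records` data frame
#'   (`generation` from 0, `mean_gamma`, `mean_epsilon`, `frac_plants_grew`,
#'   `frac_fungi_grew`), plus `outcome` (one of `reached_cap`,
#'   `plant_extinct`, `fungus_extinct`, `both_extinct`),
#'   `terminal_generation` (number of generations evaluated), `seed` and
#'   `config`.
#' @export
run_evolution <- function(config, seed = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "evolution_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  pops <- init_populations(config)
  cap <- config$generation_cap
  if (engine == "cpp") {
    res <- .run_evolution_cpp(pops$plant, pops$fungus, config$alpha,
                              config$beta, config$steps, config$mutation_sd,
                              config$weight == "gain", cap)
    g <- res$terminal
    rec <- res$records
    outcome <- c("reached_cap", "plant_extinct", "fungus_extinct",
                 "both_extinct")[res$outcome + 1L]
  } else {
    rec <- matrix(NA_real_, nrow = cap, ncol = 4L)
    outcome <- "reached_cap"
    g <- 0L
    while (g < cap) {
      st <- step_generation(pops$plant, pops$fungus, config)
      rec[g + 1L, ] <- c(st$mean_gamma, st$mean_epsilon,
                         st$frac_plants_grew, st$frac_fungi_grew)
      g <- g + 1L
      if (st$plant_extinct || st$fungus_extinct) {
        outcome <- if (st$plant_extinct && st$fungus_extinct) "both_extinct"
                   else if (st$plant_extinct) "plant_extinct"
                   else "fungus_extinct"
        break
      }
      if (g < cap) pops <- list(plant = st$next_plant, fungus = st$next_fungus)
    }
  }
  records <- data.frame(
    generation = seq_len(g) - 1L,
    mean_gamma = rec[seq_len(g), 1L],
    mean_epsilon = rec[seq_len(g), 2L],
    frac_plants_grew = rec[seq_len(g), 3L],
    frac_fungi_grew = rec[seq_len(g), 4L])
  structure(list(records = records, outcome = outcome,
                 terminal_generation = g, seed = seed, config = config),
            class = "evolution_trajectory")
}

#' @export
print.evolution_trajectory <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf(
    "Evolution trajectory: alpha=%g beta=%g, %d generations, outcome %s\n",
    x$config$alpha, x$config$beta, x$terminal_generation, x$outcome))
  cat(sprintf("  final mean strategy (%.4f, %.4f); grew: plants %.0f%%, fungi %.0f%%\n",
              last$mean_gamma, last$mean_epsilon,
              100 * last$frac_plants_grew, 100 * last$frac_fungi_grew))
  invisible(x)
}

#' Derive independent child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` child seeds so that
#' replicate `k` of a batch is reproducible on its own. The caller's random
#' stream is left untouched.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, all below 2^31.
#' @export
derive_seeds <- function(master, n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}
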