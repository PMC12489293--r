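#' One gather-exchange-grow step of the paired lifecycle
#'
#' Resolves a single timestep for a plant of biomass `x` paired with a fungus
#' of biomass `y`. Both organisms first gather: the plant acquires C equal to
#' its biomass and P equal to `alpha * x`; the fungus acquires P equal to its
#' biomass and C equal to `beta * y`. They then exchange simultaneously, one
#' transfer per resource: a non-negative `gamma` gives that share of the
#' plant's gathered C to the fungus, a negative `gamma` takes `|gamma| * x` of
#' C from the fungus, clamped to what the fungus gathered this step ("all the
#' available resource, but no more"); `epsilon` acts symmetrically on the
#' fungus's gathered P. Finally each organism grows by the smaller of its two
#' post-exchange pools (Liebig's law of the minimum).
#'
#' @param x,y Current plant and fungus biomass (both > 0).
#' @param alpha Plant P uptake efficiency, in `[0, 1]`.
#' @param beta Fungus C uptake efficiency, in `[0, 1]`.
#' @param gamma Share of plant C given to the fungus, in `[-1, 1]`;
#'   negative values take.
#' @param epsilon Share of fungus P given to the plant, in `[-1, 1]`;
#'   negative values take.
#' @return A list of class `"trade_step"`: post-exchange pools
#'   (`plant_c_pool`, `plant_p_pool`, `fungus_c_pool`, `fungus_p_pool`),
#'   signed transfers (`c_transfer` positive = plant to fungus, `p_transfer`
#'   positive = fungus to plant, both after clamping), and the Liebig growth
#'   increments (`plant_growth`, `fungus_growth`).
#' @examples
#' resolve_exchange(1, 1, alpha = 0.1, beta = 0.2, gamma = 0.3, epsilon = 0.4)
#' @export
resolve_exchange <- function(x, y, alpha, beta, gamma, epsilon) {
  check_scalar(x, "x"); check_scalar(y, "y")
  if (x <= 0 || y <= 0) domain_error("biomasses x and y must be positive")
  check_uptake(alpha, beta)
  check_strategy(gamma, epsilon)

  plant_c <- x
  plant_p <- alpha * x
  fungus_p <- y
  fungus_c <- beta * y
  c_transfer <- if (gamma >= 0) gamma * plant_c else
    -min(-gamma * x, fungus_c)
  p_transfer <- if (epsilon >= 0) epsilon * fungus_p else
    -min(-epsilon * y, plant_p)

  pools <- list(
    plant_c_pool = plant_c - c_transfer,
    plant_p_pool = plant_p + p_transfer,
    fungus_c_pool = fungus_c + c_transfer,
    fungus_p_pool = fungus_p - p_transfer,
    c_transfer = c_transfer,
    p_transfer = p_transfer)
  pools$plant_growth <- min(pools$plant_c_pool, pools$plant_p_pool)
  pools$fungus_growth <- min(pools$fungus_c_pool, pools$fungus_p_pool)
  structure(pools, class = "trade_step")
}

#' Simulate one plant-fungus pair over its lifecycle
#'
#' Iterates [resolve_exchange()] from founding biomasses of 1, adding each
#' growth increment to biomass. Resource pools are discarded between steps
#' (no storage); the final biomasses are the pair's fitness values.
#'
#' @inheritParams resolve_exchange
#' @param steps Number of timesteps in the lifecycle (default 10).
#' @return An object of class `"trade_lifecycle"` with biomass trajectories
#'   (`plant_biomass`, `fungus_biomass`; length `steps + 1`), per-step signed
#'   transfers (`c_transfers`, `p_transfers`), final fitnesses, net transfer
#'   totals (`total_c_to_fungus`, `total_p_to_plant`) plus given/taken
#'   magnitude splits, and `plant_grew`/`fungus_grew` flags (final biomass
#'   above 1 beyond float noise).
#' @examples
#' simulate_lifecycle(alpha = 0.1, beta = 0.3, gamma = 0, epsilon = 0)
#' @export
simulate_lifecycle <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  check_uptake(alpha, beta)
  check_strategy(gamma, epsilon)
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) domain_error("steps must be >= 1")

  X <- numeric(steps + 1L); Y <- numeric(steps + 1L)
  ct <- numeric(steps); pt <- numeric(steps)
  X[1L] <- 1; Y[1L] <- 1
  for (n in seq_len(steps)) {
    st <- resolve_exchange(X[n], Y[n], alpha, beta, gamma, epsilon)
    X[n + 1L] <- X[n] + st$plant_growth
    Y[n + 1L] <- Y[n] + st$fungus_growth
    ct[n] <- st$c_transfer
    pt[n] <- st$p_transfer
  }
  structure(list(
    plant_biomass = X,
    fungus_biomass = Y,
    c_transfers = ct,
    p_transfers = pt,
    plant_fitness = X[steps + 1L],
    fungus_fitness = Y[steps + 1L],
    total_c_to_fungus = sum(ct),
    total_p_to_plant = sum(pt),
    c_given = sum(ct[ct >= 0]), c_taken = -sum(ct[ct < 0]),
    p_given = sum(pt[pt >= 0]), p_taken = -sum(pt[pt < 0]),
    plant_grew = X[steps + 1L] > 1 + 1e-12,
    fungus_grew = Y[steps + 1L] > 1 + 1e-12,
    steps = steps,
    alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon),
    class = "trade_lifecycle")
}

#' @export
print.trade_lifecycle <- function(x, ...) {
  cat(sprintf(
    "Plant-fungus lifecycle: %d steps, alpha=%g beta=%g gamma=%g epsilon=%g\n",
    x$steps, x$alpha, x$beta, x$gamma, x$epsilon))
  cat(sprintf("  plant fitness  %0.6g (%s)\n", x$plant_fitness,
              if (x$plant_grew) "grew" else "no growth"))
  cat(sprintf("  fungus fitness %0.6g (%s)\n", x$fungus_fitness,
              if (x$fungus_grew) "grew" else "no growth"))
  cat(sprintf("  net C to fungus %0.6g, net P to plant %0.6g\n",
              x$total_c_to_fungus, x$total_p_to_plant))
  invisible(x)
}

#' Closed-form lifecycle fitness where one exists
#'
#' Two parameter families admit an exact geometric-growth solution: with no
#' exchange (`gamma = epsilon = 0`) fitnesses are `(1 + alpha)^steps` and
#' `(1 + beta)^steps`; with no nonspecialised uptake and a symmetric giving
#' strategy (`alpha = beta = 0`, `gamma = epsilon = g >= 0`) both fitnesses
#' are `(1 + min(g, 1 - g))^steps`. Used as an analytic oracle for the
#' simulation.
#'
#' @inheritParams simulate_lifecycle
#' @return A named numeric vector `c(plant, fungus)`, or `NULL` when no
#'   closed form applies.
#' @export
closed_form_fitness <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  check_uptake(alpha, beta)
  check_strategy(gamma, epsilon)
  if (gamma == 0 && epsilon == 0)
    return(c(plant = (1 + alpha)^steps, fungus = (1 + beta)^steps))
  if (alpha == 0 && beta == 0 && gamma == epsilon && gamma >= 0) {
    m <- min(gamma, 1 - gamma)
    return(c(plant = (1 + m)^steps, fungus = (1 + m)^steps))
  }
  NULL
}

#' Vectorised lifecycle evaluation
#'
#' Runs the compiled lifecycle for each `(gamma[i], epsilon[i])` strategy at a
#' fixed uptake combination. This is the production path behind landscapes and
#' the individual-based model.
#'
#' @inheritParams simulate_lifecycle
#' @param gamma,epsilon Equal-length numeric vectors of strategies.
#' @return A data frame with one row per strategy: `plant_fitness`,
#'   `fungus_fitness`, net transfer totals, given/taken splits, and grew
#'   flags.
#' @export
lifecycle_batch <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  check_uptake(alpha, beta)
  if (length(gamma) != length(epsilon))
    domain_error("gamma and epsilon must have equal length")
  if (any(!is.finite(gamma)) || any(!is.finite(epsilon)) ||
      any(abs(gamma) > 1) || any(abs(epsilon) > 1))
    domain_error("all strategies must be finite and lie in [-1, 1]")
  out <- .lifecycle_batch_cpp(alpha, beta, as.numeric(gamma),
                              as.numeric(epsilon), as.integer(steps))
  as.data.frame(out)
}

#' Reference ledger lifecycle (verification bookkeeping)
#'
#' A deliberately simple scalar implementation of the lifecycle that walks
#' through every gather / give / take / clamp / grow step with explicit
#' bookkeeping. It shares no code with [simulate_lifecycle()] or the compiled
#' batch path and exists so results can be cross-checked against an
#' independent route; it is also what [generate_fixtures()] uses to compute
#' expected values.
#'
#' @inheritParams simulate_lifecycle
#' @return A list with `plant_fitness`, `fungus_fitness`, `total_c_to_fungus`,
#'   `total_p_to_plant`, `plant_grew`, `fungus_grew`.
#' @export
ledger_lifecycle <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  x <- 1; y <- 1
  c_total <- 0; p_total <- 0
  for (n in seq_len(steps)) {
    # gather
    plant_has_c <- x
    plant_has_p <- alpha * x
    fungus_has_p <- y
    fungus_has_c <- beta * y
    # plant side of the C exchange
    if (gamma >= 0) {
      moved_c <- gamma * plant_has_c
      plant_has_c <- plant_has_c - moved_c
      fungus_has_c <- fungus_has_c + moved_c
    } else {
      want <- -gamma * x
      moved_c <- -(if (want <= fungus_has_c) want else fungus_has_c)
      fungus_has_c <- fungus_has_c + moved_c
      plant_has_c <- plant_has_c - moved_c
    }
    # fungus side of the P exchange
    if (epsilon >= 0) {
      moved_p <- epsilon * fungus_has_p
      fungus_has_p <- fungus_has_p - moved_p
      plant_has_p <- plant_has_p + moved_p
    } else {
      want <- -epsilon * y
      moved_p <- -(if (want <= plant_has_p) want else plant_has_p)
      plant_has_p <- plant_has_p + moved_p
      fungus_has_p <- fungus_has_p - moved_p
    }
    # grow by the limiting resource
    x <- x + (if (plant_has_c < plant_has_p) plant_has_c else plant_has_p)
    y <- y + (if (fungus_has_c < fungus_has_p) fungus_has_c else fungus_has_p)
    c_total <- c_total + moved_c
    p_total <- p_total + moved_p
  }
  list(plant_fitness = x, fungus_fitness = y,
       total_c_to_fungus = c_total, total_p_to_plant = p_total,
       plant_grew = x > 1 + 1e-12, fungus_grew = y > 1 + 1e-12)
}
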