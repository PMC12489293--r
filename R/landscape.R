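#' Evenly spaced strategy grid
#'
#' Builds the axis values over which coupled fitness landscapes are computed:
#' `resolution` evenly spaced values per axis, endpoints inclusive. The
#' default mirrors the 500-point grid between -100% and 100% used for the
#' full-resolution landscapes.
#'
#' @param resolution Number of values per axis (>= 2).
#' @param lo,hi Axis bounds, with `-1 <= lo < hi <= 1`.
#' @return An object of class `"strategy_grid"`: list with `gamma`,
#'   `epsilon` (identical ascending value vectors) and `resolution`.
#' @export
strategy_grid <- function(resolution = 500L, lo = -1, hi = 1) {
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    domain_error("resolution must be an integer >= 2")
  check_scalar(lo, "lo"); check_scalar(hi, "hi")
  if (lo < -1 || hi > 1 || lo >= hi)
    domain_error("grid bounds must satisfy -1 <= lo < hi <= 1")
  vals <- seq(lo, hi, length.out = resolution)
  structure(list(gamma = vals, epsilon = vals, resolution = resolution),
            class = "strategy_grid")
}

#' Classify an interaction relative to the no-exchange baseline
#'
#' Compares fitnesses at a strategy with fitnesses at the `(0, 0)` strategy
#' for the same uptake efficiencies. Both above baseline is mutualism, both
#' below is competition; one above and one below is parasitism, named for the
#' beneficiary (`plant_parasitic` = plant gains at the fungus's expense).
#' A fitness within relative tolerance `tol` of its baseline makes the
#' interaction `neutral` (ties occur on whole regions here, e.g. a plant with
#' `alpha = 0` never grows without received P).
#'
#' @param plant_fit,fungus_fit Fitness values (vectors or matrices).
#' @param baseline_plant,baseline_fungus Fitnesses at the `(0, 0)` strategy.
#' @param tol Relative tolerance for calling a fitness equal to baseline.
#' @return Character vector/matrix with levels `mutualism`,
#'   `plant_parasitic`, `fungus_parasitic`, `competition`, `neutral`.
#' @export
classify_interaction <- function(plant_fit, fungus_fit,
                                 baseline_plant, baseline_fungus,
                                 tol = 1e-9) {
  dp <- plant_fit - baseline_plant
  df <- fungus_fit - baseline_fungus
  tie_p <- abs(dp) <= tol * baseline_plant
  tie_f <- abs(df) <= tol * baseline_fungus
  out <- ifelse(tie_p | tie_f, "neutral",
         ifelse(dp > 0 & df > 0, "mutualism",
         ifelse(dp < 0 & df < 0, "competition",
         ifelse(dp > 0, "plant_parasitic", "fungus_parasitic"))))
  if (is.matrix(plant_fit)) dim(out) <- dim(plant_fit)
  out
}

#' Coupled fitness, interaction-type and transfer landscapes
#'
#' Evaluates the full lifecycle at every strategy on the grid for one uptake
#' combination and derives all landscape layers: the coupled plant and fungus
#' fitness surfaces, the interaction-type partition against the `(0, 0)`
#' baseline, the extinction-zone partition from the grew flags, the viable
#' resource exchange range (both organisms grew), and the net resources
#' received totals.
#'
#' @inheritParams simulate_lifecycle
#' @param grid A [strategy_grid()].
#' @param tol Relative tolerance for the neutral interaction class.
#' @return Object of class `"trade_landscape"`: the axis vectors plus
#'   gamma-by-epsilon matrices `plant_fitness`, `fungus_fitness`,
#'   `interaction`, `extinction`, `viable`, `total_p_to_plant`,
#'   `total_c_to_fungus`, and the scalar baselines.
#' @export
compute_landscape <- function(alpha, beta, grid = strategy_grid(),
                              steps = 10L, tol = 1e-9) {
  check_uptake(alpha, beta)
  stopifnot(inherits(grid, "strategy_grid"))
  raw <- .landscape_batch_cpp(alpha, beta, grid$gamma, grid$epsilon,
                              as.integer(steps))
  base <- simulate_lifecycle(alpha, beta, 0, 0, steps = steps)
  interaction <- classify_interaction(raw$plant_fitness, raw$fungus_fitness,
                                      base$plant_fitness, base$fungus_fitness,
                                      tol = tol)
  extinction <- ifelse(raw$plant_grew,
                       ifelse(raw$fungus_grew, "none", "fungus_only"),
                       ifelse(raw$fungus_grew, "plant_only", "both"))
  dim(extinction) <- dim(raw$plant_fitness)
  structure(list(
    alpha = alpha, beta = beta,
    gamma = grid$gamma, epsilon = grid$epsilon,
    plant_fitness = raw$plant_fitness,
    fungus_fitness = raw$fungus_fitness,
    interaction = interaction,
    extinction = extinction,
    viable = raw$plant_grew & raw$fungus_grew,
    total_p_to_plant = raw$total_p_to_plant,
    total_c_to_fungus = raw$total_c_to_fungus,
    baseline_plant_fitness = base$plant_fitness,
    baseline_fungus_fitness = base$fungus_fitness,
    tol = tol, steps = as.integer(steps)),
    class = "trade_landscape")
}

#' @export
print.trade_landscape <- function(x, ...) {
  cat(sprintf(
    "Coupled fitness landscape: alpha=%g beta=%g, %d x %d strategies\n",
    x$alpha, x$beta, length(x$gamma), length(x$epsilon)))
  cat(sprintf("  baselines: plant %0.6g, fungus %0.6g\n",
              x$baseline_plant_fitness, x$baseline_fungus_fitness))
  tab <- table(x$interaction)
  cat("  interaction cells:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  viable cells: %d (%.1f%%)\n", sum(x$viable),
              100 * mean(x$viable)))
  invisible(x)
}

#' Extinction-zone partition of a landscape
#'
#' Per-cell category derived from the grew flags: `none` (both grew),
#' `plant_only` / `fungus_only` (only that organism failed to grow), `both`.
#'
#' @param landscape A [compute_landscape()] result.
#' @return Character matrix over the strategy grid.
#' @export
extinction_mask <- function(landscape) {
  stopifnot(inherits(landscape, "trade_landscape"))
  landscape$extinction
}

#' Viable resource exchange range
#'
#' Logical matrix marking strategies at which both organisms achieved greater
#' than zero growth; the complement of the extinction zones.
#'
#' @inheritParams extinction_mask
#' @export
viable_range <- function(landscape) {
  stopifnot(inherits(landscape, "trade_landscape"))
  landscape$viable
}

#' Lifetime resources received under one strategy
#'
#' Net totals of the actual (post-clamp) per-step transfers over a lifecycle:
#' C moved from plant to fungus and P moved from fungus to plant. Resource
#' taken accumulates as a negative contribution.
#'
#' @inheritParams simulate_lifecycle
#' @return Named numeric vector `c(total_p_to_plant, total_c_to_fungus)`.
#' @export
resources_received <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  lc <- simulate_lifecycle(alpha, beta, gamma, epsilon, steps = steps)
  c(total_p_to_plant = lc$total_p_to_plant,
    total_c_to_fungus = lc$total_c_to_fungus)
}

# argmax of one layer with lexicographic (gamma, epsilon) tie-breaking;
# returns the first tied cell plus all ties.
layer_argmax <- function(layer, gamma, epsilon) {
  mx <- max(layer)
  idx <- which(layer == mx, arr.ind = TRUE)
  ties <- data.frame(gamma = gamma[idx[, 1L]], epsilon = epsilon[idx[, 2L]],
                     value = layer[idx])
  ties <- ties[order(ties$gamma, ties$epsilon), , drop = FALSE]
  rownames(ties) <- NULL
  list(gamma = ties$gamma[1L], epsilon = ties$epsilon[1L], value = mx,
       ties = ties)
}

#' Strategies maximising fitness and resources received
#'
#' Grid argmax of the plant fitness, fungus fitness, total P to plant and
#' total C to fungus layers. Ties are broken by the smallest `(gamma,
#' epsilon)` in lexicographic order; all tied cells are also reported.
#'
#' @inheritParams extinction_mask
#' @return List with elements `plant_fitness`, `fungus_fitness`,
#'   `total_p_to_plant`, `total_c_to_fungus`, each a list
#'   `(gamma, epsilon, value, ties)`.
#' @export
fitness_maxima <- function(landscape) {
  stopifnot(inherits(landscape, "trade_landscape"))
  lapply(landscape[c("plant_fitness", "fungus_fitness",
                     "total_p_to_plant", "total_c_to_fungus")],
         layer_argmax, gamma = landscape$gamma, epsilon = landscape$epsilon)
}

#' Look up the landscape cell nearest to a strategy point
#'
#' @inheritParams extinction_mask
#' @param gamma,epsilon Strategy coordinates (vectors allowed).
#' @return Data frame with the snapped grid coordinates and that cell's
#'   `interaction` and `extinction` categories.
#' @export
locate_strategy <- function(landscape, gamma, epsilon) {
  stopifnot(inherits(landscape, "trade_landscape"))
  i <- vapply(gamma, function(g) which.min(abs(landscape$gamma - g)), 1L)
  j <- vapply(epsilon, function(e) which.min(abs(landscape$epsilon - e)), 1L)
  data.frame(gamma = landscape$gamma[i], epsilon = landscape$epsilon[j],
             interaction = landscape$interaction[cbind(i, j)],
             extinction = landscape$extinction[cbind(i, j)])
}

#' @export
as.data.frame.trade_landscape <- function(x, ...) {
  ng <- length(x$gamma); ne <- length(x$epsilon)
  data.frame(
    gamma = rep(x$gamma, times = ne),
    epsilon = rep(x$epsilon, each = ng),
    plant_fitness = as.vector(x$plant_fitness),
    fungus_fitness = as.vector(x$fungus_fitness),
    interaction_type = as.vector(x$interaction),
    extinction = as.vector(x$extinction),
    total_p_to_plant = as.vector(x$total_p_to_plant),
    total_c_to_fungus = as.vector(x$total_c_to_fungus))
}
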