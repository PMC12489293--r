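#' Construct a stable-strategy area (covariance ellipse)
#'
#' A stable resource exchange strategy area is represented as an ellipse in
#' strategy space: a centre, two semi-axes and an orientation. Areas are
#' normally produced by [fit_strategy_areas()]; this constructor also lets
#' tests build synthetic or degenerate areas directly.
#'
#' @param center Numeric length-2 `(gamma, epsilon)` centre.
#' @param semi_axes Numeric length-2 semi-axis lengths (>= 0).
#' @param angle Orientation of the first axis, radians.
#' @param n_points Number of trajectory points the area was fitted on.
#' @return Object of class `"strategy_area"`.
#' @export
strategy_area <- function(center, semi_axes, angle = 0, n_points = NA_integer_) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(is.finite(center)), all(semi_axes >= 0))
  if (any(abs(center) > 1)) domain_error("area centre must lie in [-1, 1]^2")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 angle = as.numeric(angle),
                 n_points = as.integer(n_points)),
            class = "strategy_area")
}

#' @export
print.strategy_area <- function(x, ...) {
  cat(sprintf(
    "Strategy area: centre (%.4f, %.4f), semi-axes (%.4f, %.4f), angle %.3f rad\n",
    x$center[1L], x$center[2L], x$semi_axes[1L], x$semi_axes[2L], x$angle))
  invisible(x)
}

#' Scale an area's semi-axes about its centre
#'
#' @param area A [strategy_area()].
#' @param factor Non-negative multiplier applied to both semi-axes.
#' @return The scaled `"strategy_area"`.
#' @export
scale_area <- function(area, factor) {
  stopifnot(inherits(area, "strategy_area"), factor >= 0)
  area$semi_axes <- area$semi_axes * factor
  area
}

#' Test whether strategy points fall inside an area
#'
#' @param area A [strategy_area()].
#' @param gamma,epsilon Strategy coordinates (vectors allowed).
#' @return Logical vector. A zero-length semi-axis admits only points lying
#'   exactly on the corresponding axis of the ellipse.
#' @export
area_contains <- function(area, gamma, epsilon) {
  stopifnot(inherits(area, "strategy_area"))
  dx <- gamma - area$center[1L]
  dy <- epsilon - area$center[2L]
  co <- cos(area$angle); si <- sin(area$angle)
  u <- co * dx + si * dy
  v <- -si * dx + co * dy
  term <- function(d, a) {
    if (a > 0) (d / a)^2 else ifelse(abs(d) <= 1e-15, 0, Inf)
  }
  term(u, area$semi_axes[1L]) + term(v, area$semi_axes[2L]) <= 1 + 1e-9
}

#' Fit candidate stable areas to pooled trajectory endpoints
#'
#' Clusters a cloud of per-generation mean-strategy points (pooled over the
#' stationary tails of exploratory evolution runs) by single linkage at a
#' fixed distance threshold, then fits each cluster a covariance ellipse
#' scaled so that it covers `coverage` of the cluster's points (empirical
#' Mahalanobis quantile). For large clouds the linkage step runs on a
#' deterministic subsample and the remaining points are assigned to the
#' nearest subsampled point's cluster before the ellipse fit.
#'
#' @param points Two-column matrix/data frame of `(gamma, epsilon)` points.
#' @param linkage_threshold Single-linkage merge distance, strategy units.
#' @param coverage Fraction of cluster points the ellipse must cover.
#' @param min_points Minimum cluster size to yield a candidate.
#' @param max_linkage_points Subsample cap for the linkage step.
#' @return List of [strategy_area()] candidates, largest cluster first.
#' @export
fit_strategy_areas <- function(points, linkage_threshold = 0.1,
                               coverage = 0.95, min_points = 25L,
                               max_linkage_points = 800L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < min_points) return(list())
  sub_idx <- unique(round(seq(1L, n, length.out = min(n, max_linkage_points))))
  sub <- pts[sub_idx, , drop = FALSE]
  memb_sub <- if (nrow(sub) > 1L) {
    cutree(hclust(dist(sub), method = "single"), h = linkage_threshold)
  } else 1L
  # assign every pooled point to the cluster of its nearest subsampled point
  nearest <- integer(n)
  block <- 4096L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(pts[s:e, 1L], sub[, 1L], "-")^2 +
          outer(pts[s:e, 2L], sub[, 2L], "-")^2
    nearest[s:e] <- max.col(-d2, ties.method = "first")
  }
  memb <- memb_sub[nearest]
  areas <- list()
  for (k in unique(memb)) {
    sel <- pts[memb == k, , drop = FALSE]
    if (nrow(sel) < min_points) next
    ctr <- colMeans(sel)
    S <- cov(sel) + diag(1e-12, 2L)
    d2 <- mahalanobis(sel, ctr, S)
    r2 <- quantile(d2, coverage, names = FALSE)
    eg <- eigen(S, symmetric = TRUE)
    semi <- sqrt(pmax(eg$values, 0) * r2)
    ang <- atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L])
    areas[[length(areas) + 1L]] <-
      strategy_area(pmin(1, pmax(-1, ctr)), semi, ang, n_points = nrow(sel))
  }
  areas[order(vapply(areas, function(a) a$n_points, 1L), decreasing = TRUE)]
}

#' Explore a landscape for candidate stable strategy areas
#'
#' Runs the individual-based model from a coarse grid of viable founding
#' strategies. For runs that reach the generation cap, the population mean
#' strategies of the final `tail_generations` generations are pooled and
#' passed to [fit_strategy_areas()].
#'
#' @inheritParams simulate_lifecycle
#' @param config An [evolution_config()] template; its founding strategy is
#'   overridden per start.
#' @param founders Two-column matrix of founding strategies, or `NULL` for
#'   the default 5 x 5 grid spanning `[-0.8, 0.8]^2`. Founders at which
#'   either organism has no growth are dropped (they found extinct
#'   monomorphic populations).
#' @param seed Master seed; each run gets an independent derived child seed.
#' @param tail_generations Stationary tail pooled from each capped run.
#' @param ... Passed to [fit_strategy_areas()].
#' @return List with `areas` (candidate [strategy_area()]s), `runs` (one row
#'   per viable founder: start, outcome, final mean strategy, index of the
#'   containing candidate area or `NA`), and `n_pooled`.
#' @export
explore_candidates <- function(alpha, beta, config = evolution_config(alpha, beta),
                               founders = NULL, seed = 1L,
                               tail_generations = 500L, ...) {
  check_uptake(alpha, beta)
  stopifnot(inherits(config, "evolution_config"))
  if (is.null(founders)) {
    v <- seq(-0.8, 0.8, length.out = 5L)
    founders <- as.matrix(expand.grid(gamma = v, epsilon = v))
  }
  founders <- as.matrix(founders)[, 1:2, drop = FALSE]
  lc <- lifecycle_batch(alpha, beta, founders[, 1L], founders[, 2L],
                        steps = config$steps)
  founders <- founders[lc$plant_grew & lc$fungus_grew, , drop = FALSE]
  n_starts <- nrow(founders)
  runs <- data.frame(start_gamma = numeric(0), start_epsilon = numeric(0),
                     outcome = character(0), final_gamma = numeric(0),
                     final_epsilon = numeric(0), area = integer(0))
  if (n_starts == 0L)
    return(list(areas = list(), runs = runs, n_pooled = 0L))
  seeds <- derive_seeds(seed, n_starts)
  pooled <- vector("list", n_starts)
  runs <- data.frame(start_gamma = founders[, 1L],
                     start_epsilon = founders[, 2L],
                     outcome = NA_character_,
                     final_gamma = NA_real_, final_epsilon = NA_real_,
                     area = NA_integer_)
  for (i in seq_len(n_starts)) {
    cfg <- config
    cfg$init_gamma <- founders[i, 1L]
    cfg$init_epsilon <- founders[i, 2L]
    tr <- run_evolution(cfg, seed = seeds[i])
    runs$outcome[i] <- tr$outcome
    last <- tr$records[nrow(tr$records), ]
    runs$final_gamma[i] <- last$mean_gamma
    runs$final_epsilon[i] <- last$mean_epsilon
    if (tr$outcome == "reached_cap") {
      tail_idx <- seq(max(1L, tr$terminal_generation - tail_generations + 1L),
                      tr$terminal_generation)
      pooled[[i]] <- cbind(tr$records$mean_gamma[tail_idx],
                           tr$records$mean_epsilon[tail_idx])
    }
  }
  pooled <- do.call(rbind, pooled)
  areas <- if (is.null(pooled)) list() else fit_strategy_areas(pooled, ...)
  if (length(areas) > 0L) {
    for (i in seq_len(n_starts)) {
      if (is.na(runs$final_gamma[i]) || runs$outcome[i] != "reached_cap") next
      hit <- which(vapply(areas, area_contains, TRUE,
                          gamma = runs$final_gamma[i],
                          epsilon = runs$final_epsilon[i]))
      if (length(hit) > 0L) runs$area[i] <- hit[1L]
    }
  }
  list(areas = areas, runs = runs,
       n_pooled = if (is.null(pooled)) 0L else nrow(pooled))
}

#' Stability test of a candidate strategy area
#'
#' Starts `n_replicates` independent seeded evolution runs at the area centre
#' (monomorphic founding) and checks whether each remains inside the area —
#' population mean strategy inside the ellipse, no extinction — for
#' `min_generations` consecutive generations from generation 0. The area is
#' `stable` if all replicates remain, `semi_stable` if at least one (but not
#' all) remains, `none` otherwise.
#'
#' The area passed in should be the full roaming region of a stationary
#' population (see [characterize_uptake()], which scales the fitted
#' tail ellipse once at construction), not the raw 95%-coverage fit: strict
#' membership in a 95% ellipse would fail even a perfectly stationary
#' replicate about 5% of the time per generation. `membership_scale` can
#' inflate the tested ellipse further and is 1 by default.
#'
#' @inheritParams area_contains
#' @inheritParams init_populations
#' @param n_replicates Number of replicate runs.
#' @param min_generations Consecutive generations a replicate must remain.
#' @param seed Master seed; replicates get independent derived child seeds.
#' @param membership_scale Additional semi-axis inflation applied for the
#'   membership test only.
#' @return List with `verdict`, `replicates_remaining`, and the per-replicate
#'   logical `remained`.
#' @export
test_stability <- function(area, config, n_replicates = 36L,
                           min_generations = 500L, seed = 1L,
                           membership_scale = 1) {
  stopifnot(inherits(area, "strategy_area"),
            inherits(config, "evolution_config"))
  test_area <- scale_area(area, membership_scale)
  cfg <- config
  cfg$init_gamma <- area$center[1L]
  cfg$init_epsilon <- area$center[2L]
  cfg$generation_cap <- as.integer(min_generations)
  seeds <- derive_seeds(seed, n_replicates)
  remained <- vapply(seq_len(n_replicates), function(k) {
    tr <- run_evolution(cfg, seed = seeds[k])
    tr$outcome == "reached_cap" &&
      all(area_contains(test_area, tr$records$mean_gamma,
                        tr$records$mean_epsilon))
  }, TRUE)
  n_rem <- sum(remained)
  verdict <- if (n_rem == n_replicates) "stable"
             else if (n_rem > 0L) "semi_stable" else "none"
  list(verdict = verdict, replicates_remaining = n_rem, remained = remained)
}

#' Classify a stable area against the interaction-type landscape
#'
#' Examines the interaction categories of the landscape cells inside the
#' area. The landscape is `mutualism_stable` when at least `mutualism_min` of
#' the interior cells are mutualism, and `mutualism_parasitism_stable` when
#' the interior spans mutualism and more than `parasitism_min` of a parasitic
#' category. Any other combination is flagged as a novel outcome rather than
#' silently mapped to a category. An absent area classifies as `none`.
#'
#' Neutral (tied-fitness) cells are reported in `types_spanned` and
#' `fractions` but excluded from the zone-membership denominators: ties live
#' on zone boundaries (e.g. the single grid column where giving costs a
#' still-unconstrained plant nothing), and a boundary touch must not flip the
#' category of an otherwise unambiguous area.
#'
#' @param area A [strategy_area()] or `NULL`.
#' @inheritParams extinction_mask
#' @param mutualism_min,parasitism_min Zone-membership thresholds (fractions
#'   of interior cells).
#' @return List with `category` (`mutualism_stable`,
#'   `mutualism_parasitism_stable`, `none`, or `novel`), `novel` flag,
#'   `types_spanned`, the interior `fractions`, and `empty_interior` (ellipse
#'   fell between grid points; nearest cell used).
#' @export
classify_landscape <- function(area, landscape,
                               mutualism_min = 0.99, parasitism_min = 0.01) {
  stopifnot(inherits(landscape, "trade_landscape"))
  if (is.null(area))
    return(list(category = "none", novel = FALSE,
                types_spanned = character(0), fractions = NULL,
                empty_interior = FALSE))
  ng <- length(landscape$gamma); ne <- length(landscape$epsilon)
  gg <- rep(landscape$gamma, times = ne)
  ee <- rep(landscape$epsilon, each = ng)
  inside <- area_contains(area, gg, ee)
  empty <- !any(inside)
  if (empty) {
    d2 <- (gg - area$center[1L])^2 + (ee - area$center[2L])^2
    inside <- seq_along(gg) == which.min(d2)
  }
  types <- as.vector(landscape$interaction)[inside]
  frac <- table(types) / length(types)
  zoned <- types[types != "neutral"]
  zfrac <- if (length(zoned) > 0) table(zoned) / length(zoned) else table(zoned)
  f <- function(nm) if (nm %in% names(zfrac)) as.numeric(zfrac[[nm]]) else 0
  par_frac <- f("plant_parasitic") + f("fungus_parasitic")
  if (f("mutualism") >= mutualism_min) {
    category <- "mutualism_stable"; novel <- FALSE
  } else if (f("mutualism") > 0 && par_frac > parasitism_min) {
    category <- "mutualism_parasitism_stable"; novel <- FALSE
  } else {
    category <- "novel"; novel <- TRUE
  }
  list(category = category, novel = novel,
       types_spanned = sort(names(frac)), fractions = frac,
       empty_interior = empty)
}

#' Fitness maxima within a stable area
#'
#' Maximum plant and fungus fitness over landscape cells inside the area, and
#' whether each organism's global fitness argmax lies inside the area (within
#' one grid cell).
#'
#' @inheritParams classify_landscape
#' @return List with `max_plant_fitness`, `max_fungus_fitness`,
#'   `plant_coincides`, `fungus_coincides`, `empty_interior`.
#' @export
area_fitness_maxima <- function(area, landscape) {
  stopifnot(inherits(area, "strategy_area"),
            inherits(landscape, "trade_landscape"))
  ng <- length(landscape$gamma); ne <- length(landscape$epsilon)
  gg <- rep(landscape$gamma, times = ne)
  ee <- rep(landscape$epsilon, each = ng)
  inside <- matrix(area_contains(area, gg, ee), ng, ne)
  empty <- !any(inside)
  if (empty) {
    d2 <- (gg - area$center[1L])^2 + (ee - area$center[2L])^2
    inside <- matrix(seq_along(gg) == which.min(d2), ng, ne)
  }
  coincides <- function(layer) {
    mx <- which(layer == max(layer), arr.ind = TRUE)
    # inside (or within one grid cell of) any tied global argmax
    for (r in seq_len(nrow(mx))) {
      i <- mx[r, 1L]; j <- mx[r, 2L]
      ii <- max(1L, i - 1L):min(ng, i + 1L)
      jj <- max(1L, j - 1L):min(ne, j + 1L)
      if (any(inside[ii, jj])) return(TRUE)
    }
    FALSE
  }
  list(
    max_plant_fitness = max(landscape$plant_fitness[inside]),
    max_fungus_fitness = max(landscape$fungus_fitness[inside]),
    plant_coincides = coincides(landscape$plant_fitness),
    fungus_coincides = coincides(landscape$fungus_fitness),
    empty_interior = empty)
}

#' Characterise one uptake efficiency combination
#'
#' Full per-combination pipeline: compute the landscape, explore for
#' candidate stable areas, stability-test the candidates (largest first),
#' classify the best surviving area against the interaction-type landscape,
#' and measure fitness maxima within it.
#'
#' A candidate from [explore_candidates()] is the 95%-coverage ellipse of one
#' run's stationary tail cloud; the stable resource exchange strategy *area*
#' is taken as that ellipse scaled by `area_scale`, which is the region
#' replicate populations actually roam while remaining stationary. The same
#' scaled area is used for the 36-replicate membership test, the
#' interaction-zone classification, the fitness maxima, and reporting.
#'
#' @inheritParams simulate_lifecycle
#' @inheritParams explore_candidates
#' @param grid Strategy grid for the classification landscape.
#' @param n_replicates,min_generations Stability-test settings.
#' @param max_candidates Stability-test at most this many candidates
#'   (largest clusters first).
#' @param area_scale Factor from fitted tail ellipse to the stable area.
#' @param ... Passed to [explore_candidates()].
#' @return Object of class `"stability_report"`: uptake values, `category`,
#'   `stability` (`stable`, `semi_stable`, `not_applicable`), the chosen
#'   `area` (or `NULL`), `replicates_remaining`, interaction types spanned,
#'   area fitness maxima with coincidence flags, and the exploration `runs`
#'   table.
#' @export
characterize_uptake <- function(alpha, beta,
                                config = evolution_config(alpha, beta),
                                grid = strategy_grid(201L),
                                seed = 1L,
                                n_replicates = 36L, min_generations = 500L,
                                max_candidates = 3L, area_scale = 3, ...) {
  landscape <- compute_landscape(alpha, beta, grid = grid,
                                 steps = config$steps)
  seeds <- derive_seeds(seed, 2L)
  expl <- explore_candidates(alpha, beta, config = config, seed = seeds[1L],
                             ...)
  cand <- lapply(expl$areas[seq_len(min(length(expl$areas), max_candidates))],
                 scale_area, factor = area_scale)
  best <- NULL; best_test <- NULL
  if (length(cand) > 0L) {
    cand_seeds <- derive_seeds(seeds[2L], length(cand))
    for (i in seq_along(cand)) {
      ts <- test_stability(cand[[i]], config, n_replicates = n_replicates,
                           min_generations = min_generations,
                           seed = cand_seeds[i])
      if (ts$verdict == "none") next
      if (is.null(best_test) ||
          ts$replicates_remaining > best_test$replicates_remaining) {
        best <- cand[[i]]; best_test <- ts
      }
      if (ts$verdict == "stable") break
    }
  }
  if (is.null(best)) {
    cls <- classify_landscape(NULL, landscape)
    report <- list(alpha = alpha, beta = beta, category = "none",
                   stability = "not_applicable", area = NULL,
                   replicates_remaining = 0L,
                   n_replicates = n_replicates,
                   types_spanned = character(0), novel = FALSE,
                   max_plant_fitness = NA_real_,
                   max_fungus_fitness = NA_real_,
                   plant_coincides = NA, fungus_coincides = NA,
                   runs = expl$runs, n_candidates = length(expl$areas))
  } else {
    cls <- classify_landscape(best, landscape)
    fm <- area_fitness_maxima(best, landscape)
    report <- list(alpha = alpha, beta = beta, category = cls$category,
                   stability = best_test$verdict, area = best,
                   replicates_remaining = best_test$replicates_remaining,
                   n_replicates = n_replicates,
                   types_spanned = cls$types_spanned, novel = cls$novel,
                   max_plant_fitness = fm$max_plant_fitness,
                   max_fungus_fitness = fm$max_fungus_fitness,
                   plant_coincides = fm$plant_coincides,
                   fungus_coincides = fm$fungus_coincides,
                   runs = expl$runs, n_candidates = length(expl$areas))
  }
  structure(report, class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report: alpha=%g beta=%g -> %s (%s, %d/%d replicates)\n",
              x$alpha, x$beta, x$category, x$stability,
              x$replicates_remaining, x$n_replicates))
  if (!is.null(x$area))
    cat(sprintf("  area centre (%.4f, %.4f); types: %s\n",
                x$area$center[1L], x$area$center[2L],
                paste(x$types_spanned, collapse = ", ")))
  invisible(x)
}

#' Sweep uptake efficiency combinations
#'
#' Runs [characterize_uptake()] for every `(alpha, beta)` combination and
#' aggregates category and stability percentages. The default grids are 21
#' plant P uptake efficiencies (0 to 1 by 0.05) crossed with 11 fungus C
#' uptake efficiencies (0 to 1 by 0.1): 231 combinations. Fully reproducible
#' from `seed`; per-combination failures are recorded, not fatal.
#'
#' @param alpha_values,beta_values Uptake efficiency value vectors.
#' @param config_fn Function of `(alpha, beta)` returning the
#'   [evolution_config()] for that combination.
#' @param seed Master seed; each combination gets a derived child seed.
#' @param grid Strategy grid used for classification landscapes.
#' @param progress Print one line per combination.
#' @param ... Passed to [characterize_uptake()].
#' @return Object of class `"trade_sweep"`: `summary` data frame (one row per
#'   combination), `percentages` (category shares and the share of
#'   combinations whose area was semi-stable), `reports`, and the grids.
#' @export
run_sweep <- function(alpha_values = seq(0, 1, by = 0.05),
                      beta_values = seq(0, 1, by = 0.1),
                      config_fn = function(alpha, beta)
                        evolution_config(alpha, beta),
                      seed = 1L, grid = strategy_grid(201L),
                      progress = FALSE, ...) {
  stopifnot(length(alpha_values) > 0L, length(beta_values) > 0L)
  combos <- expand.grid(alpha = alpha_values, beta = beta_values,
                        KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  reports <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    a <- combos$alpha[i]; b <- combos$beta[i]
    rep_i <- tryCatch(
      characterize_uptake(a, b, config = config_fn(a, b), grid = grid,
                          seed = seeds[i], ...),
      error = function(e) e)
    if (inherits(rep_i, "error")) {
      rows[[i]] <- data.frame(
        alpha = a, beta = b, category = "error", stability = "error",
        replicates_remaining = NA_integer_, center_gamma = NA_real_,
        center_epsilon = NA_real_, semi_axis_1 = NA_real_,
        semi_axis_2 = NA_real_, angle = NA_real_,
        max_plant_fitness = NA_real_, max_fungus_fitness = NA_real_,
        plant_coincides = NA, fungus_coincides = NA, novel = NA,
        error = conditionMessage(rep_i))
    } else {
      reports[[i]] <- rep_i
      ar <- rep_i$area
      rows[[i]] <- data.frame(
        alpha = a, beta = b, category = rep_i$category,
        stability = rep_i$stability,
        replicates_remaining = rep_i$replicates_remaining,
        center_gamma = if (is.null(ar)) NA_real_ else ar$center[1L],
        center_epsilon = if (is.null(ar)) NA_real_ else ar$center[2L],
        semi_axis_1 = if (is.null(ar)) NA_real_ else ar$semi_axes[1L],
        semi_axis_2 = if (is.null(ar)) NA_real_ else ar$semi_axes[2L],
        angle = if (is.null(ar)) NA_real_ else ar$angle,
        max_plant_fitness = rep_i$max_plant_fitness,
        max_fungus_fitness = rep_i$max_fungus_fitness,
        plant_coincides = rep_i$plant_coincides,
        fungus_coincides = rep_i$fungus_coincides,
        novel = rep_i$novel, error = NA_character_)
    }
    if (progress)
      message(sprintf("[%d/%d] alpha=%.2f beta=%.2f -> %s", i, nrow(combos),
                      a, b, rows[[i]]$category))
  }
  summary <- do.call(rbind, rows)
  n <- nrow(summary)
  pct <- list(
    mutualism_stable = 100 * sum(summary$category == "mutualism_stable") / n,
    mutualism_parasitism_stable =
      100 * sum(summary$category == "mutualism_parasitism_stable") / n,
    none = 100 * sum(summary$category == "none") / n,
    semi_stable = 100 * sum(summary$stability == "semi_stable") / n)
  structure(list(summary = summary, percentages = pct,
                 alpha_values = alpha_values, beta_values = beta_values,
                 seed = seed, reports = reports),
            class = "trade_sweep")
}

#' @export
print.trade_sweep <- function(x, ...) {
  cat(sprintf("Uptake efficiency sweep: %d combinations (%d alpha x %d beta)\n",
              nrow(x$summary), length(x$alpha_values), length(x$beta_values)))
  p <- x$percentages
  cat(sprintf("  mutualism stable        %5.1f%%\n", p$mutualism_stable))
  cat(sprintf("  mutualism-parasitism    %5.1f%%\n",
              p$mutualism_parasitism_stable))
  cat(sprintf("  no stable strategy      %5.1f%%\n", p$none))
  cat(sprintf("  semi-stable areas       %5.1f%%\n", p$semi_stable))
  invisible(x)
}
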