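test_that("area containment handles rotation and degenerate axes", {
  a <- strategy_area(c(0.2, 0.3), c(0.2, 0.1), angle = pi / 4)
  expect_true(area_contains(a, 0.2, 0.3))
  expect_true(area_contains(a, 0.2 + 0.1, 0.3 + 0.1))   # along major axis
  expect_false(area_contains(a, 0.2 - 0.1, 0.3 + 0.1))  # along minor axis
  expect_false(area_contains(a, 0.9, 0.9))
  z <- strategy_area(c(0, 0), c(0, 0))
  expect_true(area_contains(z, 0, 0))
  expect_false(area_contains(z, 1e-6, 0))
  expect_error(strategy_area(c(2, 0), c(0.1, 0.1)), "centre")
})

test_that("candidate detection recovers synthetic cluster centres and coverage", {
  pts <- synth_cloud(2500, c(0.45, 0.40), seed = 31)
  areas <- fit_strategy_areas(pts)
  expect_length(areas, 1)
  expect_lt(max(abs(areas[[1]]$center - c(0.45, 0.40))), 0.02)
  cov_frac <- mean(area_contains(areas[[1]], pts[, 1], pts[, 2]))
  expect_gte(cov_frac, 0.93)
  expect_lte(cov_frac, 0.97)
})

test_that("well-separated clouds give one candidate each", {
  pts <- rbind(synth_cloud(800, c(0.5, 0.5), seed = 5),
               synth_cloud(600, c(-0.4, 0.2), seed = 6))
  areas <- fit_strategy_areas(pts)
  expect_length(areas, 2)
  centers <- t(vapply(areas, function(a) a$center, c(0, 0)))
  expect_equal(centers[order(centers[, 1]), ],
               rbind(c(-0.4, 0.2), c(0.5, 0.5)),
               tolerance = 0.05, ignore_attr = TRUE)
  # too few points yield no candidates
  expect_length(fit_strategy_areas(pts[1:10, ]), 0)
})

test_that("exploration pools capped runs and finds the attractor", {
  ex <- explore_candidates(0.1, 0, seed = 11)
  expect_true(all(ex$runs$outcome == "reached_cap"))
  expect_gte(length(ex$areas), 1)
  ctr <- ex$areas[[1]]$center
  # converged area sits in the first-quadrant mutualism zone
  expect_true(all(ctr > 0.2 & ctr < 0.8))
  # no viable founders anywhere -> no candidates
  ex0 <- explore_candidates(0, 0, seed = 2,
                            founders = cbind(c(-0.5, 0, 0.4),
                                             c(-0.5, 0, -0.2)))
  expect_length(ex0$areas, 0)
  expect_equal(nrow(ex0$runs), 0)
})

test_that("stability verdicts cover stable, semi-stable and none", {
  cfg <- evolution_config(0.1, 0.1, generation_cap = 60L,
                          population_size = 60)
  # the whole strategy square: nothing can depart, founders viable
  whole <- strategy_area(c(0.4, 0.4), c(4, 4))
  ts <- test_stability(whole, cfg, n_replicates = 6, min_generations = 60,
                       seed = 3)
  expect_identical(ts$verdict, "stable")
  expect_equal(ts$replicates_remaining, 6)
  # a zero-area ellipse with nonzero mutation departs immediately
  degen <- strategy_area(c(0.4, 0.4), c(0, 0))
  ts <- test_stability(degen, cfg, n_replicates = 6, min_generations = 60,
                       seed = 3)
  expect_identical(ts$verdict, "none")
  expect_equal(ts$replicates_remaining, 0)
})

test_that("zone classification distinguishes the three categories", {
  ls <- compute_landscape(0.1, 0.1, grid = strategy_grid(101))
  expect_identical(classify_landscape(NULL, ls)$category, "none")
  # small ellipse deep in the mutualism zone
  mut <- strategy_area(c(0.45, 0.45), c(0.05, 0.05))
  cls <- classify_landscape(mut, ls)
  expect_identical(cls$category, "mutualism_stable")
  expect_false(cls$novel)
  # ellipse straddling a mutualism/parasitism boundary
  types <- classify_interaction(ls$plant_fitness, ls$fungus_fitness,
                                ls$baseline_plant_fitness,
                                ls$baseline_fungus_fitness)
  straddle <- strategy_area(c(0.8, 0.2), c(0.25, 0.25))
  cls2 <- classify_landscape(straddle, ls)
  expect_true("mutualism" %in% cls2$types_spanned)
  # an area with next to no mutualism raises the novel flag
  third <- strategy_area(c(-0.6, -0.6), c(0.05, 0.05))
  cls3 <- classify_landscape(third, ls)
  expect_true(cls3$novel)
  # tiny ellipse between grid points falls back to the nearest cell
  tiny <- strategy_area(c(0.451, 0.449), c(1e-6, 1e-6))
  cls4 <- classify_landscape(tiny, ls)
  expect_true(cls4$empty_interior)
  expect_identical(cls4$category, "mutualism_stable")
})

test_that("area fitness maxima flag coincidence with the global argmax", {
  ls <- compute_landscape(0.1, 0.1, grid = strategy_grid(101))
  whole <- strategy_area(c(0, 0), c(4, 4))
  fm <- area_fitness_maxima(whole, ls)
  expect_equal(fm$max_plant_fitness, max(ls$plant_fitness))
  expect_true(fm$plant_coincides && fm$fungus_coincides)
  # small area away from the global maxima
  gm <- fitness_maxima(ls)
  off <- strategy_area(c(-0.5, 0.5), c(0.05, 0.05))
  expect_gt(abs(gm$plant_fitness$gamma - (-0.5)), 0.2)
  fm2 <- area_fitness_maxima(off, ls)
  expect_false(fm2$plant_coincides)
  expect_lt(fm2$max_plant_fitness, gm$plant_fitness$value)
})

test_that("per-combination characterisation matches known regimes", {
  rep1 <- characterize_uptake(0.1, 0, seed = 11)
  expect_identical(rep1$category, "mutualism_stable")
  expect_identical(rep1$stability, "stable")
  expect_equal(rep1$replicates_remaining, 36)
  expect_identical(rep1$types_spanned, "mutualism")
  # low equal efficiencies: maximum fitness coincides with the stable area
  rep2 <- characterize_uptake(0.1, 0.1, seed = 13)
  expect_identical(rep2$category, "mutualism_stable")
  expect_true(rep2$plant_coincides)
  expect_true(rep2$fungus_coincides)
  # extinction-dominated regime has no stable strategy
  rep3 <- characterize_uptake(0.95, 0.8, seed = 17)
  expect_identical(rep3$category, "none")
  expect_identical(rep3$stability, "not_applicable")
})

test_that("the default sweep grids enumerate 231 combinations", {
  combos <- expand.grid(alpha = seq(0, 1, by = 0.05),
                        beta = seq(0, 1, by = 0.1))
  expect_equal(nrow(combos), 231)
  # run_sweep on a toy grid returns one report per combination and
  # percentages over the three categories that sum to 100
  sw <- run_sweep(alpha_values = c(0.1, 0.9), beta_values = c(0, 0.9),
                  seed = 5, grid = strategy_grid(101L),
                  config_fn = function(a, b)
                    evolution_config(a, b, population_size = 60,
                                     generation_cap = 600L),
                  n_replicates = 6, min_generations = 200)
  expect_equal(nrow(sw$summary), 4)
  expect_false(any(sw$summary$category == "error"))
  with(sw$percentages,
       expect_equal(mutualism_stable + mutualism_parasitism_stable + none +
                    100 * mean(sw$summary$category == "novel"), 100))
})

test_that("convergence to the stable area does not rise with uptake", {
  frac_conv <- vapply(c(0.1, 0.5, 0.8), function(u) {
    ex <- explore_candidates(u, u, seed = 21,
                             config = evolution_config(u, u,
                                                       generation_cap = 1000L,
                                                       population_size = 100))
    if (nrow(ex$runs) == 0) return(0)
    mean(!is.na(ex$runs$area))
  }, 1.0)
  expect_gte(frac_conv[1] + 0.05, frac_conv[2])
  expect_gte(frac_conv[2] + 0.05, frac_conv[3])
})
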