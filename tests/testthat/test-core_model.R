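test_that("a single exchange step resolves gathering, transfers and growth", {
  st <- resolve_exchange(1, 1, alpha = 0.1, beta = 0.2,
                         gamma = 0.3, epsilon = 0.4)
  expect_equal(st$plant_c_pool, 0.7)
  expect_equal(st$plant_p_pool, 0.5)
  expect_equal(st$fungus_c_pool, 0.5)
  expect_equal(st$fungus_p_pool, 0.6)
  expect_equal(st$c_transfer, 0.3)
  expect_equal(st$p_transfer, 0.4)
  expect_equal(st$plant_growth, 0.5)
  expect_equal(st$fungus_growth, 0.5)
})

test_that("taking is clamped to what the partner gathered", {
  # fungus gathered no C at all: nothing to take
  st <- resolve_exchange(1, 1, alpha = 0.5, beta = 0,
                         gamma = -0.5, epsilon = 0)
  expect_identical(st$c_transfer, 0)
  # plant claims 5 C, fungus gathered only 0.2
  st <- resolve_exchange(10, 1, alpha = 0, beta = 0.2,
                         gamma = -0.5, epsilon = 0)
  expect_equal(st$c_transfer, -0.2)
  expect_equal(st$fungus_c_pool, 0)
  expect_equal(st$plant_c_pool, 10.2)
  # the claim scales with the taker's biomass, not the partner's
  st <- resolve_exchange(1, 10, alpha = 0.3, beta = 1,
                         gamma = -0.5, epsilon = 0)
  expect_equal(st$c_transfer, -0.5)
})

test_that("parameters outside their domains are rejected", {
  expect_error(resolve_exchange(1, 1, alpha = 1.2, beta = 0, gamma = 0,
                                epsilon = 0), "alpha")
  expect_error(resolve_exchange(1, 1, alpha = 0, beta = 0, gamma = -1.5,
                                epsilon = 0), "gamma")
  expect_error(resolve_exchange(0, 1, alpha = 0, beta = 0, gamma = 0,
                                epsilon = 0), "positive")
  expect_error(simulate_lifecycle(0.5, 0.5, 0, 0, steps = 0), "steps")
  expect_error(evolution_config(0.5, 0.5, population_size = 1),
               "population_size")
})

test_that("lifecycle matches geometric closed forms without exchange", {
  for (ab in list(c(0, 0), c(1, 1), c(0.1, 0.3), c(0.2, 0.5))) {
    lc <- simulate_lifecycle(ab[1], ab[2], 0, 0)
    expect_equal(lc$plant_fitness, (1 + ab[1])^10, tolerance = 1e-14)
    expect_equal(lc$fungus_fitness, (1 + ab[2])^10, tolerance = 1e-14)
  }
  # symmetric giving with no nonspecialised uptake
  for (g in c(0.25, 0.5, 0.8, 1)) {
    lc <- simulate_lifecycle(0, 0, g, g)
    expect_equal(lc$plant_fitness, (1 + min(g, 1 - g))^10, tolerance = 1e-14)
    expect_equal(lc$fungus_fitness, lc$plant_fitness)
  }
})

test_that("closed_form_fitness covers exactly the two analytic families", {
  expect_equal(closed_form_fitness(0.2, 0.5, 0, 0),
               c(plant = 1.2^10, fungus = 1.5^10))
  expect_equal(closed_form_fitness(0, 0, 1, 1), c(plant = 1, fungus = 1))
  expect_null(closed_form_fitness(0.3, 0.1, 0.2, 0.1))
  expect_null(closed_form_fitness(0, 0, 0.2, 0.3))
  # agreement with the simulation wherever the closed form exists
  cases <- rbind(expand.grid(alpha = c(0, 0.3, 1), beta = c(0, 0.7),
                             gamma = 0, epsilon = 0),
                 data.frame(alpha = 0, beta = 0, gamma = c(0.2, 0.9),
                            epsilon = c(0.2, 0.9)))
  for (k in seq_len(nrow(cases))) {
    cf <- closed_form_fitness(cases$alpha[k], cases$beta[k],
                              cases$gamma[k], cases$epsilon[k])
    lc <- simulate_lifecycle(cases$alpha[k], cases$beta[k],
                             cases$gamma[k], cases$epsilon[k])
    expect_equal(unname(cf), c(lc$plant_fitness, lc$fungus_fitness),
                 tolerance = 1e-12)
  }
})

test_that("no-exchange, no-uptake organisms never grow", {
  lc <- simulate_lifecycle(0, 0, 0, 0)
  expect_equal(lc$plant_fitness, 1)
  expect_equal(lc$fungus_fitness, 1)
  expect_false(lc$plant_grew)
  expect_false(lc$fungus_grew)
})

test_that("biomass is non-decreasing and pools conserve gathered resources", {
  cases <- draw_params(400, seed = 421)
  for (k in seq_len(nrow(cases))) {
    a <- cases$alpha[k]; b <- cases$beta[k]
    g <- cases$gamma[k]; e <- cases$epsilon[k]
    lc <- simulate_lifecycle(a, b, g, e)
    expect_true(all(diff(lc$plant_biomass) >= 0))
    expect_true(all(diff(lc$fungus_biomass) >= 0))
    expect_gte(lc$plant_fitness, 1)
    expect_gte(lc$fungus_fitness, 1)
    # per-step conservation and non-negativity at a random biomass state
    st <- resolve_exchange(lc$plant_biomass[3], lc$fungus_biomass[3],
                           a, b, g, e)
    x <- lc$plant_biomass[3]; y <- lc$fungus_biomass[3]
    expect_equal(st$plant_c_pool + st$fungus_c_pool, x + b * y,
                 tolerance = 1e-12)
    expect_equal(st$plant_p_pool + st$fungus_p_pool, a * x + y,
                 tolerance = 1e-12)
    expect_true(all(c(st$plant_c_pool, st$plant_p_pool,
                      st$fungus_c_pool, st$fungus_p_pool) >= 0))
  }
})

test_that("swapping roles (alpha,gamma) <-> (beta,epsilon) swaps fitnesses", {
  cases <- draw_params(200, seed = 99)
  for (k in seq_len(nrow(cases))) {
    lc1 <- simulate_lifecycle(cases$alpha[k], cases$beta[k],
                              cases$gamma[k], cases$epsilon[k])
    lc2 <- simulate_lifecycle(cases$beta[k], cases$alpha[k],
                              cases$epsilon[k], cases$gamma[k])
    expect_equal(lc1$plant_fitness, lc2$fungus_fitness, tolerance = 1e-14)
    expect_equal(lc1$fungus_fitness, lc2$plant_fitness, tolerance = 1e-14)
    expect_equal(lc1$total_c_to_fungus, lc2$total_p_to_plant,
                 tolerance = 1e-14)
  }
})

test_that("production batch path equals the scalar ledger on random draws", {
  cases <- draw_params(10000, seed = 2024)
  batch <- lifecycle_batch(0.5, 0.5, cases$gamma, cases$epsilon)
  # mixed-uptake draws exercise the full parameter space scalar-by-scalar
  idx <- seq(1, nrow(cases), by = 13)
  for (k in idx) {
    led <- ledger_lifecycle(cases$alpha[k], cases$beta[k],
                            cases$gamma[k], cases$epsilon[k])
    lc <- simulate_lifecycle(cases$alpha[k], cases$beta[k],
                             cases$gamma[k], cases$epsilon[k])
    expect_equal(lc$plant_fitness, led$plant_fitness, tolerance = 1e-12)
    expect_equal(lc$fungus_fitness, led$fungus_fitness, tolerance = 1e-12)
  }
  # and the compiled batch agrees with the ledger at fixed uptake, all draws
  led_p <- vapply(seq_len(nrow(cases)), function(k)
    ledger_lifecycle(0.5, 0.5, cases$gamma[k], cases$epsilon[k])$plant_fitness,
    1.0)
  expect_equal(batch$plant_fitness, led_p, tolerance = 1e-12)
})

test_that("net transfer totals follow the signed per-step transfers", {
  expect_equal(unname(resources_received(0.3, 0.4, 0, 0)), c(0, 0))
  # plant at alpha=0 stays at biomass 1 and gives 0.3 per step
  rr <- resources_received(0, 0, 0.3, 0)
  expect_equal(unname(rr["total_c_to_fungus"]), 3)
  lc <- simulate_lifecycle(0, 0, 0.3, 0)
  expect_equal(lc$fungus_fitness, 4)
  # nothing to take from a fungus that gathers no C
  rr <- resources_received(0.7, 0, -0.5, 0.2)
  expect_equal(unname(rr["total_c_to_fungus"]), 0)
})
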