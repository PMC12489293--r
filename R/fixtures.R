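#' Generate plain-text test fixtures
#'
#' Emits small JSON fixture files consumed by the test suite: hand-ledger
#' exchange cases (including the clamp branches) with their expected step
#' outcomes, closed-form lifecycle cases, a 5 x 5 landscape at
#' `alpha = beta = 0` with expected viability/interaction structure, and a
#' two-genotype selection scenario with its analytic one-step expectation.
#' Expected step outcomes are written as hand-derivable arithmetic; lifecycle
#' expectations come from [closed_form_fitness()] or the independent
#' [ledger_lifecycle()] bookkeeping, never from the production simulation
#' path.
#'
#' @param dir Writable output directory (created if needed).
#' @return Invisibly, the paths of the written files.
#' @export
generate_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wj <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
    path
  }

  # -- single-step exchange cases, expected pools worked out by hand --------
  exchange <- list(
    list(comment = "plain giving on both sides",
         x = 1, y = 1, alpha = 0.1, beta = 0.2, gamma = 0.3, epsilon = 0.4,
         expected = list(plant_c_pool = 0.7, plant_p_pool = 0.1 + 0.4,
                         fungus_c_pool = 0.2 + 0.3, fungus_p_pool = 0.6,
                         c_transfer = 0.3, p_transfer = 0.4,
                         plant_growth = 0.5, fungus_growth = 0.5)),
    list(comment = "empty-pool clamp: fungus gathered no C",
         x = 1, y = 1, alpha = 0.5, beta = 0, gamma = -0.5, epsilon = 0,
         expected = list(c_transfer = 0, p_transfer = 0,
                         plant_c_pool = 1, fungus_c_pool = 0,
                         plant_p_pool = 0.5, fungus_p_pool = 1,
                         plant_growth = 0.5, fungus_growth = 0)),
    list(comment = "partial-take clamp: plant wants 5 C, fungus has 0.2",
         x = 10, y = 1, alpha = 0, beta = 0.2, gamma = -0.5, epsilon = 0,
         expected = list(c_transfer = -0.2, p_transfer = 0,
                         plant_c_pool = 10.2, fungus_c_pool = 0,
                         plant_p_pool = 0, fungus_p_pool = 1,
                         plant_growth = 0, fungus_growth = 0)),
    list(comment = "gamma = 1 edge: plant gives all its gathered C",
         x = 2, y = 1, alpha = 0.5, beta = 0.1, gamma = 1, epsilon = 0.25,
         expected = list(c_transfer = 2, p_transfer = 0.25,
                         plant_c_pool = 0, fungus_c_pool = 0.1 + 2,
                         plant_p_pool = 1 + 0.25, fungus_p_pool = 0.75,
                         plant_growth = 0, fungus_growth = 0.75)))

  # -- lifecycle cases with closed-form expectations ------------------------
  cf <- function(alpha, beta, gamma, epsilon, steps = 10L) {
    e <- closed_form_fitness(alpha, beta, gamma, epsilon, steps)
    list(alpha = alpha, beta = beta, gamma = gamma, epsilon = epsilon,
         steps = steps,
         expected = list(plant_fitness = unname(e[1L]),
                         fungus_fitness = unname(e[2L])))
  }
  lifecycle <- list(
    cf(0, 0, 0, 0), cf(1, 1, 0, 0), cf(0.1, 0.3, 0, 0), cf(0.2, 0.5, 0, 0),
    cf(0, 0, 0.5, 0.5), cf(0, 0, 1, 1), cf(0, 0, 0.3, 0.3),
    cf(0.2, 0.5, 0, 0, steps = 7L))

  # -- 5 x 5 landscape structure at alpha = beta = 0 ------------------------
  # With no nonspecialised uptake an organism's growth pool is positive only
  # if its partner gives: the viable range is exactly the open first
  # quadrant, where both gain over the no-exchange baseline of 1 (mutualism);
  # everywhere else at least one organism sits exactly at baseline (neutral).
  vals <- seq(-1, 1, length.out = 5L)
  cells <- expand.grid(gamma = vals, epsilon = vals)
  cells$viable <- cells$gamma > 0 & cells$epsilon > 0
  cells$interaction <- ifelse(cells$viable & cells$gamma < 1 & cells$epsilon < 1,
                              "mutualism", "neutral")
  # at gamma = 1 the plant keeps no C (zero growth -> baseline -> neutral);
  # symmetric for epsilon = 1
  cells$viable <- cells$viable & cells$gamma < 1 & cells$epsilon < 1
  landscape5 <- list(alpha = 0, beta = 0, gamma_values = vals,
                     epsilon_values = vals, cells = cells)

  # -- two-genotype selection scenario --------------------------------------
  # Monomorphic fungi so pairing does not matter; expected next-generation
  # share of the fitter plant genotype from the weighted-sampling formula,
  # with weights taken from the independent ledger bookkeeping.
  alpha <- 0.1; beta <- 0.2; eps0 <- 0.4
  gA <- 0.4; gB <- 0.1; nA <- 50L; nB <- 150L
  wA <- ledger_lifecycle(alpha, beta, gA, eps0)$plant_fitness
  wB <- ledger_lifecycle(alpha, beta, gB, eps0)$plant_fitness
  selection <- list(
    alpha = alpha, beta = beta, epsilon = eps0,
    genotype_a = gA, genotype_b = gB, n_a = nA, n_b = nB,
    weight_a = wA, weight_b = wB,
    expected_share_a = nA * wA / (nA * wA + nB * wB))

  paths <- c(wj(exchange, "exchange_cases.json"),
             wj(lifecycle, "lifecycle_cases.json"),
             wj(landscape5, "landscape_5x5.json"),
             wj(selection, "selection_case.json"))
  invisible(paths)
}
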