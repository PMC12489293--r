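# Scalar bookkeeping oracle used across the suite: an explicit
# gather/give/take/clamp/grow ledger for one timestep, independent of the
# package's implementation paths.
oracle_step <- function(x, y, alpha, beta, gamma, epsilon) {
  gathered <- c(plant_c = x, plant_p = alpha * x,
                fungus_p = y, fungus_c = beta * y)
  if (gamma >= 0) {
    move_c <- gamma * gathered[["plant_c"]]
  } else {
    claim <- abs(gamma) * x
    move_c <- -min(claim, gathered[["fungus_c"]])
  }
  if (epsilon >= 0) {
    move_p <- epsilon * gathered[["fungus_p"]]
  } else {
    claim <- abs(epsilon) * y
    move_p <- -min(claim, gathered[["plant_p"]])
  }
  pools <- c(plant_c = gathered[["plant_c"]] - move_c,
             plant_p = gathered[["plant_p"]] + move_p,
             fungus_c = gathered[["fungus_c"]] + move_c,
             fungus_p = gathered[["fungus_p"]] - move_p)
  list(pools = pools, c_transfer = move_c, p_transfer = move_p,
       plant_growth = min(pools[["plant_c"]], pools[["plant_p"]]),
       fungus_growth = min(pools[["fungus_c"]], pools[["fungus_p"]]))
}

oracle_lifecycle <- function(alpha, beta, gamma, epsilon, steps = 10L) {
  x <- 1; y <- 1; ct <- 0; pt <- 0
  for (i in seq_len(steps)) {
    st <- oracle_step(x, y, alpha, beta, gamma, epsilon)
    x <- x + st$plant_growth
    y <- y + st$fungus_growth
    ct <- ct + st$c_transfer
    pt <- pt + st$p_transfer
  }
  list(plant_fitness = x, fungus_fitness = y,
       total_c_to_fungus = ct, total_p_to_plant = pt)
}

# random parameter draws shared by property tests
draw_params <- function(n, seed) {
  set.seed(seed)
  data.frame(alpha = runif(n), beta = runif(n),
             gamma = runif(n, -1, 1), epsilon = runif(n, -1, 1))
}

# Synthetic stationary clouds for parameter-recovery checks.
synth_cloud <- function(n, center, sd = c(0.02, 0.015), rho = 0.3,
                        seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- center[1] + sd[1] * z1
  y <- center[2] + sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  cbind(x, y)
}
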