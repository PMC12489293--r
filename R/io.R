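# Delimited-text writers with a JSON sidecar. Numeric columns are printed
# with %.17g so a write/read cycle reproduces doubles bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, file) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

sidecar_path <- function(file) paste0(file, ".json")

write_sidecar <- function(file, meta) {
  meta$package_version <- as.character(packageVersion("mycotrade"))
  jsonlite::write_json(meta, sidecar_path(file), auto_unbox = TRUE,
                       digits = I(17), null = "null")
}

config_to_list <- function(config) unclass(config)

config_from_list <- function(x) {
  do.call(evolution_config, x[c("alpha", "beta", "population_size",
                                "mutation_sd", "generation_cap",
                                "init_gamma", "init_epsilon",
                                "initial_spread", "steps", "weight")])
}

#' Write / read a landscape as a long table with a JSON sidecar
#'
#' The table holds one row per strategy cell (`gamma`, `epsilon`,
#' `plant_fitness`, `fungus_fitness`, `interaction_type`, `extinction`,
#' `total_p_to_plant`, `total_c_to_fungus`); the sidecar (`<file>.json`)
#' holds the uptake efficiencies, resolution, tolerance, baselines and
#' package version. The round trip is bit-exact.
#'
#' @inheritParams extinction_mask
#' @param file Path of the table; the sidecar is written next to it.
#' @return `write_landscape` returns `file` invisibly; `read_landscape`
#'   returns the reconstructed `"trade_landscape"`.
#' @export
write_landscape <- function(landscape, file) {
  stopifnot(inherits(landscape, "trade_landscape"))
  write_tsv(as.data.frame(landscape), file)
  write_sidecar(file, list(
    alpha = landscape$alpha, beta = landscape$beta,
    n_gamma = length(landscape$gamma), n_epsilon = length(landscape$epsilon),
    tol = landscape$tol, steps = landscape$steps,
    baseline_plant_fitness = landscape$baseline_plant_fitness,
    baseline_fungus_fitness = landscape$baseline_fungus_fitness))
  invisible(file)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(file) {
  meta <- jsonlite::read_json(sidecar_path(file), simplifyVector = TRUE)
  df <- read.delim(file, stringsAsFactors = FALSE)
  ng <- meta$n_gamma; ne <- meta$n_epsilon
  m <- function(col) matrix(df[[col]], ng, ne)
  extinction <- m("extinction")
  structure(list(
    alpha = meta$alpha, beta = meta$beta,
    gamma = df$gamma[seq_len(ng)],
    epsilon = df$epsilon[seq(1L, nrow(df), by = ng)],
    plant_fitness = m("plant_fitness"),
    fungus_fitness = m("fungus_fitness"),
    interaction = m("interaction_type"),
    extinction = extinction,
    viable = extinction == "none",
    total_p_to_plant = m("total_p_to_plant"),
    total_c_to_fungus = m("total_c_to_fungus"),
    baseline_plant_fitness = meta$baseline_plant_fitness,
    baseline_fungus_fitness = meta$baseline_fungus_fitness,
    tol = meta$tol, steps = as.integer(meta$steps)),
    class = "trade_landscape")
}

#' Write / read an evolution trajectory with a JSON run manifest
#'
#' The table holds the per-generation records; the manifest (`<file>.json`)
#' holds the full configuration, seed, outcome and terminal generation —
#' enough to reproduce the run exactly.
#'
#' @param trajectory A [run_evolution()] result.
#' @param file Path of the table; the manifest is written next to it.
#' @return `write_trajectory` returns `file` invisibly; `read_trajectory`
#'   returns the reconstructed `"evolution_trajectory"`.
#' @export
write_trajectory <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "evolution_trajectory"))
  write_tsv(trajectory$records, file)
  write_sidecar(file, list(
    config = config_to_list(trajectory$config),
    seed = trajectory$seed,
    outcome = trajectory$outcome,
    terminal_generation = trajectory$terminal_generation))
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  meta <- jsonlite::read_json(sidecar_path(file), simplifyVector = TRUE)
  records <- read.delim(file, stringsAsFactors = FALSE)
  records$generation <- as.integer(records$generation)
  for (col in c("mean_gamma", "mean_epsilon", "frac_plants_grew",
                "frac_fungi_grew"))
    records[[col]] <- as.double(records[[col]])
  structure(list(records = records,
                 outcome = meta$outcome,
                 terminal_generation = as.integer(meta$terminal_generation),
                 seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed),
                 config = config_from_list(meta$config)),
            class = "evolution_trajectory")
}

#' Write / read a sweep summary with a JSON manifest
#'
#' One table row per uptake efficiency combination plus a manifest holding
#' the value grids, master seed, category percentages and package version.
#' Per-combination reports are not serialised.
#'
#' @param sweep A [run_sweep()] result.
#' @param file Path of the table; the manifest is written next to it.
#' @return `write_sweep` returns `file` invisibly; `read_sweep` returns a
#'   `"trade_sweep"` (with empty `reports`).
#' @export
write_sweep <- function(sweep, file) {
  stopifnot(inherits(sweep, "trade_sweep"))
  write_tsv(sweep$summary, file)
  write_sidecar(file, list(
    alpha_values = sweep$alpha_values,
    beta_values = sweep$beta_values,
    seed = sweep$seed,
    percentages = sweep$percentages))
  invisible(file)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(file) {
  meta <- jsonlite::read_json(sidecar_path(file), simplifyVector = TRUE)
  summary <- read.delim(file, stringsAsFactors = FALSE)
  summary$replicates_remaining <- as.integer(summary$replicates_remaining)
  structure(list(summary = summary,
                 percentages = as.list(meta$percentages),
                 alpha_values = meta$alpha_values,
                 beta_values = meta$beta_values,
                 seed = meta$seed,
                 reports = list()),
            class = "trade_sweep")
}
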