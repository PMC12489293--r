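#' Plot a landscape layer
#'
#' Raster map of one landscape layer over the strategy plane. The interaction
#' layer uses light blue = mutualism, green = plant parasitic, orange =
#' fungus parasitic, yellow = competition, white = neutral; the extinction
#' layer shades light/medium/dark grey for plant-only/fungus-only/both.
#'
#' @param x A `"trade_landscape"`.
#' @param layer One of `"interaction"`, `"extinction"`, `"plant_fitness"`,
#'   `"fungus_fitness"`, `"total_p_to_plant"`, `"total_c_to_fungus"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.trade_landscape <- function(x, layer = "interaction", ...) {
  layer <- match.arg(layer, c("interaction", "extinction", "plant_fitness",
                              "fungus_fitness", "total_p_to_plant",
                              "total_c_to_fungus"))
  main <- sprintf("%s (alpha=%g, beta=%g)", layer, x$alpha, x$beta)
  if (layer %in% c("interaction", "extinction")) {
    lv <- if (layer == "interaction") {
      c(mutualism = "#9ecae1", plant_parasitic = "#74c476",
        fungus_parasitic = "#fd8d3c", competition = "#ffeda0",
        neutral = "#ffffff")
    } else {
      c(none = "#ffffff", plant_only = "#d9d9d9", fungus_only = "#969696",
        both = "#525252")
    }
    z <- matrix(match(x[[layer]], names(lv)), nrow = length(x$gamma))
    graphics::image(x$gamma, x$epsilon, z, col = lv,
                    zlim = c(1, length(lv)), xlab = "gamma (plant C to fungus)",
                    ylab = "epsilon (fungus P to plant)", main = main,
                    useRaster = TRUE, ...)
  } else {
    graphics::image(x$gamma, x$epsilon, x[[layer]],
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "gamma (plant C to fungus)",
                    ylab = "epsilon (fungus P to plant)", main = main,
                    useRaster = TRUE, ...)
  }
  invisible(x)
}

#' Plot an evolutionary trajectory in strategy space
#'
#' Mean resource exchange strategy per generation, optionally over the
#' landscape's interaction-type map.
#'
#' @param x An `"evolution_trajectory"`.
#' @param landscape Optional `"trade_landscape"` background.
#' @param ... Passed to plotting primitives.
#' @export
plot.evolution_trajectory <- function(x, landscape = NULL, ...) {
  r <- x$records
  if (!is.null(landscape)) {
    plot(landscape, layer = "interaction")
    graphics::points(r$mean_gamma, r$mean_epsilon, pch = 16, cex = 0.3, ...)
  } else {
    plot(r$mean_gamma, r$mean_epsilon, type = "p", pch = 16, cex = 0.3,
         xlim = c(-1, 1), ylim = c(-1, 1),
         xlab = "mean gamma", ylab = "mean epsilon",
         main = sprintf("alpha=%g beta=%g: %s", x$config$alpha,
                        x$config$beta, x$outcome), ...)
  }
  graphics::points(r$mean_gamma[1L], r$mean_epsilon[1L], pch = 21,
                   bg = "blue", cex = 1.2)
  graphics::points(r$mean_gamma[nrow(r)], r$mean_epsilon[nrow(r)], pch = 21,
                   bg = "orange", cex = 1.2)
  invisible(x)
}
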