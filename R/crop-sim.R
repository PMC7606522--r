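#' Configuration for the synthetic crop map
#'
#' Per grid cell, the generator draws area shares for the configured crops
#' plus an implicit "other/none" remainder from a symmetric Dirichlet
#' distribution (so shares are nonnegative and sum to at most 1), and lays
#' out one contiguous growing season per crop anchored to the cell's local
#' temperature seasonality: the season starts at `warmest month +
#' season_start_rule[crop]` (months, modular) and runs for
#' `season_length_months[crop]` months.
#'
#' @param crops Crop names.
#' @param share_concentration Dirichlet concentration; small values give
#'   near single-crop cells, `0` is the degenerate case where each cell is
#'   assigned exactly one crop with share 1.
#' @param season_length_months Named integer vector, months in `[1, 12]`.
#' @param season_start_rule Named integer vector of month offsets relative
#'   to the cell's warmest month.
#' @return A `crop_map_config` list.
#' @export
crop_map_config <- function(crops = c("maize", "wheat", "rice"),
                            share_concentration = 0.5,
                            season_length_months = c(maize = 5, wheat = 4,
                                                     rice = 4),
                            season_start_rule = c(maize = -2, wheat = 3,
                                                  rice = 0)) {
  if (any(season_length_months < 1 | season_length_months > 12)) {
    abort_hg("season lengths must be in [1, 12]", "crop_config_error")
  }
  if (!all(crops %in% names(season_length_months)) ||
      !all(crops %in% names(season_start_rule))) {
    abort_hg("season parameters must be named for every crop", "crop_config_error")
  }
  structure(list(crops = crops, share_concentration = share_concentration,
                 season_length_months = season_length_months,
                 season_start_rule = season_start_rule),
            class = "crop_map_config")
}

#' Generate a synthetic crop map for a climate grid
#'
#' @param config A [crop_map_config()].
#' @param grid A `climate_grid`.
#' @param seed Integer master seed (crop substream).
#' @return A `crop_map` tibble: one row per (cell, crop) with the area
#'   `share` in `[0, 1]` (summing to at most 1 within each cell) and the
#'   season as `season_start` (calendar month) and `season_len`.
#' @export
generate_crop_map <- function(config, grid, seed = 1) {
  stopifnot(inherits(config, "crop_map_config"), inherits(grid, "climate_grid"))
  nc <- nrow(grid$cells)
  k <- length(config$crops)

  # warmest calendar month per cell from the grid climatology
  mon <- ym_month(grid$months)
  clim <- vapply(1:12, function(m) {
    rowMeans(grid$temp[, mon == m, drop = FALSE])
  }, numeric(nc))
  warmest <- max.col(clim, ties.method = "first")

  withr::with_seed(substream_seed(seed, "crops"), {
    if (config$share_concentration == 0) {
      pick <- sample.int(k, nc, replace = TRUE)
      shares <- matrix(0, nc, k)
      shares[cbind(seq_len(nc), pick)] <- 1
    } else {
      g <- matrix(stats::rgamma(nc * (k + 1), shape = config$share_concentration),
                  nc, k + 1)
      shares <- (g / rowSums(g))[, seq_len(k), drop = FALSE]
    }
  })

  out <- purrr::map_dfr(seq_along(config$crops), function(j) {
    crop <- config$crops[j]
    len <- config$season_length_months[[crop]]
    start <- (warmest - 1 + config$season_start_rule[[crop]]) %% 12 + 1
    tibble::tibble(cell = grid$cells$cell, crop = crop,
                   share = shares[, j],
                   season_start = as.integer(start),
                   season_len = as.integer(len))
  })
  out <- dplyr::arrange(out, .data$cell, .data$crop)
  class(out) <- c("crop_map", class(out))
  out
}

#' Growing-season calendar months for one cell and crop
#'
#' @param cropmap A `crop_map`.
#' @param cell Cell index.
#' @param crop Crop name.
#' @return Integer vector of calendar months (1-12), contiguous modulo 12.
#' @export
season_months <- function(cropmap, cell, crop) {
  row <- cropmap[cropmap$cell == cell & cropmap$crop == crop, ]
  if (nrow(row) != 1) abort_hg("crop not present in map for this cell",
                               "crop_config_error")
  (row$season_start - 1 + seq_len(row$season_len) - 1) %% 12 + 1
}
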