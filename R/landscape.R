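# Landscape projection: which genotype (and hence which species ancestry)
# the fitted model expects to perform best in each climate-grid cell,
# under historic and future winter temperatures.

#' Read a tabular climate grid
#'
#' @param path CSV with columns `cell_id`, `lon`, `lat`, `mcmt_historic`,
#'   `mcmt_future`.
#' @return validated data frame.
#' @export
read_climate_grid <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lon", "lat", "mcmt_historic", "mcmt_future")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols)) {
    stop("climate grid lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(g$cell_id)) stop("duplicate cell ids")
  g
}

#' Best-performing genotype per climate-grid cell
#'
#' For every unmasked cell, evaluates each genotype's combined fitness
#' (population level) at the cell's MCMT and records the winner and its
#' species-ancestry proportion. Cells with MCMT outside `mask_range` are
#' masked. Ties are broken by genotype id order and logged as an
#' attribute. The default mask is the garden-observed winter-temperature
#' window used for the published maps (-13.05 to 10.85 C); the somewhat
#' wider garden range itself can be passed instead.
#'
#' @param fit a `zigmm`.
#' @param genotypes data frame of genotype covariates (with `ancestry`).
#' @param grid data frame from [read_climate_grid()] (or equivalent).
#' @param scenario `"historic"` or `"future"` (selects the MCMT column).
#' @param mask_range ordered length-2 numeric, degrees C.
#' @return a `projection_map` data frame: cell_id, lon, lat, mcmt, masked,
#'   best_genotype, best_ancestry, best_fitness, scenario.
#' @export
best_genotype_per_cell <- function(fit, genotypes, grid,
                                   scenario = c("historic", "future"),
                                   mask_range = c(-13.05, 10.85)) {
  scenario <- match.arg(scenario)
  stopifnot(nrow(genotypes) > 0, mask_range[1] <= mask_range[2])
  mcmt <- grid[[paste0("mcmt_", scenario)]]
  masked <- !is.finite(mcmt) | mcmt < mask_range[1] | mcmt > mask_range[2]
  # genotype ordering fixes tie-breaking
  genotypes <- genotypes[order(genotypes$genotype), , drop = FALSE]
  if (all(masked)) {
    warning("all cells masked")
    out <- data.frame(cell_id = grid$cell_id, lon = grid$lon,
                      lat = grid$lat, mcmt = mcmt, masked = TRUE,
                      best_genotype = NA_character_,
                      best_ancestry = NA_real_, best_fitness = NA_real_,
                      scenario = scenario, stringsAsFactors = FALSE)
    attr(out, "tie_cells") <- character(0)
    class(out) <- c("projection_map", class(out))
    return(out)
  }
  umcmt <- unique(mcmt[!masked])
  # fitness matrix: unique MCMT values x genotypes
  fitmat <- vapply(seq_len(nrow(genotypes)), function(i) {
    nd <- data.frame(garden_MCMT = umcmt,
                     home_MCMT = genotypes$home_MCMT[i],
                     PC1 = genotypes$PC1[i], PC2 = genotypes$PC2[i],
                     PC3 = genotypes$PC3[i])
    stats::predict(fit, nd, component = "response",
                   include_random = FALSE)
  }, numeric(length(umcmt)))
  if (length(umcmt) == 1) fitmat <- matrix(fitmat, nrow = 1)
  win_idx <- apply(fitmat, 1, which.max)
  ties <- apply(fitmat, 1, function(r) sum(r == max(r)) > 1)
  lookup <- match(mcmt, umcmt)
  out <- data.frame(
    cell_id = grid$cell_id, lon = grid$lon, lat = grid$lat,
    mcmt = mcmt, masked = masked,
    best_genotype = ifelse(masked, NA_character_,
                           genotypes$genotype[win_idx[lookup]]),
    best_ancestry = ifelse(masked, NA_real_,
                           genotypes$ancestry[win_idx[lookup]]),
    best_fitness = ifelse(masked, NA_real_,
                          fitmat[cbind(lookup, win_idx[lookup])]),
    scenario = scenario,
    stringsAsFactors = FALSE
  )
  tie_cells <- out$cell_id[!out$masked & ties[lookup]]
  if (length(tie_cells)) {
    message(length(tie_cells), " cell(s) had tied winners; ",
            "first genotype id kept")
  }
  attr(out, "tie_cells") <- tie_cells
  class(out) <- c("projection_map", class(out))
  out
}

#' Ancestry shift between two projection scenarios
#'
#' Future winner ancestry minus historic winner ancestry per cell; cells
#' masked in either scenario are masked in the shift.
#'
#' @param historic,future `projection_map` objects over the same cells.
#' @return data frame: cell_id, lon, lat, masked, ancestry_historic,
#'   ancestry_future, shift.
#' @export
ancestry_shift <- function(historic, future) {
  if (!identical(historic$cell_id, future$cell_id)) {
    stop("projection maps cover different cell sets")
  }
  masked <- historic$masked | future$masked
  data.frame(
    cell_id = historic$cell_id, lon = historic$lon, lat = historic$lat,
    masked = masked,
    ancestry_historic = ifelse(masked, NA_real_, historic$best_ancestry),
    ancestry_future = ifelse(masked, NA_real_, future$best_ancestry),
    shift = ifelse(masked, NA_real_,
                   future$best_ancestry - historic$best_ancestry)
  )
}

#' Generate a synthetic climate grid
#'
#' A stand-in for the external climate rasters: random cells over a
#' lon/lat box with historic MCMT drawn over a range and future MCMT
#' warmer by a configurable mean shift.
#'
#' @param n_cells number of cells.
#' @param mcmt_range historic MCMT range (degrees C).
#' @param warming mean future-minus-historic MCMT shift (degrees C).
#' @param seed integer seed.
#' @return data frame in the [read_climate_grid()] schema.
#' @export
gen_climate_grid <- function(n_cells = 1000, mcmt_range = c(-30, 12),
                             warming = 3, seed = 1) {
  set.seed(.split_seed(seed, 5))
  hist <- stats::runif(n_cells, mcmt_range[1], mcmt_range[2])
  data.frame(
    cell_id = sprintf("c%05d", seq_len(n_cells)),
    lon = stats::runif(n_cells, -150, -100),
    lat = stats::runif(n_cells, 40, 65),
    mcmt_historic = hist,
    mcmt_future = hist + stats::rnorm(n_cells, warming, 0.5)
  )
}
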