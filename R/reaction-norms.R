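# Genotype-specific reaction norms over a continuous winter-temperature
# grid, transfer-distance curves, and provenance-level future change.

#' Equally spaced MCMT grid
#'
#' @param min,max endpoints in degrees C (both included).
#' @param n number of grid points (>= 2).
#' @return numeric vector, strictly increasing.
#' @export
mcmt_grid <- function(min = -23.9, max = 9.8, n = 100) {
  stopifnot(min < max, n >= 2)
  seq(min, max, length.out = n)
}

#' Predict a genotype's reaction norm
#'
#' Population-level predictions (no random modes) of growth, mortality
#' probability and combined fitness for one genotype across an MCMT grid,
#' using its home climate and genomic PC scores as the genotype-specific
#' inputs. Grid points outside the garden-observed MCMT range are flagged
#' `extrapolated`; the optimum is the grid argmax of combined fitness
#' (first, i.e. coldest, index on ties).
#'
#' @param fit a `zigmm`.
#' @param genotype one-row data frame (or list) with `genotype`,
#'   `home_MCMT`, `PC1`, `PC2`, `PC3` and optionally `ancestry`.
#' @param grid MCMT values, e.g. [mcmt_grid()].
#' @return a `reaction_norm` data frame: genotype, mcmt, growth,
#'   p_mortality, fitness, extrapolated; attributes `optimum_mcmt`,
#'   `ancestry`.
#' @export
genotype_reaction_norm <- function(fit, genotype, grid = mcmt_grid()) {
  stopifnot(all(is.finite(grid)))
  nd <- data.frame(garden_MCMT = grid,
                   home_MCMT = genotype$home_MCMT[1],
                   PC1 = genotype$PC1[1], PC2 = genotype$PC2[1],
                   PC3 = genotype$PC3[1])
  pr <- stats::predict(fit, nd, include_random = FALSE)
  rng <- fit$garden_mcmt_range
  out <- data.frame(
    genotype = if (!is.null(genotype$genotype)) genotype$genotype[1] else NA,
    mcmt = grid,
    growth = pr$conditional,
    p_mortality = pr$zprob,
    fitness = pr$response,
    extrapolated = grid < rng[1] | grid > rng[2]
  )
  attr(out, "optimum_mcmt") <- grid[which.max(out$fitness)]
  attr(out, "ancestry") <- if (!is.null(genotype$ancestry))
    genotype$ancestry[1] else NA_real_
  class(out) <- c("reaction_norm", class(out))
  out
}

#' Reaction norms for a set of genotypes, long format
#'
#' @param fit a `zigmm`.
#' @param genotypes data frame of genotype covariates (one row per
#'   genotype).
#' @param grid MCMT values.
#' @return long data frame stacking [genotype_reaction_norm()] results,
#'   with an `optimum_mcmt` column repeated per genotype.
#' @export
reaction_norms <- function(fit, genotypes, grid = mcmt_grid()) {
  out <- lapply(seq_len(nrow(genotypes)), function(i) {
    rn <- genotype_reaction_norm(fit, genotypes[i, ], grid)
    rn$optimum_mcmt <- attr(rn, "optimum_mcmt")
    rn$ancestry <- attr(rn, "ancestry")
    rn
  })
  do.call(rbind, out)
}

#' Shift a reaction norm to the climate-transfer-distance axis
#'
#' Transfer distance is garden MCMT minus home MCMT: positive means the
#' genotype is growing somewhere warmer than its origin. Values are
#' unchanged; only the x-axis shifts.
#'
#' @param norm a `reaction_norm`.
#' @param home_mcmt the genotype's home MCMT (degrees C).
#' @return the norm with a `transfer_distance` column.
#' @export
transfer_distance_curve <- function(norm, home_mcmt) {
  norm$transfer_distance <- norm$mcmt - home_mcmt
  norm
}

#' Per-genotype fitness change between historic and future home climate
#'
#' Evaluates each genotype's fitted reaction norm at its provenance's
#' historic and future MCMT and reports the change in growth, mortality
#' probability and combined fitness (future minus historic, exactly).
#'
#' @param fit a `zigmm`.
#' @param genotypes data frame with genotype covariates and `home_MCMT`
#'   (historic).
#' @param future_mcmt per-genotype future MCMT (same order), or a single
#'   value recycled.
#' @return data frame: one row per genotype with historic/future values
#'   and deltas for all three components.
#' @export
provenance_future_change <- function(fit, genotypes, future_mcmt) {
  n <- nrow(genotypes)
  future_mcmt <- rep_len(future_mcmt, n)
  eval_at <- function(mcmt) {
    nd <- data.frame(garden_MCMT = mcmt, home_MCMT = genotypes$home_MCMT,
                     PC1 = genotypes$PC1, PC2 = genotypes$PC2,
                     PC3 = genotypes$PC3)
    stats::predict(fit, nd, include_random = FALSE)
  }
  hist <- eval_at(genotypes$home_MCMT)
  fut <- eval_at(future_mcmt)
  data.frame(
    genotype = genotypes$genotype,
    historic_mcmt = genotypes$home_MCMT, future_mcmt = future_mcmt,
    growth_historic = hist$conditional, growth_future = fut$conditional,
    p_historic = hist$zprob, p_future = fut$zprob,
    fitness_historic = hist$response, fitness_future = fut$response,
    delta_growth = fut$conditional - hist$conditional,
    delta_p = fut$zprob - hist$zprob,
    delta_fitness = fut$response - hist$response
  )
}
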