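# AIC-based scan over candidate climate variables.

#' Rank candidate climate variables by model AIC
#'
#' Refits the growth model with each candidate variable in the role of
#' the climate axis (both garden-year value and genotype home value) and
#' ranks the fits by AIC. Following the study protocol the block random
#' term is dropped so that every candidate converges, and a single
#' measurement year is used. The dataset must carry columns
#' `garden_<var>` and `home_<var>` for every candidate (for `"MCMT"` the
#' standard columns are used).
#'
#' @param dataset an `analysis_dataset` whose `data` retains the candidate
#'   columns.
#' @param candidate_variables character vector, e.g.
#'   `c("MCMT", "MAT", "MWMT")`.
#' @param year measurement year to fit (single).
#' @param spec base model specification (default [make_model("full")] with
#'   the block term dropped).
#' @param zero_density,control passed to [fit_zigmm()].
#' @return data frame ranked by AIC: variable, aic, loglik, converged.
#' @export
climate_scan <- function(dataset, candidate_variables, year,
                         spec = NULL, zero_density = "point_mass",
                         control = list()) {
  stopifnot(length(year) == 1)
  if (is.null(spec)) spec <- make_model("full")
  # block is dropped per the scan protocol; a single measurement year also
  # degenerates the year factor (one level) and the individual factor (one
  # record per tree), so the scan keeps genotype only
  spec$random <- intersect(spec$random, "genotype")
  spec$zi_random <- intersect(spec$zi_random, "genotype")
  df <- dataset$data
  df <- df[df$year %in% year, , drop = FALSE]
  if (nrow(df) == 0) stop("no records for year ", year)
  rows <- lapply(candidate_variables, function(v) {
    gcol <- if (v == "MCMT") "garden_MCMT" else paste0("garden_", v)
    hcol <- if (v == "MCMT") "home_MCMT" else paste0("home_", v)
    if (!all(c(gcol, hcol) %in% names(df))) {
      stop("candidate variable '", v, "' needs columns ", gcol, " and ",
           hcol)
    }
    d2 <- df
    d2$garden_MCMT <- df[[gcol]]
    d2$home_MCMT <- df[[hcol]]
    ds2 <- .subset_dataset(dataset, d2)
    res <- tryCatch({
      fit <- fit_zigmm(spec, ds2, zero_density = zero_density,
                       control = control)
      data.frame(variable = v, aic = fit$aic, loglik = fit$loglik,
                 converged = isTRUE(fit$convergence))
    }, error = function(e) data.frame(variable = v, aic = NA_real_,
                                      loglik = NA_real_,
                                      converged = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
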