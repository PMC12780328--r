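# Prediction from a fitted zero-inflated Gaussian mixed model.

#' Predict growth, mortality probability and combined response
#'
#' Computes, for each row of `newdata`, the conditional mean growth
#' (back-transformed to cm), the structural-zero (mortality) probability,
#' and the combined response `(1 - p) * growth`, the overall fitness
#' proxy. Population-level prediction (`include_random = FALSE`) uses the
#' fixed effects only; `include_random = TRUE` adds the posterior modes of
#' all random intercepts, and a character vector selects a subset of
#' factors (e.g. genotype and year modes but population-level garden, the
#' convention for predicting into a garden the model has never seen).
#'
#' @param object a fitted `zigmm`.
#' @param newdata data frame with raw covariate columns (`garden_MCMT`,
#'   `home_MCMT`, `PC1`-`PC3` as the spec requires) and, when random modes
#'   are requested, the corresponding identifier columns.
#' @param component `"all"` (default, returns a data frame with every
#'   component) or one of `"conditional"`, `"zprob"`, `"response"` to get a
#'   numeric vector. `"conditional"` is in cm; `"mu"` gives the
#'   conditional mean on the transformed scale.
#' @param include_random `FALSE` (population level), `TRUE`, or a character
#'   vector of factor names. Unseen levels of an included factor are an
#'   error.
#' @param ... unused.
#' @return data frame (`mu`, `conditional`, `zprob`, `response`) or a
#'   numeric vector.
#' @export
predict.zigmm <- function(object, newdata,
                          component = c("all", "response", "conditional",
                                        "zprob", "mu"),
                          include_random = FALSE, ...) {
  component <- match.arg(component)
  df <- .scale_newdata(object, newdata)
  X <- .fixed_matrix(df, object$spec$cond_terms)
  mu <- as.numeric(X %*% object$beta)
  if (!is.null(object$gamma)) {
    Xz <- .fixed_matrix(df, object$spec$zi_terms)
    eta <- as.numeric(Xz %*% object$gamma)
  } else {
    eta <- rep(-Inf, nrow(df))
  }

  fac_request <- function(part_factors, modes) {
    if (isTRUE(include_random)) return(intersect(part_factors,
                                                 names(modes)))
    if (isFALSE(include_random)) return(character(0))
    intersect(include_random, part_factors)
  }
  add_modes <- function(lin, factors, modes) {
    for (f in factors) {
      key <- switch(f,
                    block = paste(df$garden, df$block, sep = ":"),
                    genotype = as.character(df$genotype),
                    year = as.character(df$year),
                    individual = as.character(df$individual))
      m <- modes[[f]]
      unseen <- setdiff(unique(key), names(m))
      if (length(unseen)) {
        stop("unseen level(s) of random factor '", f, "': ",
             paste(utils::head(unseen, 10), collapse = ", "))
      }
      lin <- lin + as.numeric(m[key])
    }
    lin
  }
  mu <- add_modes(mu, fac_request(object$spec$random,
                                  object$re_modes$cond),
                  object$re_modes$cond)
  if (!is.null(object$gamma)) {
    eta <- add_modes(eta, fac_request(object$spec$zi_random,
                                      object$re_modes$zi),
                     object$re_modes$zi)
  }
  p <- stats::plogis(eta)
  conditional <- inverse_transform_growth(mu)
  response <- (1 - p) * conditional
  out <- data.frame(mu = mu, conditional = conditional, zprob = p,
                    response = response)
  if (component == "all") out else out[[component]]
}

.scale_newdata <- function(object, newdata) {
  need <- c("garden_MCMT", "home_MCMT", "PC1", "PC2", "PC3")
  have_raw <- all(need %in% names(newdata))
  have_scaled <- all(c("g_s", "h_s", "pc1_s", "pc2_s", "pc3_s") %in%
                       names(newdata))
  if (!have_raw && !have_scaled) {
    stop("newdata lacks column(s): ",
         paste(setdiff(need, names(newdata)), collapse = ", "))
  }
  if (have_raw) {
    # always rescale from the raw columns with the training divisors, so
    # that predictions from a fit trained on a subset are consistent
    s <- object$scaling
    newdata$g_s <- newdata$garden_MCMT / s[["garden_MCMT"]]
    newdata$h_s <- newdata$home_MCMT / s[["home_MCMT"]]
    newdata$pc1_s <- newdata$PC1 / s[["PC1"]]
    newdata$pc2_s <- newdata$PC2 / s[["PC2"]]
    newdata$pc3_s <- newdata$PC3 / s[["PC3"]]
  }
  newdata
}
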