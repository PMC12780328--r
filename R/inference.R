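# Wald inference on the fixed effects.

#' Type II Wald chi-squared tests
#'
#' Tests each fixed-effect term respecting marginality: term `t` is tested
#' adjusted for every other term except its higher-order relatives (terms
#' whose variable set strictly contains `t`'s). With `W(S)` the Wald
#' statistic of the joint hypothesis that all coefficients in `S` are
#' zero, the type II statistic for `t` with relatives `R` is
#' `W(R + t) - W(R)`; for a term with no relatives this reduces to the
#' squared z statistic. The result does not depend on the order in which
#' terms were specified.
#'
#' @param fit a `zigmm`.
#' @param component `"conditional"`, `"zi"`, or `"both"` (default).
#' @return data frame with component, term, chisq, df, p.
#' @export
wald_type2 <- function(fit, component = c("both", "conditional", "zi")) {
  component <- match.arg(component)
  one_part <- function(coefs, vcov, terms, label) {
    if (is.null(coefs)) return(NULL)
    res <- lapply(terms, function(t) {
      rel <- terms[vapply(terms, function(u) {
        u != t && all(.term_vars(t) %in% .term_vars(u)) &&
          length(.term_vars(u)) > length(.term_vars(t))
      }, TRUE)]
      w_of <- function(set) {
        if (length(set) == 0) return(0)
        b <- coefs[set]
        V <- vcov[set, set, drop = FALSE]
        as.numeric(t(b) %*% solve(V, b))
      }
      chisq <- max(w_of(c(rel, t)) - w_of(rel), 0)
      data.frame(component = label, term = t, chisq = chisq, df = 1L,
                 p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
    })
    do.call(rbind, res)
  }
  out <- list()
  if (component %in% c("both", "conditional")) {
    out$cond <- one_part(fit$beta, fit$vcov_beta, fit$spec$cond_terms,
                         "conditional")
  }
  if (component %in% c("both", "zi") && !is.null(fit$gamma)) {
    out$zi <- one_part(fit$gamma, fit$vcov_gamma, fit$spec$zi_terms, "zi")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Standardized fixed-effect estimates with confidence intervals
#'
#' Puts coefficients on a comparable scale across terms. The default
#' (`"sd_ratio"`) multiplies each conditional coefficient by the SD of its
#' design column and divides by the SD of the (transformed) response of
#' survivors, the usual standardized-beta convention; `"sd_x"` multiplies
#' by the predictor SD only. Zero-inflation coefficients act on a latent
#' logit with no observable SD, so they are always standardized by the
#' predictor SD alone.
#'
#' @param fit a `zigmm`.
#' @param dataset the `analysis_dataset` the model was fitted to.
#' @param method `"sd_ratio"` (default) or `"sd_x"`.
#' @param level confidence level (default 0.95).
#' @return data frame: component, term, estimate, se, std_estimate,
#'   ci_low, ci_high.
#' @export
standardized_estimates <- function(fit, dataset,
                                   method = c("sd_ratio", "sd_x"),
                                   level = 0.95) {
  method <- match.arg(method)
  df <- dataset$data
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  sd_y <- stats::sd(df$y[df$y > 0])
  one_part <- function(coefs, vcov, terms, label, use_ratio) {
    if (is.null(coefs)) return(NULL)
    X <- .fixed_matrix(df, terms)
    res <- lapply(terms, function(t) {
      sdx <- stats::sd(X[, t])
      if (sdx == 0) stop("zero-SD predictor: ", t)
      fac <- if (use_ratio) sdx / sd_y else sdx
      est <- coefs[[t]]
      se <- sqrt(vcov[t, t])
      data.frame(component = label, term = t, estimate = est, se = se,
                 std_estimate = est * fac,
                 ci_low = (est - zcrit * se) * fac,
                 ci_high = (est + zcrit * se) * fac)
    })
    do.call(rbind, res)
  }
  res <- rbind(
    one_part(fit$beta, fit$vcov_beta, fit$spec$cond_terms, "conditional",
             method == "sd_ratio"),
    if (!is.null(fit$gamma)) {
      one_part(fit$gamma, fit$vcov_gamma, fit$spec$zi_terms, "zi", FALSE)
    }
  )
  rownames(res) <- NULL
  res
}
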