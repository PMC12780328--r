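# Predictive-ability evaluation: training-fit correlations,
# leave-one-garden-out cross-validation, transfer to novel genotypes and
# sites, mortality calibration, and model comparison.

#' Pearson correlation between observed and predicted growth
#'
#' @param observed,predicted equal-length growth vectors (cm).
#' @param drop_dead if `TRUE`, records of dead trees are removed first
#'   (the conditional-component convention: the growth part of the model
#'   predicts survivors only).
#' @param dead logical vector flagging dead records; defaults to
#'   `observed == 0` (the structural-zero coding).
#' @return Pearson r.
#' @export
prediction_correlation <- function(observed, predicted, drop_dead = FALSE,
                                   dead = observed == 0) {
  stopifnot(length(observed) == length(predicted))
  if (drop_dead) {
    observed <- observed[!dead]
    predicted <- predicted[!dead]
  }
  if (length(observed) < 3) stop("fewer than 3 records after filtering")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(observed, predicted)
}

#' Training-fit correlations of a fitted model
#'
#' Convenience wrapper computing the observed-vs-predicted Pearson r on
#' the data the model was fitted to, for the overall and conditional
#' components, with or without random-effect modes.
#'
#' @param fit a `zigmm`.
#' @param dataset the training `analysis_dataset`.
#' @param include_random passed to [predict.zigmm()].
#' @return named vector `c(overall = , conditional = )`.
#' @export
training_correlations <- function(fit, dataset, include_random = TRUE) {
  pr <- stats::predict(fit, dataset$data, include_random = include_random)
  c(overall = prediction_correlation(dataset$data$growth_cm, pr$response),
    conditional = prediction_correlation(dataset$data$growth_cm,
                                         pr$conditional, drop_dead = TRUE,
                                         dead = dataset$data$dead))
}

#' Leave-one-garden-out cross-validation
#'
#' One fold per garden: the model is refitted with that garden's records
#' excluded and its growth predicted from the refit. Held-out predictions
#' use the genotype and year random modes (all genotypes appear in
#' training by design) but population-level garden and block effects —
#' the only defensible convention for a garden the refit has never seen.
#' Folds that fail to converge are flagged and excluded from the yearly
#' means with a warning.
#'
#' @param dataset an `analysis_dataset`.
#' @param spec a [model_spec()].
#' @param zero_density,control passed to [fit_zigmm()].
#' @return a `cv_result`: data frame of per (garden, year, component)
#'   Pearson r with fold metadata, plus `summary` (mean r per year and
#'   component over converged folds).
#' @export
loo_garden_cv <- function(dataset, spec, zero_density = "point_mass",
                          control = list()) {
  df <- dataset$data
  gardens <- sort(unique(df$garden))
  if (length(gardens) < 3) stop("need at least 3 gardens for garden-level CV")
  rows <- list()
  for (g in gardens) {
    train <- df[df$garden != g, , drop = FALSE]
    test <- df[df$garden == g, , drop = FALSE]
    train_ds <- .subset_dataset(dataset, train)
    fold <- tryCatch({
      fit <- fit_zigmm(spec, train_ds, zero_density = zero_density,
                       control = control)
      pr <- stats::predict(fit, test,
                           include_random = c("genotype", "year"))
      list(fit = fit, pr = pr, ok = isTRUE(fit$convergence))
    }, error = function(e) list(ok = FALSE, err = conditionMessage(e)))
    for (yr in sort(unique(test$year))) {
      sel <- test$year == yr
      mk <- function(component, r) {
        data.frame(garden = g, year = yr, component = component, r = r,
                   n = sum(sel), converged = isTRUE(fold$ok))
      }
      if (!isTRUE(fold$ok)) {
        rows[[length(rows) + 1]] <- mk("overall", NA_real_)
        rows[[length(rows) + 1]] <- mk("conditional", NA_real_)
        next
      }
      r_overall <- tryCatch(
        prediction_correlation(test$growth_cm[sel], fold$pr$response[sel]),
        error = function(e) NA_real_)
      r_cond <- tryCatch(
        prediction_correlation(test$growth_cm[sel],
                               fold$pr$conditional[sel], drop_dead = TRUE,
                               dead = test$dead[sel]),
        error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- mk("overall", r_overall)
      rows[[length(rows) + 1]] <- mk("conditional", r_cond)
    }
  }
  folds <- do.call(rbind, rows)
  if (any(!folds$converged)) {
    warning(sum(!folds$converged) / 2, " fold(s) did not converge; ",
            "excluded from yearly means")
  }
  ok <- folds[folds$converged & !is.na(folds$r), , drop = FALSE]
  summary <- stats::aggregate(r ~ year + component, data = ok, FUN = mean)
  structure(list(folds = folds, summary = summary), class = "cv_result")
}

.subset_dataset <- function(dataset, rows) {
  # rebuild scaling on the subset so refits are self-contained
  ds <- dataset
  rows <- droplevels(rows)
  scaling <- c(
    garden_MCMT = scale_no_center(rows$garden_MCMT)$divisor,
    home_MCMT = scale_no_center(rows$home_MCMT)$divisor,
    PC1 = scale_no_center(rows$PC1)$divisor,
    PC2 = scale_no_center(rows$PC2)$divisor,
    PC3 = scale_no_center(rows$PC3)$divisor
  )
  rows$g_s <- rows$garden_MCMT / scaling[["garden_MCMT"]]
  rows$h_s <- rows$home_MCMT / scaling[["home_MCMT"]]
  rows$pc1_s <- rows$PC1 / scaling[["PC1"]]
  rows$pc2_s <- rows$PC2 / scaling[["PC2"]]
  rows$pc3_s <- rows$PC3 / scaling[["PC3"]]
  ds$data <- rows
  ds$scaling <- scaling
  ds$garden_mcmt_range <- range(rows$garden_MCMT)
  ds
}

#' Transfer evaluation on the large evaluation gardens
#'
#' Predicts growth of (mostly novel) genotypes at the evaluation gardens
#' from a model trained on the small-garden trial, at population level
#' for garden and genotype (year modes are used when the year was seen in
#' training). Genotypes lacking PC scores are excluded with a count.
#'
#' @param fit a `zigmm` trained on the mini-garden data.
#' @param maxi_dataset an `analysis_dataset` built from the evaluation
#'   (maxi) garden tables.
#' @return data frame with one row per garden x component and the Pearson
#'   r, plus attribute `n_excluded_missing_pc`.
#' @export
maxi_transfer_eval <- function(fit, maxi_dataset) {
  df <- maxi_dataset$data
  has_pc <- stats::complete.cases(df[c("PC1", "PC2", "PC3", "home_MCMT")])
  n_excl <- sum(!has_pc)
  df <- df[has_pc, , drop = FALSE]
  if (nrow(df) == 0) stop("no evaluation records with complete covariates")
  seen_years <- names(fit$re_modes$cond$year)
  inc <- if (all(as.character(df$year) %in% seen_years)) "year"
         else FALSE
  pr <- stats::predict(fit, df, include_random = inc)
  out <- do.call(rbind, lapply(sort(unique(df$garden)), function(g) {
    sel <- df$garden == g
    if (sum(sel) == 0) stop("empty evaluation garden: ", g)
    rbind(
      data.frame(garden = g, component = "overall",
                 r = tryCatch(prediction_correlation(df$growth_cm[sel],
                                                     pr$response[sel]),
                              error = function(e) NA_real_),
                 n = sum(sel)),
      data.frame(garden = g, component = "conditional",
                 r = tryCatch(
                   prediction_correlation(df$growth_cm[sel],
                                          pr$conditional[sel],
                                          drop_dead = TRUE,
                                          dead = df$dead[sel]),
                   error = function(e) NA_real_),
                 n = sum(sel & !df$dead))
    )
  }))
  attr(out, "n_excluded_missing_pc") <- n_excl
  out
}

#' Calibration of predicted mortality probabilities
#'
#' Logistic regression of the observed death indicator on the predicted
#' mortality probability; a significantly positive slope means predicted
#' risk tracks realized mortality.
#'
#' @param predicted_p probabilities in `[0, 1]`.
#' @param observed_dead logical (or 0/1) outcomes.
#' @return list with slope, intercept, p_value and the fitted glm.
#' @export
mortality_calibration <- function(predicted_p, observed_dead) {
  stopifnot(length(predicted_p) == length(observed_dead))
  if (any(predicted_p < 0 | predicted_p > 1)) {
    stop("predicted probabilities outside [0, 1]")
  }
  d <- as.logical(observed_dead)
  if (all(d) || all(!d)) stop("all outcomes identical: separation")
  if (stats::sd(predicted_p) == 0) stop("constant predicted probability")
  m <- stats::glm(d ~ predicted_p, family = stats::binomial())
  co <- summary(m)$coefficients
  list(slope = co["predicted_p", "Estimate"],
       intercept = co["(Intercept)", "Estimate"],
       p_value = co["predicted_p", "Pr(>|z|)"],
       model = m)
}

#' Compare models by their cross-validated predictive ability
#'
#' One-way ANOVA across models with the cross-validation folds as
#' replicates, plus exact paired Wilcoxon signed-rank tests per model
#' pair (normal approximation beyond 25 folds). All models must have been
#' evaluated on identical folds.
#'
#' @param cv_by_model named list of `cv_result` objects.
#' @param component which component's r to compare (default "overall").
#' @return list: `anova` (data frame with F and p), `wilcoxon` (pairwise
#'   table), `folds` (the aligned fold-level r matrix).
#' @export
compare_model_cv <- function(cv_by_model, component = "overall") {
  stopifnot(length(cv_by_model) >= 2, !is.null(names(cv_by_model)))
  get_r <- function(cv) {
    f <- cv$folds[cv$folds$component == component, ]
    f <- f[order(f$garden, f$year), ]
    stats::setNames(f$r, paste(f$garden, f$year, sep = ":"))
  }
  rs <- lapply(cv_by_model, get_r)
  keys <- names(rs[[1]])
  if (!all(vapply(rs, function(x) identical(names(x), keys), TRUE))) {
    stop("models were evaluated on different folds")
  }
  m <- do.call(cbind, rs)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  long <- data.frame(
    r = as.numeric(m),
    model = factor(rep(colnames(m), each = nrow(m))),
    fold = factor(rep(rownames(m), ncol(m)))
  )
  a <- stats::anova(stats::lm(r ~ model, data = long))
  pairs <- utils::combn(colnames(m), 2)
  wil <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    wt <- .signed_rank_test(m[, pairs[1, k]] - m[, pairs[2, k]])
    data.frame(model_a = pairs[1, k], model_b = pairs[2, k],
               statistic = wt$statistic, p = wt$p)
  }))
  list(anova = data.frame(F = a$`F value`[1], df1 = a$Df[1],
                          df2 = a$Df[2], p = a$`Pr(>F)`[1]),
       wilcoxon = wil, folds = m)
}

# paired Wilcoxon signed-rank test on a difference vector. Exact null
# enumeration (dynamic programming over sign assignments, midranks for
# tied magnitudes) for n <= 25; normal approximation with tie correction
# above. Zero differences are dropped, the usual convention.
.signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p = NA_real_))
  r2 <- 2 * rank(abs(d))               # doubled midranks are integers
  v2 <- sum(r2[d > 0])
  if (n <= 25) {
    # distribution of the doubled statistic over all 2^n sign vectors
    total <- sum(r2)
    probs <- c(1, numeric(total))      # index s+1 <-> statistic s
    for (r in r2) {
      shifted <- c(numeric(r), probs[seq_len(total + 1 - r)])
      probs <- (probs + shifted) / 2
    }
    lo <- sum(probs[seq_len(round(v2) + 1)])
    hi <- sum(probs[seq(round(v2) + 1, total + 1)])
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- sum(r2) / 2 / 2
    ties <- table(r2)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (v2 / 2 - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v2 / 2, p = p)
}
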