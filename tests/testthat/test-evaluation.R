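# Prediction correlations, cross-validation, transfer, calibration and
# model comparison.

test_that("prediction correlation behaves like Pearson r with the
          survivor convention", {
  x <- c(1, 3, 7, 2, 9)
  expect_equal(prediction_correlation(x, x), 1)
  expect_equal(prediction_correlation(x, -x), -1)
  # joint affine rescaling leaves r unchanged
  expect_equal(prediction_correlation(2 * x + 1, 2 * rev(x) + 1),
               prediction_correlation(x, rev(x)))
  expect_error(prediction_correlation(x, rep(1, 5)), "zero variance")
  expect_error(prediction_correlation(x[1:2], x[1:2]), "fewer than 3")
  # dead records (observed zeros) drop out of the conditional convention
  obs <- c(0, 5, 9, 14, 0, 3)
  pred <- c(8, 5.5, 8.5, 13, 1, 3.4)
  expect_equal(prediction_correlation(obs, pred, drop_dead = TRUE),
               cor(obs[obs > 0], pred[obs > 0]))
})

test_that("mortality calibration detects signal and degenerate input", {
  set.seed(3)
  p <- runif(2000, 0.02, 0.9)
  d <- runif(2000) < p           # perfectly calibrated
  cal <- mortality_calibration(p, d)
  expect_gt(cal$slope, 0)
  expect_lt(cal$p_value, 1e-3)
  expect_error(mortality_calibration(rep(0.3, 100),
                                     runif(100) < 0.3), "constant")
  expect_error(mortality_calibration(p, rep(FALSE, 2000)), "identical")
  expect_error(mortality_calibration(c(-0.1, 0.5, 0.5), c(TRUE, FALSE,
                                                          TRUE)),
               "outside")
  # under the null (outcomes independent of p) the slope is near zero
  set.seed(4)
  sl <- replicate(30, {
    p0 <- runif(500, 0.1, 0.9)
    mortality_calibration(p0, runif(500) < 0.4)$p_value
  })
  expect_lt(mean(sl < 0.05), 0.25)
})

.subset_dataset_2g <- function(ds) {
  g2 <- unique(ds$data$garden)[1:2]
  hybridnorm:::.subset_dataset(ds, ds$data[ds$data$garden %in% g2, ])
}

test_that("garden-level cross-validation leaves the held-out garden
          untouched and summarizes per year", {
  sim <- small_study(41, n_genotypes = 8, n_gardens = 4)
  spec <- model_spec(c("G", "G2", "PC1"))
  cv <- loo_garden_cv(sim$dataset, spec)
  gardens <- unique(sim$dataset$data$garden)
  years <- unique(sim$dataset$data$year)
  expect_equal(nrow(cv$folds),
               length(gardens) * length(years) * 2)  # 2 components
  expect_true(all(cv$folds$r[!is.na(cv$folds$r)] >= -1 &
                    cv$folds$r[!is.na(cv$folds$r)] <= 1))
  expect_true(all(c("overall", "conditional") %in% cv$summary$component))

  # structural check: a refit without garden s01 carries no block modes
  # for that garden
  train <- sim$dataset$data[sim$dataset$data$garden != gardens[1], ]
  ds_tr <- hybridnorm:::.subset_dataset(sim$dataset, train)
  fit_tr <- fit_zigmm(spec, ds_tr)
  expect_false(any(grepl(paste0("^", gardens[1], ":"),
                         names(fit_tr$re_modes$cond$block))))
  expect_error(loo_garden_cv(.subset_dataset_2g(sim$dataset), spec),
               "3 gardens")
})

test_that("with no garden-level effects, held-out and training accuracy
          agree", {
  tr <- sim_truth(sd_cond = c(block = 0, genotype = 0.15, year = 0.05,
                              individual = 0.2),
                  sd_zi = c(block = 0, genotype = 0.1, year = 0.05,
                            individual = 0))
  study <- simulate_study(sim_config(seed = 42, n_genotypes = 20,
                                     n_gardens = 6), truth = tr)
  ds <- filter_records(study$tables)
  spec <- model_spec(c("G", "G2", "PC1", "PC1:G"))
  fit <- fit_zigmm(spec, ds)
  # within-sample accuracy stratified the same way as the CV folds
  # (per garden-year), so the two means estimate the same quantity
  pr <- predict(fit, ds$data, include_random = c("genotype", "year"))
  key <- interaction(ds$data$garden, ds$data$year)
  r_in <- vapply(levels(key), function(k) {
    sel <- key == k
    prediction_correlation(ds$data$growth_cm[sel], pr$response[sel])
  }, 0)
  cv <- loo_garden_cv(ds, spec)
  ok <- cv$folds$component == "overall" & !is.na(cv$folds$r)
  r_heldout <- mean(cv$folds$r[ok])
  expect_lt(abs(r_heldout - mean(r_in)), 0.1)
})

test_that("transfer evaluation to novel genotypes and sites works and
          degrades gracefully", {
  sim <- small_study(43, n_genotypes = 15, n_gardens = 6)
  fit <- fit_zigmm(model_spec(c("G", "G2", "PC1", "PC1:G")), sim$dataset)
  # novel genotypes at three gardens, same generative truth
  cfg2 <- sim_config(seed = 44, n_genotypes = 40, n_gardens = 3,
                     n_blocks = 3)
  study2 <- simulate_study(cfg2)
  maxi <- filter_records(study2$tables)
  res <- maxi_transfer_eval(fit, maxi)
  expect_equal(sort(unique(res$garden)),
               sort(unique(maxi$data$garden)))
  expect_true(all(c("overall", "conditional") %in% res$component))
  expect_true(all(abs(res$r[!is.na(res$r)]) <= 1))
  expect_equal(attr(res, "n_excluded_missing_pc"), 0)

  # genotypes lacking PC scores are excluded with a count
  maxi2 <- maxi
  maxi2$data$PC1[maxi2$data$genotype == maxi2$data$genotype[1]] <- NA
  res2 <- maxi_transfer_eval(fit, maxi2)
  expect_gt(attr(res2, "n_excluded_missing_pc"), 0)
})

test_that("model comparison reproduces exact signed-rank and ANOVA
          behavior", {
  mk_cv <- function(r_vec) {
    folds <- data.frame(garden = sprintf("s%02d", seq_along(r_vec)),
                        year = 2021, component = "overall", r = r_vec,
                        n = 50, converged = TRUE)
    structure(list(folds = folds, summary = NULL), class = "cv_result")
  }
  set.seed(6)
  base <- runif(17, 0.1, 0.7)
  same <- list(a = mk_cv(base), b = mk_cv(base), c = mk_cv(base))
  cmp_same <- compare_model_cv(same)
  expect_lt(cmp_same$anova$F, 1e-20)

  shifted <- list(a = mk_cv(base), b = mk_cv(base + 0.2))
  cmp <- compare_model_cv(shifted)
  # constant 0.2 shift across 17 folds: smallest attainable exact
  # two-sided signed-rank p-value, 2 / 2^17
  expect_equal(cmp$wilcoxon$p, 2^-16, tolerance = 1e-12)

  # label permutation leaves the ANOVA F unchanged
  three <- list(a = mk_cv(base), b = mk_cv(base + 0.1),
                c = mk_cv(base - 0.05))
  f1 <- compare_model_cv(three)$anova$F
  f2 <- compare_model_cv(three[c(2, 3, 1)])$anova$F
  expect_equal(f1, f2, tolerance = 1e-10)

  # mismatched folds are an error
  bad <- mk_cv(base); bad$folds$garden[1] <- "zzz"
  expect_error(compare_model_cv(list(a = mk_cv(base), b = bad)),
               "different folds")
})
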