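# Likelihood, Laplace marginal, fitting, prediction and inference.

test_that("joint likelihood matches closed forms and a re-summation oracle", {
  df <- data.frame(individual = "t1", genotype = "g1", garden = "s1",
                   block = "b1", year = 2021,
                   garden_MCMT = c(-2, 5), home_MCMT = -10,
                   PC1 = 0.3, PC2 = 0.1, PC3 = -0.2, growth_cm = c(0, 4))
  ds <- toy_dataset(df)
  # single zero record at p = 0.5, no random effects: -log 0.5
  d1 <- build_design(toy_dataset(df[1, ]), model_spec(character(0),
                                                      random = character(0)))
  th1 <- zigmm_theta(beta = 0, gamma = 0, sigma = 1)
  expect_equal(joint_negloglik(th1, numeric(0), d1), -log(0.5),
               tolerance = 1e-12)
  # single y = 1 record at its mean, sigma = 1, zero inflation suppressed
  df2 <- df[2, ]; df2$growth_cm <- exp(1) - 1    # y = 1 on log1p scale
  d2 <- build_design(toy_dataset(df2),
                     model_spec(character(0), zi_terms = NULL,
                                random = character(0)))
  th2 <- zigmm_theta(beta = 1, gamma = NULL, sigma = 1)
  expect_equal(joint_negloglik(th2, numeric(0), d2), -log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)

  # 10-record fixture vs a direct sum-over-terms oracle
  set.seed(2)
  df10 <- data.frame(
    individual = paste0("t", 1:10), genotype = rep(c("g1", "g2"), 5),
    garden = "s1", block = "b1", year = 2021,
    garden_MCMT = rnorm(10, -3, 6), home_MCMT = rnorm(10, -12, 4),
    PC1 = rnorm(10), PC2 = rnorm(10), PC3 = rnorm(10),
    growth_cm = c(0, 0, 0, rexp(7, 0.1)))
  ds10 <- toy_dataset(df10)
  spec <- model_spec("G", random = "genotype")
  d10 <- build_design(ds10, spec)
  th <- zigmm_theta(beta = c(1.5, 0.4), gamma = c(-0.5, 0.3), sigma = 0.8,
                    sd_cond = c(genotype = 0.5), sd_zi = c(genotype = 0.4))
  b <- c(0.2, -0.1, 0.15, -0.3)   # cond then zi block, 2 levels each
  got <- joint_negloglik(th, b, d10)
  # oracle: plain loops over records and prior terms
  g <- as.integer(factor(df10$genotype))
  mu <- 1.5 + 0.4 * ds10$data$g_s + c(0.2, -0.1)[g]
  eta <- -0.5 + 0.3 * ds10$data$g_s + c(0.15, -0.3)[g]
  p <- plogis(eta)
  y <- ds10$data$y
  ll <- sum(ifelse(y == 0, log(p), log(1 - p) + dnorm(y, mu, 0.8, TRUE)))
  prior <- sum(dnorm(c(0.2, -0.1), 0, 0.5, TRUE)) +
    sum(dnorm(c(0.15, -0.3), 0, 0.4, TRUE))
  expect_equal(got, -(ll + prior), tolerance = 1e-10)
})

test_that("Laplace equals the exact Gaussian mixed-model marginal", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 40
    df <- data.frame(
      individual = paste0("t", 1:n),
      genotype = sample(paste0("g", 1:6), n, TRUE),
      garden = sample(paste0("s", 1:4), n, TRUE), block = "b1",
      year = sample(2021:2022, n, TRUE),
      garden_MCMT = rnorm(n, -3, 7), home_MCMT = rnorm(n, -12, 4),
      PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n),
      growth_cm = rexp(n, 0.08))
    ds <- toy_dataset(df)
    spec <- model_spec(c("G", "H"), zi_terms = NULL,
                       random = c("genotype", "year"))
    d <- build_design(ds, spec)
    sdc <- c(genotype = runif(1, 0.1, 0.8), year = runif(1, 0.1, 0.6))
    th <- zigmm_theta(beta = c(2, 0.3, -0.1), gamma = NULL,
                      sigma = runif(1, 0.3, 1), sd_cond = sdc)
    lap <- as.numeric(marginal_negloglik(th, d))
    var_col <- sdc[d$rf$factors[d$rf$factor_of_col]]^2
    oracle <- lmm_dense_nll(d$y, d$X, d$Z, th$beta, th$sigma, var_col)
    expect_equal(lap, as.numeric(oracle), tolerance = 1e-6)
  }
})

test_that("Laplace tracks 64-node Gauss-Hermite quadrature on zi toys", {
  for (seed in 1:3) {
    set.seed(seed)
    nper <- 14; nlev <- 3
    level <- rep(paste0("g", 1:nlev), each = nper); n <- nlev * nper
    df <- data.frame(individual = paste0("t", 1:n), genotype = level,
                     garden = rep(c("s1", "s2"), length.out = n),
                     block = "b1", year = rep(2021:2022, length.out = n),
                     garden_MCMT = rnorm(n, -3, 8),
                     home_MCMT = rnorm(n, -12, 5), PC1 = rnorm(n),
                     PC2 = rnorm(n), PC3 = rnorm(n), growth_cm = 1)
    ds0 <- toy_dataset(df)
    beta <- c(2, 0.3); gamma <- c(-0.8, 0.4); sigma <- 0.6
    sd_c <- 0.2; sd_z <- 0.2
    X <- cbind(1, ds0$data$g_s)
    gi <- as.integer(factor(level))
    mu <- X %*% beta + rnorm(nlev, 0, sd_c)[gi]
    p <- plogis(X %*% gamma + rnorm(nlev, 0, sd_z)[gi])
    dead <- runif(n) < p
    df$growth_cm <- ifelse(dead, 0, pmax(expm1(rnorm(n, mu, sigma)), 0.01))
    ds <- toy_dataset(df)
    d <- build_design(ds, model_spec("G", random = "genotype"))
    th <- zigmm_theta(beta, gamma, sigma, c(genotype = sd_c),
                      c(genotype = sd_z))
    lap <- as.numeric(marginal_negloglik(th, d))
    orc <- zigmm_gh_nll(ds$data$y, d$X, d$X_zi, level, beta, gamma,
                        sigma, sd_c, sd_z)
    expect_lt(abs(lap - orc), 1e-3)
  }
})

test_that("marginal with no random effects reduces to the joint", {
  df <- data.frame(individual = paste0("t", 1:8), genotype = "g1",
                   garden = "s1", block = "b1", year = 2021,
                   garden_MCMT = rnorm(8), home_MCMT = -10, PC1 = 0,
                   PC2 = 0, PC3 = 0, growth_cm = c(0, rexp(7, 0.1)))
  ds <- toy_dataset(df)
  d <- build_design(ds, model_spec("G", random = character(0)))
  th <- zigmm_theta(c(1, 0.2), c(-1, 0.1), 0.7)
  expect_equal(as.numeric(marginal_negloglik(th, d)),
               joint_negloglik(th, numeric(0), d))
})

test_that("fitting recovers generative parameters on the default design", {
  study <- simulate_study(sim_config(seed = 7))
  ds <- filter_records(study$tables)
  fit <- fit_zigmm(make_model("full"), ds,
                   control = list(rel_tol = 1e-7))
  expect_true(fit$convergence)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)  # AIC identity

  bt0 <- truth_on_dataset_scale(study$truth, ds, "beta")
  bt <- vapply(names(fit$beta),
               function(t) if (t %in% names(bt0)) bt0[[t]] else 0, 0)
  z <- (fit$beta - bt) / sqrt(diag(fit$vcov_beta))
  expect_true(all(abs(z) < 3.5))
  expect_gt(mean(abs(z) < 2), 0.8)
  # concave fitted response to garden winter temperature
  expect_lt(fit$beta[["G2"]], 0)

  # reported likelihood agrees with the general marginal machinery
  th <- zigmm_theta(fit$beta, fit$gamma, fit$sigma, fit$sd_cond,
                    fit$sd_zi)
  d <- build_design(ds, fit$spec)
  expect_equal(fit$loglik, -as.numeric(marginal_negloglik(th, d)),
               tolerance = 1e-4)
})

test_that("estimates are invariant to record ordering", {
  sim <- small_study(9, n_genotypes = 8, n_gardens = 5)
  tb <- sim$study$tables
  set.seed(1)
  tb_perm <- tb
  tb_perm$phenotypes <- tb_perm$phenotypes[sample(nrow(tb$phenotypes)), ]
  spec <- model_spec(c("G", "G2", "PC1"))
  f1 <- fit_zigmm(spec, filter_records(tb))
  f2 <- fit_zigmm(spec, filter_records(tb_perm))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("a zero-variance factor in truth is fitted at the boundary", {
  tr <- sim_truth(sd_cond = c(block = 0, genotype = 0.15, year = 0.1,
                              individual = 0.25))
  sim <- small_study(10, n_genotypes = 12, n_gardens = 8,
                     sd_cond = tr$sd_cond)
  fit <- fit_zigmm(model_spec(c("G", "G2")), sim$dataset)
  expect_lt(fit$sd_cond[["block"]], 0.05)
})

test_that("the mixture zero convention reproduces the reference fit", {
  sim <- small_study(11, n_genotypes = 10, n_gardens = 6)
  ds <- sim$dataset
  spec <- model_spec(c("G", "G2", "PC1"), random = c("genotype", "year"))
  ours <- fit_zigmm(spec, ds, zero_density = "mixture")
  ref <- glmmTMB::glmmTMB(
    y ~ g_s + I(g_s^2) + pc1_s + (1 | genotype) + (1 | year),
    ziformula = ~ g_s + I(g_s^2) + pc1_s + (1 | genotype) + (1 | year),
    data = ds$data, family = stats::gaussian())
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-4)
  expect_equal(unname(ours$beta), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_equal(unname(ours$gamma), unname(glmmTMB::fixef(ref)$zi),
               tolerance = 1e-2)
  expect_equal(ours$sigma, stats::sigma(ref), tolerance = 1e-3)
})

test_that("predictions combine components and are pure", {
  sim <- small_study(12, n_genotypes = 8, n_gardens = 5)
  fit <- fit_zigmm(model_spec(c("G", "G2", "PC1")), sim$dataset)
  nd <- sim$dataset$data[1:20, ]
  p1 <- predict(fit, nd, include_random = FALSE)
  p2 <- predict(fit, nd, include_random = FALSE)
  expect_identical(p1, p2)
  expect_equal(p1$response, (1 - p1$zprob) * p1$conditional,
               tolerance = 1e-14)
  expect_true(all(p1$response <= p1$conditional + 1e-12))
  expect_true(all(p1$zprob >= 0 & p1$zprob <= 1))
  # with random modes the linear predictor shifts by the stored modes
  p3 <- predict(fit, nd, include_random = TRUE)
  expect_false(isTRUE(all.equal(p1$mu, p3$mu)))
  # unseen level with random modes requested: error listing the level
  nd2 <- nd; nd2$genotype[1] <- "novel-geno"
  expect_error(predict(fit, nd2, include_random = TRUE), "novel-geno")
  expect_silent(predict(fit, nd2, include_random = FALSE))
})

test_that("fitted models serialize to JSON with their prediction
          metadata", {
  sim <- small_study(15, n_genotypes = 6, n_gardens = 4)
  fit <- fit_zigmm(model_spec(c("G", "G2")), sim$dataset)
  path <- tempfile(fileext = ".json")
  write_zigmm_json(fit, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$beta), fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma, fit$sigma, tolerance = 1e-12)
  expect_equal(unlist(back$scaling), fit$scaling, tolerance = 1e-12)
  expect_identical(back$transform, "log1p")
  expect_identical(back$zero_density, "point_mass")
})

test_that("type II Wald tests give closed-form single-term results and are
          order-invariant", {
  fake <- structure(list(
    beta = c(`(Intercept)` = 0.5, G = 2),
    vcov_beta = diag(c(0.3, 1)), gamma = NULL,
    spec = model_spec("G", zi_terms = NULL)), class = "zigmm")
  dimnames(fake$vcov_beta) <- list(names(fake$beta), names(fake$beta))
  w <- wald_type2(fake)
  expect_equal(w$chisq, 4, tolerance = 1e-12)
  expect_equal(w$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)

  sim <- small_study(13, n_genotypes = 8, n_gardens = 5)
  s1 <- model_spec(c("G", "G2", "PC1", "PC1:G"))
  s2 <- model_spec(c("PC1:G", "PC1", "G2", "G"))
  w1 <- wald_type2(fit_zigmm(s1, sim$dataset))
  w2 <- wald_type2(fit_zigmm(s2, sim$dataset))
  w2 <- w2[match(paste(w1$component, w1$term),
                 paste(w2$component, w2$term)), ]
  # the two orderings are separate fits, so agreement is up to the
  # optimizer's convergence tolerance
  expect_equal(w1$chisq, w2$chisq, tolerance = 5e-3)
})

test_that("Wald test of a null term rejects at the nominal rate", {
  # Gaussian-only small design, true PC2 effect = 0
  tr <- sim_truth(beta = c(`(Intercept)` = 3.0, G = 0.3, G2 = -0.45),
                  gamma = c(`(Intercept)` = -30),   # essentially no deaths
                  sd_cond = c(block = 0.1, genotype = 0.1, year = 0.05,
                              individual = 0.15),
                  negative_increment_rate = 0)
  spec <- model_spec(c("G", "G2", "PC2"), zi_terms = NULL)
  rej <- logical(200)
  for (i in seq_len(200)) {
    study <- simulate_study(sim_config(seed = 5000 + i, n_genotypes = 12,
                                       n_gardens = 6), truth = tr)
    ds <- filter_records(study$tables)
    fit <- fit_zigmm(spec, ds)
    w <- wald_type2(fit)
    rej[i] <- w$p[w$term == "PC2"] < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("standardized estimates rescale correctly and survive unit
          changes", {
  sim <- small_study(14, n_genotypes = 10, n_gardens = 6)
  fit <- fit_zigmm(model_spec(c("G", "G2", "PC1")), sim$dataset)
  se <- standardized_estimates(fit, sim$dataset)
  sub <- se[se$component == "conditional" & se$term == "G", ]
  sd_x <- sd(sim$dataset$data$g_s)
  sd_y <- sd(sim$dataset$data$y[sim$dataset$data$y > 0])
  expect_equal(sub$std_estimate, fit$beta[["G"]] * sd_x / sd_y,
               tolerance = 1e-10)
  expect_true(all(se$ci_low <= se$std_estimate &
                    se$std_estimate <= se$ci_high))

  # changing a predictor's raw units leaves standardized estimates alone
  tb2 <- sim$study$tables
  tb2$genotypes$PC1 <- tb2$genotypes$PC1 * 2
  fit2 <- fit_zigmm(model_spec(c("G", "G2", "PC1")),
                    filter_records(tb2))
  se2 <- standardized_estimates(fit2, filter_records(tb2))
  expect_equal(se$std_estimate, se2$std_estimate, tolerance = 1e-6)
})
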