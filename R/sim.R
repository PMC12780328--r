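# Synthetic common-garden study generator.
#
# Emulates the study design the model assumes: clonal genotypes sampled
# along a continuous ancestry gradient, with home winter temperature and
# genomic PC1 strongly negatively correlated; gardens spanning a wide
# winter-temperature gradient with yearly climate jitter; a concave
# (quadratic) growth response to garden MCMT whose optimum shifts with
# ancestry; zero-inflated mortality rising at both temperature extremes;
# random intercepts for garden block, genotype, year and individual; and a
# small rate of corrupted negative growth increments (herbivory /
# measurement error) so the filtering stage has real work to do.
#
# All randomness flows from a single seed through a deterministic
# stream-splitting scheme, so each stage is reproducible in isolation.

#' Synthetic study configuration
#'
#' Defaults mirror the study layout: 44 genotypes (after outlier removal),
#' 17 gardens x 2 blocks x 1 ramet per block, 2 measurement years, garden
#' MCMT spanning -16.5 to 9.8 C and home MCMT -23.9 to -3.8 C.
#'
#' @param n_genotypes,n_gardens,n_blocks,n_years design counts.
#' @param garden_mcmt_range,home_mcmt_range ranges in degrees C.
#' @param years calendar years labeling the measurement occasions.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 44, n_gardens = 17, n_blocks = 2,
                       n_years = 2,
                       garden_mcmt_range = c(-16.5, 9.8),
                       home_mcmt_range = c(-23.9, -3.8),
                       years = seq(2021, length.out = n_years),
                       seed = 1) {
  stopifnot(n_genotypes >= 1, n_gardens >= 1, n_blocks >= 1, n_years >= 1,
            diff(garden_mcmt_range) >= 0, diff(home_mcmt_range) >= 0,
            length(years) == n_years)
  structure(as.list(environment()), class = "sim_config")
}

#' Generative truth parameters
#'
#' Coefficients act on covariates scaled (without centering) at generation
#' time; the conditional part is on the log1p growth scale, the
#' zero-inflation part on the logit-mortality scale. Defaults were chosen
#' once to produce reaction norms with the qualitative shape the study
#' system shows (concave growth response with a warm-shifted optimum for
#' low-PC1 genotypes, mortality rising at both extremes, roughly a quarter
#' of records zero); they are not estimates from any dataset.
#'
#' @param beta named conditional coefficients (subset of the term catalog
#'   plus `(Intercept)`).
#' @param gamma named zero-inflation coefficients.
#' @param sigma residual SD on the transformed scale.
#' @param sd_cond,sd_zi named random-intercept SDs.
#' @param pc1_home_corr target correlation between genomic PC1 and home
#'   MCMT (enforced exactly in the sample).
#' @param negative_increment_rate fraction of surviving records corrupted
#'   to negative growth before export.
#' @return a `sim_truth` list.
#' @export
sim_truth <- function(
    beta = c(`(Intercept)` = 3.0, G = 0.30, G2 = -0.45, H = 0.08,
             H2 = -0.05, GH = 0.12, PC1 = -0.25, PC3 = -0.12,
             `PC1:G` = -0.22, `PC1:G2` = -0.08),
    gamma = c(`(Intercept)` = -1.7, G = -0.3, G2 = 0.6, PC1 = 0.2,
              `PC1:G` = 0.25),
    sigma = 0.55,
    sd_cond = c(block = 0.20, genotype = 0.15, year = 0.10,
                individual = 0.25),
    sd_zi = c(block = 0.30, genotype = 0.10, year = 0.10,
              individual = 0.00),
    pc1_home_corr = -0.69,
    negative_increment_rate = 0.08) {
  stopifnot(sigma > 0, all(sd_cond >= 0), all(sd_zi >= 0),
            abs(pc1_home_corr) < 1,
            negative_increment_rate >= 0, negative_increment_rate < 1)
  if (!is.na(beta["G2"]) && beta[["G2"]] >= 0) {
    stop("conditional garden-MCMT quadratic coefficient must be negative",
         " (concave growth response)")
  }
  structure(list(beta = beta, gamma = gamma, sigma = sigma,
                 sd_cond = sd_cond, sd_zi = sd_zi,
                 pc1_home_corr = pc1_home_corr,
                 negative_increment_rate = negative_increment_rate),
            class = "sim_truth")
}

# deterministic stream splitting: one master seed, one integer per stage
.split_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 1299721) %% 2147483629
}

#' Generate synthetic genotypes
#'
#' Home MCMT is uniform over the configured range; PC1 is constructed to
#' have exactly the target sample correlation with home MCMT; PC2 and PC3
#' are standard normal scores orthogonalized against home MCMT and given
#' mild target correlations with it (-0.22, -0.40, matching the weaker
#' associations of intraspecific structure with climate); ancestry follows
#' a logistic gradient along PC1.
#'
#' @param config a [sim_config()].
#' @param truth a [sim_truth()].
#' @return data frame of genotype covariates.
#' @export
gen_genotypes <- function(config, truth = sim_truth()) {
  set.seed(.split_seed(config$seed, 1))
  n <- config$n_genotypes
  home <- stats::runif(n, config$home_mcmt_range[1],
                       config$home_mcmt_range[2])
  if (n == 1 || stats::sd(home) == 0) {
    pc1 <- stats::rnorm(n); pc2 <- stats::rnorm(n); pc3 <- stats::rnorm(n)
  } else {
    zh <- as.numeric(scale(home))
    mk_corr <- function(rho) {
      e <- stats::rnorm(n)
      e <- stats::residuals(stats::lm(e ~ zh))
      e <- e / stats::sd(e)
      rho * zh + sqrt(1 - rho^2) * e
    }
    pc1 <- mk_corr(truth$pc1_home_corr)
    pc2 <- mk_corr(-0.22)
    pc3 <- mk_corr(-0.40)
  }
  ancestry <- stats::plogis(1.5 * pc1 + 0.5 * stats::rnorm(n))
  data.frame(
    genotype = sprintf("g%02d", seq_len(n)),
    home_MCMT = home, PC1 = pc1, PC2 = pc2, PC3 = pc3,
    ancestry = ancestry, outlier = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic gardens
#'
#' Garden-site MCMT values are evenly spread over the configured range;
#' each measurement year gets an independent jitter (SD = 5% of the range
#' width) clamped back into the range.
#'
#' @param config a [sim_config()].
#' @return data frame with one row per garden x year (`garden`, `year`,
#'   `garden_MCMT`).
#' @export
gen_gardens <- function(config) {
  set.seed(.split_seed(config$seed, 2))
  rng <- config$garden_mcmt_range
  base <- if (config$n_gardens == 1) mean(rng) else
    seq(rng[1], rng[2], length.out = config$n_gardens)
  jit_sd <- 0.05 * diff(rng)
  out <- expand.grid(garden = sprintf("s%02d", seq_len(config$n_gardens)),
                     year = config$years, stringsAsFactors = FALSE)
  out$garden_MCMT <- pmin(pmax(base[match(out$garden,
                                          sprintf("s%02d",
                                                  seq_len(config$n_gardens)))] +
                                 stats::rnorm(nrow(out), 0, jit_sd),
                               rng[1]), rng[2])
  out
}

#' Simulate phenotype records under the zero-inflated model
#'
#' One tree per genotype x garden x block, measured every year. Mortality
#' is drawn per record from the logit-linear zero-inflation predictor;
#' survivors get Gaussian log1p-scale growth back-transformed to cm
#' (floored at zero), and a configured fraction of surviving records is
#' then corrupted to negative increments to exercise the filtering stage.
#'
#' @param genotypes,gardens outputs of [gen_genotypes()], [gen_gardens()].
#' @param truth a [sim_truth()].
#' @param config a [sim_config()].
#' @return list: `tables` (a `phenotype_tables` object), `truth` (the
#'   input truth augmented with the generator-side scaling divisors and
#'   the mean simulated mortality probability).
#' @export
simulate_phenotypes <- function(genotypes, gardens, truth, config) {
  set.seed(.split_seed(config$seed, 3))
  blocks <- sprintf("b%d", seq_len(config$n_blocks))
  trees <- expand.grid(genotype = genotypes$genotype,
                       garden = unique(gardens$garden),
                       block = blocks, stringsAsFactors = FALSE)
  trees$individual <- paste(trees$garden, trees$block, trees$genotype,
                            sep = "_")
  rec <- merge(trees, data.frame(year = config$years), by = NULL)
  rec <- merge(rec, gardens, by = c("garden", "year"), sort = FALSE)
  rec <- merge(rec, genotypes, by = "genotype", sort = FALSE)
  rec <- rec[order(rec$garden, rec$block, rec$genotype, rec$year), ]
  rownames(rec) <- NULL
  n <- nrow(rec)

  divisors <- c(
    garden_MCMT = scale_no_center(rec$garden_MCMT)$divisor,
    home_MCMT = scale_no_center(rec$home_MCMT)$divisor,
    PC1 = scale_no_center(rec$PC1)$divisor,
    PC2 = scale_no_center(rec$PC2)$divisor,
    PC3 = scale_no_center(rec$PC3)$divisor
  )
  sdf <- data.frame(g_s = rec$garden_MCMT / divisors[["garden_MCMT"]],
                    h_s = rec$home_MCMT / divisors[["home_MCMT"]],
                    pc1_s = rec$PC1 / divisors[["PC1"]],
                    pc2_s = rec$PC2 / divisors[["PC2"]],
                    pc3_s = rec$PC3 / divisors[["PC3"]])
  lin_pred <- function(coefs) {
    terms <- setdiff(names(coefs), "(Intercept)")
    bad <- setdiff(terms, names(.term_defs))
    if (length(bad)) stop("unknown truth term(s): ",
                          paste(bad, collapse = ", "))
    eta <- rep(coefs[["(Intercept)"]], n)
    for (t in terms) eta <- eta + coefs[[t]] * .term_defs[[t]](sdf)
    eta
  }
  draw_re <- function(keys, sd) {
    lev <- unique(keys)
    stats::setNames(stats::rnorm(length(lev), 0, sd), lev)[keys]
  }
  re_sum <- function(sds) {
    out <- numeric(n)
    keys <- list(block = paste(rec$garden, rec$block, sep = ":"),
                 genotype = rec$genotype,
                 year = as.character(rec$year),
                 individual = rec$individual)
    for (f in names(sds)) {
      if (sds[[f]] > 0) out <- out + draw_re(keys[[f]], sds[[f]])
    }
    out
  }

  eta_zi <- lin_pred(truth$gamma) + re_sum(truth$sd_zi)
  p <- stats::plogis(eta_zi)
  dead <- stats::runif(n) < p

  mu <- lin_pred(truth$beta) + re_sum(truth$sd_cond)
  ystar <- stats::rnorm(n, mu, truth$sigma)
  growth <- pmax(expm1(ystar), 0)
  growth[dead] <- 0

  # herbivory / measurement-error artifact: negative increments among
  # survivors, removed later by the filter stage
  surv_idx <- which(!dead)
  n_corrupt <- round(truth$negative_increment_rate * length(surv_idx))
  if (n_corrupt > 0) {
    corrupt <- sample(surv_idx, n_corrupt)
    growth[corrupt] <- -abs(stats::rnorm(n_corrupt, 3, 2))
  }

  phen <- data.frame(individual = rec$individual, genotype = rec$genotype,
                     garden = rec$garden, block = rec$block,
                     year = rec$year, growth_cm = growth, dead = dead,
                     missing_growth = FALSE, stringsAsFactors = FALSE)
  tables <- phenotype_tables(phen, genotypes, gardens, dialect = "mini")
  truth$divisors <- divisors
  truth$mean_p <- mean(p)
  list(tables = tables, truth = truth)
}

#' Simulate a complete study in one call
#'
#' @param config a [sim_config()].
#' @param truth a [sim_truth()].
#' @return list with `tables`, `genotypes`, `gardens`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), truth = sim_truth()) {
  genotypes <- gen_genotypes(config, truth)
  gardens <- gen_gardens(config)
  sim <- simulate_phenotypes(genotypes, gardens, truth, config)
  list(tables = sim$tables, genotypes = genotypes, gardens = gardens,
       truth = sim$truth)
}

#' Express generative truth coefficients on a fitted dataset's scale
#'
#' The generator and the analysis both scale covariates without centering,
#' but compute their divisors on different row sets (all generated records
#' vs the filtered analysis rows), so the true coefficient for an analysis
#' design column is the generative one times the divisor ratio of that
#' column. Needed to compare fitted coefficients against truth.
#'
#' @param truth the truth record returned by [simulate_phenotypes()]
#'   (carries the generator divisors).
#' @param dataset the fitted `analysis_dataset` (carries the analysis
#'   divisors).
#' @param which `"beta"` or `"gamma"`.
#' @return named coefficient vector on the analysis scale.
#' @export
truth_on_dataset_scale <- function(truth, dataset, which = c("beta",
                                                             "gamma")) {
  which <- match.arg(which)
  coefs <- truth[[which]]
  dg <- truth$divisors; da <- dataset$scaling
  var_div <- c(G = "garden_MCMT", G2 = "garden_MCMT", H = "home_MCMT",
               H2 = "home_MCMT", PC1 = "PC1", PC2 = "PC2", PC3 = "PC3")
  var_pow <- c(G = 1, G2 = 2, H = 1, H2 = 2, PC1 = 1, PC2 = 1, PC3 = 1)
  out <- coefs
  for (t in names(coefs)) {
    if (t == "(Intercept)") next
    ratio <- 1
    for (v in .term_vars(t)) {
      ratio <- ratio * (da[[var_div[[v]]]] / dg[[var_div[[v]]]])^
        var_pow[[v]]
    }
    out[[t]] <- coefs[[t]] * ratio
  }
  out
}

#' Generate a synthetic biallelic SNP matrix along an ancestry gradient
#'
#' Two ancestral allele-frequency profiles are drawn; each genotype's site
#' frequencies are the ancestry-weighted mixture and dosages are binomial
#' draws, so a PCA of the matrix recovers the ancestry gradient on PC1.
#'
#' @param genotypes output of [gen_genotypes()] (uses `ancestry`).
#' @param n_sites number of biallelic sites.
#' @param seed integer seed.
#' @return integer matrix (genotypes x sites) with entries 0/1/2 and the
#'   genotype ids as row names.
#' @export
gen_snp_matrix <- function(genotypes, n_sites = 2000, seed = 1) {
  set.seed(.split_seed(seed, 4))
  n <- nrow(genotypes)
  pA <- stats::runif(n_sites, 0.02, 0.98)
  pB <- pmin(pmax(pA + stats::rnorm(n_sites, 0, 0.35), 0.02), 0.98)
  a <- genotypes$ancestry
  freq <- outer(a, pB) + outer(1 - a, pA)
  m <- matrix(stats::rbinom(n * n_sites, 2, as.numeric(freq)),
              nrow = n, ncol = n_sites)
  rownames(m) <- genotypes$genotype
  m
}
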