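# Independent oracles used across tests: dense closed-form Gaussian
# mixed-model marginal likelihood, Gauss-Hermite quadrature for the
# zero-inflated toy, and a tiny dataset constructor.

# Gauss-Hermite nodes/weights via Golub-Welsch (eigen of the Jacobi matrix)
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# exact marginal negative log-likelihood of a Gaussian mixed model by
# dense multivariate-normal evaluation: y ~ N(X beta, sigma^2 I + Z D Z')
lmm_dense_nll <- function(y, X, Z, beta, sigma, var_col) {
  n <- length(y)
  V <- diag(sigma^2, n) + as.matrix(Z %*% (var_col * Matrix::t(Z)))
  r <- y - as.numeric(X %*% beta)
  0.5 * (n * log(2 * pi) + determinant(V)$modulus +
           sum(r * solve(V, r)))
}

# brute-force marginal nll of a one-factor zero-inflated Gaussian toy by
# 2-D Gauss-Hermite integration per level (conditional and zero-inflation
# random intercepts integrated jointly)
zigmm_gh_nll <- function(y, X, Xz, level, beta, gamma, sigma, sd_c, sd_z,
                         n_nodes = 64) {
  gh <- gh_rule(n_nodes)
  total <- 0
  for (l in unique(level)) {
    idx <- level == l
    yi <- y[idx]
    mu0 <- as.numeric(X[idx, , drop = FALSE] %*% beta)
    et0 <- as.numeric(Xz[idx, , drop = FALSE] %*% gamma)
    val <- 0
    for (a in seq_len(n_nodes)) {
      bc <- sqrt(2) * sd_c * gh$nodes[a]
      mu <- mu0 + bc
      for (b in seq_len(n_nodes)) {
        bz <- sqrt(2) * sd_z * gh$nodes[b]
        p <- stats::plogis(et0 + bz)
        ll <- sum(ifelse(yi == 0, log(p),
                         log(1 - p) + stats::dnorm(yi, mu, sigma,
                                                   log = TRUE)))
        val <- val + gh$weights[a] * gh$weights[b] * exp(ll) / pi
      }
    }
    total <- total - log(val)
  }
  total
}

# small analysis-dataset-like object built directly from a data frame of
# raw covariates + response, bypassing the reader; degenerate columns
# (single row, all-zero) fall back to divisor 1 so toys stay simple
toy_dataset <- function(df) {
  div1 <- function(x) tryCatch(scale_no_center(x)$divisor,
                               error = function(e) 1)
  scaling <- c(garden_MCMT = div1(df$garden_MCMT),
               home_MCMT = div1(df$home_MCMT),
               PC1 = div1(df$PC1), PC2 = div1(df$PC2),
               PC3 = div1(df$PC3))
  df$g_s <- df$garden_MCMT / scaling[["garden_MCMT"]]
  df$h_s <- df$home_MCMT / scaling[["home_MCMT"]]
  df$pc1_s <- df$PC1 / scaling[["PC1"]]
  df$pc2_s <- df$PC2 / scaling[["PC2"]]
  df$pc3_s <- df$PC3 / scaling[["PC3"]]
  df$y <- transform_growth(df$growth_cm)
  structure(list(data = df, scaling = scaling, transform = "log1p",
                 report = list(), garden_mcmt_range = range(df$garden_MCMT)),
            class = "analysis_dataset")
}

# random small study datasets used by several property tests
small_study <- function(seed, n_genotypes = 10, n_gardens = 6, ...) {
  study <- simulate_study(sim_config(seed = seed,
                                     n_genotypes = n_genotypes,
                                     n_gardens = n_gardens),
                          truth = sim_truth(...))
  list(study = study, dataset = filter_records(study$tables))
}
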