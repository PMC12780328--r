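# Zero-inflated Gaussian mixed-model likelihood.
#
# Observation i contributes, with p_i = logit^-1(eta_zi_i) the structural
# zero (mortality) probability and mu_i the conditional mean of the
# transformed growth:
#   y_i  = 0 : log p_i                                (point-mass default)
#            : log(p_i + (1 - p_i) N(0; mu_i, s^2))   (mixture convention)
#   y_i != 0 : log(1 - p_i) + log N(y_i; mu_i, s^2)
# Random intercepts b enter both linear predictors and carry independent
# Gaussian priors with one variance per grouping factor. The marginal
# likelihood integrates b out by a Laplace approximation around the joint
# mode.

#' Parameter container for the zero-inflated Gaussian mixed model
#'
#' @param beta conditional fixed coefficients (named by term, intercept
#'   first).
#' @param gamma zero-inflation fixed coefficients (logit scale), or `NULL`
#'   when zero inflation is suppressed.
#' @param sigma residual SD of the conditional part (> 0).
#' @param sd_cond named vector of random-intercept SDs of the conditional
#'   part, one per grouping factor (may be 0).
#' @param sd_zi same for the zero-inflation part.
#' @return a `zigmm_theta` list.
#' @export
zigmm_theta <- function(beta, gamma = NULL, sigma, sd_cond = numeric(0),
                        sd_zi = numeric(0)) {
  stopifnot(sigma > 0, all(sd_cond >= 0), all(sd_zi >= 0))
  structure(list(beta = beta, gamma = gamma, sigma = sigma,
                 sd_cond = sd_cond, sd_zi = sd_zi), class = "zigmm_theta")
}

# per-observation negative log-likelihood and derivatives in (mu, eta)
.obs_nll <- function(y, zero, mu, eta, sigma, zero_density) {
  n <- length(y)
  s2 <- sigma^2
  f <- numeric(n)
  dmu <- numeric(n); deta <- numeric(n)
  wmm <- numeric(n); wee <- numeric(n); wme <- numeric(n)

  has_zi <- !is.null(eta)
  if (!has_zi) eta <- numeric(n)
  p <- stats::plogis(eta)

  nz <- !zero
  if (any(nz)) {
    r <- y[nz] - mu[nz]
    f[nz] <- 0.5 * log(2 * pi * s2) + r^2 / (2 * s2)
    dmu[nz] <- -r / s2
    wmm[nz] <- 1 / s2
    if (has_zi) {
      # -log(1 - p) = log(1 + e^eta)
      f[nz] <- f[nz] + .log1pexp(eta[nz])
      deta[nz] <- p[nz]
      wee[nz] <- p[nz] * (1 - p[nz])
    }
  }
  if (any(zero)) {
    if (!has_zi) stop("zero responses but zero inflation is suppressed")
    if (zero_density == "point_mass") {
      f[zero] <- .log1pexp(-eta[zero])      # -log p
      deta[zero] <- -(1 - p[zero])
      wee[zero] <- p[zero] * (1 - p[zero])
    } else {
      a <- p[zero]; m <- mu[zero]
      phi0 <- stats::dnorm(0, m, sigma)
      L <- a + (1 - a) * phi0
      dL_eta <- a * (1 - a) * (1 - phi0)
      dL_mu <- (1 - a) * phi0 * (-m / s2)
      d2L_eta <- a * (1 - a) * (1 - 2 * a) * (1 - phi0)
      d2L_mu <- (1 - a) * phi0 * (m^2 / s2^2 - 1 / s2)
      d2L_em <- a * (1 - a) * phi0 * m / s2
      f[zero] <- -log(L)
      dmu[zero] <- -dL_mu / L
      deta[zero] <- -dL_eta / L
      wmm[zero] <- -d2L_mu / L + (dL_mu / L)^2
      wee[zero] <- -d2L_eta / L + (dL_eta / L)^2
      wme[zero] <- -d2L_em / L + dL_mu * dL_eta / L^2
    }
  }
  list(f = sum(f), dmu = dmu, deta = deta, wmm = wmm, wee = wee, wme = wme)
}

.log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 33
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

# active random-effect layout for a design + theta: which Z columns carry a
# conditional / zero-inflation random intercept, and their prior variances
.re_layout <- function(design, theta, var_floor = 0) {
  rf <- design$rf
  lay <- function(factors, sds) {
    if (length(factors) == 0) {
      return(list(cols = integer(0), var = numeric(0)))
    }
    sds <- sds[factors]
    if (anyNA(sds)) stop("random-effect SD missing for factor(s): ",
                         paste(factors[is.na(sds)], collapse = ", "))
    keep <- sds > 0 | var_floor > 0
    factors <- factors[keep]; sds <- sds[keep]
    cols <- which(rf$factor_of_col %in%
                    match(factors, rf$factors))
    fac_of <- rf$factors[rf$factor_of_col[cols]]
    v <- pmax(sds[fac_of]^2, var_floor)
    list(cols = cols, var = as.numeric(v))
  }
  list(cond = lay(design$random, theta$sd_cond),
       zi = if (is.null(theta$gamma)) list(cols = integer(0),
                                           var = numeric(0))
            else lay(design$zi_random, theta$sd_zi))
}

#' Joint negative log-likelihood of data and random effects
#'
#' The objective whose mode over `b` the Laplace approximation expands
#' around: observation terms plus the Gaussian prior density of the random
#' effects (including its normalizing constant).
#'
#' @param theta a [zigmm_theta()].
#' @param b random-effects vector: conditional block then zero-inflation
#'   block, ordered as the active columns of the design's incidence matrix
#'   (factors with SD 0 carry no entries).
#' @param design a `zigmm_design` from [build_design()].
#' @param zero_density `"point_mass"` (default; observed zeros are
#'   structural) or `"mixture"` (adds the Gaussian density at zero, the
#'   convention of reference mixed-model software for zero-inflated
#'   continuous responses).
#' @return scalar negative log-likelihood.
#' @export
joint_negloglik <- function(theta, b, design,
                            zero_density = c("point_mass", "mixture")) {
  zero_density <- match.arg(zero_density)
  lay <- .re_layout(design, theta)
  qc <- length(lay$cond$cols); qz <- length(lay$zi$cols)
  stopifnot(length(b) == qc + qz)
  bc <- b[seq_len(qc)]; bz <- b[qc + seq_len(qz)]
  mu <- as.numeric(design$X %*% theta$beta)
  if (qc) mu <- mu + as.numeric(design$Z[, lay$cond$cols, drop = FALSE] %*% bc)
  eta <- if (is.null(theta$gamma)) NULL else {
    e <- as.numeric(design$X_zi %*% theta$gamma)
    if (qz) e <- e + as.numeric(design$Z[, lay$zi$cols, drop = FALSE] %*% bz)
    e
  }
  obs <- .obs_nll(design$y, design$zero, mu, eta, theta$sigma, zero_density)
  prior <- 0
  if (qc) prior <- prior + sum(0.5 * bc^2 / lay$cond$var +
                                 0.5 * log(2 * pi * lay$cond$var))
  if (qz) prior <- prior + sum(0.5 * bz^2 / lay$zi$var +
                                 0.5 * log(2 * pi * lay$zi$var))
  obs$f + prior
}

# Newton minimization of the joint negative log-likelihood over b.
# Returns the mode, the sparse Hessian there, and the objective value.
.inner_newton <- function(theta, design, zero_density, b_init = NULL,
                          tol = 1e-9, max_iter = 60L) {
  lay <- .re_layout(design, theta)
  qc <- length(lay$cond$cols); qz <- length(lay$zi$cols)
  q <- qc + qz
  Zc <- design$Z[, lay$cond$cols, drop = FALSE]
  Zz <- design$Z[, lay$zi$cols, drop = FALSE]
  dinv <- c(1 / lay$cond$var, 1 / lay$zi$var)
  b <- if (is.null(b_init) || length(b_init) != q) numeric(q) else b_init

  Xb <- as.numeric(design$X %*% theta$beta)
  Xg <- if (is.null(theta$gamma)) NULL
        else as.numeric(design$X_zi %*% theta$gamma)

  eval_at <- function(b) {
    bc <- b[seq_len(qc)]; bz <- b[qc + seq_len(qz)]
    mu <- Xb; if (qc) mu <- mu + as.numeric(Zc %*% bc)
    eta <- Xg; if (!is.null(eta) && qz) eta <- eta + as.numeric(Zz %*% bz)
    obs <- .obs_nll(design$y, design$zero, mu, eta, theta$sigma,
                    zero_density)
    obs$val <- obs$f + sum(0.5 * b^2 * dinv + 0.5 * log(2 * pi / dinv))
    obs
  }

  o <- eval_at(b)
  chol_cache <- NULL
  for (iter in seq_len(max_iter)) {
    g <- c(if (qc) as.numeric(Matrix::crossprod(Zc, o$dmu)) else numeric(0),
           if (qz) as.numeric(Matrix::crossprod(Zz, o$deta)) else numeric(0)) +
      b * dinv
    H <- .joint_hessian(Zc, Zz, o, dinv, qc, qz)
    if (max(abs(g)) < tol) break
    ch <- tryCatch({
      chol_cache <- if (is.null(chol_cache)) {
        Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
      } else {
        Matrix::update(chol_cache, H)
      }
      chol_cache
    }, error = function(e) NULL)
    if (is.null(ch)) {
      warning("ridge-stabilizing a singular inner Hessian")
      H <- H + Matrix::Diagonal(q, 1e-8)
      chol_cache <- Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
      ch <- chol_cache
    }
    step <- as.numeric(Matrix::solve(ch, g))
    # line search: halve until the objective does not increase
    lam <- 1
    repeat {
      b_new <- b - lam * step
      o_new <- eval_at(b_new)
      if (is.finite(o_new$val) && o_new$val <= o$val + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { b_new <- b; o_new <- o; break }
    }
    if (abs(o$val - o_new$val) < 1e-12 && lam < 1) { b <- b_new; o <- o_new; break }
    b <- b_new; o <- o_new
  }
  H <- .joint_hessian(Zc, Zz, o, dinv, qc, qz)
  list(b = b, H = H, value = o$val, q = q, layout = lay)
}

.joint_hessian <- function(Zc, Zz, o, dinv, qc, qz) {
  blocks <- list()
  Hcc <- if (qc) Matrix::crossprod(Zc, Zc * o$wmm) else NULL
  Hzz <- if (qz) Matrix::crossprod(Zz, Zz * o$wee) else NULL
  if (qc && qz) {
    if (any(o$wme != 0)) {
      Hcz <- Matrix::crossprod(Zc, Zz * o$wme)
      H <- rbind(cbind(Hcc, Hcz), cbind(Matrix::t(Hcz), Hzz))
    } else {
      H <- Matrix::bdiag(Hcc, Hzz)
    }
  } else if (qc) H <- Hcc else H <- Hzz
  H <- Matrix::forceSymmetric(H + Matrix::Diagonal(qc + qz, dinv))
  H
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' Minimizes the joint negative log-likelihood over the random effects by
#' sparse Newton iteration (the conditional block is quadratic, the
#' zero-inflation block is a convex logistic ridge) and returns
#' \deqn{f(\hat b) + \tfrac12 \log\det H - \tfrac q2 \log 2\pi,}
#' with `H` the Hessian of the joint objective at the mode. Exact when the
#' zero-inflation component is suppressed (Gaussian mixed model).
#' Deterministic given `theta`.
#'
#' @inheritParams joint_negloglik
#' @param b_init optional warm start for the inner Newton solve.
#' @return scalar; attributes `b_hat` (mode) and `q` (random dimension).
#' @export
marginal_negloglik <- function(theta, design,
                               zero_density = c("point_mass", "mixture"),
                               b_init = NULL) {
  zero_density <- match.arg(zero_density)
  lay <- .re_layout(design, theta)
  q <- length(lay$cond$cols) + length(lay$zi$cols)
  if (q == 0) {
    val <- joint_negloglik(theta, numeric(0), design, zero_density)
    return(structure(val, b_hat = numeric(0), q = 0L))
  }
  inner <- .inner_newton(theta, design, zero_density, b_init = b_init)
  ld <- 2 * Matrix::determinant(
    Matrix::Cholesky(inner$H, LDL = FALSE), sqrt = TRUE)$modulus
  val <- inner$value + 0.5 * as.numeric(ld) - inner$q / 2 * log(2 * pi)
  structure(val, b_hat = inner$b, q = inner$q)
}
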