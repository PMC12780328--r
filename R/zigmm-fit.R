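# Maximum-likelihood fitting.
#
# Under the point-mass zero convention the likelihood separates exactly:
#  * conditional part = Gaussian mixed model on the survivors' transformed
#    growth, fitted by the profiled marginal deviance (fixed effects and
#    residual variance solved in closed form per candidate vector of
#    relative random-effect SDs, which a box-constrained quasi-Newton
#    optimizer searches);
#  * zero-inflation part = logistic mixed model on the zero indicator,
#    fitted by maximizing the Laplace marginal over the fixed coefficients
#    and the random-effect SDs jointly, with a warm-started sparse Newton
#    solve for the random-effect modes inside each evaluation.
# Under the mixture convention the two parts couple at zero observations
# and a generic optimizer over all parameters is used instead.

#' Fit the zero-inflated Gaussian mixed model
#'
#' @param spec a [model_spec()].
#' @param dataset an `analysis_dataset` from [filter_records()].
#' @param zero_density zero-likelihood convention, see
#'   [marginal_negloglik()].
#' @param control list of optimizer settings: `rel_tol` (outer relative
#'   tolerance, default 1e-8), `max_iter` (default 500), `start` (optional
#'   named list with `theta_cond`, `gamma`, `sd_zi`).
#' @return a `zigmm` fit: coefficients, residual SD, per-factor
#'   random-effect SDs for both parts, random-effect modes, Laplace
#'   marginal log-likelihood, AIC, fixed-effect covariance matrices,
#'   convergence flags, and the scaling/transform metadata needed for
#'   prediction.
#' @export
fit_zigmm <- function(spec, dataset, zero_density = c("point_mass",
                                                      "mixture"),
                      control = list()) {
  zero_density <- match.arg(zero_density)
  ctrl <- utils::modifyList(list(rel_tol = 1e-8, max_iter = 500L,
                                 start = NULL), control)
  design <- build_design(dataset, spec)
  if (zero_density == "point_mass") {
    fit <- .fit_point_mass(spec, design, ctrl)
  } else {
    fit <- .fit_generic(spec, design, ctrl, zero_density)
  }
  fit$spec <- spec
  fit$zero_density <- zero_density
  fit$scaling <- dataset$scaling
  fit$transform <- dataset$transform
  fit$garden_mcmt_range <- dataset$garden_mcmt_range
  fit$n_obs <- design$n
  fit$n_params <- length(fit$beta) + 1L + length(fit$sd_cond) +
    length(fit$gamma) + length(fit$sd_zi)
  fit$aic <- 2 * fit$n_params - 2 * fit$loglik
  class(fit) <- "zigmm"
  fit
}

.fit_point_mass <- function(spec, design, ctrl) {
  nz <- !design$zero
  if (!any(nz)) stop("no nonzero responses: conditional part unidentifiable")

  # ---- conditional part: profiled Gaussian mixed model on survivors ----
  Xc <- design$X[nz, , drop = FALSE]
  rf <- design$rf
  cond_fac_idx <- match(spec$random, rf$factors)
  cond_cols_all <- which(rf$factor_of_col %in% cond_fac_idx)
  Zc_all <- design$Z[nz, cond_cols_all, drop = FALSE]
  used <- Matrix::colSums(Zc_all) > 0    # levels seen among survivors
  Zc <- Zc_all[, used, drop = FALSE]
  fac_of_col <- match(rf$factors[rf$factor_of_col[cond_cols_all][used]],
                      spec$random)
  lmm <- .fit_lmm_profiled(Xc, Zc, design$y[nz], fac_of_col,
                           n_fac = length(spec$random), ctrl = ctrl)
  sd_cond <- stats::setNames(lmm$theta * lmm$sigma, spec$random)
  b_cond_full <- numeric(length(cond_cols_all))
  b_cond_full[used] <- lmm$b

  # ---- zero-inflation part: Laplace logistic mixed model, all rows ----
  if (!is.null(spec$zi_terms)) {
    zi_fac_idx <- match(spec$zi_random, rf$factors)
    zi_cols <- which(rf$factor_of_col %in% zi_fac_idx)
    Zz <- design$Z[, zi_cols, drop = FALSE]
    fac_zi <- match(rf$factors[rf$factor_of_col[zi_cols]], spec$zi_random)
    zi <- .fit_zi_laplace(design$X_zi, Zz, design$zero, fac_zi,
                          n_fac = length(spec$zi_random), ctrl = ctrl)
    gamma <- stats::setNames(zi$gamma, colnames(design$X_zi))
    sd_zi <- stats::setNames(zi$sd, spec$zi_random)
    loglik <- lmm$loglik + zi$loglik
    conv <- lmm$convergence == 0 && zi$convergence == 0
  } else {
    zi <- NULL; gamma <- NULL; sd_zi <- numeric(0)
    loglik <- lmm$loglik
    conv <- lmm$convergence == 0
  }

  modes <- list(
    cond = .name_modes(b_cond_full, rf, cond_cols_all),
    zi = if (!is.null(zi)) .name_modes(zi$b, rf, zi_cols) else NULL
  )
  list(beta = stats::setNames(lmm$beta, colnames(design$X)),
       gamma = gamma,
       sigma = lmm$sigma, sd_cond = sd_cond, sd_zi = sd_zi,
       re_modes = modes, rf = rf,
       vcov_beta = lmm$vcov_beta, vcov_gamma = if (!is.null(zi)) zi$vcov,
       loglik = loglik, convergence = conv,
       convergence_detail = list(cond = lmm$convergence,
                                 zi = if (!is.null(zi)) zi$convergence))
}

.name_modes <- function(b, rf, cols) {
  fac <- rf$factors[rf$factor_of_col[cols]]
  lev <- unlist(lapply(rf$factors, function(f) rf$levels[[f]]))[cols]
  out <- split(stats::setNames(b, lev), fac)
  out[unique(fac)]
}

# profiled ML deviance of a Gaussian mixed model: theta are per-factor
# SDs relative to sigma; beta and sigma are profiled out exactly
.fit_lmm_profiled <- function(X, Z, y, fac_of_col, n_fac, ctrl) {
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  ZtX <- Matrix::crossprod(Z, X); Zty <- Matrix::crossprod(Z, y)
  ZtZ <- Matrix::crossprod(Z)
  env <- new.env(); env$chM <- NULL; env$chA <- NULL

  profile <- function(theta, smooth = TRUE) {
    lam <- theta[fac_of_col]
    # smooth floor keeps the sparsity pattern of the factor constant so
    # the symbolic Cholesky can be reused; the perturbation is O(1e-12)
    if (smooth) lam <- sqrt(lam^2 + 1e-12)
    Dl <- Matrix::Diagonal(x = lam)
    A <- Matrix::forceSymmetric(Dl %*% ZtZ %*% Dl + Matrix::Diagonal(q))
    ZtXl <- ZtX * lam
    M <- Matrix::forceSymmetric(rbind(cbind(A, ZtXl),
                                      cbind(Matrix::t(ZtXl), XtX)))
    rhs <- c(as.numeric(Zty) * lam, as.numeric(Xty))
    ch <- tryCatch({
      env$chM <- if (is.null(env$chM) || !smooth) {
        Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      } else Matrix::update(env$chM, M)
      env$chM
    }, error = function(e) Matrix::Cholesky(M, LDL = FALSE, perm = TRUE))
    sol <- as.numeric(Matrix::solve(ch, rhs))
    r2 <- max(yty - sum(rhs * sol), 1e-12)
    chA <- tryCatch({
      env$chA <- if (is.null(env$chA) || !smooth) {
        Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
      } else Matrix::update(env$chA, A)
      env$chA
    }, error = function(e) Matrix::Cholesky(A, LDL = FALSE, perm = TRUE))
    ld <- 2 * as.numeric(Matrix::determinant(chA, sqrt = TRUE)$modulus)
    dev <- ld + n * (1 + log(2 * pi * r2 / n))
    list(dev = dev, sol = sol, r2 = r2, M = M)
  }
  obj <- function(theta) profile(theta)$dev
  start <- rep(1, n_fac)
  opt <- .nlminb_restart(start, obj, lower = rep(0, n_fac),
                         control = list(rel.tol = ctrl$rel_tol,
                                        iter.max = ctrl$max_iter))
  pr <- profile(opt$par, smooth = FALSE)
  sigma2 <- pr$r2 / n
  beta <- pr$sol[q + seq_len(p)]
  u <- pr$sol[seq_len(q)]
  b <- opt$par[fac_of_col] * u
  # covariance of beta at the optimum: sigma^2 x the fixed-effect block of
  # the inverted penalized normal equations
  Einv <- Matrix::solve(pr$M,
                        rbind(Matrix::Matrix(0, q, p), diag(p)))
  vcov_beta <- as.matrix(sigma2 * Einv[q + seq_len(p), , drop = FALSE])
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  list(theta = opt$par, beta = beta, sigma = sqrt(sigma2), b = b,
       loglik = -opt$objective / 2, vcov_beta = vcov_beta,
       convergence = opt$convergence)
}

# box-constrained quasi-Newton with a single restart: PORT occasionally
# reports soft failure ("false convergence") right at a variance boundary;
# restarting from the final iterate either confirms the optimum or
# finishes the descent
.nlminb_restart <- function(start, objective, ...) {
  opt <- stats::nlminb(start, objective, ...)
  if (opt$convergence != 0) {
    opt2 <- stats::nlminb(opt$par, objective, ...)
    if (opt2$objective <= opt$objective) opt <- opt2
  }
  opt
}

# joint penalized IRLS over (gamma, b): cheap high-quality start for the
# outer optimization of the zero-inflation part
.zi_pirls <- function(Xz, Z, z01, var_col, gamma, env, max_iter = 25L) {
  p <- ncol(Xz); q <- ncol(Z)
  dinv <- 1 / var_col
  b <- env$b
  val_at <- function(gamma, b) {
    eta <- as.numeric(Xz %*% gamma) + as.numeric(Z %*% b)
    sum(.log1pexp(ifelse(z01 > 0, -eta, eta))) + 0.5 * sum(b^2 * dinv)
  }
  f <- val_at(gamma, b)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xz %*% gamma) + as.numeric(Z %*% b)
    pr <- stats::plogis(eta)
    u <- pr - z01
    g <- c(as.numeric(crossprod(Xz, u)),
           as.numeric(Matrix::crossprod(Z, u)) + b * dinv)
    if (max(abs(g)) < 1e-8) break
    w <- pmax(pr * (1 - pr), 1e-10)
    Hxx <- crossprod(Xz, Xz * w)
    Hxz <- Matrix::crossprod(Z, Xz * w)
    Hzz <- Matrix::crossprod(Z, Z * w) + Matrix::Diagonal(q, dinv)
    M <- Matrix::forceSymmetric(
      rbind(cbind(Matrix::Matrix(Hxx), Matrix::t(Hxz)),
            cbind(Hxz, Hzz)))
    step <- as.numeric(Matrix::solve(M, g))
    lam <- 1
    repeat {
      gamma_new <- gamma - lam * step[seq_len(p)]
      b_new <- b - lam * step[p + seq_len(q)]
      f_new <- val_at(gamma_new, b_new)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { gamma_new <- gamma; b_new <- b; f_new <- f; break }
    }
    gamma <- gamma_new; b <- b_new; f <- f_new
  }
  env$b <- b
  gamma
}

# Laplace marginal fit of the logistic (zero-inflation) mixed model:
# outer box-constrained quasi-Newton over (gamma, per-factor SDs), inner
# warm-started Newton over the random-effect vector
.fit_zi_laplace <- function(Xz, Z, zero, fac_of_col, n_fac, ctrl) {
  n <- nrow(Xz); p <- ncol(Xz); q <- ncol(Z)
  z01 <- as.numeric(zero)
  env <- new.env()
  env$b <- numeric(q)
  env$chol <- NULL

  inner <- function(gamma, var_col, keep_state = TRUE) {
    off <- as.numeric(Xz %*% gamma)
    b <- env$b
    dinv <- 1 / var_col
    val_at <- function(b) {
      eta <- off + as.numeric(Z %*% b)
      pnll <- .log1pexp(ifelse(zero, -eta, eta))
      sum(pnll) + sum(0.5 * b^2 * dinv + 0.5 * log(2 * pi * var_col))
    }
    f <- val_at(b)
    for (it in seq_len(60L)) {
      eta <- off + as.numeric(Z %*% b)
      pr <- stats::plogis(eta)
      g <- as.numeric(Matrix::crossprod(Z, pr - z01)) + b * dinv
      if (max(abs(g)) < 1e-9) break
      w <- pr * (1 - pr)
      H <- Matrix::crossprod(Z, Z * w) + Matrix::Diagonal(q, dinv)
      H <- Matrix::forceSymmetric(H)
      ch <- tryCatch({
        env$chol <- if (is.null(env$chol)) {
          Matrix::Cholesky(H, LDL = FALSE, perm = TRUE)
        } else Matrix::update(env$chol, H)
        env$chol
      }, error = function(e) {
        env$chol <- Matrix::Cholesky(H + Matrix::Diagonal(q, 1e-8),
                                     LDL = FALSE, perm = TRUE)
        env$chol
      })
      step <- as.numeric(Matrix::solve(ch, g))
      lam <- 1
      repeat {
        b_new <- b - lam * step
        f_new <- val_at(b_new)
        if (is.finite(f_new) && f_new <= f + 1e-12) break
        lam <- lam / 2
        if (lam < 1e-10) { b_new <- b; f_new <- f; break }
      }
      b <- b_new; f <- f_new
    }
    eta <- off + as.numeric(Z %*% b)
    pr <- stats::plogis(eta)
    w <- pr * (1 - pr)
    H <- Matrix::forceSymmetric(Matrix::crossprod(Z, Z * w) +
                       Matrix::Diagonal(q, 1 / var_col))
    ch <- tryCatch(Matrix::Cholesky(H, LDL = FALSE), error = function(e)
      Matrix::Cholesky(H + Matrix::Diagonal(q, 1e-8), LDL = FALSE))
    ld <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    if (keep_state) env$b <- b
    list(val = f + 0.5 * ld - q / 2 * log(2 * pi), b = b, w = w, H = H,
         u = pr - z01, wp = w * (1 - 2 * pr))
  }

  # variance per Z column from outer parameters; the small additive floor
  # keeps the objective smooth in sd through 0 and the Hessian pattern
  # constant, at a negligible O(1e-8) perturbation of the variances
  var_of <- function(sd) sd[fac_of_col]^2 + 1e-8

  # analytic gradient of the Laplace objective at the inner mode, using
  # the implicit derivative of the mode and per-row quadratic forms
  # s_i = z_i' H^-1 z_i obtained from sparse triangular solves
  grad_at <- function(gamma, sd, fin) {
    var_col <- var_of(sd)
    b <- fin$b; w <- fin$w; wp <- fin$wp; u <- fin$u
    ch <- Matrix::Cholesky(fin$H, LDL = FALSE, perm = TRUE)
    Lz <- Matrix::solve(ch, Matrix::solve(ch, Matrix::t(Z),
                                          system = "P"), system = "L")
    s <- Matrix::colSums(Lz^2)                    # diag(Z H^-1 Z')
    LI <- Matrix::solve(ch, Matrix::solve(ch, Matrix::Diagonal(q),
                                          system = "P"), system = "L")
    hinv_diag <- Matrix::colSums(LI^2)            # diag(H^-1)
    sw <- s * wp
    # gamma block
    ZtWX <- Matrix::crossprod(Z, Xz * w)          # q x p
    deta <- Xz - as.matrix(Z %*% Matrix::solve(ch, ZtWX))
    g_gamma <- as.numeric(crossprod(Xz, u)) +
      0.5 * as.numeric(crossprod(deta, sw))
    # sd block, via v_f = sd_f^2 + floor
    g_sd <- numeric(n_fac)
    for (f in seq_len(n_fac)) {
      j <- which(fac_of_col == f)
      if (!length(j)) next
      v <- var_col[j[1]]
      r <- numeric(q); r[j] <- b[j] / v^2
      dbdv <- as.numeric(Matrix::solve(ch, r))
      det_b <- as.numeric(Z %*% dbdv)
      dgdv <- sum(1 / (2 * v) - b[j]^2 / (2 * v^2)) -
        sum(hinv_diag[j]) / (2 * v^2) +
        0.5 * sum(sw * det_b)
      g_sd[f] <- dgdv * 2 * sd[f]
    }
    c(g_gamma, g_sd)
  }

  eval_par <- function(par) {
    gamma <- par[seq_len(p)]
    sd <- par[p + seq_len(n_fac)]
    if (!identical(par, env$last_par)) {
      env$last_fin <- inner(gamma, var_of(sd))
      env$last_par <- par
    }
    env$last_fin
  }
  obj <- function(par) eval_par(par)$val
  gr <- function(par) {
    fin <- eval_par(par)
    grad_at(par[seq_len(p)], par[p + seq_len(n_fac)], fin)
  }

  start_gamma <- if (!is.null(ctrl$start$gamma)) ctrl$start$gamma else
    tryCatch(stats::glm.fit(Xz, z01,
                            family = stats::binomial())$coefficients,
             error = function(e) numeric(p))
  start_gamma[!is.finite(start_gamma)] <- 0
  start_sd <- if (!is.null(ctrl$start$sd_zi)) ctrl$start$sd_zi else
    rep(0.5, n_fac)
  # refine the fixed-coefficient start by a joint penalized IRLS over
  # (gamma, b) at the starting SDs
  start_gamma <- .zi_pirls(Xz, Z, z01, var_of(start_sd), start_gamma, env)
  env$last_par <- NULL
  opt <- .nlminb_restart(c(start_gamma, start_sd), obj, gradient = gr,
                         lower = c(rep(-Inf, p), rep(0, n_fac)),
                         control = list(rel.tol = ctrl$rel_tol,
                                        iter.max = ctrl$max_iter))
  gamma <- opt$par[seq_len(p)]
  sd <- opt$par[p + seq_len(n_fac)]
  fin <- inner(gamma, var_of(sd))
  # fixed-effect covariance: Schur complement of the joint (gamma, b)
  # Hessian of the joint negative log-likelihood at the mode
  W <- fin$w
  Hgg <- crossprod(Xz, Xz * W)
  Hgb <- Matrix::crossprod(Z, Xz * W)          # q x p
  S <- Hgg - as.matrix(Matrix::crossprod(Hgb, Matrix::solve(fin$H, Hgb)))
  vcov <- tryCatch(solve(S), error = function(e) {
    warning("singular zero-inflation information; ridge added")
    solve(S + diag(1e-8, p))
  })
  dimnames(vcov) <- list(colnames(Xz), colnames(Xz))
  list(gamma = gamma, sd = sd, b = fin$b, loglik = -fin$val,
       vcov = vcov, convergence = opt$convergence)
}

# generic fit used for the mixture zero convention: outer optimization of
# the Laplace marginal over all parameters at once
.fit_generic <- function(spec, design, ctrl, zero_density) {
  p <- ncol(design$X)
  pz <- if (is.null(design$X_zi)) 0L else ncol(design$X_zi)
  kc <- length(spec$random)
  kz <- length(spec$zi_random)
  env <- new.env(); env$b <- NULL

  unpack <- function(par) {
    beta <- par[seq_len(p)]
    gamma <- if (pz) par[p + seq_len(pz)] else NULL
    sigma <- unname(exp(par[p + pz + 1]))
    sd_cond <- stats::setNames(pmax(par[p + pz + 1 + seq_len(kc)], 0),
                               spec$random)
    sd_zi <- if (kz) stats::setNames(pmax(par[p + pz + 1 + kc + seq_len(kz)],
                                          0), spec$zi_random) else numeric(0)
    zigmm_theta(beta, gamma, sigma, sd_cond, sd_zi)
  }
  obj <- function(par) {
    th <- unpack(par)
    th$sd_cond <- pmax(th$sd_cond, 1e-6)
    if (length(th$sd_zi)) th$sd_zi <- pmax(th$sd_zi, 1e-6)
    v <- marginal_negloglik(th, design, zero_density, b_init = env$b)
    env$b <- attr(v, "b_hat")
    as.numeric(v)
  }
  # deterministic start: point-mass fit if available, else neutral values
  start <- tryCatch({
    pmfit <- .fit_point_mass(spec, design, ctrl)
    c(pmfit$beta, pmfit$gamma, log(pmfit$sigma),
      pmax(pmfit$sd_cond, 0.05), pmax(pmfit$sd_zi, 0.05))
  }, error = function(e) c(rep(0, p + pz), 0, rep(exp(-1), kc + kz)))
  lower <- c(rep(-Inf, p + pz), -Inf, rep(1e-6, kc + kz))
  opt <- .nlminb_restart(start, obj, lower = lower,
                         control = list(rel.tol = ctrl$rel_tol,
                                        iter.max = ctrl$max_iter))
  th <- unpack(opt$par)
  vcov_all <- .numeric_fixed_vcov(opt$par, obj, p, pz)
  modes_v <- attr(marginal_negloglik(th, design, zero_density,
                                     b_init = env$b), "b_hat")
  lay <- .re_layout(design, th)
  rf <- design$rf
  qc <- length(lay$cond$cols)
  list(beta = stats::setNames(th$beta, colnames(design$X)),
       gamma = if (pz) stats::setNames(th$gamma, colnames(design$X_zi)),
       sigma = th$sigma, sd_cond = th$sd_cond, sd_zi = th$sd_zi,
       re_modes = list(
         cond = .name_modes(modes_v[seq_len(qc)], rf, lay$cond$cols),
         zi = if (pz) .name_modes(modes_v[qc + seq_along(lay$zi$cols)], rf,
                                  lay$zi$cols)),
       rf = rf,
       vcov_beta = vcov_all$beta, vcov_gamma = vcov_all$gamma,
       loglik = -opt$objective, convergence = opt$convergence == 0,
       convergence_detail = list(joint = opt$convergence))
}

# numeric observed-information covariance for the fixed blocks
.numeric_fixed_vcov <- function(par, obj, p, pz) {
  idx <- seq_len(p + pz)
  hstep <- 1e-4 * pmax(abs(par[idx]), 1)
  k <- length(idx)
  Hn <- matrix(0, k, k)
  f0 <- obj(par)
  fp <- numeric(k); fm <- numeric(k)
  for (i in seq_len(k)) {
    e <- numeric(length(par)); e[idx[i]] <- hstep[i]
    fp[i] <- obj(par + e); fm[i] <- obj(par - e)
    Hn[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hstep[i]^2
  }
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    e1 <- numeric(length(par)); e1[idx[i]] <- hstep[i]
    e2 <- numeric(length(par)); e2[idx[j]] <- hstep[j]
    fpp <- obj(par + e1 + e2)
    Hn[i, j] <- Hn[j, i] <-
      (fpp - fp[i] - fp[j] + f0) / (hstep[i] * hstep[j])
  }
  V <- tryCatch(solve(Hn), error = function(e) solve(Hn + diag(1e-8, k)))
  list(beta = V[seq_len(p), seq_len(p), drop = FALSE],
       gamma = if (pz) V[p + seq_len(pz), p + seq_len(pz), drop = FALSE])
}

#' @export
print.zigmm <- function(x, ...) {
  cat("Zero-inflated Gaussian mixed model (Laplace ML), model '",
      x$spec$name, "'\n", sep = "")
  cat("  n =", x$n_obs, " logLik =", round(x$loglik, 2),
      " AIC =", round(x$aic, 2),
      " converged:", x$convergence, "\n")
  cat("  sigma =", round(x$sigma, 4), "\n")
  cat("  random-effect SDs (conditional):",
      paste(names(x$sd_cond), round(x$sd_cond, 3), sep = "=",
            collapse = ", "), "\n")
  if (length(x$sd_zi)) {
    cat("  random-effect SDs (zero-infl.):",
        paste(names(x$sd_zi), round(x$sd_zi, 3), sep = "=",
              collapse = ", "), "\n")
  }
  cat("  conditional coefficients:\n")
  print(round(x$beta, 4))
  if (!is.null(x$gamma)) {
    cat("  zero-inflation coefficients (logit):\n")
    print(round(x$gamma, 4))
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Stores everything needed to reconstruct predictions: coefficients,
#' variance components, random-effect modes, scaling divisors, transform
#' tag, and convergence diagnostics.
#'
#' @param fit a `zigmm` object.
#' @param path output path.
#' @export
write_zigmm_json <- function(fit, path) {
  stopifnot(inherits(fit, "zigmm"))
  out <- fit[c("beta", "gamma", "sigma", "sd_cond", "sd_zi", "loglik",
               "aic", "n_params", "n_obs", "convergence", "scaling",
               "transform", "garden_mcmt_range", "zero_density")]
  out$re_modes <- fit$re_modes
  out$spec <- unclass(fit$spec)
  # named vectors become JSON objects, not bare arrays
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  out <- keep_names(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
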