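#' Restricted log-likelihood of the one-GRM mixed model
#'
#' Evaluates, by dense Cholesky factorization, the standard restricted
#' log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right],}
#' with \eqn{V = \sigma_G^2 A + \sigma_e^2 I} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}, up to the usual
#' additive constant. Exposed so optimizer, oracle tests and
#' likelihood-ratio tests share one definition. This code path is
#' deliberately independent of the eigendecomposition route used by
#' \code{\link{fit_univariate}}.
#'
#' @param sigma_g2,sigma_e2 variance components.
#' @param y response vector (no missing values).
#' @param X fixed-effect design matrix, full column rank.
#' @param A GRM matrix (plain matrix) aligned with \code{y}.
#' @return restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(sigma_g2, sigma_e2, y, X, A) {
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(A) == n, ncol(A) == n)
  V <- sigma_g2 * A + diag(sigma_e2, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("V is not positive definite")
  logdet_v <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) stop("X'V^{-1}X is singular")
  logdet_x <- 2 * sum(log(diag(Rx)))
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  -0.5 * (logdet_v + logdet_x + yPy)
}

# drop columns that are linearly dependent on the retained rows so the
# fixed-effect design is full column rank (warn: the dropped effects are
# not estimable on this subsample)
drop_rank_deficient <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    warning("design rank deficient on the retained rows; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  X
}

# restricted log-likelihood of the residual-only model (sigma_g2 = 0),
# maximized over sigma_e2; closed form via OLS
null_reml <- function(y, X) {
  n <- length(y)
  p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  se <- rss / (n - p)
  logdet_xtx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
  logl <- -0.5 * ((n - p) * log(se) + logdet_xtx + (n - p))
  list(sigma_e2 = se, loglik = logl)
}

# core univariate AI-REML in the eigenbasis of A:
# ytil = Q'y, Xtil = Q'X, V = diag(sg * lambda + se)
reml_eigen_core <- function(lambda, ytil, Xtil, Vp, constrain = TRUE,
                            max_iter = 100L, tol = 1e-8) {
  n <- length(ytil)
  p <- ncol(Xtil)
  floor_v <- 1e-6 * Vp
  theta <- c(Vp / 2, Vp / 2) # (sigma_g2, sigma_e2)

  eval_theta <- function(th) {
    d <- th[1] * lambda + th[2]
    if (any(d <= 0)) return(NULL)
    u <- ytil / d
    Wx <- Xtil / d
    XtViX <- crossprod(Xtil, Wx)
    Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(Rx)) return(NULL)
    Cx <- chol2inv(Rx)
    b <- Cx %*% crossprod(Xtil, u)
    Py <- u - Wx %*% b
    yPy <- sum(ytil * Py)
    logl <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(Rx))) + yPy)
    list(d = d, Py = as.numeric(Py), yPy = yPy, logl = logl, Cx = Cx,
         Wx = Wx)
  }

  # gradient, AI matrix and traces at a state
  derivs <- function(th, st) {
    vks <- list(lambda, rep(1, n))
    Py <- st$Py
    # apply P to a vector: Pz = z/d - Wx Cx Xtil'(z/d), Wx = Xtil/d
    Pv <- function(z) {
      u <- z / st$d
      as.numeric(u - st$Wx %*% (st$Cx %*% crossprod(Xtil, u)))
    }
    w <- lapply(vks, function(v) v * Py)
    yPVkPy <- vapply(w, function(wk) sum(wk * Py), numeric(1))
    trPVk <- vapply(vks, function(v) {
      # tr(P Vk) = tr(V^-1 Vk) - tr(Cx Xtil' diag(v/d^2) Xtil)
      Mv <- crossprod(st$Wx * v, st$Wx)
      sum(v / st$d) - sum(st$Cx * t(Mv))
    }, numeric(1))
    grad <- -0.5 * (trPVk - yPVkPy)
    AI <- matrix(0, 2, 2)
    Pw <- lapply(w, Pv)
    for (i in 1:2) for (j in i:2) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
    }
    list(grad = grad, AI = AI, yPVkPy = yPVkPy, trPVk = trPVk)
  }

  st <- eval_theta(theta)
  if (is.null(st)) stop("starting point gives singular V")
  # one EM-REML warm-up step
  dv <- derivs(theta, st)
  theta_em <- theta + theta^2 * (dv$yPVkPy - dv$trPVk) / n
  theta_em <- pmax(theta_em, floor_v)
  st_em <- eval_theta(theta_em)
  if (!is.null(st_em) && st_em$logl >= st$logl) {
    theta <- theta_em
    st <- st_em
  }

  converged <- FALSE
  identifiable <- TRUE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dv <- derivs(theta, st)
    rc <- tryCatch(rcond(dv$AI), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) {
      identifiable <- FALSE
      # EM fallback keeps iterating along the identifiable direction
      delta <- theta^2 * (dv$yPVkPy - dv$trPVk) / n
    } else {
      delta <- as.numeric(solve(dv$AI, dv$grad))
    }
    step <- 1
    improved <- FALSE
    for (h in 1:12) {
      cand <- theta + step * delta
      if (constrain) cand <- pmax(cand, floor_v)
      stc <- eval_theta(cand)
      if (!is.null(stc) && stc$logl >= st$logl - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) { # EM fallback step
      cand <- pmax(theta + theta^2 * (dv$yPVkPy - dv$trPVk) / n, floor_v)
      stc <- eval_theta(cand)
      if (is.null(stc) || stc$logl < st$logl - 1e-10) {
        converged <- TRUE # cannot improve further
        break
      }
    }
    gain <- stc$logl - st$logl
    theta <- if (improved) pmax(theta + step * delta,
                                if (constrain) floor_v else -Inf) else cand
    st <- stc
    if (abs(gain) < tol) {
      converged <- TRUE
      break
    }
  }
  dv <- derivs(theta, st)
  rc <- tryCatch(rcond(dv$AI), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) identifiable <- FALSE
  Sigma <- if (identifiable) solve(dv$AI) else matrix(NA_real_, 2, 2)
  boundary <- constrain & any(theta <= floor_v * (1 + 1e-9))
  list(theta = theta, loglik = st$logl, Sigma = Sigma, iterations = iter,
       converged = converged, identifiable = identifiable,
       boundary = boundary)
}

#' Fit a univariate GREML model by AI-REML
#'
#' Maximizes the restricted likelihood of \eqn{y = X\beta + g + e},
#' \eqn{g \sim N(0, \sigma_G^2 A)}, \eqn{e \sim N(0, \sigma_e^2 I)}.
#' Internally the GRM is eigendecomposed once, making each AI iteration
#' linear in n. Optimization: one EM-REML step from
#' \eqn{(V_P/2, V_P/2)}, then average-information updates with
#' step-halving and EM fallback so the restricted likelihood never
#' decreases; convergence when the improvement falls below 1e-8 (at most
#' 100 iterations); components constrained above \eqn{10^{-6} V_P} with a
#' boundary flag. The SE of \eqn{h^2 = \sigma_G^2/(\sigma_G^2+\sigma_e^2)}
#' comes from the inverse average-information matrix by the delta method.
#' A likelihood-ratio test against \eqn{\sigma_G^2 = 0} (one-tailed
#' boundary mixture) is included.
#'
#' @param y response with missing values allowed (rows dropped).
#' @param X fixed-effect design matrix aligned with \code{y} (a plain
#'   intercept is used if NULL).
#' @param A GRM matrix aligned with \code{y}, or a \code{grm} object.
#' @param eig optional precomputed \code{eigen(A[obs, obs])} for replicate
#'   designs re-using one GRM with an identical missingness pattern.
#' @param constrain constrain components non-negative (default TRUE).
#' @param max_iter,tol optimizer controls.
#' @param min_n warn when fewer observations remain (default 30).
#' @return An object of class \code{reml_fit}.
#' @export
fit_univariate <- function(y, X = NULL, A = NULL, eig = NULL,
                           constrain = TRUE, max_iter = 100L, tol = 1e-8,
                           min_n = 30L) {
  if (inherits(A, "grm")) A <- A$A
  n_all <- length(y)
  if (!is.null(A) && nrow(A) != n_all) {
    stop("GRM has ", nrow(A), " rows but y has ", n_all,
         " elements; align them (subset_grm + match by IID) first")
  }
  if (is.null(X)) X <- matrix(1, n_all, 1)
  if (nrow(X) != n_all) stop("X and y have different numbers of rows")
  obs <- which(!is.na(y))
  n <- length(obs)
  if (n < min_n) {
    warning("only ", n, " observations available (fewer than ", min_n, ")")
  }
  Xo <- drop_rank_deficient(X[obs, , drop = FALSE])
  if (n <= ncol(Xo) + 2L) stop("too few observations to fit the model")
  yo <- y[obs]
  if (is.null(eig)) {
    stopifnot(!is.null(A))
    eig <- eigen(A[obs, obs, drop = FALSE], symmetric = TRUE)
  }
  ytil <- crossprod(eig$vectors, yo)[, 1]
  Xtil <- crossprod(eig$vectors, Xo)
  Vp <- stats::var(yo)
  core <- reml_eigen_core(eig$values, ytil, Xtil, Vp, constrain = constrain,
                          max_iter = max_iter, tol = tol)
  if (!core$converged) {
    warning("REML did not converge in ", max_iter, " iterations")
  }
  if (!core$identifiable) {
    warning("variance components not jointly identifiable (average-",
            "information matrix numerically singular); estimates span a ",
            "flat likelihood direction")
  }
  nm <- null_reml(yo, Xo)
  if (constrain && core$theta[1] <= 1e-6 * Vp * (1 + 1e-9) &&
      nm$loglik > core$loglik) {
    # the floored component is a numerical stand-in for the boundary of
    # the parameter space; sigma_g2 = 0 is the constrained optimum here
    core$theta <- c(0, nm$sigma_e2)
    core$loglik <- nm$loglik
    core$boundary <- TRUE
  }
  sg <- core$theta[1]
  se <- core$theta[2]
  vp <- sg + se
  h2 <- sg / vp
  grad_h2 <- c(se, -sg) / vp^2
  se_h2 <- if (all(is.finite(core$Sigma))) {
    sqrt(max(0, drop(t(grad_h2) %*% core$Sigma %*% grad_h2)))
  } else NA_real_
  lrt <- lrt_p(core$loglik, nm$loglik, boundary = TRUE)
  structure(list(
    sigma_g2 = sg, sigma_e2 = se, sigma_p2 = vp, h2 = h2, se_h2 = se_h2,
    log_likelihood = core$loglik, null_log_likelihood = nm$loglik,
    lrt_p = lrt, n_used = n, converged = core$converged,
    identifiable = core$identifiable, boundary = core$boundary,
    iterations = core$iterations, sampling_cov = core$Sigma,
    obs_index = obs
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("GREML fit: n=%d  sigma_g2=%.4f  sigma_e2=%.4f  h2=%.3f (SE %.3f)\n",
              x$n_used, x$sigma_g2, x$sigma_e2, x$h2, x$se_h2))
  cat(sprintf("  logL=%.4f  LRT p=%.3g  converged=%s%s\n",
              x$log_likelihood, x$lrt_p, x$converged,
              if (!x$identifiable) "  [NOT IDENTIFIABLE]" else ""))
  invisible(x)
}

#' Likelihood-ratio test p-value for variance-component and covariance tests
#'
#' \eqn{\Lambda = 2(\ell_{full} - \ell_{null})}, floored at 0. With
#' \code{boundary = TRUE} (a variance tested on the boundary of its space)
#' the null distribution is the one-tailed mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}, so
#' \eqn{p = \tfrac12 P(\chi^2_1 \ge \Lambda)} (and p = 0.5 at
#' \eqn{\Lambda = 0}); with \code{boundary = FALSE} (an interior
#' parameter, e.g. a covariance) the ordinary \eqn{\chi^2_1} applies.
#'
#' @param full_loglik,null_loglik restricted log-likelihoods.
#' @param boundary is the tested parameter on its boundary?
#' @return p-value.
#' @export
lrt_p <- function(full_loglik, null_loglik, boundary = TRUE) {
  lambda <- 2 * (full_loglik - null_loglik)
  if (lambda < -1e-6) {
    stop("full model log-likelihood below null beyond tolerance ",
         "(optimizer defect): Lambda = ", lambda)
  }
  lambda <- max(0, lambda)
  p <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  if (boundary) {
    if (lambda == 0) 0.5 else 0.5 * p
  } else {
    p
  }
}
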