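# Bivariate GREML: stacked mixed model over the union of rows observed for
# either trait. Var(y_t) = sg_t A + se_t I on trait-t rows;
# Cov(y1, y2) = cg A between any pair of individuals, plus ce on the
# diagonal cells of individuals observed for both traits. Component order
# throughout: (sg1, sg2, se1, se2, cg, ce).

# build V for a parameter vector
bivar_V <- function(th, blocks) {
  with(blocks, {
    V11 <- th[1] * A11 + diag(th[3], n1)
    V22 <- th[2] * A22 + diag(th[4], n2)
    V12 <- th[5] * A12
    if (n_overlap > 0) {
      V12[overlap_cells] <- V12[overlap_cells] + th[6]
    }
    rbind(cbind(V11, V12), cbind(t(V12), V22))
  })
}

# restricted log-likelihood only (cheap line-search evaluation); the
# Cholesky factor is attached so an accepted candidate's factorization can
# be re-used by the derivative pass
bivar_loglik <- function(th, blocks, with_chol = FALSE) {
  V <- bivar_V(th, blocks)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  X <- blocks$X
  y <- blocks$y
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(-Inf)
  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  out <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) + yPy)
  if (with_chol) attr(out, "chol") <- R
  out
}

# trace of P Vk and Vk %*% Py for each active component, plus AI matrix
bivar_derivs <- function(th, blocks, active, R = NULL) {
  if (is.null(R)) R <- chol(bivar_V(th, blocks))
  Vi <- chol2inv(R)
  X <- blocks$X
  y <- blocks$y
  VX <- Vi %*% X
  XtViX <- crossprod(X, VX)
  Cx <- solve(XtViX)
  Viy <- Vi %*% y
  b <- Cx %*% crossprod(X, Viy)
  Py <- as.numeric(Viy - VX %*% b)
  yPy <- sum(y * Py)
  logl <- -0.5 * (2 * sum(log(diag(R))) +
                    as.numeric(determinant(XtViX)$modulus) + yPy)
  P <- Vi - VX %*% tcrossprod(Cx, VX)
  n1 <- blocks$n1; n2 <- blocks$n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  P11 <- P[i1, i1, drop = FALSE]
  P22 <- P[i2, i2, drop = FALSE]
  P12 <- P[i1, i2, drop = FALSE]
  Py1 <- Py[i1]; Py2 <- Py[i2]
  tr <- numeric(6)
  W <- matrix(0, n1 + n2, 6)
  tr[1] <- sum(P11 * blocks$A11)
  W[i1, 1] <- blocks$A11 %*% Py1
  tr[2] <- sum(P22 * blocks$A22)
  W[i2, 2] <- blocks$A22 %*% Py2
  tr[3] <- sum(diag(P11))
  W[i1, 3] <- Py1
  tr[4] <- sum(diag(P22))
  W[i2, 4] <- Py2
  tr[5] <- 2 * sum(P12 * blocks$A12)
  W[i1, 5] <- blocks$A12 %*% Py2
  W[i2, 5] <- crossprod(blocks$A12, Py1)
  if (blocks$n_overlap > 0) {
    oc <- blocks$overlap_cells
    tr[6] <- 2 * sum(P12[oc])
    w6 <- numeric(n1 + n2)
    w6[oc[, 1]] <- Py2[oc[, 2]]
    w6[n1 + oc[, 2]] <- Py1[oc[, 1]]
    W[, 6] <- w6
  }
  grad <- -0.5 * (tr - as.numeric(crossprod(W, Py)))
  PW <- P %*% W[, active, drop = FALSE]
  AI <- 0.5 * crossprod(W[, active, drop = FALSE], PW)
  list(logl = logl, grad = grad[active], AI = AI, Py = Py)
}

#' Fit a bivariate GREML model by AI-REML
#'
#' Stacked model over the union of rows observed for either trait: each
#' trait has its own genetic and residual variance; the cross-trait
#' genetic covariance \code{cov_g} acts through the GRM between all pairs
#' of individuals, while the residual covariance \code{cov_e} only applies
#' to individuals observed on both traits (and is fixed at 0, with a
#' warning, when there is no overlap). Starting values come from the two
#' univariate fits with zero covariances; optimization is
#' average-information REML with step-halving so the restricted likelihood
#' never decreases, tolerance 1e-8, at most 100 iterations, variance
#' components floored at 1e-6 of the trait's phenotypic variance and (by
#' default) covariances constrained so the 2x2 component matrices stay
#' positive semi-definite.
#'
#' @param y1,y2 trait vectors aligned with the GRM ids, NA = unobserved.
#' @param X1,X2 full-length design matrices for each trait (NULL =
#'   intercept).
#' @param A GRM matrix or \code{grm} object for all individuals.
#' @param constrain keep component matrices PSD (default TRUE).
#' @param fix_cov_g fix the genetic covariance at 0 (the reference model of
#'   the likelihood-ratio test for the genetic correlation).
#' @param max_iter,tol optimizer controls.
#' @param min_n_union warn below this union size (default 60).
#' @return An object of class \code{bivar_fit} with per-trait components,
#'   covariances, 6x6 sampling covariance (order sg1, sg2, se1, se2, cg,
#'   ce), log-likelihood, per-trait and overlap Ns and flags.
#' @export
fit_bivariate <- function(y1, y2, X1 = NULL, X2 = NULL, A,
                          constrain = TRUE, fix_cov_g = FALSE,
                          max_iter = 100L, tol = 1e-8,
                          min_n_union = 60L) {
  if (inherits(A, "grm")) A <- A$A
  n_all <- length(y1)
  stopifnot(length(y2) == n_all, nrow(A) == n_all)
  if (is.null(X1)) X1 <- matrix(1, n_all, 1)
  if (is.null(X2)) X2 <- matrix(1, n_all, 1)
  idx1 <- which(!is.na(y1))
  idx2 <- which(!is.na(y2))
  n1 <- length(idx1); n2 <- length(idx2)

  # degenerate case: one trait entirely missing -> univariate fit
  if (n2 == 0L || n1 == 0L) {
    warning("one trait has no observations; returning the univariate fit ",
            "of the other in bivariate form")
    if (n1 == 0L) { # swap so trait 1 is the observed one
      uni <- fit_univariate(y2, X2, A)
      return(.uni_as_bivar(uni, which_trait = 2L))
    }
    uni <- fit_univariate(y1, X1, A)
    return(.uni_as_bivar(uni, which_trait = 1L))
  }
  if (n1 + n2 < min_n_union) {
    warning("union of observed rows is only ", n1 + n2)
  }
  f1 <- fit_univariate(y1, X1, A, min_n = 0L)
  f2 <- fit_univariate(y2, X2, A, min_n = 0L)

  overlap <- intersect(idx1, idx2)
  n_overlap <- length(overlap)
  est_ce <- n_overlap > 0L
  if (!est_ce) {
    warning("no individuals observed on both traits: residual covariance ",
            "is unidentifiable and fixed at 0")
  }
  X1o <- drop_rank_deficient(X1[idx1, , drop = FALSE])
  X2o <- drop_rank_deficient(X2[idx2, , drop = FALSE])
  X <- rbind(cbind(X1o, matrix(0, n1, ncol(X2o))),
             cbind(matrix(0, n2, ncol(X1o)), X2o))
  blocks <- list(
    A11 = A[idx1, idx1, drop = FALSE],
    A22 = A[idx2, idx2, drop = FALSE],
    A12 = A[idx1, idx2, drop = FALSE],
    overlap_cells = cbind(match(overlap, idx1), match(overlap, idx2)),
    n1 = n1, n2 = n2, n_overlap = n_overlap,
    X = X, y = c(y1[idx1], y2[idx2])
  )
  vp <- c(stats::var(y1[idx1]), stats::var(y2[idx2]))
  floor_v <- 1e-6 * vp

  # Haseman-Elston moment starting values for the covariances: regress
  # centred cross products on the GRM over pairs of *different*
  # individuals (same-individual cells carry ce as well), then read ce
  # off the overlap residual
  # starting variances floored at 5% of Vp: a univariate fit that landed
  # near zero would otherwise pin the covariance clamp and make the
  # first iterations crawl along the PSD boundary
  sg_start <- c(max(f1$sigma_g2, 0.05 * vp[1]), max(f2$sigma_g2, 0.05 * vp[2]))
  r1 <- y1[idx1] - mean(y1[idx1])
  r2 <- y2[idx2] - mean(y2[idx2])
  A12w <- blocks$A12
  if (n_overlap > 0) A12w[blocks$overlap_cells] <- 0
  cg0 <- sum((r1 %*% t(r2)) * A12w) / max(sum(A12w^2), 1e-12)
  cg0 <- max(min(cg0, 0.9 * sqrt(prod(sg_start))),
             -0.9 * sqrt(prod(sg_start)))
  ce0 <- 0
  if (est_ce) {
    oc <- blocks$overlap_cells
    ce0 <- mean(r1[oc[, 1]] * r2[oc[, 2]]) - cg0
    ce0 <- max(min(ce0, 0.9 * sqrt(f1$sigma_e2 * f2$sigma_e2)),
               -0.9 * sqrt(f1$sigma_e2 * f2$sigma_e2))
  }
  if (fix_cov_g) cg0 <- 0
  theta <- c(sg_start, f1$sigma_e2, f2$sigma_e2, cg0, ce0)
  active <- seq_len(6)
  if (!est_ce) active <- setdiff(active, 6L)
  if (fix_cov_g) active <- setdiff(active, 5L)

  project <- function(th) {
    th[1:2] <- pmax(th[1:2], floor_v)
    th[3:4] <- pmax(th[3:4], floor_v)
    if (constrain) {
      cg_max <- sqrt(th[1] * th[2]) # PSD boundary, inclusive
      th[5] <- max(min(th[5], cg_max), -cg_max)
      ce_max <- sqrt(th[3] * th[4])
      th[6] <- max(min(th[6], ce_max), -ce_max)
    }
    if (!est_ce) th[6] <- 0
    if (fix_cov_g) th[5] <- 0
    th
  }
  theta <- project(theta)
  # empirical GRMs can be slightly indefinite, so a PSD component start
  # does not guarantee a positive-definite V: shrink the starting
  # covariances until the stacked covariance factorizes
  for (tries in 1:30) {
    if (is.finite(bivar_loglik(theta, blocks))) break
    theta[5:6] <- if (tries < 30L) theta[5:6] / 2 else c(0, 0)
    theta <- project(theta)
  }

  # With constrain = TRUE the optimization runs in a Cholesky
  # parameterization of the two 2x2 component matrices,
  # G = L L' (l11, l21, l22) and E = M M' (m11, m21, m22), where positive
  # semi-definiteness is automatic and the PSD boundary (|r| = 1, i.e.
  # l22 = 0) is an interior point of the parameter space. With
  # constrain = FALSE the step is taken directly in component space.
  # Either way the expensive quantities (gradient, average information)
  # are computed once per iteration in component space and mapped by the
  # chain rule.
  c2theta <- function(cc) {
    c(cc[1]^2, cc[2]^2 + cc[3]^2, cc[4]^2, cc[5]^2 + cc[6]^2,
      cc[1] * cc[2], cc[4] * cc[5])
  }
  chol_jacobian <- function(cc) {
    J <- matrix(0, 6, 6) # rows: theta (sg1, sg2, se1, se2, cg, ce)
    J[1, 1] <- 2 * cc[1]
    J[2, 2] <- 2 * cc[2]; J[2, 3] <- 2 * cc[3]
    J[3, 4] <- 2 * cc[4]
    J[4, 5] <- 2 * cc[5]; J[4, 6] <- 2 * cc[6]
    J[5, 1] <- cc[2]; J[5, 2] <- cc[1]
    J[6, 4] <- cc[5]; J[6, 5] <- cc[4]
    J
  }
  theta2c <- function(th) {
    l11 <- sqrt(th[1]); l21 <- th[5] / l11
    l22 <- sqrt(max(th[2] - l21^2, 1e-12))
    m11 <- sqrt(th[3]); m21 <- th[6] / m11
    m22 <- sqrt(max(th[4] - m21^2, 1e-12))
    c(l11, l21, l22, m11, m21, m22)
  }
  # free coordinates: fixed covariances pin the corresponding
  # off-diagonal Cholesky entry at 0
  free_c <- 1:6
  if (fix_cov_g) free_c <- setdiff(free_c, 2L)
  if (!est_ce) free_c <- setdiff(free_c, 5L)

  cpar <- theta2c(theta)
  if (fix_cov_g) cpar[2] <- 0
  if (!est_ce) cpar[5] <- 0
  dv <- bivar_derivs(theta, blocks, active)
  converged <- FALSE
  iter <- 0L
  n_small_gain <- 0L
  mu_levels <- c(0, 0.1, 1, 10, 100, 1e4)
  mu_start <- 1L # adaptive damping: remember the level that last worked
  cpar_hist <- list() # recent accepted iterates, for tail extrapolation
  prev_gain <- Inf
  freeze_count <- c(l22 = 0L, m22 = 0L)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (constrain) {
      J <- chol_jacobian(cpar)[active, free_c, drop = FALSE]
      grad_w <- as.numeric(crossprod(J, dv$grad))
      H_w <- crossprod(J, dv$AI %*% J)
    } else {
      grad_w <- dv$grad
      H_w <- dv$AI
    }
    scale_h <- mean(abs(diag(H_w))) + 1e-12
    accepted <- FALSE
    newton_full <- FALSE
    n_trials <- 0L
    for (mu_idx in seq(mu_start, length(mu_levels))) {
      mu <- mu_levels[mu_idx]
      delta_w <- tryCatch(
        as.numeric(solve(H_w + mu * scale_h * diag(nrow(H_w)), grad_w)),
        error = function(e) NULL)
      if (is.null(delta_w)) next
      step <- 1
      for (h in 1:4) {
        n_trials <- n_trials + 1L
        if (constrain) {
          cc <- cpar
          cc[free_c] <- cc[free_c] + step * delta_w
          cand <- project(c2theta(cc))
        } else {
          delta <- numeric(6)
          delta[active] <- delta_w
          cand <- project(theta + step * delta)
        }
        new_logl <- bivar_loglik(cand, blocks, with_chol = TRUE)
        if (is.finite(new_logl) && new_logl > dv$logl + 1e-13) {
          accepted <- TRUE
          newton_full <- (mu == 0 && step == 1)
          if (constrain) cpar <- cc
          break
        }
        step <- step / 2
        if (n_trials >= 12L) break
      }
      if (accepted || n_trials >= 12L) break
    }
    if (accepted) {
      mu_start <- max(1L, mu_idx - 1L)
    } else if (mu_start < length(mu_levels) && n_trials >= 12L) {
      mu_start <- min(mu_start + 2L, length(mu_levels))
      next # try again from heavier damping before giving up
    }
    if (!accepted) {
      # no damped direction improves the restricted likelihood: at the
      # optimum (possibly a floor) up to line-search resolution
      converged <- TRUE
      break
    }
    gain <- as.numeric(new_logl) - dv$logl
    theta <- cand
    cur_logl <- as.numeric(new_logl)
    chol_cur <- attr(new_logl, "chol")

    # boundary optima make projected steps converge geometrically; in the
    # tail, Aitken-extrapolate the iterate sequence and jump if it helps
    if (constrain) {
      # active-set freeze: when the orthogonal Cholesky coordinate of a
      # component matrix has collapsed (the fit is on the PSD boundary,
      # |r| within 2.5e-3 of 1), its Jacobian column vanishes and damped
      # steps crawl; pin it at 0 and Newton on the boundary manifold
      if (gain < 1e-2) {
        for (k in c(3L, 6L)) {
          v_idx <- if (k == 3L) 2L else 4L
          nm_k <- if (k == 3L) "l22" else "m22"
          if (k %in% free_c &&
              abs(cpar[k]) < 0.05 * sqrt(max(theta[v_idx], 1e-12))) {
            freeze_count[nm_k] <- freeze_count[nm_k] + 1L
            if (freeze_count[nm_k] >= 2L) {
              cpar[k] <- 0
              free_c <- setdiff(free_c, k)
              theta <- project(c2theta(cpar))
              chol_cur <- NULL # theta moved; refactorize in the deriv pass
              cpar_hist <- list()
            }
          } else {
            freeze_count[nm_k] <- 0L
          }
        }
      }
      cpar_hist <- c(cpar_hist, list(cpar))
      if (length(cpar_hist) > 3L) cpar_hist <- cpar_hist[-1]
      if (gain < 1e-3 && length(cpar_hist) == 3L) {
        d1 <- cpar_hist[[2]] - cpar_hist[[1]]
        d2 <- cpar_hist[[3]] - cpar_hist[[2]]
        ok <- abs(d1) > 1e-12
        if (any(ok)) {
          rho <- stats::median(pmin(pmax(d2[ok] / d1[ok], 0), 0.98))
          if (rho > 0.2) {
            cc_ex <- cpar + d2 * rho / (1 - rho)
            cc_ex[setdiff(1:6, free_c)] <- 0
            cand_ex <- project(c2theta(cc_ex))
            ll_ex <- bivar_loglik(cand_ex, blocks, with_chol = TRUE)
            if (is.finite(ll_ex) && ll_ex > cur_logl + 1e-13) {
              gain <- gain + as.numeric(ll_ex) - cur_logl
              cur_logl <- as.numeric(ll_ex)
              chol_cur <- attr(ll_ex, "chol")
              theta <- cand_ex
              cpar <- cc_ex
              cpar_hist <- list()
            }
          }
        }
      }
    }
    dv <- bivar_derivs(theta, blocks, active, R = chol_cur)

    # stop on: a full Newton step that no longer helps; repeated
    # sub-tolerance gains; or a geometric gain sequence whose projected
    # remaining improvement is negligible
    n_small_gain <- if (gain < tol) n_small_gain + 1L else 0L
    geo_done <- FALSE
    if (gain < 1e-6 && is.finite(prev_gain) && prev_gain > 0 &&
        gain < prev_gain) {
      rho_g <- gain / prev_gain
      geo_done <- gain * rho_g / (1 - rho_g) < tol
    }
    prev_gain <- gain
    if ((gain < tol && newton_full) || n_small_gain >= 3L || geo_done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("bivariate REML did not converge in ", max_iter,
                          " iterations")
  rc <- tryCatch(rcond(dv$AI), error = function(e) 0)
  Sigma <- matrix(NA_real_, 6, 6)
  if (is.finite(rc) && rc > 1e-12) {
    Sigma[active, active] <- solve(dv$AI)
    for (fx in setdiff(1:6, active)) {
      Sigma[fx, ] <- 0
      Sigma[, fx] <- 0
    }
  }
  dimnames(Sigma) <- rep(list(c("sg1", "sg2", "se1", "se2", "cg", "ce")), 2)
  boundary <- any(theta[1:4] <= 1e-6 * rep(vp, 2) * (1 + 1e-9)) ||
    (constrain &&
       abs(theta[5]) >= sqrt(theta[1] * theta[2]) * (1 - 1e-6))
  structure(list(
    sigma_g2 = stats::setNames(theta[1:2], c("trait1", "trait2")),
    sigma_e2 = stats::setNames(theta[3:4], c("trait1", "trait2")),
    cov_g = theta[5], cov_e = theta[6],
    log_likelihood = dv$logl, sampling_cov = Sigma,
    n1 = n1, n2 = n2, n_overlap = n_overlap,
    converged = converged, boundary = boundary, iterations = iter,
    uni_fits = list(f1, f2)
  ), class = "bivar_fit")
}

# wrap a univariate fit as a degenerate bivariate result
.uni_as_bivar <- function(uni, which_trait) {
  sg <- c(NA_real_, NA_real_)
  se <- c(NA_real_, NA_real_)
  sg[which_trait] <- uni$sigma_g2
  se[which_trait] <- uni$sigma_e2
  structure(list(
    sigma_g2 = stats::setNames(sg, c("trait1", "trait2")),
    sigma_e2 = stats::setNames(se, c("trait1", "trait2")),
    cov_g = NA_real_, cov_e = NA_real_,
    log_likelihood = uni$log_likelihood,
    sampling_cov = matrix(NA_real_, 6, 6),
    n1 = if (which_trait == 1L) uni$n_used else 0L,
    n2 = if (which_trait == 2L) uni$n_used else 0L,
    n_overlap = 0L, converged = uni$converged, boundary = uni$boundary,
    iterations = uni$iterations, uni_fits = list(uni)
  ), class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf("bivariate GREML: n1=%d n2=%d overlap=%d  logL=%.4f\n",
              x$n1, x$n2, x$n_overlap, x$log_likelihood))
  cat(sprintf("  sg=(%.4f, %.4f) se=(%.4f, %.4f) cov_g=%.4f cov_e=%.4f\n",
              x$sigma_g2[1], x$sigma_g2[2], x$sigma_e2[1], x$sigma_e2[2],
              x$cov_g, x$cov_e))
  invisible(x)
}
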