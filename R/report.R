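# Headline quantities from fitted variance components: genetic correlation,
# decomposition of the phenotypic correlation, delta-method SEs, and
# tabular reports. Component order everywhere: (sg1, sg2, se1, se2, cg, ce).

#' Assemble a bivariate component set from summary values
#'
#' Builds a \code{bivar_fit}-shaped object from printed summary statistics
#' (heritabilities, genetic correlation, and either the residual
#' correlation or the overall phenotypic correlation), assuming unit
#' phenotypic variances. Useful to push published table values through the
#' decomposition arithmetic.
#'
#' @param h2_1,h2_2 heritabilities of the two traits.
#' @param r_g genetic correlation.
#' @param r_e residual correlation (optional if \code{r_p_overall} given).
#' @param r_p_overall overall phenotypic correlation (used to back out
#'   \code{r_e} when it is not supplied).
#' @param sampling_cov optional 6x6 sampling covariance.
#' @return object of class \code{bivar_fit} (no likelihood, no Ns).
#' @export
bivariate_components <- function(h2_1, h2_2, r_g, r_e = NULL,
                                 r_p_overall = NULL, sampling_cov = NULL) {
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1, abs(r_g) <= 1)
  cg <- r_g * sqrt(h2_1 * h2_2)
  se1 <- 1 - h2_1
  se2 <- 1 - h2_2
  if (is.null(r_e)) {
    if (is.null(r_p_overall)) stop("supply r_e or r_p_overall")
    ce <- r_p_overall - cg # unit phenotypic variances
  } else {
    stopifnot(abs(r_e) <= 1)
    ce <- r_e * sqrt(se1 * se2)
  }
  if (is.null(sampling_cov)) sampling_cov <- matrix(NA_real_, 6, 6)
  structure(list(
    sigma_g2 = c(trait1 = h2_1, trait2 = h2_2),
    sigma_e2 = c(trait1 = se1, trait2 = se2),
    cov_g = cg, cov_e = ce,
    log_likelihood = NA_real_, sampling_cov = sampling_cov,
    n1 = NA_integer_, n2 = NA_integer_, n_overlap = NA_integer_,
    converged = TRUE, boundary = FALSE, iterations = 0L
  ), class = "bivar_fit")
}

.components <- function(fit) {
  c(fit$sigma_g2[[1]], fit$sigma_g2[[2]], fit$sigma_e2[[1]],
    fit$sigma_e2[[2]], fit$cov_g, fit$cov_e)
}

#' Genetic correlation from a bivariate fit
#'
#' \eqn{r_G = Cov(G) / \sqrt{\sigma^2_{G1}\sigma^2_{G2}}}, with its
#' delta-method SE propagated from the component sampling covariance
#' using the exact gradient.
#'
#' @param fit a \code{bivar_fit}.
#' @return list with \code{r_g}, \code{se} and \code{reliable} (FALSE when
#'   a genetic variance sits at its boundary floor).
#' @export
genetic_correlation <- function(fit) {
  th <- .components(fit)
  if (any(th[1:2] <= 0)) stop("both genetic variances must be positive")
  r_g <- th[5] / sqrt(th[1] * th[2])
  grad <- c(-r_g / (2 * th[1]), -r_g / (2 * th[2]), 0, 0,
            1 / sqrt(th[1] * th[2]), 0)
  se <- delta_se(NULL, th, fit$sampling_cov, gradient = grad)
  list(r_g = r_g, se = se, reliable = !isTRUE(fit$boundary))
}

#' Decompose the phenotypic correlation into genetic and residual parts
#'
#' With \eqn{h^2_t = \sigma^2_{Gt}/\sigma^2_{Pt}} and
#' \eqn{e^2_t = 1 - h^2_t}, the model-implied phenotypic correlation
#' splits as
#' \deqn{r_P = \sqrt{h^2_1}\, r_G \sqrt{h^2_2} +
#'             \sqrt{e^2_1}\, r_E \sqrt{e^2_2},}
#' i.e. a genetic part \eqn{Cov(G)/\sqrt{\sigma^2_{P1}\sigma^2_{P2}}} and a
#' residual part \eqn{Cov(E)/\sqrt{\sigma^2_{P1}\sigma^2_{P2}}} that sum
#' to the overall correlation exactly. The genetic share is the ratio of
#' the genetic part to the overall. All SEs are delta-method, propagated
#' from the full 6x6 component sampling covariance with exact gradients.
#'
#' @param fit a \code{bivar_fit}.
#' @return An object of class \code{decomposition} with r_g, r_e, h2, e2,
#'   the three parts of r(P), the genetic share, and an SE for each.
#' @export
decompose_phenotypic_correlation <- function(fit) {
  th <- .components(fit)
  sg1 <- th[1]; sg2 <- th[2]; se1 <- th[3]; se2 <- th[4]
  cg <- th[5]; ce <- th[6]
  p1 <- sg1 + se1
  p2 <- sg2 + se2
  S <- fit$sampling_cov
  sqp <- sqrt(p1 * p2)

  r_g <- cg / sqrt(sg1 * sg2)
  r_e <- ce / sqrt(se1 * se2)
  h2 <- c(sg1 / p1, sg2 / p2)
  e2 <- 1 - h2
  r_p_gen <- cg / sqp
  r_p_env <- ce / sqp
  r_p <- r_p_gen + r_p_env

  # exact gradients wrt (sg1, sg2, se1, se2, cg, ce)
  g_rg <- c(-r_g / (2 * sg1), -r_g / (2 * sg2), 0, 0,
            1 / sqrt(sg1 * sg2), 0)
  g_re <- c(0, 0, -r_e / (2 * se1), -r_e / (2 * se2), 0,
            1 / sqrt(se1 * se2))
  g_h21 <- c(se1 / p1^2, 0, -sg1 / p1^2, 0, 0, 0)
  g_h22 <- c(0, se2 / p2^2, 0, -sg2 / p2^2, 0, 0)
  # d/dθ of c / sqrt(p1 p2): scale terms hit both variance components
  part_grad <- function(cc, d_c) {
    c(-cc / (2 * p1 * sqp), -cc / (2 * p2 * sqp),
      -cc / (2 * p1 * sqp), -cc / (2 * p2 * sqp), 0, 0) +
      d_c / sqp
  }
  g_gen <- part_grad(cg, c(0, 0, 0, 0, 1, 0))
  g_env <- part_grad(ce, c(0, 0, 0, 0, 0, 1))
  g_tot <- g_gen + g_env

  share <- if (abs(r_p) > 1e-6) r_p_gen / r_p else NA_real_
  if (is.na(share)) {
    warning("overall correlation is ~0; genetic share undefined")
  }
  g_share <- if (!is.na(share)) {
    (g_gen * r_p - r_p_gen * g_tot) / r_p^2
  } else rep(NA_real_, 6)

  se_of <- function(grad) delta_se(NULL, th, S, gradient = grad)
  structure(list(
    r_g = r_g, se_r_g = se_of(g_rg),
    r_e = r_e, se_r_e = se_of(g_re),
    h2_1 = h2[1], se_h2_1 = se_of(g_h21),
    h2_2 = h2[2], se_h2_2 = se_of(g_h22),
    e2_1 = e2[1], e2_2 = e2[2],
    r_p_overall = r_p, se_r_p_overall = se_of(g_tot),
    r_p_genetic = r_p_gen, se_r_p_genetic = se_of(g_gen),
    r_p_environmental = r_p_env, se_r_p_environmental = se_of(g_env),
    genetic_share = share,
    se_genetic_share = if (all(is.na(g_share))) NA_real_ else
      se_of(g_share),
    genetic_share_rounded_pct = if (!is.na(share)) {
      10 * round(10 * share)
    } else NA_real_
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("r(G) = %.3f (%.3f)   r(E) = %.3f (%.3f)\n",
              x$r_g, x$se_r_g, x$r_e, x$se_r_e))
  cat(sprintf("r(P) = %.3f (%.3f) = genetic %.3f (%.3f) + residual %.3f (%.3f)\n",
              x$r_p_overall, x$se_r_p_overall, x$r_p_genetic,
              x$se_r_p_genetic, x$r_p_environmental,
              x$se_r_p_environmental))
  if (!is.na(x$genetic_share)) {
    cat(sprintf("genetic share = %.3f (~%d%%)\n", x$genetic_share,
                as.integer(x$genetic_share_rounded_pct)))
  }
  invisible(x)
}

#' Delta-method standard error of a function of variance components
#'
#' \eqn{SE = \sqrt{J' \Sigma J}} with J the gradient of \code{value_fn} at
#' \code{components}, either supplied exactly via \code{gradient} or
#' computed by central finite differences with step
#' \eqn{10^{-5}\max(1, |\theta_i|)}.
#'
#' @param value_fn smooth scalar function of the component vector (ignored
#'   when \code{gradient} is given).
#' @param components numeric component vector.
#' @param sampling_cov symmetric PSD sampling covariance of the components.
#' @param gradient optional exact gradient vector.
#' @return standard error (scalar); negative variances under the root are
#'   clipped to 0 with a warning.
#' @export
delta_se <- function(value_fn, components, sampling_cov, gradient = NULL) {
  if (is.null(gradient)) {
    stopifnot(is.function(value_fn))
    k <- length(components)
    gradient <- numeric(k)
    for (i in seq_len(k)) {
      h <- 1e-5 * max(1, abs(components[i]))
      up <- components; up[i] <- up[i] + h
      dn <- components; dn[i] <- dn[i] - h
      gradient[i] <- (value_fn(up) - value_fn(dn)) / (2 * h)
    }
  }
  if (length(gradient) != nrow(sampling_cov)) {
    stop("gradient and sampling covariance dimensions differ")
  }
  if (anyNA(sampling_cov)) return(NA_real_)
  v <- drop(t(gradient) %*% sampling_cov %*% gradient)
  if (v < 0) {
    warning("negative variance under the root (numerical); clipped to 0")
    v <- 0
  }
  sqrt(v)
}

#' Write a univariate fit in the GCTA .hsq layout
#'
#' Source / Variance / SE rows for V(G), V(e), Vp and V(G)/Vp, followed
#' by the log-likelihood, the one-tailed LRT p-value and n.
#'
#' @param fit a \code{reml_fit}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_hsq <- function(fit, path) {
  se2 <- function(g) {
    if (all(is.finite(fit$sampling_cov))) {
      sqrt(max(0, drop(t(g) %*% fit$sampling_cov %*% g)))
    } else NA_real_
  }
  rows <- c(
    "Source\tVariance\tSE",
    sprintf("V(G)\t%.6f\t%.6f", fit$sigma_g2, se2(c(1, 0))),
    sprintf("V(e)\t%.6f\t%.6f", fit$sigma_e2, se2(c(0, 1))),
    sprintf("Vp\t%.6f\t%.6f", fit$sigma_p2, se2(c(1, 1))),
    sprintf("V(G)/Vp\t%.6f\t%.6f", fit$h2, fit$se_h2),
    sprintf("logL\t%.4f", fit$log_likelihood),
    sprintf("Pval\t%.4g", fit$lrt_p),
    sprintf("n\t%d", fit$n_used)
  )
  writeLines(rows, path)
  invisible(path)
}

#' Render univariate and bivariate results as report tables
#'
#' Emits a per-trait heritability block (h2, SE, LRT p, n) and a bivariate
#' block (h2s, r(G) with SE and LRT p, overall / genetic parts of the
#' phenotypic correlation, genetic share, per-trait n) as data.frames,
#' optionally written to tab-delimited files, with convergence or boundary
#' flags surfaced in a \code{flags} column.
#'
#' @param uni_fits named list of \code{reml_fit} objects (one per trait).
#' @param bivar_fit a \code{bivar_fit}.
#' @param decomposition the matching \code{decomposition}; computed from
#'   \code{bivar_fit} when NULL.
#' @param r_g_p optional likelihood-ratio p-value for r(G) (from a
#'   \code{fix_cov_g = TRUE} refit).
#' @param prefix optional path prefix; writes \code{<prefix>.hsq.txt} and
#'   \code{<prefix>.bivar.txt}.
#' @return list of the two data.frames, invisibly if \code{prefix} given.
#' @export
render_report <- function(uni_fits, bivar_fit, decomposition = NULL,
                          r_g_p = NA_real_, prefix = NULL) {
  if (is.null(decomposition)) {
    decomposition <- decompose_phenotypic_correlation(bivar_fit)
  }
  flag_of <- function(f) {
    paste0(c(if (!f$converged) "not-converged",
             if (isTRUE(f$boundary)) "boundary",
             if (isFALSE(f$identifiable)) "not-identifiable"),
           collapse = ";")
  }
  uni <- do.call(rbind, lapply(names(uni_fits), function(nm) {
    f <- uni_fits[[nm]]
    data.frame(trait = nm, h2 = f$h2, se = f$se_h2, lrt_p = f$lrt_p,
               n = f$n_used, sigma_g2 = f$sigma_g2, sigma_e2 = f$sigma_e2,
               logL = f$log_likelihood, flags = flag_of(f),
               stringsAsFactors = FALSE)
  }))
  d <- decomposition
  bv <- data.frame(
    h2_trait1 = d$h2_1, se_h2_trait1 = d$se_h2_1,
    h2_trait2 = d$h2_2, se_h2_trait2 = d$se_h2_2,
    r_g = d$r_g, se_r_g = d$se_r_g, p_r_g = r_g_p,
    r_p_overall = d$r_p_overall, se_r_p_overall = d$se_r_p_overall,
    r_p_genetic = d$r_p_genetic, se_r_p_genetic = d$se_r_p_genetic,
    genetic_share_pct = d$genetic_share_rounded_pct,
    n1 = bivar_fit$n1, n2 = bivar_fit$n2, n_overlap = bivar_fit$n_overlap,
    flags = paste0(c(if (!bivar_fit$converged) "not-converged",
                     if (isTRUE(bivar_fit$boundary)) "boundary"),
                   collapse = ";"),
    stringsAsFactors = FALSE
  )
  out <- list(heritability = uni, bivariate = bv)
  if (!is.null(prefix)) {
    utils::write.table(uni, paste0(prefix, ".hsq.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(bv, paste0(prefix, ".bivar.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
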