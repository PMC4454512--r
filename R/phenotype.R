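#' Build the analysis-ready phenotype set
#'
#' Applies the study's inclusion rules: NEB is set missing for women
#' younger than 45 at interview (fertility not yet complete); AFB is set
#' missing for childless women (NEB = 0) of any age; IVF users are removed
#' from both analyses entirely. A woman aged under 45 with a child still
#' contributes AFB but not NEB. Rows with a non-missing NEB but no usable
#' age are dropped with a message.
#'
#' @param raw data.frame with columns FID, IID, AFB, NEB, BIRTHYEAR,
#'   COUNTRY, DZ, IVF (the synthetic-data layout).
#' @param interview_year calendar year used to derive age at interview from
#'   BIRTHYEAR (default 2010).
#' @return The table with an added AGE column and availability applied;
#'   attributes \code{n_afb}, \code{n_neb}, \code{n_ivf_excluded},
#'   \code{n_age_rejected} record the bookkeeping. Values that remain are
#'   never altered, only availability changes.
#' @export
build_analysis_set <- function(raw, interview_year = 2010L) {
  need <- c("FID", "IID", "AFB", "NEB", "COUNTRY", "IVF")
  if (!all(need %in% names(raw))) {
    stop("phenotype table must have columns ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  out <- raw
  out$AGE <- interview_year - out$BIRTHYEAR
  n_ivf <- sum(out$IVF == 1, na.rm = TRUE)
  out <- out[is.na(out$IVF) | out$IVF != 1, , drop = FALSE]
  bad_age <- is.na(out$AGE) & !is.na(out$NEB)
  if (any(bad_age)) {
    message("dropping ", sum(bad_age),
            " row(s) with non-missing NEB but missing age")
    out <- out[!bad_age, , drop = FALSE]
  }
  out$NEB[!is.na(out$AGE) & out$AGE < 45] <- NA_integer_
  childless <- !is.na(out$NEB) & out$NEB == 0
  out$AFB[childless] <- NA_real_
  # childless women are childless regardless of the age filter: a raw
  # NEB of 0 also blanks AFB even when NEB itself was masked above
  raw_kept <- raw[match(out$IID, raw$IID), ]
  out$AFB[!is.na(raw_kept$NEB) & raw_kept$NEB == 0] <- NA_real_
  rownames(out) <- NULL
  attr(out, "n_afb") <- sum(!is.na(out$AFB))
  attr(out, "n_neb") <- sum(!is.na(out$NEB))
  attr(out, "n_ivf_excluded") <- n_ivf
  attr(out, "n_age_rejected") <- sum(bad_age)
  out
}

#' Log-transform number of children ever born
#'
#' Returns \code{log(NEB + 1)}: the +1 offset keeps childless women
#' (NEB = 0, mapped to 0) in the analysis while pulling in the right tail
#' of the count distribution. Monotone, so ranks are preserved.
#'
#' @param neb non-negative integer vector (NA allowed).
#' @return real vector.
#' @export
transform_neb <- function(neb) {
  if (any(neb < 0, na.rm = TRUE)) stop("NEB must be non-negative")
  log1p(neb)
}

#' Z-standardize a trait within country
#'
#' Within each country, subtracts the mean and divides by the SD of the
#' non-missing values; missing values stay missing. This removes
#' between-country level differences (e.g. the roughly one-year later mean
#' AFB in the Dutch cohort) before the cohorts are pooled.
#'
#' @param values real vector.
#' @param country label vector of the same length.
#' @return standardized real vector.
#' @export
standardize_by_country <- function(values, country) {
  stopifnot(length(values) == length(country))
  out <- rep(NA_real_, length(values))
  for (cc in unique(country)) {
    idx <- which(country == cc)
    v <- values[idx]
    ok <- !is.na(v)
    if (sum(ok) < 2) {
      stop("country '", cc, "' has fewer than 2 non-missing values")
    }
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0) {
      stop("country '", cc, "' has zero within-country variance")
    }
    out[idx] <- (v - mean(v[ok])) / s
  }
  out
}

#' Build the fixed-effect covariate design
#'
#' Intercept + the first k principal components + country indicators +
#' birth-decade indicators (reference = earliest decade; a linear-year
#' coding is available via \code{birth_cohort = "linear"}) + DZ-twin
#' indicator. Columns that are constant or linearly dependent on earlier
#' columns are dropped with a warning so the design is full column rank.
#'
#' @param table phenotype table (needs IID, COUNTRY, BIRTHYEAR, DZ).
#' @param pcs a \code{pc_set} from \code{\link{compute_pcs}}, or NULL for
#'   no PC columns. Ids must match \code{table$IID} (any order).
#' @param k number of PCs to include (default all available, at most 20).
#' @param birth_cohort \code{"decade"} (default) or \code{"linear"}.
#' @return numeric design matrix with rownames = IID, full column rank.
#' @export
build_covariates <- function(table, pcs = NULL, k = NULL,
                             birth_cohort = c("decade", "linear")) {
  birth_cohort <- match.arg(birth_cohort)
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(table$IID, "intercept"))
  if (!is.null(pcs)) {
    idx <- match(table$IID, pcs$ids$iid)
    if (anyNA(idx)) {
      stop("ids not found in the PC set: ",
           paste(utils::head(table$IID[is.na(idx)], 5), collapse = ", "))
    }
    if (is.null(k)) k <- min(ncol(pcs$vectors), 20L)
    X <- cbind(X, pcs$vectors[idx, seq_len(k), drop = FALSE])
  }
  country <- factor(table$COUNTRY)
  if (nlevels(country) > 1) {
    C <- stats::model.matrix(~country)[, -1, drop = FALSE]
    colnames(C) <- paste0("country_", levels(country)[-1])
    X <- cbind(X, C)
  }
  if (birth_cohort == "decade") {
    decade <- factor(10 * (table$BIRTHYEAR %/% 10))
    if (nlevels(decade) > 1) {
      D <- stats::model.matrix(~decade)[, -1, drop = FALSE]
      colnames(D) <- paste0("decade_", levels(decade)[-1])
      X <- cbind(X, D)
    }
  } else {
    X <- cbind(X, birthyear = as.numeric(table$BIRTHYEAR))
  }
  if (!is.null(table$DZ) && length(unique(table$DZ)) > 1) {
    X <- cbind(X, dz = as.numeric(table$DZ))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    warning("dropping rank-deficient covariate column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  X
}

#' Observed phenotypic correlation over complete pairs
#'
#' Pearson correlation of AFB and NEB over the rows complete for both
#' traits (childless and under-45 rows are excluded upstream by
#' construction), with the complete-pair count.
#'
#' @param table analysis-ready phenotype table (columns AFB and NEB; pass
#'   transformed/standardized columns to mirror the pooled analysis).
#' @param afb,neb optional explicit vectors overriding the columns.
#' @return list with \code{r} and \code{n}.
#' @export
observed_correlation <- function(table = NULL, afb = table$AFB,
                                 neb = table$NEB) {
  ok <- !is.na(afb) & !is.na(neb)
  if (sum(ok) < 3) stop("fewer than 3 complete AFB/NEB pairs")
  list(r = stats::cor(afb[ok], neb[ok]), n = sum(ok))
}

#' Write GCTA-style phenotype and covariate files
#'
#' \code{.phen}: FID IID value; \code{.covar}: FID IID then discrete
#' covariates; \code{.qcovar}: FID IID then quantitative covariates.
#'
#' @param table phenotype table with FID/IID.
#' @param values named list of phenotype vectors (one .phen file each).
#' @param design covariate design matrix from \code{\link{build_covariates}}.
#' @param prefix output prefix.
#' @return invisibly, files written.
#' @export
write_gcta_inputs <- function(table, values, design, prefix) {
  files <- character(0)
  for (nm in names(values)) {
    f <- paste0(prefix, ".", nm, ".phen")
    utils::write.table(data.frame(table$FID, table$IID, values[[nm]]), f,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  qc <- design[, colnames(design) != "intercept", drop = FALSE]
  f <- paste0(prefix, ".qcovar")
  utils::write.table(cbind(table$FID, table$IID, as.data.frame(qc)), f,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(files, f))
}
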