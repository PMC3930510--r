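# Per-feature association scans and multiple-testing machinery.

# OLS of y on cbind(1, X); returns coefficients, SEs, t, two-sided p and
# residuals. Small helper used by stepwise selection and the MR module.
ols_fit <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(X, y)
  k <- fit$rank
  n <- length(y)
  df <- n - k
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  R <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
  se <- rep(NA_real_, ncol(X))
  se[fit$qr$pivot[seq_len(k)]] <- sqrt(diag(R) * sigma2)
  coef <- fit$coefficients
  tval <- coef / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(coef = coef, se = se, t = tval, p = p, df = df, rss = rss,
       residuals = fit$residuals, fitted = y - fit$residuals, rank = k)
}

# signed z equivalent of a two-sided p: z = sign * qnorm(1 - p/2),
# computed on the log scale so genome-wide p-values keep precision
signed_z <- function(log_p_two_sided, sign) {
  z <- stats::qnorm(log_p_two_sided - log(2), lower.tail = FALSE,
                    log.p = TRUE)
  sign * pmax(z, 0)
}

#' Forward stepwise covariate selection for one metabolome feature
#'
#' Repeatedly adds the candidate factor with the smallest marginal
#' P-value (conditional on factors already included) while that P-value
#' is below `alpha`. Categorical factors are expanded to indicator
#' columns before selection; ties are broken by factor name, so the
#' procedure is deterministic regardless of input order.
#'
#' @param y Numeric feature values (one feature).
#' @param factors Data frame of candidate factors (columns: numeric,
#'   logical or factor/character; the latter are expanded to indicators).
#' @param alpha Inclusion threshold; default is Bonferroni over the
#'   number of candidate columns, `0.05 / n_factors`.
#' @return Character vector of selected (expanded) factor names, with the
#'   design matrix of the selected factors as attribute `"design"`.
#' @export
select_covariates <- function(y, factors, alpha = NULL) {
  stopifnot(is.numeric(y), nrow(factors) == length(y))
  X <- expand_factors(factors)
  if (ncol(X) < 1L) stop("no candidate factors", call. = FALSE)
  if (is.null(alpha)) alpha <- 0.05 / ncol(X)
  # drop exact duplicates/collinear columns up front (keep earlier)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1L) {
    keep <- sort(qx$pivot[seq_len(qx$rank)]) - 1L
    keep <- keep[keep >= 1L]
    warning(sprintf("dropping %d collinear candidate factor column(s)",
                    ncol(X) - length(keep)), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  selected <- character(0)
  remaining <- colnames(X)[order(colnames(X))]
  tss <- sum((y - mean(y))^2)
  repeat {
    if (length(remaining) == 0L) break
    if (length(selected) > 0L) {
      # a numerically perfect fit leaves nothing to select on
      cur <- ols_fit(y, X[, selected, drop = FALSE])
      if (cur$rss <= 1e-12 * tss) break
    }
    pvals <- vapply(remaining, function(nm) {
      f <- ols_fit(y, X[, c(selected, nm), drop = FALSE])
      f$p[length(f$p)]
    }, numeric(1))
    pvals[is.na(pvals)] <- 1
    best <- remaining[which.min(pvals)] # ties: first in name order
    if (min(pvals) < alpha) {
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
    } else break
  }
  structure(selected, design = X[, selected, drop = FALSE])
}

# expand a data.frame of mixed-type factors into a numeric design matrix
expand_factors <- function(factors) {
  factors <- as.data.frame(factors)
  cols <- lapply(names(factors), function(nm) {
    v <- factors[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      m <- matrix(as.numeric(v), ncol = 1L,
                  dimnames = list(NULL, nm))
    } else {
      v <- factor(v)
      m <- stats::model.matrix(~ v)[, -1L, drop = FALSE]
      colnames(m) <- paste0(nm, ".", levels(v)[-1L])
    }
    m
  })
  do.call(cbind, cols)
}

#' Association scan of metabolome features against SNP dosages
#'
#' Per SNP and feature, ordinary least squares of the feature on dosage
#' plus covariates plus an intercept; two-sided P from the t distribution
#' with n - k degrees of freedom. The scan is vectorized across SNPs for
#' each feature, using complete cases of that feature. Monomorphic SNPs
#' yield `beta = 0, p = 1` and are flagged.
#'
#' The signed test statistic `z = sign(beta) * qnorm(1 - p/2)` is stored
#' alongside, making statistics comparable across cohorts of different
#' size (as needed by metabomatching).
#'
#' @param features A [feature_matrix()], a numeric matrix (samples x
#'   features) or a single numeric vector.
#' @param dosage Numeric matrix of allelic dosages in `[0, 2]`,
#'   individuals x SNPs, or a [simulate_genotypes()] result.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param map Optional data frame `snp_id, chr, pos` (taken from the
#'   genotype object when available).
#' @param scale_features If `TRUE` (default), each feature is scaled to
#'   unit variance on its complete cases before regression, so effect
#'   sizes are in feature-SD units per dosage.
#' @return Data frame of association records with columns
#'   `snp_id, chr, pos, feature, beta, se, z, p, n, note`.
#' @export
associate <- function(features, dosage, covariates = NULL, map = NULL,
                      scale_features = TRUE) {
  if (inherits(dosage, "sim_genotypes")) {
    if (is.null(map)) map <- dosage$map
    dosage <- dosage$dosage
  }
  dosage <- as.matrix(dosage)
  if (inherits(features, "feature_matrix")) {
    Y <- features$values
    feature_labels <- features$feature_ppm
  } else if (is.matrix(features)) {
    Y <- features
    feature_labels <- colnames(features)
    if (is.null(feature_labels)) feature_labels <- seq_len(ncol(Y))
  } else {
    Y <- matrix(features, ncol = 1L)
    feature_labels <- "feature"
  }
  if (nrow(Y) != nrow(dosage))
    stop("features and dosage must cover the same individuals",
         call. = FALSE)
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9, na.rm = TRUE))
    stop("dosage values must lie in [0, 2]", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(expand_factors(as.data.frame(covariates)))
    if (nrow(covariates) != nrow(Y))
      stop("covariates must cover the same individuals", call. = FALSE)
  }
  if (is.null(map)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(ncol(dosage)))
    map <- data.frame(snp_id = ids, chr = NA_integer_, pos = NA_integer_)
  }
  S <- ncol(dosage); Fq <- ncol(Y)
  out_beta <- out_se <- out_z <- out_p <- matrix(NA_real_, S, Fq)
  out_n <- matrix(NA_integer_, S, Fq)
  out_note <- matrix("", S, Fq)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  for (f in seq_len(Fq)) {
    y <- Y[, f]
    ok <- !is.na(y)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    n <- sum(ok)
    k <- n_cov + 2L # intercept + dosage + covariates
    if (n <= k)
      stop("fewer observations than model parameters", call. = FALSE)
    yf <- y[ok]
    G <- dosage[ok, , drop = FALSE]
    # Frisch-Waugh: residualize feature and dosages on [1, covariates]
    C <- if (is.null(covariates)) matrix(1, n, 1L) else
      cbind(1, covariates[ok, , drop = FALSE])
    qc <- qr(C)
    yr <- qr.resid(qc, yf)
    if (scale_features) {
      s <- sqrt(sum(yr^2) / n)
      if (s > 0) yr <- yr / s
    }
    Gr <- qr.resid(qc, G)
    gg <- colSums(Gr^2)
    gy <- as.vector(crossprod(Gr, yr))
    yy <- sum(yr^2)
    mono <- gg < 1e-12
    beta <- ifelse(mono, 0, gy / ifelse(mono, 1, gg))
    rss <- pmax(yy - beta * gy, 0)
    df <- n - k
    sigma2 <- rss / df
    se <- sqrt(sigma2 / ifelse(mono, NA, gg))
    tval <- beta / se
    logp <- log(2) + stats::pt(abs(tval), df, lower.tail = FALSE,
                               log.p = TRUE)
    p <- pmin(exp(logp), 1)
    z <- signed_z(pmin(logp, 0), sign(beta))
    degen <- !mono & rss <= 1e-12 * yy
    p[mono] <- 1; beta[mono] <- 0; z[mono] <- 0
    out_beta[, f] <- beta; out_se[, f] <- se
    out_z[, f] <- z; out_p[, f] <- pmax(p, .Machine$double.xmin)
    out_n[, f] <- n
    out_note[mono, f] <- "monomorphic"
    out_note[degen, f] <- "degenerate_fit"
  }
  data.frame(
    snp_id = rep(map$snp_id, times = Fq),
    chr = rep(map$chr, times = Fq),
    pos = rep(map$pos, times = Fq),
    feature = rep(feature_labels, each = S),
    beta = as.vector(out_beta),
    se = as.vector(out_se),
    z = as.vector(out_z),
    p = as.vector(out_p),
    n = as.vector(out_n),
    note = as.vector(out_note),
    stringsAsFactors = FALSE)
}

#' Pairwise feature correlation matrix
#'
#' Pearson correlation between features, using pairwise-complete
#' observations. Input to clumping, metabomatching pruning and
#' [effective_tests()].
#'
#' @param m A [feature_matrix()] or numeric matrix (samples x features).
#' @return Correlation matrix (features x features).
#' @export
feature_correlation <- function(m) {
  v <- if (inherits(m, "feature_matrix")) m$values else as.matrix(m)
  if (!anyNA(v)) return(stats::cor(v))
  # pairwise-complete Pearson via crossproducts (much faster than
  # cor(use = "pairwise") for wide matrices)
  M <- !is.na(v)
  X <- v; X[!M] <- 0
  Mn <- M + 0
  n <- crossprod(Mn)
  S <- crossprod(X)
  SX <- crossprod(X, Mn)     # sum of x_j over pairwise-complete rows
  SXX <- crossprod(X^2, Mn)
  num <- S - SX * t(SX) / n
  den <- sqrt(pmax(SXX - SX^2 / n, 0) * t(pmax(SXX - SX^2 / n, 0)))
  r <- num / den
  r[!is.finite(r)] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(colnames(v), colnames(v))
  r
}

#' Effective number of independent tests among correlated features
#'
#' simpleM-style estimate: eigendecompose the feature correlation matrix
#' and report the smallest number of leading eigenvalues whose sum
#' reaches `var_fraction` of the total.
#'
#' @param m A [feature_matrix()], numeric matrix, or a precomputed
#'   feature correlation matrix (square, unit diagonal).
#' @param var_fraction Fraction of total variance to capture (default
#'   0.995, the method's published default).
#' @return Integer `M_eff`.
#' @export
effective_tests <- function(m, var_fraction = 0.995) {
  C <- if (is.matrix(m) && nrow(m) == ncol(m) &&
           isTRUE(all(abs(diag(m) - 1) < 1e-8))) m
       else feature_correlation(m)
  if (ncol(C) < 2L) stop("need at least two features", call. = FALSE)
  if (any(!is.finite(C)))
    stop("non-finite feature correlations (constant feature?)",
         call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(which(cumsum(ev) / sum(ev) >= var_fraction - 1e-12)[1L])
}

#' Decision thresholds of the two-stage GWAS design
#'
#' Returns the suggestive-significance threshold (the genome-wide
#' constant 5e-8 applied in the discovery cohort), the combined
#' Bonferroni threshold `0.05 / (M_eff_features * n_effective_snps)`
#' correcting for both features and SNPs, and the replication threshold
#' `0.05 / n_hits`.
#'
#' @param m_eff_features Effective number of feature tests
#'   ([effective_tests()]).
#' @param n_effective_snps Effective number of SNP tests.
#' @param n_hits Number of discovered independent associations (for the
#'   replication threshold); optional.
#' @return List with elements `suggestive`, `combined`, `replication`.
#' @export
gwas_thresholds <- function(m_eff_features, n_effective_snps,
                            n_hits = NULL) {
  stopifnot(m_eff_features >= 1, n_effective_snps >= 1)
  list(suggestive = 5e-8,
       combined = 0.05 / (m_eff_features * n_effective_snps),
       replication = if (is.null(n_hits)) NA_real_ else 0.05 / n_hits)
}
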