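# Allelic heterogeneity: stepwise multivariate region models with a
# permutation-based model P-value.

# Fast forward-AIC selection core. X: centered dosage matrix (columns =
# region SNPs), y: centered (residualized) feature. Gaussian AIC up to
# constants: n log(RSS/n) + 2 * n_terms; a term is added when it lowers
# AIC, i.e. RSS_new < RSS_old * exp(-2/n). The first term (the SNP with
# the largest marginal R2 = smallest marginal P) is always included so a
# region model has at least one SNP. Candidates whose residual variance
# after projection on the selected span falls below 1% of their original
# variance (r2 > 0.99) are skipped as collinear.
stepwise_core <- function(X, y, max_terms = 10L, force_first = TRUE) {
  n <- length(y)
  S <- ncol(X)
  tss <- sum(y^2)
  if (tss <= 0) return(list(selected = integer(0), rss = tss,
                            rss_path = numeric(0), tss = tss))
  W <- X                      # residualized candidates
  norms0 <- colSums(X^2)
  r <- y
  rss <- tss
  selected <- integer(0)
  rss_path <- numeric(0)
  alive <- norms0 > 1e-12
  aic_gate <- exp(-2 / n)
  while (length(selected) < max_terms && any(alive)) {
    wn <- colSums(W^2)
    collinear <- alive & (wn < 0.01 * norms0)
    alive[collinear] <- FALSE
    if (!any(alive)) break
    wy <- as.vector(crossprod(W[, alive, drop = FALSE], r))
    red <- wy^2 / wn[alive]
    j_rel <- which.max(red)
    rss_new <- rss - red[j_rel]
    take <- if (length(selected) == 0L && force_first) TRUE
            else rss_new < rss * aic_gate
    if (!take) break
    j <- which(alive)[j_rel]
    g <- W[, j]
    gg <- wn[j]
    coef_r <- sum(g * r) / gg
    r <- r - g * coef_r
    rss <- max(rss - red[j_rel], 0)
    selected <- c(selected, j)
    rss_path <- c(rss_path, rss)
    alive[j] <- FALSE
    if (any(alive)) {
      proj <- as.vector(crossprod(W[, alive, drop = FALSE], g)) / gg
      W[, alive] <- W[, alive, drop = FALSE] -
        outer(g, proj)
    }
  }
  list(selected = selected, rss = rss, rss_path = rss_path, tss = tss)
}

# residualize y (and drop incomplete cases) on covariates
residualize_on <- function(y, covariates) {
  if (is.null(covariates)) return(y - mean(y))
  C <- cbind(1, as.matrix(covariates))
  qr.resid(qr(C), y)
}

#' Stepwise multivariate region model for one locus-feature pair
#'
#' Searches the SNPs of a region (typically the lead SNP's 1 Mb
#' neighbourhood) for the best multivariate model of the feature, by
#' forward selection minimizing AIC. The feature is residualized on the
#' covariates first. `R2_diff` is the additional variance the full model
#' explains relative to the best single-SNP association of the window —
#' the quantity the permutation test calibrates. A clearly positive
#' `R2_diff` indicates allelic heterogeneity (or imperfect tagging by the
#' lead SNP).
#'
#' @param y Numeric feature values.
#' @param dosage Region dosage matrix (individuals x SNPs, named
#'   columns).
#' @param covariates Optional covariate matrix.
#' @param max_terms Maximum number of SNPs in the model (default 10).
#' @return Object of class `region_model`: `snps` (selected ids in
#'   selection order), `betas`, `cond_p` (per-SNP conditional P in the
#'   joint model), `r2`, `r2_single` (best single-SNP R2), `r2_diff`,
#'   `aic`, `lead_snp`, `n`, `model_p` (`NA` until
#'   [permutation_model_p()] fills it).
#' @export
stepwise_select <- function(y, dosage, covariates = NULL,
                            max_terms = 10L) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) < 1L) stop("region contains no SNP", call. = FALSE)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp%04d", seq_len(ncol(dosage)))
  ok <- !is.na(y)
  yr <- residualize_on(y[ok], if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])
  X <- scale(dosage[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  fit <- stepwise_core(X, yr, max_terms = max_terms)
  if (length(fit$selected) == 0L)
    stop("no usable SNP in region (all monomorphic?)", call. = FALSE)
  r2_path <- 1 - fit$rss_path / fit$tss
  r2 <- 1 - fit$rss / fit$tss
  r2_single <- r2_path[1L] # first forward pick = best marginal SNP
  refit <- ols_fit(yr, X[, fit$selected, drop = FALSE])
  n_sel <- length(fit$selected)
  aic <- length(yr) * log(fit$rss / length(yr)) + 2 * (n_sel + 1)
  structure(
    list(snps = colnames(dosage)[fit$selected],
         betas = unname(refit$coef[-1L]),
         cond_p = unname(refit$p[-1L]),
         r2 = r2, r2_single = r2_single,
         r2_diff = max(r2 - r2_single, 0),
         aic = aic,
         lead_snp = colnames(dosage)[fit$selected[1L]],
         n = length(yr), model_p = NA_real_),
    class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model> %d SNP(s): %s\n  R2 = %.4f, R2_diff = %.4f vs lead %s, model P = %s\n",
              length(x$snps), paste(x$snps, collapse = " + "),
              x$r2, x$r2_diff, x$lead_snp,
              ifelse(is.na(x$model_p), "<not computed>",
                     format(x$model_p, digits = 3))))
  invisible(x)
}

#' Permutation model P-value for a region model
#'
#' For each of `n_perm` permutations of the residualized feature values,
#' the full stepwise selection is rerun and its `R2_diff` recorded; the
#' model P is the add-one estimate
#' `(#\{perm R2_diff >= observed\} + 1) / (n_perm + 1)`, which can never
#' be zero (the observed configuration counts as one permutation). It
#' answers: how often does pure noise, run through the same greedy
#' selection, produce as large an apparent secondary signal?
#'
#' @inheritParams stepwise_select
#' @param model The observed [stepwise_select()] model (recomputed when
#'   omitted).
#' @param n_perm Number of permutations (default 2500).
#' @param seed Integer seed for the permutation stream.
#' @return The `region_model` with `model_p` (and `perm_r2_diff`
#'   attribute) filled in.
#' @export
permutation_model_p <- function(y, dosage, covariates = NULL,
                                model = NULL, n_perm = 2500L,
                                seed = 1L, max_terms = 10L) {
  if (n_perm < 100L)
    warning("fewer than 100 permutations gives a coarse model P",
            call. = FALSE)
  dosage <- as.matrix(dosage)
  if (is.null(model))
    model <- stepwise_select(y, dosage, covariates, max_terms)
  ok <- !is.na(y)
  yr <- residualize_on(y[ok], if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])
  X <- scale(dosage[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  set_seed_if(seed)
  perm_diff <- vapply(seq_len(n_perm), function(b) {
    fit <- stepwise_core(X, sample(yr), max_terms = max_terms)
    if (length(fit$selected) == 0L) return(0)
    r2_full <- 1 - fit$rss / fit$tss
    r2_one <- 1 - fit$rss_path[1L] / fit$tss
    max(r2_full - r2_one, 0)
  }, numeric(1))
  model$model_p <- (sum(perm_diff >= model$r2_diff - 1e-12) + 1) /
    (n_perm + 1)
  attr(model, "perm_r2_diff") <- perm_diff
  model
}

#' Attempt locus-level replication of allelic heterogeneity
#'
#' Because LD structure differs between cohorts, replication is attempted
#' for the locus, not the exact SNPs: the stepwise selection and
#' permutation test are rerun in the replication cohort over the same
#' window. The locus replicates when the replication model retains at
#' least two SNPs and its permutation model P is below 0.05.
#'
#' @param discovery_model The discovery-cohort [stepwise_select()] model
#'   (carried along in the result for reporting).
#' @param y Replication-cohort feature values (aligned feature).
#' @param dosage Replication-cohort dosages for the same window.
#' @param covariates Optional replication-cohort covariates.
#' @param n_perm,seed,max_terms Passed to [permutation_model_p()].
#' @return List `replicated` (logical), `replication_model`
#'   (`region_model`), `discovery_model`.
#' @export
replicate_locus <- function(discovery_model, y, dosage,
                            covariates = NULL, n_perm = 2500L,
                            seed = 1L, max_terms = 10L) {
  stopifnot(inherits(discovery_model, "region_model"))
  if (NCOL(dosage) == 0L)
    return(list(replicated = NA, replication_model = NULL,
                discovery_model = discovery_model,
                note = "window empty in replication panel"))
  rm <- permutation_model_p(y, dosage, covariates, n_perm = n_perm,
                            seed = seed, max_terms = max_terms)
  list(replicated = length(rm$snps) >= 2L && rm$model_p < 0.05,
       replication_model = rm,
       discovery_model = discovery_model)
}
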