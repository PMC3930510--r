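# Single-instrument Mendelian randomization: first-stage strength, 2SLS
# and Wald-ratio estimates, Durbin-Hausman endogeneity test, analytic
# power.

#' First-stage regression of the exposure on the instrument
#'
#' OLS of the exposure on the genetic instrument (plus covariates); the
#' instrument's F statistic is the standard weak-instrument diagnostic
#' (F > 10 rule of thumb).
#'
#' @param g Instrument dosage vector.
#' @param x Exposure vector.
#' @param covariates Optional covariate matrix.
#' @return List `f_stat`, `beta_gx`, `se_gx`, `p_gx`, `r2_gx` (partial
#'   R2 of the instrument), `fitted`, `residuals`, `degenerate` (TRUE
#'   when the exposure is an exact function of the instrument).
#' @export
first_stage <- function(g, x, covariates = NULL) {
  stopifnot(length(g) == length(x))
  if (stats::var(g) < 1e-12)
    stop("monomorphic instrument", call. = FALSE)
  X <- if (is.null(covariates)) matrix(g, ncol = 1L) else
    cbind(g = g, as.matrix(covariates))
  fit <- ols_fit(x, X)
  tval <- fit$t[2L]
  degenerate <- fit$rss <= 1e-12 * sum((x - mean(x))^2)
  f_stat <- if (degenerate) Inf else unname(tval^2)
  r2_gx <- unname(f_stat / (f_stat + fit$df))
  list(f_stat = f_stat, beta_gx = unname(fit$coef[2L]),
       se_gx = unname(fit$se[2L]), p_gx = unname(fit$p[2L]),
       r2_gx = r2_gx, fitted = fit$fitted, residuals = fit$residuals,
       degenerate = degenerate)
}

#' Two-stage least-squares causal estimate (one-sample MR)
#'
#' Stage 1 regresses the exposure on the instrument (plus covariates);
#' stage 2 regresses the outcome on the fitted exposure (plus
#' covariates). The second-stage standard error uses the standard 2SLS
#' correction: residuals are recomputed with the observed (not fitted)
#' exposure. The OLS estimate of the same model is reported alongside
#' for comparison.
#'
#' @param g Instrument dosage vector.
#' @param x Exposure vector.
#' @param y Outcome vector.
#' @param covariates Optional covariate matrix.
#' @param weak_tol Minimum tolerated first-stage coefficient magnitude.
#' @return Object of class `mr_result` with `beta_ols, se_ols, beta_iv,
#'   se_iv, p_iv, f_stat, mode = "one_sample"`.
#' @export
tsls <- function(g, x, y, covariates = NULL, weak_tol = 1e-8) {
  stopifnot(length(g) == length(x), length(x) == length(y))
  fs <- first_stage(g, x, covariates)
  if (abs(fs$beta_gx) < weak_tol)
    stop("weak instrument: first-stage coefficient below tolerance",
         call. = FALSE)
  Xo <- if (is.null(covariates)) matrix(x, ncol = 1L) else
    cbind(x = x, as.matrix(covariates))
  ols <- ols_fit(y, Xo)
  X2 <- if (is.null(covariates)) matrix(fs$fitted, ncol = 1L) else
    cbind(x = fs$fitted, as.matrix(covariates))
  s2 <- ols_fit(y, X2)
  beta_iv <- unname(s2$coef[2L])
  # 2SLS sigma^2 from residuals using the observed exposure
  coefs <- s2$coef
  resid_iv <- y - cbind(1, Xo) %*% coefs
  df <- length(y) - length(coefs)
  sigma2 <- sum(resid_iv^2) / df
  se_iv <- unname(s2$se[2L]) * sqrt(sigma2 / (s2$rss / s2$df))
  tval <- beta_iv / se_iv
  p_iv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(beta_ols = unname(ols$coef[2L]),
                 se_ols = unname(ols$se[2L]),
                 beta_iv = beta_iv, se_iv = se_iv, p_iv = p_iv,
                 f_stat = fs$f_stat, dh_stat = NA_real_,
                 dh_p = NA_real_, mode = "one_sample", n = length(y)),
            class = "mr_result")
}

#' Wald-ratio causal estimate (two-sample MR)
#'
#' Combines harmonized summary effects from two samples: the instrument's
#' effect on the exposure `(bGX, seGX)` and on the outcome `(bGY, seGY)`.
#' `beta_iv = bGY / bGX`; the standard error is first-order delta method,
#' `sqrt(seGY^2 / bGX^2 + bGY^2 seGX^2 / bGX^4)`.
#'
#' @param b_gx,se_gx Instrument-exposure effect and SE.
#' @param b_gy,se_gy Instrument-outcome effect and SE.
#' @param weak_tol Minimum tolerated `|b_gx|`.
#' @return Object of class `mr_result` with `mode = "two_sample"`.
#' @export
wald_ratio <- function(b_gx, se_gx, b_gy, se_gy, weak_tol = 1e-8) {
  if (abs(b_gx) < weak_tol)
    stop("weak instrument: |b_gx| below tolerance", call. = FALSE)
  beta_iv <- b_gy / b_gx
  se_iv <- sqrt(se_gy^2 / b_gx^2 + b_gy^2 * se_gx^2 / b_gx^4)
  z <- if (se_iv > 0) beta_iv / se_iv else Inf
  p_iv <- if (is.finite(z)) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
          else 0
  structure(list(beta_ols = NA_real_, se_ols = NA_real_,
                 beta_iv = beta_iv, se_iv = se_iv,
                 p_iv = max(p_iv, .Machine$double.xmin),
                 f_stat = NA_real_, dh_stat = NA_real_, dh_p = NA_real_,
                 mode = "two_sample", n = NA_integer_),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> [%s] beta_iv = %.4f (se %.4f, p = %.3g)",
              x$mode, x$beta_iv, x$se_iv, x$p_iv))
  if (x$mode == "one_sample")
    cat(sprintf("; beta_ols = %.4f; first-stage F = %.2f", x$beta_ols,
                x$f_stat))
  if (!is.na(x$dh_p))
    cat(sprintf("; Durbin-Hausman p = %.3g", x$dh_p))
  cat("\n")
  invisible(x)
}

#' Durbin-Hausman test comparing OLS and 2SLS estimates
#'
#' Regression-based (control-function) form: the first-stage residual is
#' added as a regressor to the outcome-on-exposure model and its
#' coefficient t-tested (two-sided). A significant coefficient indicates
#' the exposure is endogenous, i.e. OLS and 2SLS estimate different
#' quantities.
#'
#' @inheritParams tsls
#' @return List `dh_stat` (t statistic), `dh_p`.
#' @export
durbin_hausman <- function(g, x, y, covariates = NULL) {
  fs <- first_stage(g, x, covariates)
  X <- if (is.null(covariates))
    cbind(x = x, v = fs$residuals) else
    cbind(x = x, v = fs$residuals, as.matrix(covariates))
  fit <- ols_fit(y, X)
  list(dh_stat = unname(fit$t[3L]), dh_p = unname(fit$p[3L]))
}

#' Run the full one-sample MR analysis
#'
#' Convenience wrapper: [tsls()] plus [durbin_hausman()], and optional
#' reporting (non-gating) of instrument-confounder associations as an
#' implementable instrumental-validity check.
#'
#' @inheritParams tsls
#' @param confounders Optional matrix of measured potential confounders;
#'   each is regressed on the instrument and the P-values reported.
#' @return An `mr_result` with `dh_stat`, `dh_p` (and
#'   `confounder_assoc` attribute) filled in.
#' @export
mr_analysis <- function(g, x, y, covariates = NULL, confounders = NULL) {
  res <- tsls(g, x, y, covariates)
  dh <- durbin_hausman(g, x, y, covariates)
  res$dh_stat <- dh$dh_stat
  res$dh_p <- dh$dh_p
  if (!is.null(confounders)) {
    confounders <- as.matrix(confounders)
    pv <- apply(confounders, 2L, function(u)
      ols_fit(u, matrix(g, ncol = 1L))$p[2L])
    attr(res, "confounder_assoc") <- data.frame(
      confounder = colnames(confounders) %||% seq_len(ncol(confounders)),
      p = as.numeric(pv))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic power of a single-instrument MR test
#'
#' Asymptotic power of the 2SLS Wald test at level `alpha`: the
#' non-centrality of the chi-squared(1) test statistic is
#' `lambda = n r2_gx beta_causal^2 var_x / var_y`, so
#' `power = P(chisq_1(lambda) > q_{1-alpha})`.
#'
#' @param n Sample size.
#' @param r2_gx Variance fraction of the exposure explained by the
#'   instrument, in (0, 1).
#' @param beta_causal Causal effect of the exposure on the outcome (on
#'   the declared exposure/outcome scales).
#' @param var_x,var_y Variances of exposure and outcome (default 1:
#'   standardized scales).
#' @param alpha Test level (default 0.05).
#' @return Power in `[alpha, 1)`.
#' @export
mr_power <- function(n, r2_gx, beta_causal, var_x = 1, var_y = 1,
                     alpha = 0.05) {
  stopifnot(n > 0, r2_gx > 0, r2_gx < 1, var_x > 0, var_y > 0,
            alpha > 0, alpha < 1)
  lambda <- n * r2_gx * beta_causal^2 * var_x / var_y
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}

#' Sample size required for a target MR power
#'
#' Inverts [mr_power()] in `n` by monotone bisection.
#'
#' @inheritParams mr_power
#' @param target_power Desired power in (alpha, 1).
#' @return The smallest (fractional) sample size reaching the target
#'   power; round up for planning.
#' @export
mr_required_n <- function(target_power = 0.8, r2_gx, beta_causal,
                          var_x = 1, var_y = 1, alpha = 0.05) {
  stopifnot(target_power > alpha, target_power < 1)
  if (beta_causal == 0)
    stop("infeasible target: zero causal effect never exceeds alpha power",
         call. = FALSE)
  f <- function(n) mr_power(n, r2_gx, beta_causal, var_x, var_y, alpha) -
    target_power
  lo <- 1; hi <- 10
  while (f(hi) < 0) {
    hi <- hi * 10
    if (hi > 1e12) stop("infeasible target power", call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
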