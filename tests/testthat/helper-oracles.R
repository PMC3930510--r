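# Independent oracle implementations used to cross-check the package.
# Deliberately written in the most naive style possible (loops, lm(),
# exhaustive scans) and sharing no code with the implementation.

# closed-form / lm() association oracle: feature ~ dosage + covariates
oracle_ols <- function(y, g, covariates = NULL) {
  df <- if (is.null(covariates)) data.frame(y = y, g = g)
        else data.frame(y = y, g = g, covariates)
  fit <- summary(stats::lm(y ~ ., data = df))
  co <- fit$coefficients["g", ]
  list(beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]))
}

# naive greedy pair-clumping: scan-based absorption, best P first
oracle_clump <- function(hits, ld, fc, r2_snp = 0.3, r2_feat = 0.4) {
  hits <- hits[order(hits$p, hits$snp_id, sprintf("%.4f", hits$feature)), ]
  reps <- hits[0, ]
  while (nrow(hits) > 0) {
    top <- hits[1, ]
    reps <- rbind(reps, top)
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      equiv <- ld[top$snp_id, hits$snp_id[i]] > r2_snp &&
        fc[sprintf("%.4f", top$feature),
           sprintf("%.4f", hits$feature[i])]^2 > r2_feat
      keep[i] <- !equiv
    }
    keep[1] <- FALSE
    hits <- hits[keep, , drop = FALSE]
  }
  reps
}

# naive greedy correlated-feature pruning: keep largest |z| first
oracle_prune <- function(matched, z, fc, r2 = 0.4) {
  left <- matched[order(-abs(z[matched]))]
  kept <- integer(0)
  while (length(left) > 0) {
    kept <- c(kept, left[1])
    survivors <- integer(0)
    for (j in left[-1])
      if (fc[left[1], j]^2 <= r2) survivors <- c(survivors, j)
    left <- survivors
  }
  sort(kept)
}

# inverse-variance meta oracle, straight from the formula
oracle_ivw <- function(x, se) {
  w <- 1 / se^2
  xm <- sum(w * x) / sum(w)
  sem <- sqrt(1 / sum(w))
  list(x_m = xm, se_m = sem,
       p_m = 2 * stats::pnorm(abs(xm / sem), lower.tail = FALSE))
}

# small fully-specified cohort for pipeline tests: raw dosages and
# phenotypes without any spectral rendering
toy_genotypes <- function(n, s, maf = 0.3, seed = 1) {
  set.seed(seed)
  matrix(stats::rbinom(n * s, 2, maf), n, s,
         dimnames = list(NULL, sprintf("snp%04d", seq_len(s))))
}
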