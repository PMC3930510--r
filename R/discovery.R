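# Pruning suggestive SNP-feature pairs to independent associations,
# replication rules, inverse-variance meta-analysis, locus grouping.

# canonical character key for a ppm feature label
ppm_key <- function(x) {
  if (is.numeric(x)) sprintf("%.4f", round(x, 4L)) else as.character(x)
}

#' Pairwise LD (r-squared) lookup from genotype dosages
#'
#' Squared Pearson correlation between SNP dosage vectors, the LD measure
#' used by the clumping rule.
#'
#' @param dosage Individuals x SNPs dosage matrix (or a
#'   [simulate_genotypes()] result).
#' @return Symmetric matrix of r-squared values with unit diagonal.
#' @export
ld_matrix <- function(dosage) {
  if (inherits(dosage, "sim_genotypes")) dosage <- dosage$dosage
  r <- suppressWarnings(stats::cor(dosage))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Clump suggestive SNP-feature pairs into independent associations
#'
#' Extension of PLINK-style clumping to pairs: two hits are equivalent if
#' BOTH their SNPs are in LD (`r^2 > r2_snp`) and their features are
#' correlated (`r^2 > r2_feat`). Hits are sorted by ascending P (ties by
#' SNP id then feature label); the best remaining hit is taken as a
#' representative and every remaining hit equivalent to it is absorbed.
#' Equivalence is applied greedily to the representative, not closed
#' transitively.
#'
#' @param hits Data frame of association records (from [associate()])
#'   already restricted to suggestive significance; needs columns
#'   `snp_id, feature, p`.
#' @param ld SNP r-squared matrix with SNP ids as dimnames
#'   ([ld_matrix()]).
#' @param feature_corr Feature correlation matrix (Pearson r) with
#'   feature labels as dimnames; squared internally.
#' @param r2_snp LD equivalence threshold (default 0.3).
#' @param r2_feat Feature-correlation (r-squared) equivalence threshold
#'   (default 0.4).
#' @return The hits data frame restricted to representatives, in P order,
#'   with a column `n_absorbed` counting the hits each one absorbed.
#' @export
clump_pairs <- function(hits, ld, feature_corr, r2_snp = 0.3,
                        r2_feat = 0.4) {
  if (nrow(hits) == 0L) stop("no hits to clump", call. = FALSE)
  snp <- as.character(hits$snp_id)
  feat <- ppm_key(hits$feature)
  miss_snp <- setdiff(unique(snp), rownames(ld))
  if (length(miss_snp))
    stop("missing LD entry for SNP ", miss_snp[1L], call. = FALSE)
  fkeys <- rownames(feature_corr)
  if (is.null(fkeys)) fkeys <- ppm_key(as.numeric(colnames(feature_corr)))
  miss_feat <- setdiff(unique(feat), fkeys)
  if (length(miss_feat))
    stop("missing feature correlation entry for feature ", miss_feat[1L],
         call. = FALSE)
  fc2 <- feature_corr^2
  dimnames(fc2) <- list(fkeys, fkeys)
  ord <- order(hits$p, snp, feat)
  remaining <- ord
  reps <- integer(0)
  absorbed_count <- integer(0)
  while (length(remaining) > 0L) {
    top <- remaining[1L]
    rest <- remaining[-1L]
    eq <- ld[snp[top], snp[rest]] > r2_snp &
      fc2[feat[top], feat[rest]] > r2_feat
    reps <- c(reps, top)
    absorbed_count <- c(absorbed_count, sum(eq))
    remaining <- rest[!eq]
  }
  out <- hits[reps, , drop = FALSE]
  out$n_absorbed <- absorbed_count
  rownames(out) <- NULL
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort association records for aligned SNP-feature pairs:
#' weights `w_i = 1/se_i^2`, combined effect `x_m = sum(w x)/sum(w)`,
#' `se_m = sqrt(1/sum(w))`, two-sided P from `z = x_m/se_m`. Assumes a
#' common effect size across cohorts. If both records carry
#' `effect_allele`/`other_allele` columns, effects are harmonized by
#' label matching (the second cohort's sign is flipped when its alleles
#' are swapped); strand-ambiguous A/T and C/G SNPs are flagged.
#'
#' @param a,b Data frames of association records matched row-wise
#'   (columns `beta`, `se`; optionally `snp_id`, `feature`, `p`, allele
#'   columns).
#' @return Data frame with `snp_id, feature, x_m, se_m, z_m, p_m` plus
#'   per-cohort effects `x_a, p_a, x_b, p_b` and a `note` column.
#' @export
ivw_meta <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (nrow(a) != nrow(b))
    stop("cohort record sets must be matched row-wise", call. = FALSE)
  if (any(a$se <= 0, na.rm = TRUE) || any(b$se <= 0, na.rm = TRUE) ||
      anyNA(a$se) || anyNA(b$se))
    stop("zero or missing standard error", call. = FALSE)
  beta_b <- b$beta
  note <- rep("", nrow(a))
  if (all(c("effect_allele", "other_allele") %in% names(a)) &&
      all(c("effect_allele", "other_allele") %in% names(b))) {
    swapped <- a$effect_allele == b$other_allele &
      a$other_allele == b$effect_allele
    mismatch <- !swapped & !(a$effect_allele == b$effect_allele &
                               a$other_allele == b$other_allele)
    if (any(mismatch))
      stop("allele labels cannot be harmonized for row ",
           which(mismatch)[1L], call. = FALSE)
    beta_b <- ifelse(swapped, -beta_b, beta_b)
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    ambiguous <- comp[a$effect_allele] == a$other_allele
    note[ambiguous] <- "strand_ambiguous"
  }
  wa <- 1 / a$se^2; wb <- 1 / b$se^2
  x_m <- (wa * a$beta + wb * beta_b) / (wa + wb)
  se_m <- sqrt(1 / (wa + wb))
  z_m <- x_m / se_m
  logp <- log(2) + stats::pnorm(abs(z_m), lower.tail = FALSE, log.p = TRUE)
  data.frame(
    snp_id = if ("snp_id" %in% names(a)) a$snp_id else NA_character_,
    feature = if ("feature" %in% names(a)) a$feature else NA,
    x_m = x_m, se_m = se_m, z_m = z_m,
    p_m = pmax(exp(logp), .Machine$double.xmin),
    x_a = a$beta, p_a = if ("p" %in% names(a)) a$p else NA_real_,
    x_b = b$beta, p_b = if ("p" %in% names(b)) b$p else NA_real_,
    note = note, stringsAsFactors = FALSE)
}

#' Apply the replication rules to discovered associations
#'
#' A discovery hit replicates iff (i) the discovery and replication
#' effect directions are concordant, (ii) the replication P-value is
#' below `0.05 / n_hits`, and (iii) the inverse-variance combined P-value
#' is below `combined_threshold`. Replication records are matched by SNP
#' id and by feature label after carrying discovery features onto the
#' replication grid (supply `alignment` from [align_features()] when the
#' grids differ). Hits without a matched replication record are listed as
#' not testable and excluded from the replicated count.
#'
#' @param discovery Data frame of independent discovery hits
#'   ([clump_pairs()] output) with `snp_id, feature, beta, se, p`.
#' @param replication Data frame of replication-cohort association
#'   records with the same columns.
#' @param combined_threshold Combined Bonferroni threshold
#'   (`gwas_thresholds()$combined`).
#' @param n_hits Number of discovered independent associations (defaults
#'   to `nrow(discovery)`).
#' @param alignment Optional data frame `label_a, label_b` mapping
#'   discovery feature labels to replication feature labels.
#' @return The discovery data frame with columns `testable`,
#'   `sign_concordant`, `replication_significant`, `combined_significant`,
#'   `replicated`, and the matched replication/meta statistics
#'   (`x_repl, p_repl, x_m, se_m, p_m`).
#' @export
assess_replication <- function(discovery, replication, combined_threshold,
                               n_hits = nrow(discovery),
                               alignment = NULL) {
  stopifnot(n_hits >= 1)
  repl_feat <- ppm_key(replication$feature)
  disc_feat <- ppm_key(discovery$feature)
  if (!is.null(alignment)) {
    mapped <- alignment$label_b[match(disc_feat, ppm_key(alignment$label_a))]
    disc_feat <- ifelse(is.na(mapped), NA_character_, ppm_key(mapped))
  }
  key_r <- paste(replication$snp_id, repl_feat)
  key_d <- paste(discovery$snp_id, disc_feat)
  idx <- match(key_d, key_r)
  idx[is.na(disc_feat)] <- NA_integer_
  out <- discovery
  out$testable <- !is.na(idx)
  out$x_repl <- replication$beta[idx]
  out$p_repl <- replication$p[idx]
  out$sign_concordant <- sign(out$beta) == sign(out$x_repl)
  out$replication_significant <- out$p_repl < 0.05 / n_hits
  meta <- rep(list(NULL), nrow(out))
  out$x_m <- out$se_m <- out$p_m <- NA_real_
  ok <- which(out$testable)
  if (length(ok)) {
    mm <- ivw_meta(discovery[ok, , drop = FALSE],
                   replication[idx[ok], , drop = FALSE])
    out$x_m[ok] <- mm$x_m; out$se_m[ok] <- mm$se_m; out$p_m[ok] <- mm$p_m
  }
  out$combined_significant <- out$p_m < combined_threshold
  out$replicated <- out$testable & out$sign_concordant &
    out$replication_significant & out$combined_significant
  out$replicated[is.na(out$replicated)] <- FALSE
  out
}

#' Group replicated SNP-feature associations into loci
#'
#' Single-linkage grouping: hits on the same chromosome belong to one
#' locus whenever they can be chained through neighbours closer than
#' `window`. Each locus reports its lead SNP (smallest meta P; ties by
#' smallest position) and the set of associated features.
#'
#' @param records Data frame with `snp_id, chr, pos, feature` and a meta
#'   P column `p_m` (or `p`, used as fallback).
#' @param window Linkage distance in bp (default 1 Mb).
#' @return List with `assignments` (input rows plus `locus`) and `loci`
#'   (one row per locus: `locus, chr, start, end, lead_snp, lead_p,
#'   n_snps, features`).
#' @export
group_loci <- function(records, window = 1e6) {
  if (nrow(records) == 0L)
    return(list(assignments = records, loci = records))
  p <- if ("p_m" %in% names(records)) records$p_m else records$p
  ord <- order(records$chr, records$pos)
  locus <- integer(nrow(records))
  cur <- 0L
  last_chr <- NULL; last_pos <- -Inf
  for (i in ord) {
    if (is.null(last_chr) || records$chr[i] != last_chr ||
        records$pos[i] - last_pos > window) {
      cur <- cur + 1L
    }
    locus[i] <- cur
    last_chr <- records$chr[i]; last_pos <- records$pos[i]
  }
  assignments <- records
  assignments$locus <- locus
  loci <- do.call(rbind, lapply(split(seq_len(nrow(records)), locus),
                                function(ix) {
    pl <- p[ix]
    lead <- ix[order(pl, records$pos[ix])][1L]
    data.frame(locus = locus[lead],
               chr = records$chr[lead],
               start = min(records$pos[ix]),
               end = max(records$pos[ix]),
               lead_snp = records$snp_id[lead],
               lead_p = p[lead],
               n_snps = length(unique(records$snp_id[ix])),
               features = paste(sort(unique(ppm_key(records$feature[ix]))),
                                collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  list(assignments = assignments, loci = loci)
}
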