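# Metabomatching: identify the metabolite underlying a SNP association
# by scoring the SNP's pseudo-spectrum against reference peak lists with
# a chi-squared statistic over independent matched peaks.

#' Build the pseudo-spectrum of one SNP
#'
#' The pseudo-spectrum of a SNP is its per-feature association
#' significance profile: for every metabolome feature, the signed test
#' statistic z and -log10 P of the SNP-feature association. When the
#' genetic effect is strong it resembles the NMR spectrum of the driven
#' metabolite, which is what metabomatching exploits.
#'
#' @param records Data frame of association records for a single SNP
#'   (one row per feature; columns `feature, z` and `p` or `snp_id`).
#' @return Object of class `pseudo_spectrum`: data frame
#'   `feature_ppm, z, minus_log10_p` (sorted by ppm) with the SNP id as
#'   attribute `snp_id`. -log10 P is recomputed from z on the log scale,
#'   so genome-wide significances survive floating-point underflow.
#' @export
pseudo_spectrum <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("feature", "z") %in% names(records)))
  if ("snp_id" %in% names(records) &&
      length(unique(records$snp_id)) > 1L)
    stop("records must belong to a single SNP", call. = FALSE)
  ppm <- round(as.numeric(records$feature), 4L)
  if (anyDuplicated(ppm))
    stop("duplicate feature labels in pseudo-spectrum", call. = FALSE)
  mlog10p <- -(log(2) + stats::pnorm(abs(records$z), lower.tail = FALSE,
                                     log.p = TRUE)) / log(10)
  o <- order(ppm)
  ps <- data.frame(feature_ppm = ppm[o], z = records$z[o],
                   minus_log10_p = pmax(mlog10p[o], 0))
  attr(ps, "snp_id") <- if ("snp_id" %in% names(records))
    as.character(records$snp_id[1L]) else NA_character_
  class(ps) <- c("pseudo_spectrum", "data.frame")
  ps
}

#' @export
print.pseudo_spectrum <- function(x, ...) {
  cat(sprintf("<pseudo_spectrum> SNP %s, %d features, max -log10P = %.2f at %.4f ppm\n",
              attr(x, "snp_id"), nrow(x),
              max(x$minus_log10_p), x$feature_ppm[which.max(x$minus_log10_p)]))
  invisible(x)
}

#' Map reference peaks onto metabolome feature bins
#'
#' Each peak of the reference spectrum is assigned to the feature whose
#' bin center is nearest in ppm, if the distance is within `tolerance`;
#' at an exact midpoint the lower-ppm bin wins. Peaks landing in the same
#' bin collapse to one match; unmatched peaks are dropped and counted.
#'
#' @param ref A [reference_spectrum()].
#' @param feature_ppm Sorted numeric vector of bin-center labels.
#' @param tolerance Maximum peak-to-bin-center distance in ppm (default
#'   0.02).
#' @return Integer vector of matched feature indices (unique, sorted),
#'   with attribute `n_unmatched`.
#' @export
map_peaks <- function(ref, feature_ppm, tolerance = 0.02) {
  stopifnot(inherits(ref, "reference_spectrum"))
  feature_ppm <- as.numeric(feature_ppm)
  if (is.unsorted(feature_ppm))
    stop("feature labels must be sorted", call. = FALSE)
  idx <- vapply(ref$peaks$ppm, function(p) {
    d <- abs(feature_ppm - p)
    j <- which.min(d) # ties resolve to the lower-ppm bin (first minimum)
    if (d[j] <= tolerance + 1e-12) j else NA_integer_
  }, integer(1))
  matched <- sort(unique(idx[!is.na(idx)]))
  structure(matched, n_unmatched = sum(is.na(idx)))
}

#' Prune correlated features to an independent subset
#'
#' Greedy pruning used before chi-squared scoring: repeatedly keep the
#' feature with the largest |z| and drop every remaining feature with
#' squared correlation above `r2_prune` to a kept one.
#'
#' @param matched Integer indices of matched features (into the feature
#'   label set underlying `z` and `feature_corr`).
#' @param z Signed association statistics for all features.
#' @param feature_corr Feature correlation matrix (Pearson r; squared
#'   internally).
#' @param r2_prune Squared-correlation threshold (default 0.4).
#' @return Integer vector of kept (independent) feature indices.
#' @export
prune_correlated <- function(matched, z, feature_corr, r2_prune = 0.4) {
  matched <- as.integer(matched)
  if (length(matched) <= 1L) return(matched)
  fc2 <- feature_corr[matched, matched, drop = FALSE]^2
  remaining <- order(-abs(z[matched])) # positions within `matched`
  kept <- integer(0)
  while (length(remaining) > 0L) {
    top <- remaining[1L]
    kept <- c(kept, top)
    remaining <- remaining[-1L]
    if (length(remaining))
      remaining <- remaining[fc2[top, remaining] <= r2_prune]
  }
  sort(matched[kept])
}

# shared scoring core: peaks (numeric ppm vector) -> MatchResult row
score_peaks <- function(ps, peak_ppm, feature_corr, tolerance, r2_prune,
                        id, name) {
  fake_ref <- reference_spectrum(id, name, peak_ppm, 1)
  matched <- map_peaks(fake_ref, ps$feature_ppm, tolerance)
  n_unmatched <- attr(matched, "n_unmatched")
  if (length(matched) == 0L) {
    return(data.frame(metabolite_id = id, name = name, k = 0L,
                      score = NA_real_, p = NA_real_,
                      n_unmatched_peaks = n_unmatched,
                      stringsAsFactors = FALSE))
  }
  kept <- prune_correlated(matched, ps$z, feature_corr, r2_prune)
  k <- length(kept)
  score <- sum(ps$z[kept]^2)
  p <- stats::pchisq(score, df = k, lower.tail = FALSE)
  data.frame(metabolite_id = id, name = name, k = k, score = score,
             p = max(p, .Machine$double.xmin),
             n_unmatched_peaks = n_unmatched, stringsAsFactors = FALSE)
}

#' Score one metabolite against a SNP's pseudo-spectrum
#'
#' The metabomatching score: map the metabolite's reference peaks to
#' feature bins, prune correlated bins to ensure independence, then sum
#' the squared association statistics over the k surviving features. The
#' sum is chi-squared with k degrees of freedom under the null of no
#' association, giving the match P-value.
#'
#' @param ps A [pseudo_spectrum()].
#' @param ref A [reference_spectrum()].
#' @param feature_corr Feature correlation matrix over the
#'   pseudo-spectrum's features.
#' @param tolerance Peak-to-bin tolerance in ppm (default 0.02).
#' @param r2_prune Squared-correlation pruning threshold (default 0.4).
#' @return One-row data frame `metabolite_id, name, k, score, p,
#'   n_unmatched_peaks`; `k = 0` marks an unscorable metabolite (no peak
#'   maps to a feature).
#' @export
score_metabolite <- function(ps, ref, feature_corr, tolerance = 0.02,
                             r2_prune = 0.4) {
  stopifnot(inherits(ps, "pseudo_spectrum"),
            inherits(ref, "reference_spectrum"))
  score_peaks(ps, ref$peaks$ppm, feature_corr, tolerance, r2_prune,
              ref$metabolite_id, ref$name)
}

#' Score a compound pair against a pseudo-spectrum
#'
#' Two-compound metabomatching: the two reference peak sets are pooled,
#' mapped and pruned jointly, and scored with the same chi-squared
#' statistic over the pruned union. Useful when a SNP drives two
#' co-regulated metabolites.
#'
#' @param ps A [pseudo_spectrum()].
#' @param ref_a,ref_b [reference_spectrum()] objects.
#' @inheritParams score_metabolite
#' @return One-row data frame as in [score_metabolite()], with
#'   `metabolite_id` of the form `"idA+idB"`.
#' @export
score_pair <- function(ps, ref_a, ref_b, feature_corr, tolerance = 0.02,
                       r2_prune = 0.4) {
  stopifnot(inherits(ps, "pseudo_spectrum"),
            inherits(ref_a, "reference_spectrum"),
            inherits(ref_b, "reference_spectrum"))
  score_peaks(ps, c(ref_a$peaks$ppm, ref_b$peaks$ppm), feature_corr,
              tolerance, r2_prune,
              paste(ref_a$metabolite_id, ref_b$metabolite_id, sep = "+"),
              paste(ref_a$name, ref_b$name, sep = " + "))
}

#' Rank a reference library against a pseudo-spectrum
#'
#' Scores every metabolite in the library ([score_metabolite()]) and
#' ranks the scorable ones by ascending P (ties by descending score, then
#' metabolite id). Percentile rank over scorable metabolites is reported
#' for top-x% style evaluation.
#'
#' @param ps A [pseudo_spectrum()].
#' @param library List of [reference_spectrum()] objects.
#' @inheritParams score_metabolite
#' @param pair_anchor Optional metabolite id: additionally score every
#'   pair (anchor, other metabolite) in two-compound mode and rank the
#'   pairs in the same table.
#' @return Data frame `rank, metabolite_id, name, k, score, p,
#'   percentile` sorted by rank; unscorable entries are listed last with
#'   `NA` rank and a `note`.
#' @export
rank_library <- function(ps, library, feature_corr, tolerance = 0.02,
                         r2_prune = 0.4, pair_anchor = NULL) {
  if (length(library) == 0L) stop("empty reference library", call. = FALSE)
  rows <- lapply(library, score_metabolite, ps = ps,
                 feature_corr = feature_corr, tolerance = tolerance,
                 r2_prune = r2_prune)
  if (!is.null(pair_anchor)) {
    ids <- vapply(library, `[[`, "", "metabolite_id")
    ai <- match(pair_anchor, ids)
    if (is.na(ai)) stop("pair_anchor not found in library", call. = FALSE)
    others <- setdiff(seq_along(library), ai)
    rows <- c(rows, lapply(others, function(j)
      score_pair(ps, library[[ai]], library[[j]], feature_corr,
                 tolerance, r2_prune)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  scorable <- res$k >= 1L
  if (!any(scorable)) {
    res$rank <- NA_integer_; res$percentile <- NA_real_
    res$note <- "unscorable"
    warning("no scorable metabolite in library", call. = FALSE)
    return(res)
  }
  sc <- res[scorable, , drop = FALSE]
  o <- order(sc$p, -sc$score, sc$metabolite_id)
  sc <- sc[o, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  sc$percentile <- 100 * sc$rank / nrow(sc)
  sc$note <- ""
  un <- res[!scorable, , drop = FALSE]
  if (nrow(un)) {
    un$rank <- NA_integer_; un$percentile <- NA_real_
    un$note <- "unscorable"
  }
  out <- rbind(sc, un)
  rownames(out) <- NULL
  out
}
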