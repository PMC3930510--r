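#' Bin specification for NMR spectra
#'
#' Defines the uniform chemical-shift grid used to turn a raw 1D spectrum
#' into metabolome features. Bins are half-open intervals
#' `[lo, lo + bin_width)`; each feature is labelled by its bin-center ppm
#' rounded to 4 decimals, which is how features are referred to throughout
#' (e.g. feature `1.2025` on a 0.005-ppm grid).
#'
#' @param bin_width Bin width in ppm (e.g. 0.005).
#' @param ppm_min,ppm_max Chemical-shift range covered by the grid, in ppm.
#' @return An object of class `bin_spec` with elements `bin_width`,
#'   `ppm_min`, `ppm_max`, `n_bins` and `centers` (bin-center ppm values,
#'   rounded to 4 decimals, strictly increasing).
#' @examples
#' bs <- bin_spec(0.005, 0.5, 9.5)
#' bs$n_bins
#' @export
bin_spec <- function(bin_width, ppm_min, ppm_max) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  stopifnot(is.numeric(ppm_min), is.numeric(ppm_max))
  if (ppm_max <= ppm_min)
    stop("ppm_max must exceed ppm_min", call. = FALSE)
  n_bins <- as.integer(round((ppm_max - ppm_min) / bin_width))
  if (n_bins < 1L)
    stop("bin grid contains no bins", call. = FALSE)
  centers <- round(ppm_min + (seq_len(n_bins) - 0.5) * bin_width, 4L)
  structure(
    list(bin_width = bin_width, ppm_min = ppm_min, ppm_max = ppm_max,
         n_bins = n_bins, centers = centers),
    class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("<bin_spec> %d bins of %.4g ppm on [%.4g, %.4g]\n",
              x$n_bins, x$bin_width, x$ppm_min, x$ppm_max))
  invisible(x)
}

#' Construct a feature matrix of binned spectral intensities
#'
#' The container for molecular phenotypes: one row per sample, one column
#' per ppm-labelled spectral bin. Missing bins are `NA`.
#'
#' @param values Numeric matrix, samples x features.
#' @param feature_ppm Bin-center ppm labels, strictly increasing; length
#'   must equal `ncol(values)`.
#' @param sample_ids Character vector of sample identifiers (default taken
#'   from `rownames(values)` or generated).
#' @param scale One of `"intensity"`, `"log"`, `"normalized"`; bookkeeping
#'   for which stage of preprocessing the values are at.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ppm,
                           sample_ids = NULL,
                           scale = c("intensity", "log", "normalized")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  feature_ppm <- round(as.numeric(feature_ppm), 4L)
  if (length(feature_ppm) != ncol(values))
    stop("feature_ppm length must match ncol(values)", call. = FALSE)
  if (is.unsorted(feature_ppm, strictly = TRUE))
    stop("feature_ppm labels must be strictly increasing", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids))
      sample_ids <- sprintf("S%04d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(sample_ids, sprintf("%.4f", feature_ppm))
  structure(
    list(values = values, feature_ppm = feature_ppm,
         sample_ids = sample_ids, scale = scale),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s scale], %.4f-%.4f ppm, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              min(x$feature_ppm), max(x$feature_ppm),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Bin a raw spectrum onto a fixed chemical-shift grid
#'
#' Each bin value is the mean intensity of the raw points whose ppm falls
#' in the half-open interval `[lo, lo + bin_width)`. Bins containing no
#' points are `NA` (missing). Points outside the grid range are ignored.
#'
#' @param raw Two-column numeric matrix or data frame `(ppm, intensity)`,
#'   sorted by ppm.
#' @param spec A [bin_spec()].
#' @return Named numeric vector of length `spec$n_bins`; names are the
#'   bin-center labels.
#' @export
bin_spectrum <- function(raw, spec) {
  stopifnot(inherits(spec, "bin_spec"))
  raw <- as.matrix(raw)
  if (nrow(raw) == 0L)
    stop("raw spectrum is empty", call. = FALSE)
  if (ncol(raw) < 2L)
    stop("raw spectrum needs (ppm, intensity) columns", call. = FALSE)
  ppm <- raw[, 1L]; intensity <- raw[, 2L]
  if (is.unsorted(ppm))
    stop("raw spectrum must be sorted by ppm", call. = FALSE)
  edges <- spec$ppm_min + (0:spec$n_bins) * spec$bin_width
  # half-open [lo, hi): findInterval with left.open = FALSE puts a point
  # exactly on an edge into the bin starting there
  idx <- findInterval(ppm, edges, rightmost.closed = FALSE, left.open = FALSE)
  keep <- idx >= 1L & idx <= spec$n_bins
  out <- rep(NA_real_, spec$n_bins)
  if (any(keep)) {
    sums <- rowsum(intensity[keep], idx[keep])
    cnt <- rowsum(rep(1, sum(keep)), idx[keep])
    out[as.integer(rownames(sums))] <- sums / cnt
  }
  names(out) <- sprintf("%.4f", spec$centers)
  out
}

#' Log-average replicate profiles of one individual
#'
#' Bin intensities are averaged across replicate samples on the log scale:
#' the output bin is the mean of `log(intensity)` over replicates with a
#' positive, non-missing value there. Non-positive intensities cannot be
#' log-transformed and are treated as missing (with a warning); a bin
#' missing in every replicate stays missing. The result is on the log
#' scale, which is kept for all later stages.
#'
#' @param profiles A list of binned profiles (equal-length named numeric
#'   vectors from [bin_spectrum()] on the same grid), or a matrix with one
#'   row per replicate.
#' @return Numeric vector of log-averaged bin values.
#' @export
average_replicates <- function(profiles) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L)
    stop("need at least one replicate profile", call. = FALSE)
  bad <- !is.na(profiles) & profiles <= 0
  if (any(bad)) {
    warning(sprintf("%d non-positive intensities treated as missing in log-averaging",
                    sum(bad)), call. = FALSE)
    profiles[bad] <- NA_real_
  }
  lp <- log(profiles)
  out <- colMeans(lp, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_ # all-missing bins give NaN
  out
}

#' Filter a feature matrix on missingness
#'
#' Drops features with more than `max_missing` missing values, then drops
#' samples with more than `max_missing` missing values computed on the
#' surviving features. The order (features first, then samples) matters
#' and is fixed.
#'
#' @param m A [feature_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @return The filtered `feature_matrix`.
#' @export
filter_matrix <- function(m, max_missing = 0.05) {
  stopifnot(inherits(m, "feature_matrix"))
  v <- m$values
  if (length(v) == 0L) stop("feature matrix is empty", call. = FALSE)
  feat_keep <- colMeans(is.na(v)) <= max_missing
  if (!any(feat_keep))
    stop("all features exceed the missingness threshold", call. = FALSE)
  v <- v[, feat_keep, drop = FALSE]
  samp_keep <- rowMeans(is.na(v)) <= max_missing
  if (!any(samp_keep))
    stop("all samples exceed the missingness threshold", call. = FALSE)
  feature_matrix(v[samp_keep, , drop = FALSE],
                 m$feature_ppm[feat_keep],
                 m$sample_ids[samp_keep],
                 scale = m$scale)
}

#' Normalize metabolic profiles
#'
#' Per-individual profile normalization of a log-scale feature matrix.
#'
#' * `zscore`: each sample's non-missing feature vector is centered and
#'   scaled across features to zero mean and unit variance (population,
#'   i.e. 1/n, variance). This is a profile normalization: it removes
#'   overall dilution/intensity differences between urine samples.
#' * `total_content`: divide each sample's intensities by the sample's
#'   total intensity, then log; on log-scale input this is
#'   `x - log(sum(exp(x)))` over non-missing features.
#' * `reference_feature`: divide by the intensity of a named reference bin
#'   (e.g. a creatinine bin), then log: `x - x[ref]`.
#'
#' @param m A log-scale [feature_matrix()].
#' @param method One of `"zscore"`, `"total_content"`, `"reference_feature"`.
#' @param reference_ppm Bin label (ppm, numeric) of the reference feature,
#'   required for `method = "reference_feature"`.
#' @return A `feature_matrix` with `scale = "normalized"`.
#' @export
normalize_profiles <- function(m,
                               method = c("zscore", "total_content",
                                          "reference_feature"),
                               reference_ppm = NULL) {
  stopifnot(inherits(m, "feature_matrix"))
  method <- match.arg(method)
  v <- m$values
  if (method == "zscore") {
    n_ok <- rowSums(!is.na(v))
    if (any(n_ok < 2L))
      stop(sprintf("sample '%s' has fewer than 2 non-missing features",
                   m$sample_ids[which(n_ok < 2L)[1L]]), call. = FALSE)
    mu <- rowMeans(v, na.rm = TRUE)
    cv <- v - mu
    sdv <- sqrt(rowMeans(cv^2, na.rm = TRUE)) # population variance
    zero <- sdv <= .Machine$double.eps
    if (any(zero))
      stop(sprintf("sample '%s' has zero within-sample variance",
                   m$sample_ids[which(zero)[1L]]), call. = FALSE)
    v <- cv / sdv
  } else if (method == "total_content") {
    tot <- apply(v, 1L, function(x) log(sum(exp(x[!is.na(x)]))))
    v <- v - tot
  } else {
    if (is.null(reference_ppm))
      stop("reference_ppm is required for reference_feature normalization",
           call. = FALSE)
    j <- match(round(reference_ppm, 4L), m$feature_ppm)
    if (is.na(j))
      stop("reference feature not found in matrix", call. = FALSE)
    ref <- v[, j]
    if (anyNA(ref))
      stop("reference feature has missing values", call. = FALSE)
    v <- v - ref
  }
  feature_matrix(v, m$feature_ppm, m$sample_ids, scale = "normalized")
}

#' Match features between two bin grids
#'
#' Pairs each feature of `a` with the feature of `b` whose bin center is
#' nearest, provided the distance is within `tolerance`. Used to carry
#' discovery-cohort features over to a replication cohort binned on a
#' different grid (e.g. 0.005 vs 0.0032 ppm).
#'
#' @param a,b `feature_matrix` objects, or numeric vectors of bin-center
#'   ppm labels.
#' @param tolerance Maximum allowed center-to-center distance in ppm;
#'   defaults to the larger of the two median grid spacings.
#' @return Data frame with columns `label_a`, `label_b`, `distance`; one
#'   row per feature of `a` that found a partner.
#' @export
align_features <- function(a, b, tolerance = NULL) {
  ppm_a <- if (inherits(a, "feature_matrix")) a$feature_ppm else round(as.numeric(a), 4L)
  ppm_b <- if (inherits(b, "feature_matrix")) b$feature_ppm else round(as.numeric(b), 4L)
  if (is.null(tolerance)) {
    wa <- if (length(ppm_a) > 1L) stats::median(diff(ppm_a)) else Inf
    wb <- if (length(ppm_b) > 1L) stats::median(diff(ppm_b)) else Inf
    tolerance <- max(wa, wb)
    if (!is.finite(tolerance))
      stop("cannot infer tolerance from single-feature grids; supply one",
           call. = FALSE)
  }
  if (min(ppm_a) > max(ppm_b) + tolerance || max(ppm_a) < min(ppm_b) - tolerance) {
    warning("ppm ranges do not overlap; no features aligned", call. = FALSE)
    return(data.frame(label_a = numeric(0), label_b = numeric(0),
                      distance = numeric(0)))
  }
  nearest <- vapply(ppm_a, function(p) {
    j <- which.min(abs(ppm_b - p))
    c(j, abs(ppm_b[j] - p))
  }, numeric(2))
  ok <- nearest[2L, ] <= tolerance + 1e-12
  data.frame(label_a = ppm_a[ok],
             label_b = ppm_b[nearest[1L, ok]],
             distance = nearest[2L, ok])
}

#' Preprocess raw spectra into an analysis-ready feature matrix
#'
#' Convenience wrapper chaining the standard steps: bin each replicate
#' spectrum, log-average replicates per individual, filter features then
#' samples on missingness, and normalize profiles.
#'
#' @param spectra Named list: one element per individual, each a list of
#'   replicate raw spectra (two-column `(ppm, intensity)` matrices).
#' @param spec A [bin_spec()].
#' @param max_missing Missingness threshold passed to [filter_matrix()].
#' @param normalize Normalization method, or `"none"`.
#' @param exclude_ppm Optional numeric length-2 vector; bins whose centers
#'   fall inside this interval (e.g. the water-suppression region
#'   `c(4.5, 5)`) are dropped before filtering. Default: none.
#' @return A normalized [feature_matrix()].
#' @export
preprocess_spectra <- function(spectra, spec, max_missing = 0.05,
                               normalize = c("zscore", "total_content",
                                             "none"),
                               exclude_ppm = NULL) {
  normalize <- match.arg(normalize)
  rows <- lapply(spectra, function(reps) {
    average_replicates(lapply(reps, bin_spectrum, spec = spec))
  })
  v <- do.call(rbind, rows)
  fm <- feature_matrix(v, spec$centers, names(spectra), scale = "log")
  if (!is.null(exclude_ppm)) {
    keep <- fm$feature_ppm < min(exclude_ppm) | fm$feature_ppm > max(exclude_ppm)
    fm <- feature_matrix(fm$values[, keep, drop = FALSE],
                         fm$feature_ppm[keep], fm$sample_ids, scale = "log")
  }
  fm <- filter_matrix(fm, max_missing)
  if (normalize != "none")
    fm <- normalize_profiles(fm, normalize)
  fm
}
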