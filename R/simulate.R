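# Synthetic-cohort simulator: LD-blocked genotypes, metabolite
# concentrations with additive SNP effects, Lorentzian forward-rendered
# spectra. Defines the ground truth against which every downstream stage
# is tested.

set_seed_if <- function(seed, offset = 0L) {
  if (!is.null(seed)) set.seed(as.integer(seed) + as.integer(offset))
  invisible(NULL)
}

#' Configuration of a synthetic metabolome-GWAS cohort
#'
#' Bundles every knob of the simulator: genotypes (LD-blocked diallelic
#' SNPs in one or two populations), metabolite concentrations (additive
#' SNP effects plus covariate effects and log-normal noise), and spectra
#' (sums of Lorentzian peak signatures with per-sample chemical-shift
#' jitter and missing values).
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_snps Number of SNPs.
#' @param maf_range Length-2 vector of minor-allele frequencies in
#'   (0, 0.5]; per-SNP MAFs are drawn uniformly from this range.
#' @param ld_rho Adjacent-SNP haplotype-copying continuation probability
#'   in [0, 1); higher values give longer LD blocks. A vector of length
#'   `n_populations` gives each population its own LD scale.
#' @param n_populations 1 or 2. With 2 populations the cohort is split in
#'   half; each half has its own founder haplotypes and block boundaries
#'   (distinct LD structure), sharing per-SNP allele frequencies.
#' @param n_metabolites Number of simulated metabolites.
#' @param peaks_per_metabolite Length-2 integer range; each metabolite's
#'   peak count is drawn uniformly from it.
#' @param ppm_range Chemical-shift interval covered by the spectra (ppm).
#' @param peak_width Lorentzian full width at half maximum, in ppm.
#' @param effect_table Data frame with columns `snp`, `metabolite`,
#'   `beta`: additive effect of each listed SNP (per dosage unit) on the
#'   log-concentration of the listed metabolite. Empty by default.
#' @param noise_sd Residual SD of log-concentrations.
#' @param shift_jitter_sd SD (ppm) of the per-sample global chemical-shift
#'   jitter applied to all peaks of a sample (emulates pH/reference
#'   drift).
#' @param missing_rate Fraction of binned intensities set to missing.
#' @param n_replicates Replicate spectra per individual.
#' @param seed Integer seed; all operations are reproducible given it.
#' @param n_founders Founder haplotypes per population for the
#'   haplotype-copying model.
#' @param raw_resolution Spacing (ppm) of the rendered raw spectrum grid.
#' @param baseline_level,baseline_sd Mean and SD of the additive baseline
#'   intensity noise of rendered spectra.
#' @param pos_spacing Physical spacing (bp) between adjacent SNPs on the
#'   simulated chromosome.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500L,
                       n_snps = 200L,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.8,
                       n_populations = 1L,
                       n_metabolites = 8L,
                       peaks_per_metabolite = c(2L, 6L),
                       ppm_range = c(0.5, 9.5),
                       peak_width = 0.01,
                       effect_table = NULL,
                       noise_sd = 1,
                       shift_jitter_sd = 0.002,
                       missing_rate = 0.01,
                       n_replicates = 1L,
                       seed = 1L,
                       n_founders = 24L,
                       raw_resolution = 0.001,
                       baseline_level = 0.05,
                       baseline_sd = 0.01,
                       pos_spacing = 5000L) {
  if (n_individuals < 2L)
    stop("n_individuals must be at least 2", call. = FALSE)
  stopifnot(n_snps >= 1L, n_metabolites >= 1L, n_replicates >= 1L,
            n_founders >= 2L)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1L] > maf_range[2L])
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (!(n_populations %in% c(1L, 2L)))
    stop("n_populations must be 1 or 2", call. = FALSE)
  ld_rho <- rep_len(as.numeric(ld_rho), n_populations)
  if (any(ld_rho < 0 | ld_rho >= 1))
    stop("ld_rho must lie in [0, 1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (peak_width <= 0)
    stop("peak_width must be positive", call. = FALSE)
  peaks_per_metabolite <- as.integer(rep_len(peaks_per_metabolite, 2L))
  if (any(peaks_per_metabolite < 1L) ||
      peaks_per_metabolite[1L] > peaks_per_metabolite[2L])
    stop("peaks_per_metabolite must be a positive integer range",
         call. = FALSE)
  if (diff(range(ppm_range)) <= 0)
    stop("ppm_range must be a nonempty interval", call. = FALSE)
  if (is.null(effect_table)) {
    effect_table <- data.frame(snp = integer(0), metabolite = integer(0),
                               beta = numeric(0))
  } else {
    effect_table <- as.data.frame(effect_table)
    if (!all(c("snp", "metabolite", "beta") %in% names(effect_table)))
      stop("effect_table needs columns snp, metabolite, beta", call. = FALSE)
    if (any(effect_table$snp < 1L | effect_table$snp > n_snps))
      stop("effect_table references an unknown SNP index", call. = FALSE)
    if (any(effect_table$metabolite < 1L |
            effect_table$metabolite > n_metabolites))
      stop("effect_table references an unknown metabolite index",
           call. = FALSE)
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps),
         maf_range = as.numeric(maf_range),
         ld_rho = ld_rho,
         n_populations = as.integer(n_populations),
         n_metabolites = as.integer(n_metabolites),
         peaks_per_metabolite = peaks_per_metabolite,
         ppm_range = sort(as.numeric(ppm_range)),
         peak_width = as.numeric(peak_width),
         effect_table = effect_table,
         noise_sd = as.numeric(noise_sd),
         shift_jitter_sd = as.numeric(shift_jitter_sd),
         missing_rate = as.numeric(missing_rate),
         n_replicates = as.integer(n_replicates),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         n_founders = as.integer(n_founders),
         raw_resolution = as.numeric(raw_resolution),
         baseline_level = as.numeric(baseline_level),
         baseline_sd = as.numeric(baseline_sd),
         pos_spacing = as.integer(pos_spacing)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d individuals (%d pop.), %d SNPs (rho=%s), %d metabolites, %d causal effects, seed %s\n",
              x$n_individuals, x$n_populations, x$n_snps,
              paste(format(x$ld_rho), collapse = "/"),
              x$n_metabolites, nrow(x$effect_table),
              format(x$seed)))
  invisible(x)
}

#' Effect size giving a target explained-variance fraction
#'
#' Under Hardy-Weinberg genotype variance `2 maf (1 - maf)`, a per-dosage
#' effect `beta` on a phenotype with residual SD `noise_sd` explains a
#' fraction `r2 = v / (v + noise_sd^2)` with `v = 2 maf (1 - maf) beta^2`.
#' This inverts that relation.
#'
#' @param r2 Target explained-variance fraction in (0, 1).
#' @param maf Minor-allele frequency of the causal SNP.
#' @param noise_sd Residual SD of the phenotype (default 1).
#' @return The per-dosage effect size `beta`.
#' @export
effect_size_for_r2 <- function(r2, maf, noise_sd = 1) {
  stopifnot(r2 > 0, r2 < 1, maf > 0, maf <= 0.5)
  noise_sd * sqrt(r2 / ((1 - r2) * 2 * maf * (1 - maf)))
}

# One population's haplotypes by founder copying: each haplotype walks
# along the SNPs, keeping its current founder with probability rho and
# jumping to a random founder otherwise. Founder haplotypes are built
# from per-founder AR(1) latent Gaussians (parameter rho) thresholded by
# rank, so founder alleles are serially correlated along the chromosome
# (realistic within-block LD) while per-SNP minor-allele counts are
# exact and empirical MAFs track the target frequencies.
copy_haplotypes <- function(n_hap, p, rho, n_founders) {
  n_snps <- length(p)
  k_minor <- pmin(pmax(round(n_founders * p), 1L), n_founders - 1L)
  z <- matrix(0, n_founders, n_snps)
  z[, 1L] <- stats::rnorm(n_founders)
  if (n_snps > 1L) {
    innov <- sqrt(1 - rho^2)
    for (j in 2:n_snps)
      z[, j] <- rho * z[, j - 1L] + innov * stats::rnorm(n_founders)
  }
  founders <- vapply(seq_len(n_snps), function(j) {
    a <- integer(n_founders)
    a[order(z[, j])[seq_len(k_minor[j])]] <- 1L
    a
  }, integer(n_founders)) # n_founders x n_snps
  ids <- matrix(0L, n_hap, n_snps)
  ids[, 1L] <- sample.int(n_founders, n_hap, replace = TRUE)
  if (n_snps > 1L) {
    for (j in 2:n_snps) {
      jump <- stats::runif(n_hap) >= rho
      ids[, j] <- ids[, j - 1L]
      if (any(jump))
        ids[jump, j] <- sample.int(n_founders, sum(jump), replace = TRUE)
    }
  }
  matrix(founders[cbind(as.vector(ids), rep(seq_len(n_snps), each = n_hap))],
         n_hap, n_snps)
}

#' Simulate LD-blocked diallelic genotype dosages
#'
#' Haplotype-copying model: per population, a pool of founder haplotypes
#' is laid down with per-SNP allele frequencies drawn from `maf_range`;
#' each individual haplotype copies contiguous founder stretches, jumping
#' to a random founder with probability `1 - ld_rho` between adjacent
#' SNPs. Dosage is the sum of two independent haplotypes, so genotypes are
#' in Hardy-Weinberg proportions and adjacent-SNP correlation grows with
#' `ld_rho`. With two populations, each half-cohort gets its own founder
#' pool and copying paths (distinct LD block boundaries).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genotypes`: `dosage` (individuals x SNPs
#'   matrix, values 0/1/2), `map` (data frame `snp_id, chr, pos, maf` with
#'   empirical MAFs), `population` (integer per individual).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_seed_if(config$seed, 0L)
  p <- stats::runif(config$n_snps, config$maf_range[1L], config$maf_range[2L])
  n_per <- if (config$n_populations == 2L) {
    c(ceiling(config$n_individuals / 2), floor(config$n_individuals / 2))
  } else config$n_individuals
  dosage <- matrix(0L, 0L, config$n_snps)
  pop <- integer(0)
  for (k in seq_len(config$n_populations)) {
    h1 <- copy_haplotypes(n_per[k], p, config$ld_rho[k], config$n_founders)
    h2 <- copy_haplotypes(n_per[k], p, config$ld_rho[k], config$n_founders)
    dosage <- rbind(dosage, h1 + h2)
    pop <- c(pop, rep.int(k, n_per[k]))
  }
  freq <- colMeans(dosage) / 2
  map <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(config$n_snps)),
    chr = 1L,
    pos = seq_len(config$n_snps) * config$pos_spacing,
    maf = pmin(freq, 1 - freq))
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(nrow(dosage))),
                           map$snp_id)
  structure(list(dosage = dosage, map = map, population = pop),
            class = "sim_genotypes")
}

#' @export
print.sim_genotypes <- function(x, ...) {
  cat(sprintf("<sim_genotypes> %d individuals x %d SNPs, %d population(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$population))))
  invisible(x)
}

#' Generate a synthetic reference-spectrum library
#'
#' Each metabolite receives a number of peaks drawn from
#' `peaks_per_metabolite`, with positions uniform over `ppm_range`
#' (distinct at 0.005-ppm bin resolution within a metabolite) and relative
#' intensities in (0, 1] with the tallest peak scaled to 1.
#'
#' @param config A [sim_config()].
#' @param n_metabolites Library size; defaults to `config$n_metabolites`.
#'   A larger value yields decoy entries beyond the simulated metabolites
#'   (useful for ranking experiments; entries 1..n_metabolites are the
#'   ones rendered into spectra).
#' @return Named list of [reference_spectrum()] objects.
#' @export
make_library <- function(config, n_metabolites = config$n_metabolites) {
  stopifnot(inherits(config, "sim_config"))
  set_seed_if(config$seed, 1L)
  grid_res <- 0.005
  grid <- seq(config$ppm_range[1L] + grid_res / 2, config$ppm_range[2L],
              by = grid_res)
  if (config$peaks_per_metabolite[2L] > length(grid))
    stop("peaks_per_metabolite exceeds the number of distinct bins in ppm_range",
         call. = FALSE)
  lib <- vector("list", n_metabolites)
  for (m in seq_len(n_metabolites)) {
    np <- sample(seq(config$peaks_per_metabolite[1L],
                     config$peaks_per_metabolite[2L]), 1L)
    pos <- sample(grid, np) + stats::runif(np, -grid_res / 2, grid_res / 2)
    h <- stats::runif(np, 0.2, 1)
    h <- h / max(h)
    lib[[m]] <- reference_spectrum(sprintf("SYN%03d", m),
                                   sprintf("synthetic-metabolite-%03d", m),
                                   pos, h)
  }
  names(lib) <- vapply(lib, `[[`, "", "metabolite_id")
  lib
}

#' Simulate metabolite log-concentrations with genetic effects
#'
#' Log-concentration of metabolite m in individual i is
#' `intercept_m + sum_j beta_jm dosage_ij + covariate terms +
#' Normal(0, noise_sd)`. The variance a causal SNP explains is
#' `2 maf (1 - maf) beta^2` (Hardy-Weinberg dosage variance).
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param config A [sim_config()]; `config$effect_table` lists the causal
#'   `(snp, metabolite, beta)` triples.
#' @param covariates Optional numeric matrix (individuals x covariates).
#' @param covariate_effects Optional matrix (covariates x metabolites) of
#'   covariate effects on log-concentrations.
#' @param library Optional pre-built reference library (so two cohorts
#'   can share the same metabolites); defaults to `make_library(config)`.
#' @return A list of class `ground_truth`: `concentrations` (individuals x
#'   metabolites, log scale), `causal_map` (the applied effect table),
#'   `library` (the [make_library()] result used for rendering),
#'   `covariates`.
#' @export
simulate_metabolome <- function(genotypes, config, covariates = NULL,
                                covariate_effects = NULL,
                                library = NULL) {
  stopifnot(inherits(genotypes, "sim_genotypes"),
            inherits(config, "sim_config"))
  if (ncol(genotypes$dosage) != config$n_snps)
    stop("genotypes do not match config$n_snps", call. = FALSE)
  lib <- if (is.null(library)) make_library(config) else library
  if (length(lib) < config$n_metabolites)
    stop("library smaller than config$n_metabolites", call. = FALSE)
  set_seed_if(config$seed, 2L)
  n <- nrow(genotypes$dosage)
  m <- config$n_metabolites
  intercepts <- stats::rnorm(m, mean = 1, sd = 0.25)
  conc <- matrix(rep(intercepts, each = n), n, m)
  et <- config$effect_table
  for (r in seq_len(nrow(et))) {
    conc[, et$metabolite[r]] <- conc[, et$metabolite[r]] +
      et$beta[r] * genotypes$dosage[, et$snp[r]]
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per individual", call. = FALSE)
    if (is.null(covariate_effects))
      stop("covariate_effects required when covariates are supplied",
           call. = FALSE)
    conc <- conc + covariates %*% covariate_effects
  }
  if (config$noise_sd > 0)
    conc <- conc + matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)
  dimnames(conc) <- list(rownames(genotypes$dosage), names(lib)[seq_len(m)])
  structure(list(concentrations = conc, causal_map = et, library = lib,
                 covariates = covariates),
            class = "ground_truth")
}

# Unit-height Lorentzian line shape with FWHM w
lorentzian <- function(d, w) 1 / (1 + (2 * d / w)^2)

#' Render raw NMR spectra from ground-truth concentrations
#'
#' Forward model: intensity at chemical shift x is
#' `sum_m exp(conc_m) * sum_peaks h * L(x - (pos + jitter); peak_width)`
#' plus baseline noise, with `L` a unit-height Lorentzian of FWHM
#' `peak_width` and a per-sample jitter `Normal(0, shift_jitter_sd)`
#' shifting all of that sample's peaks together.
#'
#' @param truth A [simulate_metabolome()] result.
#' @param config The matching [sim_config()].
#' @return A list of class `raw_spectra`: `ppm` (the grid), `intensity`
#'   (matrix, one row per individual-replicate), `individual`, `replicate`
#'   (row index vectors), `jitter`.
#' @export
render_spectra <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  if (config$peak_width <= 0)
    stop("peak_width must be positive", call. = FALSE)
  set_seed_if(config$seed, 3L)
  grid <- seq(config$ppm_range[1L], config$ppm_range[2L],
              by = config$raw_resolution)
  n <- nrow(truth$concentrations)
  m <- ncol(truth$concentrations)
  reps <- config$n_replicates
  amp <- exp(truth$concentrations) # individuals x metabolites
  # flatten the library (first m entries are the rendered metabolites)
  pk_m <- integer(0); pk_pos <- numeric(0); pk_h <- numeric(0)
  for (j in seq_len(m)) {
    pk <- truth$library[[j]]$peaks
    pk_m <- c(pk_m, rep.int(j, nrow(pk)))
    pk_pos <- c(pk_pos, pk$ppm)
    pk_h <- c(pk_h, pk$rel_intensity)
  }
  n_rows <- n * reps
  jitter <- stats::rnorm(n_rows, sd = config$shift_jitter_sd)
  individual <- rep(seq_len(n), each = reps)
  replicate <- rep(seq_len(reps), times = n)
  # metabolite signatures on the grid, then one matrix product; the
  # per-sample jitter shifts a sample's whole noiseless spectrum
  # rigidly, so it is applied afterwards by interpolating along the
  # uniform grid
  G <- length(grid)
  S <- matrix(0, m, G)
  for (q in seq_along(pk_pos)) {
    S[pk_m[q], ] <- S[pk_m[q], ] +
      pk_h[q] * lorentzian(grid - pk_pos[q], config$peak_width)
  }
  intensity <- amp[individual, , drop = FALSE] %*% S
  res <- config$raw_resolution
  for (r in seq_len(n_rows)) {
    if (jitter[r] == 0) next
    s <- jitter[r] / res # evaluate row at grid - jitter... shift by +s
    f <- floor(s); w <- s - f
    idx <- pmin(pmax(seq_len(G) - f, 1L), G)
    idx1 <- pmin(pmax(idx - 1L, 1L), G)
    intensity[r, ] <- (1 - w) * intensity[r, idx] +
      w * intensity[r, idx1]
  }
  if (config$baseline_level != 0 || config$baseline_sd > 0) {
    intensity <- intensity + config$baseline_level +
      matrix(stats::rnorm(length(intensity), sd = config$baseline_sd),
             nrow(intensity))
  }
  structure(list(ppm = grid, intensity = intensity,
                 individual = individual, replicate = replicate,
                 jitter = jitter),
            class = "raw_spectra")
}

#' Extract one replicate spectrum as a (ppm, intensity) table
#'
#' @param rs A [render_spectra()] result.
#' @param individual,replicate Which spectrum to extract.
#' @return Two-column matrix `(ppm, intensity)`.
#' @export
spectrum_table <- function(rs, individual, replicate = 1L) {
  stopifnot(inherits(rs, "raw_spectra"))
  r <- which(rs$individual == individual & rs$replicate == replicate)
  if (length(r) != 1L)
    stop("no such individual/replicate", call. = FALSE)
  cbind(ppm = rs$ppm, intensity = rs$intensity[r, ])
}

# Bin all rendered spectra at once (rows of rs$intensity share the grid).
bin_raw_spectra <- function(rs, spec) {
  edges <- spec$ppm_min + (0:spec$n_bins) * spec$bin_width
  idx <- findInterval(rs$ppm, edges, left.open = FALSE)
  keep <- idx >= 1L & idx <= spec$n_bins
  grp <- idx[keep]
  sums <- rowsum(t(rs$intensity[, keep, drop = FALSE]), grp) # bins x rows
  cnt <- as.vector(rowsum(rep(1, sum(keep)), grp))
  binned <- matrix(NA_real_, nrow(rs$intensity), spec$n_bins)
  binned[, as.integer(rownames(sums))] <- t(sums / cnt)
  colnames(binned) <- sprintf("%.4f", spec$centers)
  binned
}

#' Simulate a complete cohort: genotypes, spectra, feature matrix
#'
#' Runs the full generative chain — genotypes, metabolite concentrations,
#' rendered replicate spectra — then the standard preprocessing: binning,
#' missing-value injection at `missing_rate`, replicate log-averaging,
#' missingness filtering and per-profile Z-score normalization.
#'
#' @param config A [sim_config()].
#' @param bin_width Bin width used for feature construction (default
#'   0.005 ppm).
#' @param normalize Normalization method (default `"zscore"`; `"none"` to
#'   keep log-averaged intensities).
#' @param max_missing Missingness threshold for [filter_matrix()].
#' @param covariates,covariate_effects,library Passed to
#'   [simulate_metabolome()].
#' @return List of class `sim_cohort`: `genotypes`, `truth`, `features`
#'   (the processed [feature_matrix()]), `bin` (the [bin_spec()] used),
#'   `config`.
#' @export
simulate_cohort <- function(config, bin_width = 0.005,
                            normalize = c("zscore", "none"),
                            max_missing = 0.05,
                            covariates = NULL, covariate_effects = NULL,
                            library = NULL) {
  normalize <- match.arg(normalize)
  genotypes <- simulate_genotypes(config)
  truth <- simulate_metabolome(genotypes, config, covariates,
                               covariate_effects, library = library)
  rs <- render_spectra(truth, config)
  spec <- bin_spec(bin_width, config$ppm_range[1L], config$ppm_range[2L])
  binned <- bin_raw_spectra(rs, spec)
  set_seed_if(config$seed, 4L)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(binned)) < config$missing_rate,
                   nrow(binned))
    binned[drop] <- NA_real_
  }
  # log-average replicates per individual
  rows <- rowsum(suppressWarnings(log(ifelse(binned <= 0, NA, binned))),
                 rs$individual, na.rm = TRUE)
  cnts <- rowsum((!is.na(binned) & binned > 0) + 0, rs$individual)
  avg <- rows / cnts
  avg[!is.finite(avg)] <- NA_real_
  fm <- feature_matrix(avg, spec$centers,
                       rownames(genotypes$dosage), scale = "log")
  fm <- filter_matrix(fm, max_missing)
  if (normalize == "zscore") fm <- normalize_profiles(fm, "zscore")
  # genotypes restricted to samples surviving the filter
  keep <- match(fm$sample_ids, rownames(genotypes$dosage))
  genotypes$dosage <- genotypes$dosage[keep, , drop = FALSE]
  genotypes$population <- genotypes$population[keep]
  structure(list(genotypes = genotypes, truth = truth, features = fm,
                 bin = spec, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n  "); print(x$genotypes)
  cat("  "); print(x$features)
  invisible(x)
}
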