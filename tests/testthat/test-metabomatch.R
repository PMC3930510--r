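# Metabomatching: pseudo-spectra, peak-to-bin mapping, correlated-bin
# pruning, chi-squared scoring, library ranking.

flat_ps <- function(ppm, z = rep(0, length(ppm))) {
  pseudo_spectrum(data.frame(snp_id = "rs1", feature = ppm, z = z))
}

test_that("pseudo-spectra reshape association records faithfully", {
  rec <- data.frame(snp_id = "rs1", feature = c(2, 1, 3),
                    z = c(0, qnorm(1 - 0.005), 0))
  ps <- pseudo_spectrum(rec)
  expect_equal(ps$feature_ppm, c(1, 2, 3)) # sorted by ppm
  # p = 0.01 at one feature shows as -log10 p = 2 there, 0 elsewhere
  expect_equal(ps$minus_log10_p, c(2, 0, 0), tolerance = 1e-12)
  expect_error(pseudo_spectrum(data.frame(feature = c(1, 1), z = 0)),
               "duplicate")
  expect_error(pseudo_spectrum(data.frame(snp_id = c("a", "b"),
                                          feature = 1:2, z = 0)),
               "single SNP")
  # genome-wide significance survives p-value underflow
  ps2 <- pseudo_spectrum(data.frame(feature = 1, z = 45))
  expect_gt(ps2$minus_log10_p, 400)
})

test_that("pseudo-spectrum TSV round-trips losslessly", {
  ps <- flat_ps(c(1.0025, 1.0075, 1.0125), c(1.5, -2.5, 0))
  path <- tempfile(fileext = ".tsv")
  write_pseudo_spectrum(ps, path)
  back <- read_pseudo_spectrum(path)
  expect_equal(back$feature_ppm, ps$feature_ppm)
  expect_equal(back$z, ps$z)
  expect_equal(attr(back, "snp_id"), "rs1")
})

test_that("peaks map to the nearest bin center within tolerance", {
  bins <- seq(0.5025, 4.5, by = 0.005)
  # a peak exactly at a bin center maps there
  r1 <- reference_spectrum("m", peak_ppm = bins[100])
  expect_equal(as.integer(map_peaks(r1, bins)), 100L)
  # between two centers: the nearer one; exact midpoint: lower ppm
  r2 <- reference_spectrum("m", peak_ppm = bins[10] + 0.0024)
  expect_equal(as.integer(map_peaks(r2, bins)), 10L)
  rmid <- reference_spectrum("m", peak_ppm = bins[10] + 0.0025)
  expect_equal(as.integer(map_peaks(rmid, bins)), 10L)
  # out-of-tolerance peaks are dropped and counted
  rfar <- reference_spectrum("m", peak_ppm = c(bins[5], 9.9))
  got <- map_peaks(rfar, bins)
  expect_equal(as.integer(got), 5L)
  expect_equal(attr(got, "n_unmatched"), 1L)
  # peaks sharing a bin collapse to one match
  rdup <- reference_spectrum("m", peak_ppm = c(bins[7] - 0.001,
                                               bins[7] + 0.001))
  expect_equal(as.integer(map_peaks(rdup, bins)), 7L)
})

test_that("the fucose peak list lands on its four bins", {
  bins <- seq(0.0025, 9.9975, by = 0.005)
  fucose <- reference_spectrum("fucose", "fucose",
                               c(1.2575, 5.2125, 5.2275, 5.2825))
  got <- bins[map_peaks(fucose, bins)]
  expect_equal(got, c(1.2575, 5.2125, 5.2275, 5.2825))
})

test_that("correlated-bin pruning keeps the strongest independent set", {
  z <- c(3, 5, 1, 2, 4)
  # mutually uncorrelated features: all kept
  expect_equal(prune_correlated(1:5, z, diag(5)), 1:5)
  # two perfectly correlated features: the larger |z| survives
  C <- diag(2); C[1, 2] <- C[2, 1] <- 1
  expect_equal(prune_correlated(1:2, c(2, -3), C), 2L)
  # hand-built 5-feature structure vs the naive greedy oracle
  set.seed(909)
  for (i in 1:30) {
    R <- matrix(runif(25, -1, 1), 5, 5); R <- (R + t(R)) / 2; diag(R) <- 1
    zz <- rnorm(5, sd = 2)
    expect_equal(prune_correlated(1:5, zz, R),
                 oracle_prune(1:5, zz, R))
  }
})

test_that("chi-squared scoring follows the closed form", {
  bins <- seq(1.0025, 1.2, by = 0.005)
  fc <- diag(length(bins))
  # k = 1 with z = 0: score 0, p = 1
  ps0 <- flat_ps(bins)
  r1 <- reference_spectrum("m1", peak_ppm = bins[3])
  s0 <- score_metabolite(ps0, r1, fc)
  expect_equal(s0$score, 0)
  expect_equal(s0$p, 1)
  # k = 2 with z = (2, 2): score 8, p = exp(-4)
  z <- rep(0, length(bins)); z[c(3, 10)] <- 2
  ps2 <- flat_ps(bins, z)
  r2 <- reference_spectrum("m2", peak_ppm = bins[c(3, 10)])
  s2 <- score_metabolite(ps2, r2, fc)
  expect_equal(s2$k, 2L)
  expect_equal(s2$score, 8)
  expect_equal(s2$p, exp(-4))
  # k = 3 with z = (1, 2, 3): score 14, chi2_3 survival, cross-checked
  # by Monte Carlo
  z3 <- rep(0, length(bins)); z3[c(1, 5, 9)] <- 1:3
  s3 <- score_metabolite(flat_ps(bins, z3),
                         reference_spectrum("m3", peak_ppm = bins[c(1, 5, 9)]),
                         fc)
  expect_equal(s3$score, 14)
  expect_equal(s3$p, pchisq(14, 3, lower.tail = FALSE))
  set.seed(14)
  mc <- mean(rchisq(1e6, 3) >= 14)
  expect_lt(abs(s3$p - mc), 4 * sqrt(s3$p / 1e6) + 1e-5)
})

test_that("score is invariant to orderings and grows with evidence", {
  bins <- seq(2.0025, 2.2, by = 0.005)
  set.seed(10)
  z <- rnorm(length(bins))
  fc <- diag(length(bins))
  pk <- bins[c(4, 11, 19)]
  ps <- flat_ps(bins, z)
  s_a <- score_metabolite(ps, reference_spectrum("m", peak_ppm = pk), fc)
  s_b <- score_metabolite(ps, reference_spectrum("m", peak_ppm = rev(pk)),
                          fc)
  expect_equal(s_a[c("k", "score", "p")], s_b[c("k", "score", "p")])
  # adding a peak that maps to a z = 0 feature: score unchanged, k + 1,
  # p strictly larger (monotone in degrees of freedom)
  z2 <- z; z2[30] <- 0
  ps2 <- flat_ps(bins, z2)
  s_plus <- score_metabolite(ps2,
                             reference_spectrum("m", peak_ppm = c(pk, bins[30])),
                             fc)
  expect_equal(s_plus$score, s_a$score)
  expect_equal(s_plus$k, s_a$k + 1L)
  expect_gt(s_plus$p, s_a$p)
})

test_that("two-compound scoring pools, dedups and adds peak sets", {
  bins <- seq(3.0025, 3.2, by = 0.005)
  fc <- diag(length(bins))
  z <- rep(0, length(bins)); z[c(2, 9)] <- 2
  ps <- flat_ps(bins, z)
  m1 <- reference_spectrum("a", peak_ppm = bins[2])
  m2 <- reference_spectrum("b", peak_ppm = bins[9])
  # disjoint single-peak compounds with z = (2, 2): score 8, k = 2
  pair <- score_pair(ps, m1, m2, fc)
  expect_equal(pair$k, 2L)
  expect_equal(pair$score, 8)
  # the pair (m, m) collapses to the single-compound score
  self <- score_pair(ps, m1, m1, fc)
  single <- score_metabolite(ps, m1, fc)
  expect_equal(self$k, single$k)
  expect_equal(self$score, single$score)
  expect_equal(self$p, single$p)
})

test_that("library ranking orders by P with deterministic ties", {
  bins <- seq(1.0025, 1.5, by = 0.005)
  fc <- diag(length(bins))
  z <- rep(0, length(bins)); z[10] <- 5
  ps <- flat_ps(bins, z)
  lib <- list(reference_spectrum("hit", peak_ppm = bins[10]),
              reference_spectrum("miss1", peak_ppm = bins[40]),
              reference_spectrum("miss2", peak_ppm = bins[50]),
              reference_spectrum("nowhere", peak_ppm = 9.5))
  res <- rank_library(ps, lib, fc)
  expect_equal(res$metabolite_id[1], "hit")
  expect_equal(res$rank[1], 1L)
  # equal-score misses tie-break by metabolite id
  rmiss <- res[res$metabolite_id %in% c("miss1", "miss2"), ]
  expect_equal(rmiss$metabolite_id, c("miss1", "miss2"))
  # unscorable entries are listed last with a reason
  expect_equal(res$note[res$metabolite_id == "nowhere"], "unscorable")
  expect_true(is.na(res$rank[res$metabolite_id == "nowhere"]))
  # percentile over the scorable ones
  expect_equal(res$percentile[1], 100 / 3, tolerance = 1e-12)
})

test_that("anchor-mode pair ranking finds a two-metabolite signal", {
  bins <- seq(1.0025, 2.0, by = 0.005)
  fc <- diag(length(bins))
  z <- rep(0, length(bins)); z[c(5, 80)] <- c(4.5, 4.5)
  ps <- flat_ps(bins, z)
  lib <- c(list(reference_spectrum("anchor", peak_ppm = bins[5]),
                reference_spectrum("partner", peak_ppm = bins[80])),
           lapply(1:20, function(i)
             reference_spectrum(sprintf("decoy%02d", i),
                                peak_ppm = bins[100 + i])))
  res <- rank_library(ps, lib, fc, pair_anchor = "anchor")
  expect_equal(res$metabolite_id[1], "anchor+partner")
})

test_that("null metabomatching p-values are near-uniform", {
  # a SNP with no metabolite effect scored against a decoy library on
  # independent features: match P-values behave like uniform draws
  set.seed(77)
  n <- 200
  bs <- bin_spec(0.005, 0.5, 9.5)
  fm <- feature_matrix(matrix(rnorm(n * bs$n_bins), n), bs$centers,
                       scale = "log")
  g <- simulate_genotypes(sim_config(n_individuals = n, n_snps = 4,
                                     seed = 78))
  rec <- associate(fm, g)
  ps <- pseudo_spectrum(rec[rec$snp_id == "snp0002", ])
  fc <- feature_correlation(fm)
  lib <- make_library(sim_config(n_metabolites = 200,
                                 ppm_range = c(0.5, 9.5), seed = 79),
                      n_metabolites = 200)
  res <- rank_library(ps, lib, fc)
  pv <- res$p[res$note == ""]
  expect_gt(length(pv), 150)
  ks <- suppressWarnings(ks.test(pv, "punif"))
  crit_1pct <- 1.63 / sqrt(length(pv))
  expect_lt(unname(ks$statistic), crit_1pct)
})
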