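# Clumping, replication rules, inverse-variance meta-analysis, locus
# grouping.

make_hits <- function(snp, feature, p) {
  data.frame(snp_id = snp, feature = feature, p = p,
             beta = 1, se = 0.1, stringsAsFactors = FALSE)
}

test_that("pair clumping applies both equivalence conditions", {
  ld <- matrix(c(1, 1, 1, 1), 2, 2,
               dimnames = list(c("s1", "s2"), c("s1", "s2")))
  fc <- matrix(c(1, sqrt(0.2), sqrt(0.2), 1), 2, 2,
               dimnames = list(c("1.0000", "2.0000"),
                               c("1.0000", "2.0000")))
  # same SNP (r2 = 1) but feature r2 = 0.2 < 0.4: both retained
  hits <- make_hits(c("s1", "s1"), c(1, 2), c(1e-10, 1e-9))
  out <- clump_pairs(hits, ld, fc)
  expect_equal(nrow(out), 2L)
  # single hit is its own representative
  out1 <- clump_pairs(hits[1, ], ld, fc)
  expect_equal(out1$snp_id, "s1")
  # both conditions met: absorbed
  fc2 <- fc; fc2[1, 2] <- fc2[2, 1] <- sqrt(0.9)
  out2 <- clump_pairs(hits, ld, fc2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$p, 1e-10) # best P wins
  expect_equal(out2$n_absorbed, 1L)
  # missing LD entries are reported by name
  expect_error(clump_pairs(make_hits("zz", 1, 1e-9), ld, fc),
               "missing LD entry.*zz")
})

test_that("greedy clumping matches the brute-force oracle", {
  set.seed(606)
  snps <- sprintf("s%d", 1:6)
  feats <- seq(1, 1.05, by = 0.01)
  fkeys <- sprintf("%.4f", feats)
  for (i in 1:40) {
    # random LD / feature-correlation structures incl. chain topologies
    L <- matrix(runif(36), 6, 6); L <- (L + t(L)) / 2; diag(L) <- 1
    dimnames(L) <- list(snps, snps)
    Fc <- matrix(runif(36, -1, 1), 6, 6); Fc <- (Fc + t(Fc)) / 2
    diag(Fc) <- 1
    dimnames(Fc) <- list(fkeys, fkeys)
    hits <- make_hits(sample(snps, 8, replace = TRUE),
                      sample(feats, 8, replace = TRUE),
                      10^-runif(8, 8, 20))
    got <- clump_pairs(hits, L, Fc)
    want <- oracle_clump(hits, L, Fc)
    expect_equal(got$snp_id, want$snp_id)
    expect_equal(got$feature, want$feature)
    expect_equal(got$p, want$p)
    # no two representatives are still equivalent
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) for (b in (a + 1):nrow(got)) {
        both <- L[got$snp_id[a], got$snp_id[b]] > 0.3 &&
          Fc[sprintf("%.4f", got$feature[a]),
             sprintf("%.4f", got$feature[b])]^2 > 0.4
        expect_false(both)
      }
    }
  }
})

test_that("inverse-variance meta-analysis has the textbook form", {
  # equal effects and SEs: same effect, SE shrunk by sqrt(2)
  a <- data.frame(snp_id = "s", feature = 1, beta = 0.5, se = 0.1,
                  p = 1e-6)
  b <- a
  m <- ivw_meta(a, b)
  expect_equal(m$x_m, 0.5)
  expect_equal(m$se_m, 0.1 / sqrt(2))
  # x = (1, 0), se = (1, 2): x_m = 0.8, se_m = sqrt(0.8)
  m2 <- ivw_meta(data.frame(beta = 1, se = 1),
                 data.frame(beta = 0, se = 2))
  expect_equal(m2$x_m, 0.8)
  expect_equal(m2$se_m, sqrt(0.8))
  orc <- oracle_ivw(c(1, 0), c(1, 2))
  expect_equal(m2$x_m, orc$x_m)
  expect_equal(m2$p_m, orc$p_m)
  # the combined effect lies weakly between the cohort effects,
  # se_m below both cohort SEs
  set.seed(707)
  for (i in 1:50) {
    x <- rnorm(2); s <- rexp(2) + 0.05
    mm <- ivw_meta(data.frame(beta = x[1], se = s[1]),
                   data.frame(beta = x[2], se = s[2]))
    expect_gte(mm$x_m, min(x) - 1e-12)
    expect_lte(mm$x_m, max(x) + 1e-12)
    expect_lte(mm$se_m, min(s))
  }
  expect_error(ivw_meta(data.frame(beta = 1, se = 0),
                        data.frame(beta = 1, se = 1)), "error")
})

test_that("concordant similar effects never lose significance in meta", {
  for (x in c(0.2, 0.5, 1)) for (s in c(0.05, 0.2)) for (f in c(1, 1.3)) {
    a <- data.frame(beta = x, se = s)
    b <- data.frame(beta = x * f, se = s)
    m <- ivw_meta(a, b)
    p_a <- 2 * pnorm(abs(x / s), lower.tail = FALSE)
    p_b <- 2 * pnorm(abs(x * f / s), lower.tail = FALSE)
    expect_lte(m$p_m, max(p_a, p_b) + 1e-15)
  }
})

test_that("allele harmonization flips swapped effect alleles", {
  a <- data.frame(snp_id = "s", feature = 1, beta = 0.5, se = 0.1,
                  p = 1e-6, effect_allele = "A", other_allele = "G")
  b <- a; b$effect_allele <- "G"; b$other_allele <- "A"; b$beta <- -0.5
  m <- ivw_meta(a, b)
  expect_equal(m$x_m, 0.5) # flip makes the effects concordant
  amb <- a; amb$effect_allele <- "A"; amb$other_allele <- "T"
  m2 <- ivw_meta(amb, amb)
  expect_equal(m2$note, "strand_ambiguous")
  bad <- a; bad$effect_allele <- "C"
  expect_error(ivw_meta(a, bad), "harmonized")
})

test_that("replication requires concordance, P and combined thresholds", {
  disc <- data.frame(snp_id = c("s1", "s2", "s3"), feature = c(1, 2, 3),
                     beta = c(0.5, 0.5, 0.5), se = 0.05,
                     p = c(1e-12, 1e-12, 1e-12))
  repl <- data.frame(snp_id = c("s1", "s2"), feature = c(1, 2),
                     beta = c(0.45, -0.45), se = 0.05,
                     p = c(1e-8, 1e-8))
  out <- assess_replication(disc, repl, combined_threshold = 5.7e-10,
                            n_hits = 3)
  # s1 replicates; s2 has a discordant direction regardless of P;
  # s3 is not testable (no matched record)
  expect_equal(out$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(out$testable, c(TRUE, TRUE, FALSE))
  expect_false(out$sign_concordant[2])
})

test_that("replication maps features across grids via an alignment", {
  disc <- data.frame(snp_id = "s1", feature = 1.2025, beta = 0.5,
                     se = 0.05, p = 1e-12)
  repl <- data.frame(snp_id = "s1", feature = 1.2040, beta = 0.48,
                     se = 0.06, p = 1e-9)
  al <- align_features(1.2025, 1.2040, tolerance = 0.005)
  out <- assess_replication(disc, repl, combined_threshold = 5.7e-10,
                            n_hits = 1, alignment = al)
  expect_true(out$replicated)
})

test_that("two-cohort replication separates real from null hits", {
  # simulated truth: a handful of real associations plus null hits;
  # real ones replicate, false replications stay rare
  set.seed(808)
  n1 <- 400; n2 <- 300; n_snps <- 40
  g1 <- toy_genotypes(n1, n_snps, seed = 81)
  g2 <- toy_genotypes(n2, n_snps, seed = 82)
  beta_true <- 0.45
  real <- 1:4 # SNPs with a true effect on matching features
  y1 <- sapply(1:20, function(f)
    if (f <= 4) beta_true * g1[, f] + rnorm(n1) else rnorm(n1))
  y2 <- sapply(1:20, function(f)
    if (f <= 4) beta_true * g2[, f] + rnorm(n2) else rnorm(n2))
  colnames(y1) <- colnames(y2) <- sprintf("%.4f", 1:20)
  r1 <- associate(y1, g1, scale_features = FALSE)
  r2 <- associate(y2, g2, scale_features = FALSE)
  disc <- r1[r1$p < 1e-4, ] # permissive, to get nulls into the set
  out <- assess_replication(disc, r2, combined_threshold = 1e-8,
                            n_hits = nrow(disc))
  key <- paste(out$snp_id, round(as.numeric(out$feature)))
  truth <- paste(sprintf("snp%04d", real), real)
  expect_gte(sum(out$replicated & key %in% truth), 3)
  expect_equal(sum(out$replicated & !(key %in% truth)), 0)
})

test_that("locus grouping is single linkage within the window", {
  rec <- data.frame(snp_id = c("a", "b"), chr = 1,
                    pos = c(1e6, 3.2e6), feature = c(1, 1),
                    p_m = c(1e-10, 1e-12))
  out <- group_loci(rec)
  expect_equal(nrow(out$loci), 2L) # 2.2 Mb apart: two loci
  # chain at 1, 900001, 1800001: one locus by single linkage
  rec2 <- data.frame(snp_id = c("a", "b", "c"), chr = 2,
                     pos = c(1, 900001, 1800001), feature = c(1, 1, 2),
                     p_m = c(1e-10, 1e-8, 1e-14))
  out2 <- group_loci(rec2)
  expect_equal(nrow(out2$loci), 1L)
  expect_equal(out2$loci$lead_snp, "c") # smallest meta P leads
  expect_equal(out2$loci$features, "1.0000,2.0000")
  # lead ties break by position
  rec3 <- data.frame(snp_id = c("x", "y"), chr = 1, pos = c(200, 100),
                     feature = 1, p_m = c(1e-9, 1e-9))
  expect_equal(group_loci(rec3)$loci$lead_snp, "y")
})

test_that("meta-analysis in admixed LD structures narrows the signal", {
  # cohort A: long LD blocks around the causal SNP; cohort B: short.
  # Meta-analysis keeps only SNPs linked to the causal SNP in BOTH
  # cohorts, so the meta lead falls inside cohort B's (short) block.
  causal <- 10L
  contained <- sapply(1:10, function(s) {
    cfgA <- sim_config(n_individuals = 500, n_snps = 30, ld_rho = 0.97,
                       maf_range = c(0.2, 0.5), seed = 1000 + s)
    cfgB <- sim_config(n_individuals = 500, n_snps = 30, ld_rho = 0.5,
                       maf_range = c(0.2, 0.5), seed = 2000 + s)
    gA <- simulate_genotypes(cfgA)
    gB <- simulate_genotypes(cfgB)
    set.seed(3000 + s)
    yA <- 0.45 * gA$dosage[, causal] + rnorm(500)
    yB <- 0.45 * gB$dosage[, causal] + rnorm(500)
    rA <- associate(yA, gA, scale_features = FALSE)
    rB <- associate(yB, gB, scale_features = FALSE)
    m <- ivw_meta(rA, rB)
    lead <- which.min(m$p_m)
    # cohort B's block around the causal SNP: r2 > 0.3 with it
    blockB <- which(ld_matrix(gB)[causal, ] > 0.3)
    lead %in% blockB
  })
  expect_gte(mean(contained), 0.8)
})
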