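# Detector behaviour is checked against simulated data with known error
# mechanisms; Monte-Carlo replicate counts are kept modest here (the
# acceptance suite runs the full calibration).

test_that("expected genotype counts recover Hardy-Weinberg arithmetic", {
  # 50 individuals all heterozygous (A,B): expected ~half homozygotes,
  # observed none -> strong heterozygote excess
  a <- rep(100L, 50); b <- rep(102L, 50)
  out <- expected_genotype_counts(a, b, n_reps = 400, seed = 1)
  expect_equal(sum(out$obs_hom), 0)
  expect_gt(sum(out$exp_hom), 0.4 * 50)
  expect_lt(sum(out$exp_hom), 0.6 * 50)
  # and the all-heterozygote sample is never flagged for null alleles
  res <- detect_null_alleles(a, b, n_reps = 400, seed = 1)
  expect_false(res$flag)
})

test_that("an HWE-proportioned sample sits inside the Monte-Carlo bounds", {
  set.seed(42)
  p <- c(0.4, 0.3, 0.2, 0.1)
  alle <- c(100L, 102L, 104L, 106L)
  g1 <- sample(alle, 400, TRUE, p)
  g2 <- sample(alle, 400, TRUE, p)
  out <- expected_genotype_counts(pmin(g1, g2), pmax(g1, g2),
                                  n_reps = 400, seed = 2)
  expect_true(all(out$obs_hom >= out$hom_lower & out$obs_hom <= out$hom_upper))
})

test_that("screening results are deterministic given the seed", {
  cfg <- one_pop_config(5, n_families = 10, null_freq = 0.15)
  x <- apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
  g <- x$genotypes[x$genotypes$locus == "L01", ]
  r1 <- detect_null_alleles(g$allele_a, g$allele_b, n_reps = 200, seed = 9)
  r2 <- detect_null_alleles(g$allele_a, g$allele_b, n_reps = 200, seed = 9)
  expect_identical(r1, r2)
  e1 <- expected_genotype_counts(g$allele_a, g$allele_b, n_reps = 200, seed = 9)
  e2 <- expected_genotype_counts(g$allele_a, g$allele_b, n_reps = 200, seed = 9)
  expect_identical(e1, e2)
})

test_that("a monomorphic locus is reported as not screenable", {
  a <- rep(100L, 30)
  res <- detect_null_alleles(a, a, n_reps = 100, seed = 1)
  expect_true(is.na(res$flag))
  expect_match(res$note, "not screenable")
})

test_that("stuttering is detected when one-repeat heterozygotes are rescored", {
  flags <- vapply(1:8, function(i) {
    cfg <- one_pop_config(1700 + i, n_families = 40, n_off = 8, n_loci = 1,
                          n_alleles = 5, s = 0,
                          allele_freq_concentration = 10, stutter_rate = 0.4,
                          generations = 5)
    x <- apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
    g <- x$genotypes[x$genotypes$locus == "L01", ]
    detect_stuttering(g$allele_a, g$allele_b, 2, n_reps = 300, seed = i)$flag
  }, TRUE)
  expect_gte(mean(flags), 0.5)
})

test_that("loci with no one-repeat allele pairs are vacuously unflagged", {
  set.seed(1)
  alle <- c(100L, 110L, 120L)  # all pairs >= 5 repeats apart
  g1 <- sample(alle, 100, TRUE); g2 <- sample(alle, 100, TRUE)
  res <- detect_stuttering(pmin(g1, g2), pmax(g1, g2), 2,
                           n_reps = 200, seed = 3)
  expect_false(res$flag)
  expect_match(res$note, "no one-repeat")
})

test_that("large-allele dropout is detected and uniform excess is not", {
  flags <- vapply(1:8, function(i) {
    cfg <- one_pop_config(1800 + i, n_families = 40, n_off = 6, n_loci = 1,
                          n_alleles = 8, s = 0,
                          allele_freq_concentration = 20, dropout_rate = 0.7,
                          generations = 5)
    x <- apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
    g <- x$genotypes[x$genotypes$locus == "L01", ]
    detect_large_allele_dropout(g$allele_a, g$allele_b,
                                n_reps = 300, seed = i)$flag
  }, TRUE)
  expect_gte(mean(flags), 0.5)

  # constructed fixture: homozygote excess spread uniformly across classes
  # (the null-allele signature) must not trigger the dropout test
  alle <- seq(100L, 114L, 2L)
  hom <- rep(alle, each = 12)
  pairs <- t(utils::combn(alle, 2))
  het_i <- pairs[rep(seq_len(nrow(pairs)), 4), ]
  a <- c(hom, het_i[, 1]); b <- c(hom, het_i[, 2])
  res <- detect_large_allele_dropout(a, b, n_reps = 400, seed = 5)
  expect_false(res$flag)
})

test_that("null-frequency estimators match closed forms and recover truth", {
  # Ho = He -> no excess -> 0
  set.seed(8)
  alle <- c(100L, 102L)
  g1 <- sample(alle, 500, TRUE); g2 <- sample(alle, 500, TRUE)
  r <- estimate_null_frequency(pmin(g1, g2), pmax(g1, g2), "brookfield1")
  expect_lt(r$estimate, 0.03)

  # exact constructed oracle for the closed form (He - Ho)/(1 + He):
  # 100 individuals, five alleles at 40 copies each (He = 0.8), 70
  # homozygotes (Ho = 0.3) -> r = 0.5 / 1.8
  alle5 <- seq(100L, 108L, 2L)
  hom <- rep(alle5, each = 14)
  het1 <- rep(alle5, 6)
  het2 <- rep(alle5[c(2:5, 1)], 6)
  a <- c(hom, pmin(het1, het2)); b <- c(hom, pmax(het1, het2))
  r <- estimate_null_frequency(a, b, "brookfield1")
  expect_equal(r$He, 0.8)
  expect_equal(r$Ho, 0.3)
  expect_equal(r$estimate, 0.5 / 1.8)
  # chakraborty on the same sample: (He - Ho)/(He + Ho)
  expect_equal(estimate_null_frequency(a, b, "chakraborty")$estimate,
               0.5 / 1.1)

  # simulated null allele at 0.15, n = 300: oosterhout recovery (mean of 20)
  est <- vapply(1:20, function(i) {
    cfg <- one_pop_config(1200 + i, n_families = 50, n_off = 6, n_loci = 1,
                          n_alleles = 8, s = 0, null_freq = 0.15)
    x <- apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
    g <- x$genotypes[x$genotypes$locus == "L01", ]
    estimate_null_frequency(g$allele_a, g$allele_b, "oosterhout")$estimate
  }, 0)
  expect_lt(abs(mean(est) - 0.15), 0.05)
})

test_that("null-frequency estimators are monotone in homozygote excess", {
  # same allele pool, increasing homozygote fraction
  alle <- seq(100L, 110L, 2L)
  make <- function(n_hom) {
    hom <- rep(alle, length.out = n_hom)
    n_het <- 240 - n_hom
    h1 <- rep(alle, length.out = n_het)
    h2 <- rep(rev(alle), length.out = n_het)
    swap <- h1 == h2
    h2[swap] <- alle[(match(h2[swap], alle) %% length(alle)) + 1L]
    list(a = c(hom, pmin(h1, h2)), b = c(hom, pmax(h1, h2)))
  }
  for (m in c("oosterhout", "brookfield1", "chakraborty")) {
    ests <- vapply(c(80, 120, 160, 200), function(nh) {
      g <- make(nh)
      estimate_null_frequency(g$a, g$b, m)$estimate
    }, 0)
    expect_true(all(diff(ests) >= -1e-9), info = m)
  }
})

test_that("oosterhout and brookfield1 agree on well-behaved null simulations", {
  diffs <- vapply(1:10, function(i) {
    cfg <- one_pop_config(2600 + i, n_families = 60, n_off = 6, n_loci = 1,
                          n_alleles = 8, s = 0,
                          allele_freq_concentration = 20, null_freq = 0.1,
                          generations = 5)
    x <- apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
    g <- x$genotypes[x$genotypes$locus == "L01", ]
    oo <- estimate_null_frequency(g$allele_a, g$allele_b, "oosterhout")$estimate
    bf <- estimate_null_frequency(g$allele_a, g$allele_b, "brookfield1")$estimate
    oo - bf
  }, 0)
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("the screening wrapper reports one row per population and locus", {
  cfg <- simulation_config(n_populations = 2, families_per_population = 8,
                           offspring_range = c(5, 5), n_loci = 3,
                           alleles_per_locus = 6, seed = 77)
  x <- simulate_progeny_arrays(cfg)
  sc <- screen_genotyping_errors(x, n_reps = 100, seed = 4)
  expect_equal(nrow(sc), 6)
  expect_setequal(names(sc),
                  c("population", "locus", "n", "null_flag", "null_p",
                    "null_freq_estimate", "stutter_flag", "stutter_p",
                    "dropout_flag", "dropout_p"))
  sc2 <- screen_genotyping_errors(x, n_reps = 100, seed = 4)
  expect_identical(sc, sc2)
})
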