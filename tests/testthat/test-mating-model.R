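test_that("selfing transition probabilities are Mendelian", {
  expect_equal(self_transition_prob(c(100, 102), c(100, 100)), 0.25)
  expect_equal(self_transition_prob(c(100, 102), c(100, 102)), 0.5)
  expect_equal(self_transition_prob(c(100, 102), c(102, 102)), 0.25)
  expect_equal(self_transition_prob(c(100, 100), c(100, 100)), 1)
  expect_equal(self_transition_prob(c(100, 100), c(100, 102)), 0)
})

test_that("outcross transition probabilities combine maternal gamete and pollen", {
  p <- setNames(c(0.3, 0.5, 0.2), c(100, 102, 104))
  expect_equal(outcross_transition_prob(c(100, 102), c(100, 100), p),
               0.5 * 0.3)
  expect_equal(outcross_transition_prob(c(100, 100), c(100, 104), p), 0.2)
  expect_equal(outcross_transition_prob(c(100, 100), c(102, 104), p), 0)
})

test_that("transition and phenotype distributions sum to 1 (exhaustive, <=4 alleles)", {
  set.seed(123)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    alle <- sort(sample(seq(100L, 140L, 2L), k))
    p <- as.numeric(rdirichlet_test(k))
    names(p) <- alle
    mother <- sort(sample(c(alle, if (rep %% 2) -1L), 2, replace = TRUE))
    if (all(mother == -1L)) mother[2] <- alle[1]
    nf <- if (rep %% 2) runif(1, 0.05, 0.3) else 0
    if (any(mother == -1L) && nf == 0) nf <- 0.1
    t <- runif(1, 0, 1)
    # genotype-level: selfing and outcross each sum to 1 over all pairs
    pairs <- expand.grid(a = c(alle, -1L), b = c(alle, -1L))
    pairs <- pairs[pairs$a <= pairs$b, ]
    q <- c(p * (1 - nf), setNames(nf, -1))
    s_tot <- sum(apply(pairs, 1, function(g) {
      self_transition_prob(mother, as.integer(g))
    }))
    o_tot <- sum(apply(pairs, 1, function(g) {
      outcross_transition_prob(mother, as.integer(g), q)
    }))
    expect_equal(s_tot, 1, tolerance = 1e-12)
    expect_equal(o_tot, 1, tolerance = 1e-12)
    # phenotype level: sum over observable phenotypes is 1 (the untyped
    # phenotype only has positive probability when a null segregates; at
    # null-free loci it is missing data, likelihood 1 by convention, and is
    # excluded from the support)
    phens <- matearray:::enumerate_phenotypes(alle)
    if (nf == 0) phens <- phens[-length(phens)]
    tot <- sum(vapply(phens, phenotype_likelihood, 0,
                      mother = mother, t = t, pollen_freqs = p,
                      null_freq = nf))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("null masking gives apparent homozygotes positive likelihood via the null path", {
  p <- setNames(c(0.6, 0.4), c(100, 104))
  # mother (A, null), offspring observed (B,B): only true (B, null) works
  lik <- phenotype_likelihood(c(104, 104), c(-1, 100), t = 1, p,
                              null_freq = 0.2)
  expect_equal(lik, 0.5 * 0.4 * (1 - 0.2))
  # degenerate masking: null_freq = 0 equals the literal mixture
  mother <- c(100, 104)
  obs <- c(100, 104)
  t <- 0.7
  expect_equal(
    phenotype_likelihood(obs, mother, t, p, 0),
    t * outcross_transition_prob(mother, obs, p) +
      (1 - t) * self_transition_prob(mother, obs))
})

test_that("equilibrium outcrossing follows (1-F)/(1+F) and flags t > 1", {
  expect_equal(equilibrium_outcrossing(0)$t, 1)
  expect_equal(equilibrium_outcrossing(1 / 3)$t, 0.5)
  res <- equilibrium_outcrossing(-0.2)
  expect_equal(res$t, 1.5)
  expect_true(res$flagged)
  expect_error(equilibrium_outcrossing(-1), "F_is")
})

test_that("derived quantities follow their definitions", {
  d <- derived_quantities(c(t_m = 0.843, t_s = 0.672, r_p_m = 0.25,
                            r_p_s = 0.3))
  v <- setNames(d$value, d$term)
  expect_equal(unname(v["alpha_m"]), 0.157)
  expect_equal(unname(v["tm_minus_ts"]), 0.843 - 0.672)
  expect_equal(unname(v["N_ep"]), 4)
  expect_equal(unname(v["rps_minus_rpm"]), 0.05)
  # r_p_m <= 0 -> N_ep missing
  d2 <- derived_quantities(c(t_m = 1.194, t_s = 0.897, r_p_m = -0.1,
                             r_p_s = 0))
  expect_true(is.na(d2$value[d2$term == "N_ep"]))
  expect_equal(d2$value[d2$term == "tm_minus_ts"], 1.194 - 0.897)
})

test_that("maternal genotype posterior behaves at its anchors", {
  x <- toy_dataset()
  # recorded unambiguous heterozygous mother -> point mass
  post <- infer_maternal_genotypes(x, "P1", "F1")
  l1 <- post[post$locus == "L1", ]
  expect_equal(nrow(l1), 1)
  expect_equal(l1$posterior, 1)
  expect_equal(c(l1$allele_a, l1$allele_b), c(100, 102))

  # unknown mother, one untyped offspring, F = 0 -> posterior equals the
  # HWE prior over genotypes
  g <- tibble::tibble(
    population = "P1", family = "F9",
    individual = rep(c("F9-M", "F9-O1"), each = 1),
    role = c("mother", "offspring"),
    locus = "L1",
    allele_a = c(0L, 0L), allele_b = c(0L, 0L))
  loci <- locus_table("L1", alleles = list(c(100L, 102L)))
  xx <- progeny_data(g, loci)
  of <- list(L1 = setNames(c(0.7, 0.3), c(100, 102)))
  post <- infer_maternal_genotypes(xx, family = "F9", F = 0,
                                   ovule_freqs = of, pollen_freqs = of)
  expect_equal(post$posterior[post$allele_a == 100 & post$allele_b == 100],
               0.49, tolerance = 1e-6)
  expect_equal(post$posterior[post$allele_a == 100 & post$allele_b == 102],
               0.42, tolerance = 1e-6)
})

test_that("maternal genotypes are recovered from progeny when unrecorded", {
  # 200 families of 6 offspring at a 4-allele locus, mixed mating with
  # s = 0.3 (selfed offspring are directly informative about the mother);
  # the posterior uses the generating frequencies and outcrossing rate
  hits <- 0L; total <- 0L
  for (i in 1:4) {
    cfg <- one_pop_config(4000 + i, n_families = 50, n_off = 6, n_loci = 1,
                          n_alleles = 4, s = 0.3,
                          allele_freq_concentration = 5)
    x <- simulate_progeny_arrays(cfg)
    fr <- simulate_population_frequencies(cfg)
    pfl <- list(L01 = setNames(fr$freq, fr$allele))
    g <- x$genotypes
    truth <- g[g$role == "mother", ]
    g2 <- g
    g2$allele_a[g2$role == "mother"] <- 0L
    g2$allele_b[g2$role == "mother"] <- 0L
    x2 <- progeny_data(g2, x$loci, x$populations)
    for (f in unique(g$family)) {
      post <- infer_maternal_genotypes(x2, "pop01", f, t = 0.7,
                                       ovule_freqs = pfl, pollen_freqs = pfl)
      mode_i <- which.max(post$posterior)
      tr <- truth[truth$family == f, ]
      total <- total + 1L
      if (post$allele_a[mode_i] == tr$allele_a &&
          post$allele_b[mode_i] == tr$allele_b) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("fully detectable outcrossing drives t_m to 1", {
  # pollen alleles disjoint from maternal alleles: every offspring carries a
  # non-maternal allele, so outcrossing is certain
  set.seed(99)
  mothers <- list(c(100L, 102L), c(100L, 100L), c(102L, 102L), c(100L, 102L))
  pollen_alle <- c(110L, 112L)
  rows <- list()
  for (f in seq_along(mothers)) {
    fam <- paste0("F", f)
    rows[[length(rows) + 1]] <- tibble::tibble(
      population = "P1", family = fam, individual = paste0(fam, "-M"),
      role = "mother", locus = "L1",
      allele_a = mothers[[f]][1], allele_b = mothers[[f]][2])
    for (o in 1:6) {
      ma <- sample(mothers[[f]], 1); pa <- sample(pollen_alle, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        population = "P1", family = fam,
        individual = sprintf("%s-O%d", fam, o), role = "offspring",
        locus = "L1", allele_a = min(ma, pa), allele_b = max(ma, pa))
    }
  }
  x <- progeny_data(dplyr::bind_rows(rows))
  fit <- fit_mating_system(x, options = em_options(constrain_t_to_unit = TRUE))
  expect_gte(fit_terms(fit)[["t_m"]], 0.99)
})

test_that("the EM maximizer of t matches a dense grid search of the likelihood", {
  # 2 families, 1 locus, 2 alleles; frequencies frozen so the exact
  # likelihood is a function of t alone
  for (seed in c(1, 2, 3)) {
    cfg <- one_pop_config(seed, n_families = 2, n_off = 8, n_loci = 1,
                          n_alleles = 2, s = 0.4,
                          allele_freq_concentration = 5)
    x <- simulate_progeny_arrays(cfg)
    fit <- fit_mating_system(x, options = em_options(update_freqs = FALSE,
                                                     update_F = FALSE))
    pf <- fit$pollen_freqs[["L01"]]
    g <- x$genotypes
    moms <- g[g$role == "mother", ]
    offs <- g[g$role == "offspring", ]
    loglik <- function(t) {
      sum(log(vapply(seq_len(nrow(offs)), function(i) {
        m <- moms[moms$family == offs$family[i], ]
        phenotype_likelihood(c(offs$allele_a[i], offs$allele_b[i]),
                             c(m$allele_a, m$allele_b), t, pf, 0)
      }, 0)))
    }
    grid <- seq(0, 2, by = 1e-3)
    vals <- suppressWarnings(vapply(grid, loglik, 0))
    fin <- is.finite(vals)
    t_grid <- grid[which.max(vals)]
    t_fit <- fit_terms(fit)[["t_m"]]
    if (diff(range(vals[fin])) > 1e-6) {
      expect_lt(abs(t_fit - t_grid), 2e-3)
    } else {
      # flat likelihood: t is unidentified and any maximizer is exact
      expect_equal(suppressWarnings(loglik(t_fit)), max(vals[fin]),
                   tolerance = 1e-8)
    }
  }
})

test_that("the profile extension reaches MLEs above 1 unless constrained", {
  # mother (A,B); offspring dominated by non-maternal allele C with a few
  # selfing-compatible heterozygotes: the exact MLE of t exceeds 1
  rows <- list()
  for (f in 1:2) {
    fam <- paste0("F", f)
    rows[[length(rows) + 1]] <- tibble::tibble(
      population = "P1", family = fam, individual = paste0(fam, "-M"),
      role = "mother", locus = "L1", allele_a = 100L, allele_b = 102L)
    offs <- c(rep(list(c(100L, 120L)), 9), list(c(100L, 102L)))
    for (o in seq_along(offs)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        population = "P1", family = fam,
        individual = sprintf("%s-O%d", fam, o), role = "offspring",
        locus = "L1", allele_a = offs[[o]][1], allele_b = offs[[o]][2])
    }
  }
  x <- progeny_data(dplyr::bind_rows(rows))
  free <- fit_mating_system(x, options = em_options(update_freqs = FALSE,
                                                    update_F = FALSE))
  expect_gt(fit_terms(free)[["t_m"]], 1)
  boxed <- fit_mating_system(x, options = em_options(
    update_freqs = FALSE, update_F = FALSE, constrain_t_to_unit = TRUE))
  expect_lte(fit_terms(boxed)[["t_m"]], 1)
})

test_that("the EM log composite likelihood is non-decreasing", {
  for (i in 1:5) {
    cfg <- one_pop_config(5000 + i, n_families = 8, n_off = 5, n_loci = 3,
                          n_alleles = 5, s = runif(1, 0, 0.4))
    fit <- fit_mating_system(simulate_progeny_arrays(cfg))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("paternity correlation hits its boundaries", {
  # one father per family
  cfg <- one_pop_config(11, n_families = 30, n_off = 8, n_loci = 6,
                        n_alleles = 8, s = 0, r_p = 1)
  fit <- fit_mating_system(simulate_progeny_arrays(cfg))
  expect_gte(fit_terms(fit)[["r_p_m"]], 0.9)
})

test_that("selfing correlations hit their anchors", {
  # families all-selfed or all-outcrossed: r_s near its upper bound
  cfg <- one_pop_config(21, n_families = 30, n_off = 8, n_loci = 6,
                        n_alleles = 8, s = 0.5, r_s = 1)
  fit <- fit_mating_system(simulate_progeny_arrays(cfg))
  expect_gte(fit_terms(fit)[["r_s"]], 0.8)

  # identical per-locus selfing posteriors -> r_loci = 1
  W <- matrix(rep(c(0.9, 0.1, 0.5, 0.2), 3), ncol = 3)
  expect_equal(matearray:::r_loci_from_posteriors(W), 1)

  # t_m at/above 1 leaves s = 0: r_s undefined
  cfg <- one_pop_config(31, n_families = 10, n_off = 5, n_loci = 4,
                        n_alleles = 6, s = 0)
  fit0 <- fit_mating_system(simulate_progeny_arrays(cfg))
  if (fit_terms(fit0)[["t_m"]] >= 1 - 1e-6) {
    expect_true(is.na(fit_terms(fit0)[["r_s"]]))
  }
})

test_that("bootstrap standard errors behave and are reproducible", {
  cfg <- one_pop_config(41, n_families = 12, n_off = 5, n_loci = 3,
                        n_alleles = 5, s = 0.2)
  x <- simulate_progeny_arrays(cfg)
  # constant estimator -> SE 0
  b0 <- bootstrap_se(x, function(d) c(k = 1), B = 20, seed = 3)
  expect_equal(unname(b0$se), 0)
  # binomial proportion: SE matches sqrt(p(1-p)/n) within 15%
  est <- function(d) {
    fams <- unique(d$genotypes$family)
    first <- vapply(fams, function(f) {
      gi <- d$genotypes[d$genotypes$family == f &
                          d$genotypes$role == "offspring" &
                          d$genotypes$locus == "L01", ]
      gi$allele_a[1] == gi$allele_b[1]
    }, TRUE)
    c(p = mean(first))
  }
  b1 <- bootstrap_se(x, est, B = 400, seed = 5)
  p_hat <- est(x)[["p"]]
  analytic <- sqrt(p_hat * (1 - p_hat) / 12)
  expect_lt(abs(b1$se[["p"]] - analytic) / analytic, 0.15)
  # determinism
  b2 <- bootstrap_se(x, est, B = 50, seed = 9)
  b3 <- bootstrap_se(x, est, B = 50, seed = 9)
  expect_identical(b2$se, b3$se)
  # integrated mating-fit bootstrap is deterministic too
  f1 <- fit_mating_system(x, n_bootstrap = 10, seed = 2)
  f2 <- fit_mating_system(x, n_bootstrap = 10, seed = 2)
  expect_equal(f1$estimates$se, f2$estimates$se)
  expect_true(all(f1$estimates$se >= 0, na.rm = TRUE))
})

test_that("tidy, glance and autoplot expose the fit", {
  cfg <- one_pop_config(51, n_families = 8, n_off = 5, n_loci = 3,
                        n_alleles = 5, s = 0.2)
  fit <- fit_mating_system(simulate_progeny_arrays(cfg))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("population", "term", "estimate", "se"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
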