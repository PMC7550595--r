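freq_tbl <- function(...) {
  # build a frequency table from named per-population allele freq vectors
  args <- list(...)
  n <- args$n %||% 50
  args$n <- NULL
  purrr::imap_dfr(args, function(p, pop) {
    tibble::tibble(population = pop, locus = "L1",
                   allele = as.integer(names(p)), freq = as.numeric(p),
                   n = n)
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("allele frequencies count correctly and rescale for null classes", {
  g <- tibble::tibble(
    population = "P1", family = rep(c("F1", "F2"), each = 5),
    individual = paste0("I", 1:10), role = "offspring", locus = "L1",
    allele_a = c(rep(100L, 6), rep(100L, 4)),
    allele_b = c(rep(100L, 6), rep(102L, 4)))
  x <- progeny_data(g)
  f <- allele_frequencies(x)
  expect_equal(f$freq[f$allele == 100], 0.8)
  expect_equal(f$freq[f$allele == 102], 0.2)
  expect_equal(unique(f$n), 10)

  ne <- tibble::tibble(population = "P1", locus = "L1",
                       null_freq_estimate = 0.2)
  f2 <- allele_frequencies(x, ne)
  expect_equal(sum(f2$freq[f2$allele > 0]), 0.8)
  expect_equal(f2$freq[f2$allele == -1], 0.2)
  expect_equal(sum(f2$freq), 1)
})

test_that("heterozygosities match closed forms", {
  f <- freq_tbl(P1 = c(`100` = 0.5, `102` = 0.5))
  g <- tibble::tibble(
    population = "P1", family = "F1", individual = paste0("I", 1:4),
    role = "offspring", locus = "L1",
    allele_a = c(100L, 100L, 100L, 102L), allele_b = c(102L, 102L, 100L, 102L))
  x <- progeny_data(g)
  h <- heterozygosities(x, f)
  expect_equal(h$by_locus$He, 0.5)
  expect_equal(h$by_locus$Ho, 0.5)
  f1 <- freq_tbl(P1 = c(`100` = 1))
  expect_equal(heterozygosities(x, f1)$by_locus$He, 0)
})

test_that("the single-locus estimator matches hand evaluation", {
  # identical frequencies -> F_st = 0, chi2 = 0, p = 1
  f0 <- freq_tbl(P1 = c(`100` = 0.6, `102` = 0.4),
                 P2 = c(`100` = 0.6, `102` = 0.4))
  r0 <- fst_single_locus(f0, "L1")
  expect_equal(r0$fst, 0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # two populations fixed for different alleles, equal n -> 2.0 under the
  # (r - 1) normalisation
  f1 <- freq_tbl(P1 = c(`100` = 1, `102` = 0), P2 = c(`100` = 0, `102` = 1))
  r1 <- fst_single_locus(f1, "L1")
  expect_equal(r1$fst, 2)
  expect_equal(r1$chi2, (2 - 1) * 50 * 2)
  expect_equal(r1$df, 1)

  # hand-evaluated intermediate case: p = (0.8, 0.2) vs (0.4, 0.6), n = (30, 60)
  f2 <- freq_tbl(P1 = c(`100` = 0.8, `102` = 0.2),
                 P2 = c(`100` = 0.4, `102` = 0.6))
  f2$n <- ifelse(f2$population == "P1", 30, 60)
  pbar <- c(0.6, 0.4)
  num <- (30 * ((0.8 - 0.6)^2 + (0.2 - 0.4)^2) +
            60 * ((0.4 - 0.6)^2 + (0.6 - 0.4)^2)) / ((2 - 1) * 45)
  den <- sum(pbar * (1 - pbar))
  r2 <- fst_single_locus(f2, "L1")
  expect_equal(r2$fst, num / den)
  expect_equal(r2$p, pchisq(45 * r2$fst, 1, lower.tail = FALSE))

  # monomorphic everywhere -> undefined
  fm <- freq_tbl(P1 = c(`100` = 1), P2 = c(`100` = 1))
  expect_true(is.na(fst_single_locus(fm, "L1")$fst))
})

test_that("estimators are invariant to allele relabeling and sample-size scaling", {
  f <- freq_tbl(P1 = c(`100` = 0.7, `104` = 0.2, `108` = 0.1),
                P2 = c(`100` = 0.3, `104` = 0.5, `108` = 0.2))
  base <- fst_single_locus(f, "L1")$fst
  f_relab <- f
  f_relab$allele <- rep(c(300L, 210L, 112L), 2)
  expect_equal(fst_single_locus(f_relab, "L1")$fst, base)
  f_scaled <- f
  f_scaled$n <- f$n * 7
  expect_equal(fst_single_locus(f_scaled, "L1")$fst, base)
})

test_that("multilocus F_st is the ratio of summed components", {
  f <- freq_tbl(P1 = c(`100` = 0.7, `102` = 0.3),
                P2 = c(`100` = 0.2, `102` = 0.8))
  # single-locus dataset: multilocus equals single locus
  expect_equal(fst_multilocus(f)$fst, fst_single_locus(f, "L1")$fst)
  # two loci: equals ratio of summed numerators/denominators (hand check)
  f2 <- f
  f2$locus <- "L2"
  f2$freq <- rev(f2$freq)
  both <- dplyr::bind_rows(f, f2)
  c1 <- matearray:::fst_components(
    matearray:::freq_matrix(both, "L1")$P, c(50, 50))
  c2 <- matearray:::fst_components(
    matearray:::freq_matrix(both, "L2")$P, c(50, 50))
  expect_equal(fst_multilocus(both)$fst,
               (c1$num + c2$num) / (c1$den + c2$den))
  # identical populations -> 0
  fid <- freq_tbl(P1 = c(`100` = 0.5, `102` = 0.5),
                  P2 = c(`100` = 0.5, `102` = 0.5))
  expect_equal(fst_multilocus(fid)$fst, 0)
})

test_that("pairwise F_st is consistent with per-pair multilocus calls", {
  cfg <- simulation_config(n_populations = 3, families_per_population = 5,
                           offspring_range = c(4, 4), n_loci = 4,
                           alleles_per_locus = 5, m = 0.01,
                           generations = 60, N_e = 50, seed = 13)
  f <- simulate_population_frequencies(cfg)
  pw <- pairwise_fst(f)
  expect_equal(nrow(pw), 3)
  for (i in seq_len(3)) {
    sub <- f[f$population %in% c(pw$pop1[i], pw$pop2[i]), ]
    expect_equal(pw$fst[i], fst_multilocus(sub)$fst)
  }
  # duplicated population -> 0
  dup <- dplyr::bind_rows(
    f[f$population == "pop01", ],
    dplyr::mutate(f[f$population == "pop01", ], population = "copy"))
  expect_equal(pairwise_fst(dup)$fst, 0)
})

test_that("migration reduces differentiation in the island model", {
  mean_fst <- vapply(c(0.01, 0.1), function(m) {
    vals <- vapply(1:5, function(i) {
      cfg <- simulation_config(n_populations = 4,
                               families_per_population = 5,
                               offspring_range = c(4, 4), n_loci = 6,
                               alleles_per_locus = 6,
                               migration_model = "island", m = m,
                               generations = 50, N_e = 50, seed = 6000 + i)
      mean(pairwise_fst(simulate_population_frequencies(cfg))$fst,
           na.rm = TRUE)
    }, 0)
    mean(vals)
  }, 0)
  expect_gt(mean_fst[1], mean_fst[2])
})

test_that("great-circle distances follow the haversine closed form", {
  expect_equal(geographic_distance(10, 20, 10, 20), 0)
  # one degree of longitude at the equator
  expect_equal(geographic_distance(0, 0, 0, 1), 111.1949, tolerance = 1e-4)
  # closed-form check for the two outermost study populations
  hav <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
    to <- pi / 180
    a <- sin((lat2 - lat1) * to / 2)^2 +
      cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
    2 * R * asin(sqrt(a))
  }
  p <- toona_populations()
  d1 <- geographic_distance(p$latitude[1], p$longitude[1],
                            p$latitude[6], p$longitude[6])
  expect_equal(d1, hav(p$latitude[1], p$longitude[1],
                       p$latitude[6], p$longitude[6]), tolerance = 1e-6)
  expect_gt(d1, 1500)  # Baoshan to Nanping spans ~19 degrees of longitude
})

test_that("IBD regression recovers an exact linear relationship", {
  pops <- tibble::tibble(population = paste0("P", 1:5),
                         latitude = 25, longitude = seq(100, 108, 2),
                         altitude = seq(100, 900, 200))
  dist <- population_distances(pops)
  a <- -0.4; b <- 0.12
  y <- a + b * log(dist$distance_km)
  fstv <- y / (1 + y)
  pairs <- dplyr::mutate(dist, fst = fstv)
  fit <- ibd_regression(pairs, dist)
  expect_equal(fit$a, a, tolerance = 1e-10)
  expect_equal(fit$b, b, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
  td <- tidy(fit)
  expect_equal(td$b, b, tolerance = 1e-10)

  # pairs at F_st = 1 are excluded with a warning
  pairs2 <- pairs
  pairs2$fst[1] <- 1
  expect_warning(fit2 <- ibd_regression(pairs2, dist), "excluded")
  expect_equal(fit2$n_pairs, nrow(pairs) - 1)
})

test_that("altitude correlation matches cor.test and handles degeneracy", {
  pops <- tibble::tibble(population = paste0("P", 1:4),
                         latitude = 25, longitude = seq(100, 106, 2),
                         altitude = c(100, 500, 900, 1400))
  dist <- population_distances(pops)
  pairs <- dplyr::mutate(dist, fst = altitude_diff / 2000)  # exact proportionality
  res <- altitude_correlation(pairs, dist)
  expect_equal(res$r, 1)
  ct <- cor.test(pairs$fst, dist$altitude_diff)
  expect_equal(res$p, ct$p.value)
  # zero variance -> NA
  pairs0 <- dplyr::mutate(dist, fst = 0.3)
  expect_true(is.na(altitude_correlation(pairs0, dist)$r))
})
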