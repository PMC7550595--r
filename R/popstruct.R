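# Allele frequencies, heterozygosities, F_st estimators with chi-square
# tests, pairwise F_st, geographic distances, isolation-by-distance
# regression, and altitude correlation.

#' Per-population allele frequencies
#'
#' Count-based allele frequencies per population and locus. At null-flagged
#' loci with a supplied null-frequency estimate, visible-allele frequencies
#' are rescaled by `1 - null_freq` and a null class (allele code -1) is
#' appended, so each frequency vector still sums to 1.
#'
#' @param x a [progeny_data] object.
#' @param null_estimates optional tibble (`population`, `locus`,
#'   `null_freq_estimate`), e.g. from [screen_genotyping_errors()]; rows with
#'   missing estimates are ignored.
#' @return A tidy frequency table: `population`, `locus`, `allele`, `freq`,
#'   `n` (individuals sampled in the population).
#' @export
allele_frequencies <- function(x, null_estimates = NULL) {
  g <- x$genotypes
  sizes <- g |>
    dplyr::distinct(.data$population, .data$individual) |>
    dplyr::count(.data$population, name = "n")
  long <- g |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele") |>
    dplyr::filter(is_visible(.data$allele))
  freqs <- long |>
    dplyr::count(.data$population, .data$locus, .data$allele) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n")
  if (!is.null(null_estimates)) {
    ne <- null_estimates |>
      dplyr::filter(!is.na(.data$null_freq_estimate),
                    .data$null_freq_estimate > 0) |>
      dplyr::select("population", "locus", nf = "null_freq_estimate")
    freqs <- freqs |>
      dplyr::left_join(ne, by = c("population", "locus")) |>
      dplyr::mutate(freq = ifelse(is.na(.data$nf), .data$freq,
                                  .data$freq * (1 - .data$nf))) |>
      dplyr::select(-"nf")
    freqs <- dplyr::bind_rows(
      freqs,
      ne |> dplyr::mutate(allele = NULL_CODE, freq = .data$nf) |>
        dplyr::select("population", "locus", "allele", "freq"))
  }
  freqs |>
    dplyr::left_join(sizes, by = "population") |>
    dplyr::arrange(.data$population, match(.data$locus, x$loci$locus),
                   .data$allele)
}

#' Observed and expected heterozygosities
#'
#' Observed heterozygosity `Ho` is the heterozygote fraction among typed
#' phenotypes (null-masked calls scored as observed); expected
#' heterozygosity `He = 1 - sum(p_k^2)` includes the null class when the
#' frequency table carries one. Population means and SDs are taken across
#' loci, together with the mean number of observed alleles per locus.
#'
#' @param x a [progeny_data] object.
#' @param freqs a frequency table from [allele_frequencies()].
#' @return A list with `by_locus` (per population x locus `Ho`, `He`,
#'   `n_alleles`) and `summary` (per population means and SDs).
#' @export
heterozygosities <- function(x, freqs) {
  g <- mask_null_calls(x$genotypes)
  ho <- g |>
    dplyr::filter(is_visible(.data$allele_a), is_visible(.data$allele_b)) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(Ho = mean(.data$allele_a != .data$allele_b),
                     .groups = "drop")
  he <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(He = 1 - sum(.data$freq^2),
                     n_alleles = sum(is_visible(.data$allele)),
                     .groups = "drop")
  by_locus <- dplyr::full_join(ho, he, by = c("population", "locus")) |>
    dplyr::arrange(.data$population, match(.data$locus, x$loci$locus))
  summary <- by_locus |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(Ho_mean = mean(.data$Ho, na.rm = TRUE),
                     Ho_sd = sd(.data$Ho, na.rm = TRUE),
                     He_mean = mean(.data$He, na.rm = TRUE),
                     He_sd = sd(.data$He, na.rm = TRUE),
                     mean_alleles = mean(.data$n_alleles, na.rm = TRUE),
                     .groups = "drop")
  list(by_locus = by_locus, summary = summary)
}

mask_null_calls <- function(g) {
  both <- g$allele_a == NULL_CODE & g$allele_b == NULL_CODE
  one <- g$allele_a == NULL_CODE & g$allele_b != NULL_CODE
  g$allele_a[both] <- MISSING_CODE
  g$allele_b[both] <- MISSING_CODE
  g$allele_a[one] <- g$allele_b[one]
  g
}

freq_matrix <- function(freqs, locus_j) {
  d <- freqs[freqs$locus == locus_j, ]
  wide <- d |>
    dplyr::select("population", "allele", "freq") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "freq",
                       values_fill = 0)
  P <- as.matrix(wide[, -1, drop = FALSE])
  rownames(P) <- wide$population
  n <- d |> dplyr::distinct(.data$population, .data$n)
  list(P = P, n = setNames(n$n, n$population)[rownames(P)])
}

fst_components <- function(P, n) {
  r <- nrow(P)
  nbar <- mean(n)
  pbar <- colMeans(P)  # unweighted mean across populations
  num <- sum(n * rowSums(sweep(P, 2, pbar)^2)) / ((r - 1) * nbar)
  den <- sum(pbar * (1 - pbar))
  list(num = num, den = den, r = r, nbar = nbar)
}

#' Single-locus F_st with chi-square test
#'
#' The frequency-based single-locus differentiation estimator
#' `F_st(s) = [sum_i sum_k n_i (p_ijk - pbar_jk)^2 / ((r-1) nbar)] /
#' [sum_k pbar_jk (1 - pbar_jk)]`, with `pbar_jk` the unweighted mean allele
#' frequency over the `r` populations and `nbar` the mean sample size. The
#' null hypothesis `F_st = 0` is tested with `chi2 = (r-1) nbar F_st(s)` on
#' `r - 1` degrees of freedom. Note the estimator can exceed 1 (two
#' populations fixed for different alleles give 2), a property of this
#' normalisation; a Weir-Cockerham-style weighted mean of frequencies is
#' available via `weighted_mean = TRUE` for comparison.
#'
#' @param freqs a frequency table (columns `population`, `locus`, `allele`,
#'   `freq`, `n`).
#' @param locus locus name.
#' @param weighted_mean use sample-size-weighted mean frequencies instead of
#'   the unweighted mean (comparison mode).
#' @return A one-row tibble: `locus`, `fst`, `chi2`, `df`, `p`, `r`, `nbar`.
#'   `fst` is `NA` for a locus monomorphic across all populations.
#' @export
fst_single_locus <- function(freqs, locus, weighted_mean = FALSE) {
  fm <- freq_matrix(freqs, locus)
  if (nrow(fm$P) < 2) stop("need >= 2 populations with frequencies at ", locus)
  P <- fm$P
  n <- fm$n
  if (weighted_mean) {
    pbar <- colSums(P * n) / sum(n)
    r <- nrow(P); nbar <- mean(n)
    num <- sum(n * rowSums(sweep(P, 2, pbar)^2)) / ((r - 1) * nbar)
    den <- sum(pbar * (1 - pbar))
    comp <- list(num = num, den = den, r = r, nbar = nbar)
  } else {
    comp <- fst_components(P, n)
  }
  if (comp$den == 0) {
    return(tibble::tibble(locus = locus, fst = NA_real_, chi2 = NA_real_,
                          df = comp$r - 1, p = NA_real_, r = comp$r,
                          nbar = comp$nbar))
  }
  fst <- comp$num / comp$den
  chi2 <- (comp$r - 1) * comp$nbar * fst
  tibble::tibble(locus = locus, fst = fst, chi2 = chi2, df = comp$r - 1,
                 p = pchisq(chi2, comp$r - 1, lower.tail = FALSE),
                 r = comp$r, nbar = comp$nbar)
}

#' Multilocus F_st
#'
#' Ratio of the summed single-locus numerators to the summed denominators
#' across loci; loci with zero denominator (monomorphic everywhere) are
#' excluded.
#'
#' @inheritParams fst_single_locus
#' @return A one-row tibble: `fst`, `n_loci`, `r`, `nbar`.
#' @export
fst_multilocus <- function(freqs) {
  loci <- unique(freqs$locus)
  comps <- purrr::map(loci, function(l) {
    fm <- freq_matrix(freqs, l)
    if (nrow(fm$P) < 2) return(NULL)
    fst_components(fm$P, fm$n)
  })
  comps <- purrr::compact(comps)
  keep <- purrr::map_dbl(comps, "den") > 0
  if (!any(keep)) {
    return(tibble::tibble(fst = NA_real_, n_loci = 0L, r = NA_integer_,
                          nbar = NA_real_))
  }
  comps <- comps[keep]
  tibble::tibble(
    fst = sum(purrr::map_dbl(comps, "num")) /
      sum(purrr::map_dbl(comps, "den")),
    n_loci = length(comps),
    r = comps[[1]]$r,
    nbar = comps[[1]]$nbar)
}

#' Pairwise multilocus F_st
#'
#' Multilocus F_st for every unordered population pair (the estimator with
#' `r = 2`).
#'
#' @inheritParams fst_single_locus
#' @param per_locus also return per-locus pairwise values.
#' @return A tibble of pairs: `pop1`, `pop2`, `fst` (and `locus` when
#'   `per_locus = TRUE`).
#' @export
pairwise_fst <- function(freqs, per_locus = FALSE) {
  pops <- unique(freqs$population)
  stopifnot(length(pops) >= 2)
  pairs <- utils::combn(pops, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(i) {
    sub <- freqs[freqs$population %in% pairs[, i], ]
    if (per_locus) {
      purrr::map_dfr(unique(sub$locus), function(l) {
        res <- fst_single_locus(sub, l)
        tibble::tibble(pop1 = pairs[1, i], pop2 = pairs[2, i],
                       locus = l, fst = res$fst)
      })
    } else {
      tibble::tibble(pop1 = pairs[1, i], pop2 = pairs[2, i],
                     fst = fst_multilocus(sub)$fst)
    }
  })
  dplyr::bind_rows(out)
}

#' Great-circle distance between coordinates
#'
#' Haversine distance with Earth radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Distance in km.
#' @export
geographic_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Pairwise geographic distances and altitude differences
#'
#' @param populations tibble with `population`, `latitude`, `longitude`,
#'   `altitude`.
#' @return A tibble of unordered pairs: `pop1`, `pop2`, `distance_km`,
#'   `altitude_diff`.
#' @export
population_distances <- function(populations) {
  p <- populations
  pairs <- utils::combn(p$population, 2)
  i1 <- match(pairs[1, ], p$population)
  i2 <- match(pairs[2, ], p$population)
  tibble::tibble(
    pop1 = pairs[1, ], pop2 = pairs[2, ],
    distance_km = geographic_distance(p$latitude[i1], p$longitude[i1],
                                      p$latitude[i2], p$longitude[i2]),
    altitude_diff = abs(p$altitude[i1] - p$altitude[i2]))
}

canonical_pairs <- function(d) {
  p1 <- pmin(d$pop1, d$pop2)
  p2 <- pmax(d$pop1, d$pop2)
  d$pop1 <- p1
  d$pop2 <- p2
  d
}

#' Isolation-by-distance regression
#'
#' Regression of `F_st / (1 - F_st)` on the natural log of geographic
#' distance over all population pairs. `method = "ols"` reports coefficient
#' t-test p-values; `method = "mantel"` additionally computes a permutation
#' p-value for the slope by permuting population labels (pairwise values are
#' not independent, so the permutation test is the safer inference).
#' Pairs with `F_st = 1` (infinite transform) are excluded with a warning.
#'
#' @param fst_pairs tibble (`pop1`, `pop2`, `fst`), e.g. from
#'   [pairwise_fst()].
#' @param distances tibble (`pop1`, `pop2`, `distance_km`), e.g. from
#'   [population_distances()].
#' @param method `"ols"` or `"mantel"`.
#' @param n_perm permutations for the Mantel test.
#' @param seed seed for the permutation test.
#' @return An `ibd_fit` object: list with `a`, `b`, `r_squared`, `p_a`,
#'   `p_b`, `mantel_p` (NA for `"ols"`), `n_pairs`, `data` (the transformed
#'   pair table).
#' @export
ibd_regression <- function(fst_pairs, distances, method = c("ols", "mantel"),
                           n_perm = 999, seed = 1) {
  method <- match.arg(method)
  d <- dplyr::inner_join(
    canonical_pairs(dplyr::select(fst_pairs, "pop1", "pop2", "fst")),
    canonical_pairs(dplyr::select(distances, "pop1", "pop2", "distance_km")),
    by = c("pop1", "pop2"))
  stopifnot(nrow(d) >= 3, all(d$distance_km > 0))
  bad <- !is.na(d$fst) & d$fst >= 1
  if (any(bad)) {
    warning(sum(bad), " pair(s) with F_st >= 1 excluded from IBD regression")
    d <- d[!bad, ]
  }
  d <- d[!is.na(d$fst), ]
  d$y <- d$fst / (1 - d$fst)
  d$x <- log(d$distance_km)
  fit <- lm(y ~ x, data = d)
  sm <- summary(fit)
  out <- list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
              r_squared = sm$r.squared,
              p_a = sm$coefficients[1, 4], p_b = sm$coefficients[2, 4],
              mantel_p = NA_real_, n_pairs = nrow(d), data = tibble::as_tibble(d))
  if (method == "mantel") {
    pops <- unique(c(d$pop1, d$pop2))
    slope_for <- function(perm) {
      relab <- setNames(pops[perm], pops)
      key <- function(p1, p2) paste(pmin(p1, p2), pmax(p1, p2))
      y_perm <- d$y[match(key(relab[d$pop1], relab[d$pop2]),
                          key(d$pop1, d$pop2))]
      if (anyNA(y_perm)) return(NA_real_)
      stats::cov(y_perm, d$x) / stats::var(d$x)
    }
    set.seed(seed)
    obs <- out$b
    perm_b <- replicate(n_perm, slope_for(sample(length(pops))))
    perm_b <- perm_b[!is.na(perm_b)]
    out$mantel_p <- (1 + sum(perm_b >= obs)) / (length(perm_b) + 1)
  }
  class(out) <- "ibd_fit"
  out
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf(
    "<ibd_fit> Fst/(1-Fst) = %.3f + %.3f ln(km); R^2 = %.3f, p_b = %.3g%s\n",
    x$a, x$b, x$r_squared, x$p_b,
    if (!is.na(x$mantel_p)) sprintf(", Mantel p = %.3g", x$mantel_p) else ""))
  invisible(x)
}

#' Correlation between pairwise F_st and altitude difference
#'
#' Pearson correlation with a two-sided t-test p-value.
#'
#' @param fst_pairs tibble (`pop1`, `pop2`, `fst`).
#' @param distances tibble (`pop1`, `pop2`, `altitude_diff`).
#' @return A one-row tibble: `r`, `p`, `n_pairs`; `NA` when either vector has
#'   zero variance.
#' @export
altitude_correlation <- function(fst_pairs, distances) {
  d <- dplyr::inner_join(
    canonical_pairs(dplyr::select(fst_pairs, "pop1", "pop2", "fst")),
    canonical_pairs(dplyr::select(distances, "pop1", "pop2",
                                  "altitude_diff")),
    by = c("pop1", "pop2")) |>
    dplyr::filter(!is.na(.data$fst))
  stopifnot(nrow(d) >= 3)
  if (sd(d$fst) == 0 || sd(d$altitude_diff) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n_pairs = nrow(d)))
  }
  ct <- cor.test(d$fst, d$altitude_diff)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(d))
}
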