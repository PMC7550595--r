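# Micro-Checker-style genotyping-error diagnosis: null alleles, stuttering,
# large-allele dropout, and null-allele frequency estimation. All tests
# compare observed genotype-class counts with a Monte-Carlo null obtained by
# re-pairing the observed allele pool at random (random union of gametes).

drop_untyped <- function(a, b) {
  keep <- !(a == MISSING_CODE & b == MISSING_CODE) & a > 0 & b > 0
  list(a = a[keep], b = b[keep])
}

# Monte-Carlo null for one locus: permute the 2N observed allele copies into
# random pairs n_reps times; track homozygote counts per allele class, het
# involvement per class, and (optionally) one-repeat-unit heterozygote counts.
mc_genotype_null <- function(a, b, n_reps = 1000, seed = 1,
                             repeat_unit = NULL) {
  g <- drop_untyped(a, b)
  pool <- c(g$a, g$b)
  n <- length(g$a)
  alleles <- sort(unique(pool))
  k <- length(alleles)
  if (k < 2 || n < 2) {
    return(list(screenable = FALSE, n = n, alleles = alleles))
  }
  af <- factor(pool, levels = alleles)
  obs_hom <- tabulate(factor(g$a[g$a == g$b], levels = alleles), nbins = k)
  het <- g$a != g$b
  obs_het_class <- tabulate(factor(c(g$a[het], g$b[het]), levels = alleles),
                            nbins = k)
  obs_het1 <- if (!is.null(repeat_unit)) {
    sum(het & (g$b - g$a) == repeat_unit)
  } else NA_integer_
  set.seed(seed)
  rep_hom <- matrix(0L, n_reps, k)
  rep_het_class <- matrix(0L, n_reps, k)
  rep_het1 <- integer(n_reps)
  iaf <- as.integer(af)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(2 * n)
    x1 <- iaf[idx[seq_len(n)]]
    x2 <- iaf[idx[n + seq_len(n)]]
    hom <- x1 == x2
    rep_hom[r, ] <- tabulate(x1[hom], nbins = k)
    rep_het_class[r, ] <- tabulate(c(x1[!hom], x2[!hom]), nbins = k)
    if (!is.null(repeat_unit)) {
      d <- abs(alleles[x1] - alleles[x2])
      rep_het1[r] <- sum(!hom & d == repeat_unit)
    }
  }
  list(screenable = TRUE, n = n, alleles = alleles,
       obs_hom = obs_hom, obs_het_class = obs_het_class, obs_het1 = obs_het1,
       rep_hom = rep_hom, rep_het_class = rep_het_class, rep_het1 = rep_het1,
       n_reps = n_reps)
}

#' Expected genotype counts under random union of gametes
#'
#' Computes, for one locus, expected homozygote and heterozygote-involvement
#' counts per allele-size class under random union of the observed allele
#' pool, with Monte-Carlo confidence bounds from repeated random re-pairings.
#' Untyped individuals are excluded.
#'
#' @param allele_a,allele_b integer allele vectors (observed phenotypes).
#' @param n_reps number of Monte-Carlo randomizations.
#' @param seed integer seed (results are reproducible given the seed).
#' @param level confidence level for the bounds.
#' @return A tibble with one row per allele class (`allele`, `obs_hom`,
#'   `exp_hom`, `hom_lower`, `hom_upper`, `obs_het`, `exp_het`) or, for a
#'   monomorphic/unusable locus, a zero-row tibble with attribute
#'   `screenable = FALSE` and a `note`.
#' @export
expected_genotype_counts <- function(allele_a, allele_b, n_reps = 1000,
                                     seed = 1, level = 0.95) {
  mc <- mc_genotype_null(allele_a, allele_b, n_reps, seed)
  if (!mc$screenable) {
    out <- tibble::tibble(allele = integer(), obs_hom = integer(),
                          exp_hom = numeric(), hom_lower = numeric(),
                          hom_upper = numeric(), obs_het = integer(),
                          exp_het = numeric())
    attr(out, "screenable") <- FALSE
    attr(out, "note") <- "not screenable: fewer than 2 alleles or individuals"
    return(out)
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- tibble::tibble(
    allele = mc$alleles,
    obs_hom = mc$obs_hom,
    exp_hom = colMeans(mc$rep_hom),
    hom_lower = apply(mc$rep_hom, 2, stats::quantile, qs[1]),
    hom_upper = apply(mc$rep_hom, 2, stats::quantile, qs[2]),
    obs_het = mc$obs_het_class,
    exp_het = colMeans(mc$rep_het_class))
  attr(out, "screenable") <- TRUE
  out
}

mc_p_upper <- function(stat_obs, stat_reps) {
  (1 + sum(stat_reps >= stat_obs)) / (length(stat_reps) + 1)
}
mc_p_lower <- function(stat_obs, stat_reps) {
  (1 + sum(stat_reps <= stat_obs)) / (length(stat_reps) + 1)
}

screen_row <- function(test, flag, p, note = NA_character_, extra = NULL) {
  out <- tibble::tibble(test = test, flag = flag, monte_carlo_p = p,
                        note = note)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' Detect null alleles from overall homozygote excess
#'
#' Flags a locus when total homozygote excess is significant against the
#' random-union Monte-Carlo null AND the excess is spread evenly across
#' allele-size classes (at least half of the classes show positive excess and
#' no single class contributes more than half of the total positive excess),
#' the signature distinguishing null alleles from size-dependent errors.
#'
#' @inheritParams expected_genotype_counts
#' @param alpha significance level.
#' @return A one-row tibble: `test`, `flag`, `monte_carlo_p`, `note`,
#'   `null_freq_estimate`, `excess_total`.
#' @export
detect_null_alleles <- function(allele_a, allele_b, alpha = 0.05,
                                n_reps = 1000, seed = 1) {
  mc <- mc_genotype_null(allele_a, allele_b, n_reps, seed)
  if (!mc$screenable) {
    return(screen_row("null_alleles", NA, NA_real_, "not screenable",
                      tibble::tibble(null_freq_estimate = NA_real_,
                                     excess_total = NA_real_)))
  }
  p <- mc_p_upper(sum(mc$obs_hom), rowSums(mc$rep_hom))
  excess <- mc$obs_hom - colMeans(mc$rep_hom)
  pos <- excess > 0
  even <- mean(pos) >= 0.5 &&
    (sum(excess[pos]) == 0 || max(excess[pos]) / sum(excess[pos]) <= 0.5)
  flag <- p <= alpha && even
  nfe <- if (flag) {
    estimate_null_frequency(allele_a, allele_b, method = "oosterhout")$estimate
  } else NA_real_
  screen_row("null_alleles", flag, p,
             extra = tibble::tibble(null_freq_estimate = nfe,
                                    excess_total = sum(excess)))
}

#' Detect stuttering
#'
#' Flags a locus when heterozygotes whose alleles differ by exactly one
#' repeat unit are in significant deficit against the Monte-Carlo null and
#' homozygotes of larger alleles are in excess.
#'
#' @inheritParams detect_null_alleles
#' @param repeat_unit repeat unit length in bp (> 0).
#' @return A one-row tibble (`test`, `flag`, `monte_carlo_p`, `note`,
#'   `one_repeat_het_obs`, `large_hom_excess`).
#' @export
detect_stuttering <- function(allele_a, allele_b, repeat_unit, alpha = 0.05,
                              n_reps = 1000, seed = 1) {
  stopifnot(repeat_unit > 0)
  mc <- mc_genotype_null(allele_a, allele_b, n_reps, seed,
                         repeat_unit = repeat_unit)
  if (!mc$screenable) {
    return(screen_row("stuttering", NA, NA_real_, "not screenable",
                      tibble::tibble(one_repeat_het_obs = NA_integer_,
                                     large_hom_excess = NA_real_)))
  }
  if (all(diff(mc$alleles) > repeat_unit) || max(mc$rep_het1) == 0) {
    # no allele pair one repeat apart: vacuously unflagged
    return(screen_row("stuttering", FALSE, 1,
                      "no one-repeat allele pairs",
                      tibble::tibble(one_repeat_het_obs = mc$obs_het1,
                                     large_hom_excess = NA_real_)))
  }
  p <- mc_p_lower(mc$obs_het1, mc$rep_het1)
  excess <- mc$obs_hom - colMeans(mc$rep_hom)
  large <- mc$alleles > stats::median(mc$alleles)
  large_excess <- sum(excess[large])
  flag <- p <= alpha && large_excess > 0
  screen_row("stuttering", flag, p,
             extra = tibble::tibble(one_repeat_het_obs = mc$obs_het1,
                                    large_hom_excess = large_excess))
}

#' Detect large-allele dropout (short allele dominance)
#'
#' Flags a locus when per-class homozygote excess is biased toward either
#' extreme of the allele size distribution: the centred size-rank contrast of
#' homozygote excess is tested two-sided against its random-union Monte-Carlo
#' null.
#'
#' @inheritParams detect_null_alleles
#' @return A one-row tibble (`test`, `flag`, `monte_carlo_p`, `note`,
#'   `size_rank_contrast`).
#' @export
detect_large_allele_dropout <- function(allele_a, allele_b, alpha = 0.05,
                                        n_reps = 1000, seed = 1) {
  mc <- mc_genotype_null(allele_a, allele_b, n_reps, seed)
  if (!mc$screenable || length(mc$alleles) < 3) {
    return(screen_row("large_allele_dropout", NA, NA_real_,
                      "not screenable: fewer than 3 allele classes",
                      tibble::tibble(size_rank_contrast = NA_real_)))
  }
  expc <- colMeans(mc$rep_hom)
  rnk <- seq_along(mc$alleles)
  rnk <- rnk - mean(rnk)  # centred: uniform excess gives a zero contrast
  # size-rank contrast of the homozygote excess after removing its
  # frequency-proportional component (the null-allele signature, excess
  # proportional to allele frequency, must not trigger this test): dropout
  # shifts the residual excess toward a size extreme, making the contrast
  # large in magnitude; calibrated against the random-union Monte-Carlo
  # null, two-sided
  q <- (2 * mc$obs_hom + mc$obs_het_class) / (2 * mc$n)
  contrast <- function(hom) {
    e <- hom - expc
    sum((e - sum(e) * q) * rnk)
  }
  ctr_obs <- contrast(mc$obs_hom)
  ctr_rep <- apply(mc$rep_hom, 1, contrast)
  scale <- stats::mad(ctr_rep)
  if (scale == 0) {
    return(screen_row("large_allele_dropout", FALSE, 1,
                      "degenerate homozygote-excess contrast",
                      tibble::tibble(size_rank_contrast = NA_real_)))
  }
  p <- mc_p_upper(abs(ctr_obs), abs(ctr_rep))
  screen_row("large_allele_dropout", p <= alpha, p,
             extra = tibble::tibble(size_rank_contrast = ctr_obs))
}

#' Estimate the null-allele frequency at a locus
#'
#' Three estimators of the frequency of a non-amplifying allele from the
#' observed homozygote excess:
#' `"oosterhout"` (default) rescales the visible allele frequencies to sum to
#' `1 - r` and solves for the `r` at which the expected observed-homozygote
#' fraction among typed individuals, `sum(q_k^2 + 2 q_k r) / (1 - r^2)`,
#' matches the observed fraction (root found to 1e-6); `"brookfield1"` is the
#' closed form `(He - Ho) / (1 + He)`; `"chakraborty"` is
#' `(He - Ho) / (He + Ho)`. If there is no homozygote excess (`Ho >= He`) the
#' estimate is 0 with a note.
#'
#' @inheritParams expected_genotype_counts
#' @param method estimator to use.
#' @return A one-row tibble: `method`, `estimate`, `He`, `Ho`, `note`.
#' @export
estimate_null_frequency <- function(allele_a, allele_b,
                                    method = c("oosterhout", "brookfield1",
                                               "chakraborty")) {
  method <- match.arg(method)
  g <- drop_untyped(allele_a, allele_b)
  n <- length(g$a)
  pool <- factor(c(g$a, g$b))
  v <- as.numeric(table(pool)) / (2 * n)
  Ho <- mean(g$a != g$b)
  He <- 1 - sum(v^2)
  hom_obs <- 1 - Ho
  note <- NA_character_
  if (Ho >= He) {
    return(tibble::tibble(method = method, estimate = 0, He = He, Ho = Ho,
                          note = "no homozygote excess"))
  }
  est <- switch(method,
    brookfield1 = (He - Ho) / (1 + He),
    chakraborty = (He - Ho) / (He + Ho),
    oosterhout = {
      f <- function(r) {
        q <- v * (1 - r)
        sum(q^2 + 2 * q * r) / (1 - r^2) - hom_obs
      }
      if (f(0) >= 0) 0 else {
        up <- 0.999
        if (f(up) < 0) {
          note <- "excess beyond model range; boundary returned"
          up
        } else {
          uniroot(f, c(0, up), tol = 1e-6)$root
        }
      }
    })
  tibble::tibble(method = method, estimate = est, He = He, Ho = Ho,
                 note = note)
}

#' Screen a dataset for genotyping errors
#'
#' Runs the three Micro-Checker-style detectors per population and locus on
#' the pooled family sample (families treated as unrelated for screening; the
#' Hardy-Weinberg approximation this entails is a documented bias) and
#' estimates the null-allele frequency where the null test flags.
#'
#' @param x a [progeny_data] object of observed phenotypes.
#' @param alpha significance level per test.
#' @param n_reps Monte-Carlo randomizations per test.
#' @param seed integer seed; per-cell seeds are derived deterministically.
#' @return A tibble with one row per population x locus: flags, Monte-Carlo
#'   p-values and the null-frequency estimate.
#' @export
screen_genotyping_errors <- function(x, alpha = 0.05, n_reps = 1000,
                                     seed = 1) {
  g <- x$genotypes
  cells <- tidyr::expand_grid(population = x$populations$population,
                              locus = x$loci$locus)
  res <- purrr::pmap(list(cells$population, cells$locus,
                          seq_len(nrow(cells))),
                     function(p, l, idx) {
    gi <- g[g$population == p & g$locus == l, ]
    u <- x$loci$repeat_unit[x$loci$locus == l]
    cs <- as.integer((seed + 104729 * idx) %% 2147483647)
    nul <- detect_null_alleles(gi$allele_a, gi$allele_b, alpha, n_reps, cs)
    stu <- detect_stuttering(gi$allele_a, gi$allele_b, u, alpha, n_reps,
                             cs + 1L)
    dro <- detect_large_allele_dropout(gi$allele_a, gi$allele_b, alpha,
                                       n_reps, cs + 2L)
    tibble::tibble(
      population = p, locus = l,
      n = sum(!(gi$allele_a == MISSING_CODE & gi$allele_b == MISSING_CODE)),
      null_flag = nul$flag, null_p = nul$monte_carlo_p,
      null_freq_estimate = nul$null_freq_estimate,
      stutter_flag = stu$flag, stutter_p = stu$monte_carlo_p,
      dropout_flag = dro$flag, dropout_p = dro$monte_carlo_p)
  })
  dplyr::bind_rows(res)
}
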