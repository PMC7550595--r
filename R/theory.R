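# Closed-form island-model and sampling-theory helpers.

#' Composite gene flow under the island model with partial selfing
#'
#' For a population of size `N` with selfing rate `alpha`, seed migration rate
#' `m_S` and pollen migration rate `m_P`, the effective population size is
#' `N_e = N (1 - alpha/2)` and the composite gene-flow term is
#' `N (1 - alpha/2) (m_S + (1 - alpha) m_P / 2)`. Under isolation by distance
#' the reciprocal of the composite term plays the role of
#' `F_st / (1 - F_st) = a + b ln(distance)`.
#'
#' @param N population size (individuals), > 0.
#' @param alpha selfing rate in `[0, 1]`.
#' @param m_S,m_P seed and pollen migration rates in `[0, 1]`.
#' @return A tibble with columns `N_e`, `composite`, `reciprocal`. When the
#'   composite term is zero the reciprocal is `Inf`.
#' @export
composite_gene_flow <- function(N, alpha, m_S, m_P) {
  stopifnot(N > 0, alpha >= 0, alpha <= 1,
            m_S >= 0, m_S <= 1, m_P >= 0, m_P <= 1)
  N_e <- N * (1 - alpha / 2)
  composite <- N_e * (m_S + (1 - alpha) * m_P / 2)
  tibble::tibble(N_e = N_e, composite = composite,
                 reciprocal = ifelse(composite == 0, Inf, 1 / composite))
}

#' Solve the island-model relation for the selfing rate
#'
#' Inverts the composite gene-flow relation
#' `1 / (N (1 - alpha/2)(m_S + (1 - alpha) m_P / 2)) = a + b ln(distance)`
#' for `alpha` in `[0, 1]` given a fitted isolation-by-distance regression.
#' When no interior root exists the nearer boundary value is returned with
#' `boundary = TRUE`.
#'
#' @param a,b intercept and slope of the regression of `F_st/(1-F_st)` on
#'   `ln(distance)`.
#' @param distance geographic distance (same units as the fit, typically km).
#' @param N population size; `m_S`, `m_P` seed and pollen migration rates.
#' @param m_S,m_P seed and pollen migration rates.
#' @return A tibble with columns `alpha`, `boundary`, `rhs`.
#' @export
solve_alpha_from_ibd <- function(a, b, distance, N, m_S, m_P) {
  rhs <- a + b * log(distance)
  if (rhs <= 0) stop("a + b*ln(distance) must be positive")
  f <- function(alpha) {
    composite_gene_flow(N, alpha, m_S, m_P)$reciprocal - rhs
  }
  f0 <- f(0)
  f1 <- f(1)
  # reciprocal is increasing in alpha, so f is increasing
  if (f0 >= 0) {
    return(tibble::tibble(alpha = 0, boundary = TRUE, rhs = rhs))
  }
  if (f1 <= 0) {
    return(tibble::tibble(alpha = 1, boundary = TRUE, rhs = rhs))
  }
  root <- uniroot(f, c(0, 1), tol = 1e-10)$root
  tibble::tibble(alpha = root, boundary = FALSE, rhs = rhs)
}

#' Multilocus genotype match probability
#'
#' The probability that two individuals share the same multilocus genotype by
#' chance, assuming uniformly distributed alleles: the product over loci of
#' the reciprocal of the allele count.
#'
#' @param allele_counts integer vector of allele counts per locus (>= 1).
#' @return A single probability.
#' @export
match_probability <- function(allele_counts) {
  stopifnot(all(allele_counts >= 1))
  prod(1 / allele_counts)
}

#' Binomial standard error of an outcrossing-rate estimate
#'
#' The sampling standard error of a rate `t` estimated from `n` independent
#' offspring, `sqrt(t (1 - t) / n)`. The literal form `sqrt(t(1-t))/n` is
#' available for comparison via `form = "ratio"`.
#'
#' @param t rate in `[0, 1]`.
#' @param n sample size (>= 1).
#' @param form `"standard"` (default) or `"ratio"`.
#' @return Standard error.
#' @export
binomial_se <- function(t, n, form = c("standard", "ratio")) {
  form <- match.arg(form)
  stopifnot(all(t >= 0), all(t <= 1), all(n >= 1))
  if (form == "standard") sqrt(t * (1 - t) / n) else sqrt(t * (1 - t)) / n
}
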