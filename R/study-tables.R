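# Published summary tables for the Toona ciliata study system (six natural
# populations in South China, eight nuclear SSR loci). These printed summaries
# serve as worked-example inputs: the underlying genotypes are not
# redistributed here, but the synthetic generator reproduces their design.

#' SSR locus registry of the Toona ciliata study system
#'
#' Eight nuclear microsatellite loci with repeat motifs, annealing
#' temperatures, allele size ranges (bp) and observed allele counts.
#'
#' @return A tibble with one row per locus.
#' @export
toona_loci <- function() {
  tibble::tibble(
    locus = c("TCR17", "TCR18", "TCR20", "TCR26",
              "TCR51", "TCR78", "TCR83", "TCR122"),
    repeat_motif = c("(GA)n", "(AG)n", "(GA)n", "(TC)n",
                     "(GA)n", "(GA)n(AG)n", "(CT)n", "(CA)n"),
    t_annealing = c(58, 58, 58, 58, 56, 58, 58, 56),
    min_bp = c(140L, 107L, 152L, 233L, 108L, 163L, 183L, 158L),
    max_bp = c(205L, 210L, 327L, 271L, 140L, 255L, 287L, 298L),
    n_alleles = c(14L, 44L, 30L, 30L, 5L, 24L, 47L, 14L)
  )
}

#' Population samples of the Toona ciliata study system
#'
#' Locations (decimal degrees), altitudes, sampling design (seeds, families,
#' seeds per family), genotyping-error screening outcomes and diversity
#' summaries for the six populations.
#'
#' @return A tibble with one row per population.
#' @export
toona_populations <- function() {
  tibble::tibble(
    population = c("Baoshan", "Simao", "Yongren", "Tianlin",
                   "Guanshan", "Nanping"),
    latitude = c(24 + 59 / 60, 22 + 46 / 60, 26 + 1 / 60, 24 + 17 / 60,
                 28 + 32 / 60, 26 + 38 / 60),
    longitude = c(99 + 1 / 60, 100 + 58 / 60, 101 + 40 / 60, 106 + 13 / 60,
                  114 + 33 / 60, 118 + 10 / 60),
    altitude = c(1401, 600, 1580, 1200, 330, 800),
    n_seeds = c(132L, 64L, 90L, 119L, 138L, 300L),
    n_families = c(23L, 12L, 16L, 20L, 24L, 30L),
    seeds_per_family_min = c(4L, 4L, 4L, 4L, 4L, 10L),
    seeds_per_family_max = c(6L, 6L, 6L, 6L, 6L, 10L),
    stutter_loci = c("", "", "", "", "", "TCR18,TCR20,TCR51"),
    dropout_loci = c("", "", "", "", "", ""),
    null_loci = c("TCR20", "TCR17,TCR20,TCR83", "TCR17,TCR20,TCR83",
                  "TCR17,TCR20,TCR51", "TCR18,TCR20,TCR26",
                  "TCR18,TCR20,TCR51,TCR78"),
    Ho = c(0.505, 0.227, 0.266, 0.494, 0.332, 0.256),
    Ho_sd = c(0.266, 0.273, 0.291, 0.310, 0.264, 0.243),
    He = c(0.513, 0.345, 0.371, 0.603, 0.451, 0.434),
    He_sd = c(0.219, 0.249, 0.245, 0.200, 0.281, 0.286),
    mean_alleles = c(12.750, 5.500, 7.000, 12.250, 7.250, 2.875)
  )
}

#' Published mating-system estimates for the Toona ciliata study system
#'
#' The per-population mixed-mating parameter estimates with bootstrap standard
#' errors: multilocus and single-locus outcrossing rates (`t_m`, `t_s`) and
#' selfing rates (`alpha_m`, `alpha_s`), their difference, maternal inbreeding
#' `F`, correlations of selfing (`r_s`, `r_loci`) and of paternity
#' (`r_p_m`, `r_p_s`).
#'
#' @return A long tibble with columns `term`, `population`, `estimate`, `se`.
#' @export
toona_mating <- function() {
  pops <- c("Baoshan", "Simao", "Yongren", "Tianlin", "Guanshan", "Nanping")
  row <- function(term, est, se) {
    tibble::tibble(term = term, population = pops, estimate = est, se = se)
  }
  dplyr::bind_rows(
    row("t_m", c(1.166, 0.992, 1.082, 1.194, 0.980, 0.843),
        c(0.067, 0.088, 0.089, 0.031, 0.225, 0.033)),
    row("alpha_m", c(-0.166, 0.008, -0.082, -0.194, 0.020, 0.157),
        c(0.067, 0.088, 0.090, 0.031, 0.212, 0.033)),
    row("t_s", c(0.992, 0.844, 0.899, 0.897, 0.850, 0.672),
        c(0.038, 0.044, 0.046, 0.022, 0.050, 0.039)),
    row("alpha_s", c(0.008, 0.156, 0.100, 0.103, 0.150, 0.338),
        c(0.038, 0.044, 0.047, 0.022, 0.050, 0.039)),
    row("tm_minus_ts", c(0.174, 0.148, 0.183, 0.297, 0.136, 0.171),
        c(0.085, 0.081, 0.089, 0.041, 0.180, 0.022)),
    row("F", c(-0.187, -0.178, -0.141, -0.184, -0.027, -0.200),
        c(0.029, 0.052, 0.082, 0.031, 0.091, 0.001)),
    row("r_s", c(-0.765, -0.546, -0.292, -0.919, -0.261, 0.016),
        c(0.630, 0.674, 0.765, 0.391, 0.789, 0.048)),
    row("r_p_m", c(0.109, -0.133, 0.080, 0.208, 0.304, 0.312),
        c(0.037, 0.274, 0.109, 0.055, 0.120, 0.060)),
    row("r_p_s", c(0.069, -0.083, 0.116, 0.281, 0.350, 0.452),
        c(0.054, 0.180, 0.156, 0.121, 0.184, 0.087)),
    row("rps_minus_rpm", c(-0.039, 0.050, 0.036, 0.073, 0.046, 0.140),
        c(0.045, 0.282, 0.157, 0.104, 0.187, 0.043)),
    row("r_loci", c(0.293, -0.022, -0.054, -0.086, 0.017, -0.007),
        c(0.572, 0.238, 0.283, 0.107, 0.172, 0.108))
  )
}

#' Published differentiation and isolation-by-distance summaries
#'
#' Per-locus and over-loci F_st with p-values, the isolation-by-distance
#' regression coefficients (`F_st/(1-F_st) = a + b ln(distance)`) with their
#' p-values and R-squared, and the correlation between F_st and altitude
#' difference.
#'
#' @return A tibble with one row per locus plus an `"over_loci"` row.
#' @export
toona_differentiation <- function() {
  tibble::tibble(
    locus = c("TCR17", "TCR18", "TCR20", "TCR26", "TCR51", "TCR78",
              "TCR83", "TCR122", "over_loci"),
    fst = c(0.599, 0.268, 0.302, 0.167, 0.005, 0.622, 0.246, 0.207, 0.345),
    fst_p = c(0, 0, 0, 0, 0.6215, 0, 0, 0, 0),
    a = c(-4.202, -0.433, -0.403, -0.055, 0.001, -4.635, -0.255, -0.090,
          -0.682),
    a_p = c(0.021, 0.010, 0.027, 0.358, 0.767, 0.028, 0.047, 0.265, 0.0007),
    b = c(3.155, 0.367, 0.394, 0.102, 0.003, 3.497, 0.265, 0.141, 0.576),
    b_p = c(0.003, 8.81e-5, 1.39e-4, 0.002, 0.015, 0.004, 2.44e-4, 0.002,
            1.68e-6),
    r_squared = c(0.647, 0.706, 0.685, 0.537, 0.403, 0.620, 0.657, 0.550,
                  0.826),
    altitude_r = c(0.370, 0.382, 0.347, 0.297, 0.334, 0.404, 0.366, 0.287,
                   0.349),
    altitude_r_p = c(0.262, 0.160, 0.205, 0.283, 0.244, 0.218, 0.179, 0.296,
                     0.202)
  )
}

#' Cross-population summary of outcrossing-rate estimates
#'
#' Mean and standard deviation of per-population rate estimates, truncating
#' estimates above 1 to 1 (the convention used when multilocus estimates
#' exceed the parameter's natural range).
#'
#' @param estimates numeric vector of per-population estimates.
#' @param truncate_at_1 logical; truncate values above 1 before summarising.
#' @return A tibble with columns `mean`, `sd`, `n`.
#' @export
summarize_rate_estimates <- function(estimates, truncate_at_1 = TRUE) {
  x <- if (truncate_at_1) pmin(estimates, 1) else estimates
  tibble::tibble(mean = mean(x), sd = sd(x), n = length(x))
}
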