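# Shared fixtures: a hand-written two-family toy dataset and small
# simulation shortcuts. All randomness is seeded by the caller.

toy_genotypes <- function() {
  tibble::tibble(
    population = "P1",
    family = rep(c("F1", "F2"), each = 3 * 2),
    individual = rep(c("F1-M", "F1-O1", "F1-O2", "F2-M", "F2-O1", "F2-O2"),
                     each = 2),
    role = rep(rep(c("mother", "offspring", "offspring"), each = 2), 2),
    locus = rep(c("L1", "L2"), 6),
    allele_a = c(100, 200, 100, 200, 102, 204,
                 102, 202, 100, 202, 102, 202),
    allele_b = c(102, 204, 104, 208, 104, 204,
                 104, 206, 102, 206, 104, 208)
  )
}

toy_dataset <- function() {
  loci <- locus_table(c("L1", "L2"), repeat_motif = c("(GA)n", "(CT)n"),
                      min_bp = c(100L, 200L), max_bp = c(120L, 220L),
                      has_null = c(FALSE, TRUE),
                      alleles = list(seq(100L, 110L, 2L), seq(200L, 210L, 2L)))
  pops <- tibble::tibble(population = "P1", latitude = 25, longitude = 100,
                         altitude = 500)
  progeny_data(toy_genotypes(), loci, pops)
}

one_pop_config <- function(rng_seed, n_families = 20, n_off = 6, n_loci = 4,
                           n_alleles = 6, ...) {
  simulation_config(n_populations = 1, families_per_population = n_families,
                    offspring_range = c(n_off, n_off), n_loci = n_loci,
                    alleles_per_locus = n_alleles, seed = rng_seed, ...)
}

fit_terms <- function(fit) {
  setNames(fit$estimates$estimate, fit$estimates$term)
}

rdirichlet_test <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}
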