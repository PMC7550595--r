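# Synthetic progeny-array generator: drift/migration population frequencies,
# mixed mating with correlated paternity and selfing, genotyping errors.
#
# All randomness flows from the single `seed` in the config: stage k uses
# set.seed(seed + k) with offsets 0 (frequencies), 1 (progeny arrays),
# 2 (genotyping errors), so any sub-stage is independently reproducible.

#' Simulation configuration
#'
#' Full generative specification for a synthetic progeny-array dataset. All
#' rates are probabilities in `[0, 1]`; `seed` is mandatory.
#'
#' @param n_populations number of populations.
#' @param families_per_population scalar or per-population vector.
#' @param offspring_range length-2 `c(min, max)` seeds per family, or a list of
#'   per-population ranges.
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus scalar or per-locus vector of allele counts.
#' @param allele_freq_concentration symmetric Dirichlet concentration for the
#'   ancestral allele-frequency draw.
#' @param s selfing rate (scalar or per-population).
#' @param r_p correlation of paternity among outcrossed siblings (scalar or
#'   per-population): the probability two outcrossed sibs share a father.
#' @param r_s correlation of selfing among siblings within a family.
#' @param F_maternal maternal inbreeding coefficient.
#' @param biparental_rate probability an outcross father is a "half relative"
#'   of the mother (one of his gametes drawn from the maternal genotype),
#'   which induces biparental inbreeding (`t_m > t_s`).
#' @param null_freq per-locus null-allele frequency (scalar or vector).
#' @param stutter_rate per-locus probability that a heterozygote whose alleles
#'   differ by one repeat unit is mis-scored as the larger homozygote.
#' @param dropout_rate per-locus baseline probability that the larger allele
#'   of a heterozygote fails to amplify (scaled up with allele size rank).
#' @param migration_model `"island"` or `"stepping_stone"`.
#' @param m migration rate per generation.
#' @param N_e effective population size for drift (genes resampled = 2 N_e).
#' @param generations drift generations.
#' @param coords optional tibble (`population`, `latitude`, `longitude`,
#'   `altitude`); default: populations evenly spaced on a line.
#' @param locus_names,population_names optional name vectors.
#' @param repeat_motif repeat motif (scalar or per-locus); sets the repeat
#'   unit used for allele spacing and stutter errors.
#' @param size_min per-locus minimum allele size in bp.
#' @param seed integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_populations = 6,
                              families_per_population = 20,
                              offspring_range = c(4, 10),
                              n_loci = 8,
                              alleles_per_locus = 8,
                              allele_freq_concentration = 1,
                              s = 0.1,
                              r_p = 0.2,
                              r_s = 0,
                              F_maternal = 0,
                              biparental_rate = 0,
                              null_freq = 0,
                              stutter_rate = 0,
                              dropout_rate = 0,
                              migration_model = c("stepping_stone", "island"),
                              m = 0.05,
                              N_e = 100,
                              generations = 50,
                              coords = NULL,
                              locus_names = NULL,
                              population_names = NULL,
                              repeat_motif = "(GA)n",
                              size_min = 100L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  migration_model <- match.arg(migration_model)
  np <- n_populations
  nl <- n_loci
  cfg <- list(
    n_populations = np,
    families_per_population = rep_len(families_per_population, np),
    offspring_range = if (is.list(offspring_range)) offspring_range
                      else rep(list(offspring_range), np),
    n_loci = nl,
    alleles_per_locus = rep_len(as.integer(alleles_per_locus), nl),
    allele_freq_concentration = allele_freq_concentration,
    s = rep_len(s, np),
    r_p = rep_len(r_p, np),
    r_s = rep_len(r_s, np),
    F_maternal = rep_len(F_maternal, np),
    biparental_rate = rep_len(biparental_rate, np),
    null_freq = rep_len(null_freq, nl),
    stutter_rate = rep_len(stutter_rate, nl),
    dropout_rate = rep_len(dropout_rate, nl),
    migration_model = migration_model,
    m = m, N_e = N_e, generations = generations,
    population_names = population_names %||% sprintf("pop%02d", seq_len(np)),
    locus_names = locus_names %||% sprintf("L%02d", seq_len(nl)),
    repeat_motif = rep_len(repeat_motif, nl),
    size_min = rep_len(as.integer(size_min), nl),
    seed = as.integer(seed)
  )
  cfg$coords <- coords %||% tibble::tibble(
    population = cfg$population_names,
    latitude = rep(25, np),
    longitude = seq(100, 100 + (np - 1) * 2, length.out = max(np, 2))[seq_len(np)],
    altitude = rep(500, np))
  stopifnot(all(cfg$s >= 0 & cfg$s <= 1), all(cfg$r_p >= 0 & cfg$r_p <= 1),
            all(cfg$r_s >= 0 & cfg$r_s <= 1),
            all(cfg$null_freq >= 0 & cfg$null_freq < 1))
  class(cfg) <- "simulation_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

config_loci <- function(cfg) {
  units <- repeat_unit_from_motif(cfg$repeat_motif)
  alleles <- purrr::pmap(
    list(cfg$size_min, units, cfg$alleles_per_locus),
    function(lo, u, k) as.integer(lo + u * (seq_len(k) - 1)))
  locus_table(cfg$locus_names, repeat_motif = cfg$repeat_motif,
              min_bp = cfg$size_min,
              max_bp = purrr::map_int(alleles, max),
              has_null = cfg$null_freq > 0,
              alleles = alleles)
}

#' Simulate population allele frequencies under drift and migration
#'
#' Draws ancestral allele frequencies per locus from a symmetric Dirichlet
#' and evolves them forward by multinomial drift (2 `N_e` genes) with island
#' or stepping-stone migration for `generations` generations. Null alleles,
#' where configured, are appended afterwards as an extra class with fixed
#' frequency (visible frequencies rescaled), so the null frequency is a known
#' truth for estimator checks.
#'
#' @param config a [simulation_config()].
#' @return A tidy frequency table: tibble with columns `population`, `locus`,
#'   `allele` (integer bp; -1 for the null class), `freq`, `n` (the nominal
#'   sample size, `N_e`).
#' @export
simulate_population_frequencies <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  loci <- config_loci(cfg)
  np <- cfg$n_populations
  out <- vector("list", cfg$n_loci)
  for (j in seq_len(cfg$n_loci)) {
    k <- cfg$alleles_per_locus[j]
    anc <- rdirichlet1(k, cfg$allele_freq_concentration)
    P <- matrix(rep(anc, each = np), nrow = np)  # pops x alleles
    for (g in seq_len(cfg$generations)) {
      if (np > 1) {
        Pmig <- if (cfg$migration_model == "island") {
          (1 - cfg$m) * P + cfg$m * matrix(rep(colMeans(P), each = np), np)
        } else {
          nb <- rbind(P[c(1, seq_len(np - 1)), , drop = FALSE],
                      P[c(seq_len(np - 1) + 1, np), , drop = FALSE])
          (1 - cfg$m) * P + cfg$m * (nb[seq_len(np), , drop = FALSE] +
                                       nb[np + seq_len(np), , drop = FALSE]) / 2
        }
      } else {
        Pmig <- P
      }
      for (i in seq_len(np)) {
        P[i, ] <- as.numeric(stats::rmultinom(1, 2 * cfg$N_e, Pmig[i, ])) /
          (2 * cfg$N_e)
      }
    }
    nf <- cfg$null_freq[j]
    alle <- loci$alleles[[j]]
    freq <- P * (1 - nf)
    tab <- tibble::tibble(
      population = rep(cfg$population_names, each = k),
      locus = loci$locus[j],
      allele = rep(alle, times = np),
      freq = as.numeric(t(freq)))
    if (nf > 0) {
      tab <- dplyr::bind_rows(tab, tibble::tibble(
        population = cfg$population_names, locus = loci$locus[j],
        allele = NULL_CODE, freq = nf))
    }
    out[[j]] <- tab
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(n = config$N_e) |>
    dplyr::arrange(match(.data$population, cfg$population_names),
                   match(.data$locus, cfg$locus_names), .data$allele)
}

freq_list <- function(freqs) {
  # tidy freq tibble -> nested list [[pop]][[locus]] of named numeric vectors
  sp <- split(freqs, freqs$population)
  purrr::map(sp, function(d) {
    purrr::map(split(d, d$locus), ~ setNames(.x$freq, .x$allele))
  })
}

draw_genotype <- function(p, F = 0) {
  a <- sample(as.integer(names(p)), 1, prob = p)
  b <- if (F > 0 && stats::runif(1) < F) a
       else sample(as.integer(names(p)), 1, prob = p)
  sort(c(a, b))
}

#' Simulate error-free progeny arrays under the mixed-mating model
#'
#' Mothers are drawn from the population allele frequencies with inbreeding
#' `F_maternal`. Within each family, offspring selfing statuses follow a
#' correlated Bernoulli scheme (pairwise correlation `r_s`): each offspring
#' copies a family-level status with probability `sqrt(r_s)`, else draws
#' independently. Outcrossed offspring share a single communal father with
#' probability `sqrt(r_p)` (so two sibs share a father with probability
#' `r_p`); fathers are random-union draws from the pollen pool, except that
#' with probability `biparental_rate` a father is a half-relative of the
#' mother (one gamete drawn from the maternal genotype per locus). Offspring
#' genotypes arise by Mendelian gamete union. Null alleles, where configured,
#' are real allele classes here; masking happens in
#' [apply_genotyping_errors()].
#'
#' @param config a [simulation_config()].
#' @param freqs optional frequency table from
#'   [simulate_population_frequencies()]; generated from `config` if missing.
#' @return A [progeny_data] object with true genotypes; the hidden truth
#'   (selfing status and father id per offspring) is attached as
#'   `attr(x, "truth")`.
#' @export
simulate_progeny_arrays <- function(config, freqs = NULL) {
  cfg <- config
  if (is.null(freqs)) freqs <- simulate_population_frequencies(cfg)
  set.seed(cfg$seed + 1L)
  loci <- config_loci(cfg)
  fl <- freq_list(freqs)
  rows <- list()
  truth <- list()
  for (i in seq_len(cfg$n_populations)) {
    pop <- cfg$population_names[i]
    pf <- fl[[pop]][cfg$locus_names]
    phi_p <- sqrt(cfg$r_p[i])
    phi_s <- sqrt(cfg$r_s[i])
    draw_father <- function(mother) {
      if (stats::runif(1) < cfg$biparental_rate[i]) {
        purrr::imap(pf, function(p, l) {
          sort(c(sample(mother[[l]], 1),
                 sample(as.integer(names(p)), 1, prob = p)))
        })
      } else {
        purrr::map(pf, draw_genotype)
      }
    }
    for (f in seq_len(cfg$families_per_population[i])) {
      fam <- sprintf("F%02d", f)
      mother <- purrr::map(pf, draw_genotype, F = cfg$F_maternal[i])
      rng <- cfg$offspring_range[[i]]
      n_off <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
      fam_status <- stats::runif(1) < cfg$s[i]
      communal <- draw_father(mother)
      rows[[length(rows) + 1]] <- tibble::tibble(
        population = pop, family = fam, individual = paste0(fam, "-M"),
        role = "mother", locus = cfg$locus_names,
        allele_a = purrr::map_int(mother, 1),
        allele_b = purrr::map_int(mother, 2))
      for (o in seq_len(n_off)) {
        selfed <- if (stats::runif(1) < phi_s) fam_status
                  else stats::runif(1) < cfg$s[i]
        if (selfed) {
          geno <- purrr::map(mother, ~ sort(sample(.x, 2, replace = TRUE)))
          father_id <- NA_character_
        } else {
          shared <- stats::runif(1) < phi_p
          father <- if (shared) communal else draw_father(mother)
          father_id <- if (shared) paste0(fam, "-shared")
                       else paste0(fam, "-u", o)
          geno <- purrr::map2(mother, father,
                              ~ sort(c(sample(.x, 1), sample(.y, 1))))
        }
        oid <- sprintf("%s-O%02d", fam, o)
        rows[[length(rows) + 1]] <- tibble::tibble(
          population = pop, family = fam, individual = oid,
          role = "offspring", locus = cfg$locus_names,
          allele_a = purrr::map_int(geno, 1),
          allele_b = purrr::map_int(geno, 2))
        truth[[length(truth) + 1]] <- tibble::tibble(
          population = pop, family = fam, individual = oid,
          selfed = selfed, father_id = father_id)
      }
    }
  }
  pops <- cfg$coords
  x <- progeny_data(dplyr::bind_rows(rows), loci, pops)
  attr(x, "truth") <- dplyr::bind_rows(truth)
  x
}

#' Apply genotyping errors to a simulated dataset
#'
#' Transforms true genotypes into observed phenotypes: null alleles are
#' masked (a true heterozygote carrying one null allele is scored as the
#' visible homozygote; a null homozygote becomes untyped), then stuttering
#' mis-scores heterozygotes whose alleles differ by exactly one repeat unit
#' as the larger homozygote with probability `stutter_rate`, and large-allele
#' dropout rescales a heterozygote to the smaller homozygote with probability
#' `dropout_rate` scaled by the size rank of the larger allele.
#'
#' @param x a [progeny_data] object with true genotypes.
#' @param config the [simulation_config()] that generated it.
#' @return A [progeny_data] object of observed phenotypes; the truth
#'   attribute is carried over.
#' @export
apply_genotyping_errors <- function(x, config) {
  cfg <- config
  set.seed(cfg$seed + 2L)
  g <- x$genotypes
  for (j in seq_len(nrow(x$loci))) {
    l <- x$loci$locus[j]
    u <- x$loci$repeat_unit[j]
    alle <- x$loci$alleles[[j]]
    sel <- which(g$locus == l)
    a <- g$allele_a[sel]
    b <- g$allele_b[sel]
    # null masking
    both_null <- a == NULL_CODE & b == NULL_CODE
    one_null <- a == NULL_CODE & b != NULL_CODE
    a[both_null] <- MISSING_CODE; b[both_null] <- MISSING_CODE
    a[one_null] <- b[one_null]
    # stutter: one-repeat heterozygote -> larger homozygote
    jl <- match(l, cfg$locus_names)
    if (!is.na(jl) && cfg$stutter_rate[jl] > 0) {
      het1 <- which(a != b & a > 0 & (b - a) == u)
      hit <- het1[stats::runif(length(het1)) < cfg$stutter_rate[jl]]
      a[hit] <- b[hit]
    }
    # dropout: larger allele lost with probability increasing in size rank
    if (!is.na(jl) && cfg$dropout_rate[jl] > 0) {
      het <- which(a != b & a > 0)
      rnk <- match(b[het], sort(alle)) / length(alle)
      hit <- het[stats::runif(length(het)) < cfg$dropout_rate[jl] * rnk]
      b[hit] <- a[hit]
    }
    g$allele_a[sel] <- a
    g$allele_b[sel] <- b
  }
  out <- progeny_data(g, x$loci, x$populations)
  attr(out, "truth") <- attr(x, "truth")
  out
}

#' Study-like simulation preset
#'
#' Configuration reproducing the design of the Toona ciliata study system:
#' six populations at the study coordinates and altitudes, the per-population
#' family counts (23, 12, 16, 20, 24, 30) and seeds-per-family ranges, eight
#' loci with the published allele counts (14, 44, 30, 30, 5, 24, 47, 14),
#' size ranges and motifs, per-population selfing and paternity-correlation
#' values inside the published ranges, null alleles at the loci flagged in
#' the study, and stepping-stone spatial structure (populations ordered by
#' longitude) producing isolation by distance.
#'
#' @param seed integer seed.
#' @return A [simulation_config()].
#' @export
study_like_config <- function(seed) {
  loci <- toona_loci()
  pops <- toona_populations()
  simulation_config(
    n_populations = 6,
    families_per_population = pops$n_families,
    offspring_range = purrr::map2(pops$seeds_per_family_min,
                                  pops$seeds_per_family_max, c),
    n_loci = 8,
    alleles_per_locus = loci$n_alleles,
    allele_freq_concentration = 0.8,
    s = c(0, 0.008, 0, 0, 0.02, 0.157),
    r_p = c(0.109, 0, 0.080, 0.208, 0.304, 0.312),
    r_s = 0,
    F_maternal = 0,
    biparental_rate = 0.1,
    null_freq = c(0.08, 0.05, 0.10, 0.05, 0.05, 0.05, 0.05, 0),
    stutter_rate = 0,
    dropout_rate = 0,
    migration_model = "stepping_stone",
    m = 0.01,
    N_e = 70,
    generations = 80,
    coords = pops[order(pops$longitude),
                  c("population", "latitude", "longitude", "altitude")],
    locus_names = loci$locus,
    population_names = pops$population[order(pops$longitude)],
    repeat_motif = loci$repeat_motif,
    size_min = loci$min_bp,
    seed = seed)
}

#' Generate a study-like synthetic dataset
#'
#' One call producing observed phenotypes with the study design (see
#' [study_like_config()]): frequencies are simulated, progeny arrays drawn,
#' and genotyping errors applied.
#'
#' @param seed integer seed.
#' @return A [progeny_data] object (truth attached as attribute).
#' @export
generate_study_like_dataset <- function(seed) {
  cfg <- study_like_config(seed)
  apply_genotyping_errors(simulate_progeny_arrays(cfg), cfg)
}
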