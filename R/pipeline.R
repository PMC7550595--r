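# Orchestration: full screen -> diversity -> mating fits -> differentiation /
# IBD / altitude pipeline, with deterministic seeding and TSV/JSON reports.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a dataset object, a file path, or
#' a simulation preset.
#'
#' @param data a [progeny_data] object.
#' @param input path to a dataset file (see [read_progeny_dataset()]).
#' @param input_format `"tsv"` or `"mltr"`.
#' @param preset `"study_like"` to simulate a study-like dataset.
#' @param alpha,screen_reps screening options.
#' @param em an [em_options()] list.
#' @param n_bootstrap bootstrap replicates for mating-fit standard errors.
#' @param mantel_reps permutations for the IBD Mantel test.
#' @param seed master seed recorded in every output.
#' @param out_dir optional directory for TSV/JSON reports.
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(data = NULL, input = NULL, input_format = "tsv",
                            preset = NULL, alpha = 0.05, screen_reps = 1000,
                            em = em_options(), n_bootstrap = 0,
                            mantel_reps = 999, seed = 1, out_dir = NULL) {
  sources <- c(!is.null(data), !is.null(input), !is.null(preset))
  if (sum(sources) != 1) {
    stop("exactly one of data, input, preset must be given")
  }
  known_em <- names(em_options())
  if (!all(names(em) %in% known_em)) {
    stop("unknown EM option(s): ",
         paste(setdiff(names(em), known_em), collapse = ", "))
  }
  structure(list(data = data, input = input, input_format = input_format,
                 preset = preset, alpha = alpha, screen_reps = screen_reps,
                 em = em, n_bootstrap = n_bootstrap,
                 mantel_reps = mantel_reps, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

format_est_se <- function(est, se) {
  ifelse(is.na(est), "-",
         ifelse(is.na(se), sprintf("%.3f", est),
                sprintf("%.3f (%.3f)", est, se)))
}

#' Run the full progeny-array analysis
#'
#' Executes, in order: genotyping-error screening, allele frequencies and
#' diversity summaries, per-population mixed-mating fits (with bootstrap
#' standard errors when configured), and population structure (per-locus and
#' multilocus F_st with chi-square tests, pairwise F_st, isolation-by-distance
#' regression with Mantel test, altitude correlation). All stages are
#' deterministic given the config seed. When `out_dir` is set, each table is
#' written as TSV plus a JSON bundle carrying the package version, seed and
#' options.
#'
#' @param config a [pipeline_config()].
#' @return A list of tibbles: `screen`, `diversity`, `mating`,
#'   `differentiation`, `ibd`, `altitude`, plus `meta`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- config$data %||%
    (if (!is.null(config$input)) {
      read_progeny_dataset(config$input, config$input_format)
    } else if (identical(config$preset, "study_like")) {
      generate_study_like_dataset(config$seed)
    } else stop("unknown preset: ", config$preset))

  screen <- screen_genotyping_errors(x, alpha = config$alpha,
                                     n_reps = config$screen_reps,
                                     seed = config$seed)
  freqs <- allele_frequencies(
    x, null_estimates = screen[, c("population", "locus",
                                   "null_freq_estimate")])
  div <- heterozygosities(x, freqs)
  diversity <- div$summary |>
    dplyr::left_join(
      screen |>
        dplyr::group_by(.data$population) |>
        dplyr::summarise(
          null_loci = paste(.data$locus[!is.na(.data$null_flag) &
                                          .data$null_flag], collapse = ","),
          stutter_loci = paste(.data$locus[!is.na(.data$stutter_flag) &
                                             .data$stutter_flag],
                               collapse = ","),
          dropout_loci = paste(.data$locus[!is.na(.data$dropout_flag) &
                                             .data$dropout_flag],
                               collapse = ","),
          .groups = "drop"),
      by = "population")

  pops <- x$populations$population
  fits <- purrr::map(pops, function(p) {
    fit_mating_system(x, population = p, screen = screen,
                      options = config$em,
                      n_bootstrap = config$n_bootstrap,
                      seed = config$seed + match(p, pops))
  })
  names(fits) <- pops
  mating <- purrr::map_dfr(fits, function(f) {
    f$estimates |>
      dplyr::mutate(population = f$population,
                    formatted = format_est_se(.data$estimate, .data$se))
  }) |>
    dplyr::select("population", "term", "estimate", "se", "formatted")

  per_locus_fst <- purrr::map_dfr(x$loci$locus,
                                  ~ fst_single_locus(freqs, .x))
  multi <- fst_multilocus(freqs)
  differentiation <- dplyr::bind_rows(
    per_locus_fst,
    tibble::tibble(locus = "over_loci", fst = multi$fst, chi2 = NA_real_,
                   df = NA_integer_, p = NA_real_, r = multi$r,
                   nbar = multi$nbar))

  dist <- population_distances(x$populations)
  pw <- pairwise_fst(freqs)
  ibd <- ibd_regression(pw, dist, method = "mantel",
                        n_perm = config$mantel_reps, seed = config$seed)
  alt <- altitude_correlation(pw, dist)

  meta <- tibble::tibble(
    package_version = as.character(utils::packageVersion("matearray")),
    seed = config$seed, alpha = config$alpha,
    screen_reps = config$screen_reps, n_bootstrap = config$n_bootstrap,
    mantel_reps = config$mantel_reps,
    pool_pollen_ovule = config$em$pool_pollen_ovule,
    constrain_t_to_unit = config$em$constrain_t_to_unit)

  out <- list(screen = screen, diversity = diversity, mating = mating,
              differentiation = differentiation,
              ibd = generics::tidy(ibd), pairwise_fst = pw,
              altitude = alt, fits = fits, ibd_fit = ibd, meta = meta)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("screen", "diversity", "mating", "differentiation",
                 "ibd", "pairwise_fst", "altitude", "meta")) {
      readr::write_tsv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".tsv")))
    }
    jsonlite::write_json(
      purrr::map(out[c("screen", "diversity", "mating", "differentiation",
                       "ibd", "pairwise_fst", "altitude", "meta")],
                 ~ .x),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
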