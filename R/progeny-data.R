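#' @importFrom rlang .data
#' @importFrom stats optimize setNames uniroot sd cor pchisq cor.test lm coef
#' @importFrom utils head
NULL

#' Reserved allele codes
#'
#' Allele codes are integer fragment sizes in base pairs. Two codes are
#' reserved: `MISSING_CODE` (0) marks an unscored allele and `NULL_CODE` (-1)
#' marks a non-amplifying (null) allele. A genotype with both alleles missing
#' is "untyped".
#'
#' @name allele-codes
#' @keywords internal
MISSING_CODE <- 0L

#' @rdname allele-codes
#' @keywords internal
NULL_CODE <- -1L

is_visible <- function(a) a > 0L

repeat_unit_from_motif <- function(motif) {
  # "(GA)n", "(GA)n(AG)n", "GA" -> length of the first repeated unit
  m <- stringr::str_match(motif, "\\(([ACGT]+)\\)")[, 2]
  out <- ifelse(is.na(m), nchar(gsub("[^ACGT]", "", motif)), nchar(m))
  as.integer(pmax(out, 1L))
}

canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

#' Build a locus registry table
#'
#' @param locus character vector of locus names.
#' @param repeat_motif repeat motif strings, e.g. `"(GA)n"`; the repeat unit
#'   length in bp is derived from the first parenthesised unit.
#' @param min_bp,max_bp allele size range in bp.
#' @param has_null logical; whether a null (non-amplifying) allele segregates
#'   at the locus (the 0/1 status written to the exchange format).
#' @param alleles list of integer vectors of registered allele codes (bp).
#' @return A tibble with one row per locus.
#' @export
locus_table <- function(locus, repeat_motif = "(GA)n", min_bp = NULL,
                        max_bp = NULL, has_null = FALSE, alleles = NULL) {
  n <- length(locus)
  repeat_motif <- rep_len(repeat_motif, n)
  has_null <- rep_len(has_null, n)
  if (is.null(alleles)) alleles <- rep(list(integer()), n)
  if (is.null(min_bp)) min_bp <- purrr::map_int(alleles, ~ if (length(.x)) min(.x) else NA_integer_)
  if (is.null(max_bp)) max_bp <- purrr::map_int(alleles, ~ if (length(.x)) max(.x) else NA_integer_)
  tibble::tibble(
    locus = as.character(locus),
    repeat_motif = repeat_motif,
    repeat_unit = repeat_unit_from_motif(repeat_motif),
    min_bp = as.integer(min_bp),
    max_bp = as.integer(max_bp),
    has_null = as.logical(has_null),
    alleles = purrr::map(alleles, ~ sort(unique(as.integer(.x))))
  )
}

derive_locus_table <- function(genotypes) {
  obs <- genotypes |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele") |>
    dplyr::filter(is_visible(.data$allele)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(alleles = list(sort(unique(.data$allele))), .groups = "drop")
  ord <- unique(genotypes$locus)
  obs <- obs[match(ord, obs$locus), ]
  locus_table(ord, alleles = obs$alleles)
}

#' Assemble a progeny-array dataset
#'
#' The central container for open-pollinated progeny-array data: a tidy
#' genotype table (one row per individual per locus), a locus registry and a
#' population metadata table. Rows are arranged canonically (population,
#' family, mothers before offspring, individual, locus in registry order) and
#' genotypes are stored with the smaller allele code first, so two datasets
#' with the same content compare equal.
#'
#' @param genotypes tibble with columns `population`, `family`, `individual`,
#'   `role` (`"mother"` or `"offspring"`), `locus`, `allele_a`, `allele_b`
#'   (integer bp; 0 = missing, -1 = null).
#' @param loci optional locus registry from [locus_table()]; derived from the
#'   data when absent. Alleles present in the data but not registered are
#'   added with a warning.
#' @param populations optional tibble with columns `population`, `latitude`,
#'   `longitude`, `altitude`.
#' @return An object of class `progeny_data`: a list with elements
#'   `genotypes`, `loci`, `populations`.
#' @export
progeny_data <- function(genotypes, loci = NULL, populations = NULL) {
  req <- c("population", "family", "individual", "role", "locus",
           "allele_a", "allele_b")
  miss <- setdiff(req, names(genotypes))
  if (length(miss)) {
    stop("genotypes is missing columns: ", paste(miss, collapse = ", "))
  }
  genotypes <- tibble::as_tibble(genotypes)[req]
  genotypes$allele_a <- as.integer(genotypes$allele_a)
  genotypes$allele_b <- as.integer(genotypes$allele_b)
  for (col in c("population", "family", "individual", "role", "locus")) {
    genotypes[[col]] <- as.character(genotypes[[col]])
  }
  if (!all(genotypes$role %in% c("mother", "offspring"))) {
    stop("role must be 'mother' or 'offspring'")
  }
  cp <- canonical_pair(genotypes$allele_a, genotypes$allele_b)
  genotypes$allele_a <- cp$a
  genotypes$allele_b <- cp$b

  if (is.null(loci)) loci <- derive_locus_table(genotypes)
  loci <- tibble::as_tibble(loci)

  # every individual must be typed at the full registry locus list
  per_ind <- genotypes |>
    dplyr::group_by(.data$population, .data$family, .data$individual) |>
    dplyr::summarise(n_loci = dplyr::n_distinct(.data$locus),
                     n_rows = dplyr::n(), .groups = "drop")
  bad <- per_ind$n_loci != nrow(loci) | per_ind$n_rows != nrow(loci)
  if (any(bad)) {
    b <- per_ind[bad, ][1, ]
    stop(sprintf(
      "structural error: individual '%s' (family '%s', population '%s') has %d locus rows; expected %d",
      b$individual, b$family, b$population, b$n_rows, nrow(loci)))
  }

  # register unseen alleles with a warning
  seen <- genotypes |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele") |>
    dplyr::filter(is_visible(.data$allele)) |>
    dplyr::distinct(.data$locus, .data$allele)
  extra <- character()
  for (i in seq_len(nrow(loci))) {
    sl <- seen$allele[seen$locus == loci$locus[i]]
    new <- setdiff(sl, loci$alleles[[i]])
    if (length(new)) {
      loci$alleles[[i]] <- sort(unique(c(loci$alleles[[i]], new)))
      extra <- c(extra, paste0(loci$locus[i], ": ", paste(new, collapse = ",")))
    }
  }
  if (length(extra)) {
    warning("unregistered alleles added to the locus registry (",
            paste(extra, collapse = "; "), ")")
  }
  loci$min_bp <- purrr::map2_int(loci$min_bp, loci$alleles,
                                 ~ min(.x, .y, na.rm = TRUE))
  loci$max_bp <- purrr::map2_int(loci$max_bp, loci$alleles,
                                 ~ max(.x, .y, na.rm = TRUE))

  if (is.null(populations)) {
    populations <- tibble::tibble(
      population = unique(genotypes$population),
      latitude = NA_real_, longitude = NA_real_, altitude = NA_real_)
  }
  populations <- tibble::as_tibble(populations)
  stopifnot(all(abs(populations$latitude) <= 90, na.rm = TRUE),
            all(abs(populations$longitude) <= 180, na.rm = TRUE))

  genotypes <- genotypes |>
    dplyr::mutate(locus = factor(.data$locus, levels = loci$locus)) |>
    dplyr::arrange(.data$population, .data$family,
                   .data$role != "mother", .data$individual, .data$locus) |>
    dplyr::mutate(locus = as.character(.data$locus))

  structure(list(genotypes = genotypes, loci = loci,
                 populations = populations),
            class = "progeny_data")
}

#' @export
print.progeny_data <- function(x, ...) {
  g <- x$genotypes
  n_fam <- dplyr::n_distinct(paste(g$population, g$family))
  n_off <- g |> dplyr::filter(.data$role == "offspring") |>
    dplyr::distinct(.data$population, .data$family, .data$individual) |> nrow()
  cat(sprintf(
    "<progeny_data> %d population(s), %d families, %d offspring, %d loci\n",
    nrow(x$populations), n_fam, n_off, nrow(x$loci)))
  invisible(x)
}

#' @method all.equal progeny_data
#' @export
all.equal.progeny_data <- function(target, current, ...) {
  all.equal(unclass(target), unclass(current), ...)
}

# ---- native tidy TSV dialect -------------------------------------------------

meta_path <- function(path) paste0(path, ".meta.yaml")

loci_to_meta <- function(loci) {
  purrr::pmap(loci, function(locus, repeat_motif, repeat_unit, min_bp, max_bp,
                             has_null, alleles) {
    list(locus = locus, repeat_motif = repeat_motif,
         min_bp = min_bp, max_bp = max_bp, has_null = has_null,
         alleles = as.integer(alleles))
  })
}

meta_to_loci <- function(meta) {
  locus_table(
    locus = purrr::map_chr(meta, "locus"),
    repeat_motif = purrr::map_chr(meta, "repeat_motif"),
    min_bp = purrr::map_int(meta, ~ as.integer(.x$min_bp)),
    max_bp = purrr::map_int(meta, ~ as.integer(.x$max_bp)),
    has_null = purrr::map_lgl(meta, "has_null"),
    alleles = purrr::map(meta, ~ as.integer(unlist(.x$alleles)))
  )
}

#' Write a progeny-array dataset
#'
#' Two on-disk dialects are supported. `"tsv"` writes the tidy genotype table
#' (tab-separated, one row per individual per locus) plus a YAML sidecar
#' (`<path>.meta.yaml`) holding the locus registry and population
#' coordinates/altitudes. `"mltr"` writes a single self-contained text file in
#' the package's MLTR-style exchange dialect: a locus block (name, motif, size
#' range, registered alleles), a `NULLS` line of 0/1 codes flagging null-allele
#' loci (1 = null present), then per-population `POP` blocks of `FAM` family
#' blocks with one maternal (`M`) and several offspring (`O`) genotype rows.
#' Both dialects round-trip through [read_progeny_dataset()].
#'
#' @param x a [progeny_data] object.
#' @param path output file path.
#' @param format `"tsv"` or `"mltr"`.
#' @return `path`, invisibly.
#' @export
write_progeny_dataset <- function(x, path, format = c("tsv", "mltr")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(x$genotypes, path)
    yaml::write_yaml(list(loci = loci_to_meta(x$loci),
                          populations = purrr::transpose(as.list(x$populations)) |>
                            purrr::map(~ .x)),
                     meta_path(path))
  } else {
    write_mltr_format(x, path)
  }
  invisible(path)
}

#' @rdname write_progeny_dataset
#' @export
write_mltr_format <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("MATEARRAY-MLTR 1")
  wl("LOCI ", nrow(x$loci))
  for (i in seq_len(nrow(x$loci))) {
    l <- x$loci[i, ]
    wl(paste(l$locus, l$repeat_motif, l$min_bp, l$max_bp,
             paste(l$alleles[[1]], collapse = ","), sep = "\t"))
  }
  wl("NULLS ", paste(as.integer(x$loci$has_null), collapse = " "))
  g <- x$genotypes
  for (p in x$populations$population) {
    pm <- x$populations[x$populations$population == p, ]
    gp <- g[g$population == p, ]
    fams <- unique(gp$family)
    wl(paste("POP", p, pm$latitude, pm$longitude, pm$altitude, length(fams),
             sep = "\t"))
    for (f in fams) {
      gf <- gp[gp$family == f, ]
      inds <- gf |> dplyr::distinct(.data$individual, .data$role)
      offs <- inds$individual[inds$role == "offspring"]
      moms <- inds$individual[inds$role == "mother"]
      wl(paste("FAM", f, length(offs), length(moms), sep = "\t"))
      write_ind <- function(tag, id) {
        gi <- gf[gf$individual == id, ]
        gi <- gi[match(x$loci$locus, gi$locus), ]
        wl(paste(tag, id,
                 paste(gi$allele_a, gi$allele_b, collapse = "\t"),
                 sep = "\t"))
      }
      for (m in moms) write_ind("M", m)
      for (o in offs) write_ind("O", o)
    }
  }
  invisible(path)
}

#' Read a progeny-array dataset
#'
#' Reads either dialect written by [write_progeny_dataset()]. For `"tsv"`,
#' a missing metadata sidecar is tolerated: the locus registry is then derived
#' from the data with a warning.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"mltr"`.
#' @return A [progeny_data] object.
#' @export
read_progeny_dataset <- function(path, format = c("tsv", "mltr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    genotypes <- readr::read_tsv(path, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   population = "c", family = "c",
                                   individual = "c", role = "c", locus = "c",
                                   allele_a = "i", allele_b = "i"))
    loci <- NULL
    populations <- NULL
    mp <- meta_path(path)
    if (file.exists(mp)) {
      meta <- yaml::read_yaml(mp)
      loci <- meta_to_loci(meta$loci)
      populations <- dplyr::bind_rows(purrr::map(meta$populations, tibble::as_tibble))
    } else {
      warning("no metadata sidecar found; deriving locus registry from data")
    }
    progeny_data(genotypes, loci, populations)
  } else {
    read_mltr(path)
  }
}

read_mltr <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "MATEARRAY-MLTR")) {
    stop("parse error at line 1: not a MATEARRAY-MLTR file")
  }
  n_loci <- as.integer(sub("LOCI ", "", lines[2]))
  if (is.na(n_loci)) stop("parse error at line 2: expected 'LOCI <n>'")
  lrows <- lines[3:(2 + n_loci)]
  lf <- strsplit(lrows, "\t", fixed = TRUE)
  loci <- locus_table(
    locus = purrr::map_chr(lf, 1),
    repeat_motif = purrr::map_chr(lf, 2),
    min_bp = as.integer(purrr::map_chr(lf, 3)),
    max_bp = as.integer(purrr::map_chr(lf, 4)),
    has_null = FALSE,
    alleles = purrr::map(lf, ~ as.integer(strsplit(.x[5], ",")[[1]]))
  )
  i <- 3 + n_loci
  nl <- lines[i]
  if (!startsWith(nl, "NULLS ")) stop("parse error at line ", i, ": expected NULLS")
  loci$has_null <- as.integer(strsplit(sub("NULLS ", "", nl), " ")[[1]]) == 1L
  i <- i + 1
  rows <- list()
  pops <- list()
  cur_pop <- NULL
  cur_fam <- NULL
  parse_geno <- function(fields, tag, lineno) {
    id <- fields[2]
    vals <- suppressWarnings(
      as.integer(unlist(strsplit(fields[-(1:2)], " ", fixed = TRUE))))
    if (length(vals) != 2 * n_loci || anyNA(vals)) {
      stop("structural error at line ", lineno, ": individual '", id,
           "' typed at ", floor(length(vals[!is.na(vals)]) / 2),
           " loci; expected ", n_loci)
    }
    tibble::tibble(
      population = cur_pop, family = cur_fam, individual = id,
      role = if (tag == "M") "mother" else "offspring",
      locus = loci$locus,
      allele_a = vals[seq(1, 2 * n_loci, 2)],
      allele_b = vals[seq(2, 2 * n_loci, 2)])
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "POP") {
      cur_pop <- f[2]
      pops[[length(pops) + 1]] <- tibble::tibble(
        population = f[2], latitude = as.numeric(f[3]),
        longitude = as.numeric(f[4]), altitude = as.numeric(f[5]))
    } else if (f[1] == "FAM") {
      cur_fam <- f[2]
    } else if (f[1] %in% c("M", "O")) {
      rows[[length(rows) + 1]] <- parse_geno(f, f[1], i)
    } else {
      stop("parse error at line ", i, ": unrecognised record '", f[1], "'")
    }
    i <- i + 1
  }
  progeny_data(dplyr::bind_rows(rows), loci, dplyr::bind_rows(pops))
}

# ---- validation --------------------------------------------------------------

# candidate true genotypes behind an observed phenotype (null masking)
true_genotypes_of_phenotype <- function(a, b, null_locus) {
  if (a == MISSING_CODE && b == MISSING_CODE) {
    if (null_locus) return(list(c(NULL_CODE, NULL_CODE))) else return(NULL)
  }
  if (a == b) {
    out <- list(c(a, a))
    if (null_locus) out <- c(out, list(sort(c(NULL_CODE, a))))
    return(out)
  }
  list(sort(c(a, b)))
}

mendel_compatible <- function(mother, offspring, null_locus) {
  gm <- true_genotypes_of_phenotype(mother[1], mother[2], null_locus)
  go <- true_genotypes_of_phenotype(offspring[1], offspring[2], null_locus)
  if (is.null(gm) || is.null(go)) return(TRUE)  # untyped: cannot test
  for (m in gm) for (o in go) {
    if (length(intersect(m, o)) >= 1) return(TRUE)
  }
  FALSE
}

#' Validate a progeny-array dataset
#'
#' Report-only diagnostics: per-locus allele counts, missing-data rates, and
#' mother-offspring Mendelian incompatibilities (an offspring sharing no
#' allele with its recorded mother at a locus, after accounting for possible
#' null alleles at null-flagged loci).
#'
#' @param x a [progeny_data] object.
#' @return A list of tibbles: `allele_counts`, `missing_rates`,
#'   `incompatibilities`.
#' @export
validate_progeny_data <- function(x) {
  g <- x$genotypes
  long <- g |>
    tidyr::pivot_longer(c("allele_a", "allele_b"), values_to = "allele")
  allele_counts <- long |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_alleles = dplyr::n_distinct(.data$allele[is_visible(.data$allele)]),
      .groups = "drop")
  missing_rates <- g |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      missing_rate = mean(.data$allele_a == MISSING_CODE &
                            .data$allele_b == MISSING_CODE),
      .groups = "drop")

  nulls <- setNames(x$loci$has_null, x$loci$locus)
  mothers <- g |> dplyr::filter(.data$role == "mother")
  offs <- g |> dplyr::filter(.data$role == "offspring")
  joined <- offs |>
    dplyr::inner_join(mothers |>
                        dplyr::select("population", "family", "locus",
                                      m_a = "allele_a", m_b = "allele_b"),
                      by = c("population", "family", "locus"))
  if (nrow(joined)) {
    bad <- !purrr::pmap_lgl(
      list(joined$m_a, joined$m_b, joined$allele_a, joined$allele_b,
           nulls[joined$locus]),
      function(ma, mb, oa, ob, nl) mendel_compatible(c(ma, mb), c(oa, ob), nl))
    incomp <- joined[bad, c("population", "family", "individual", "locus",
                            "allele_a", "allele_b", "m_a", "m_b")]
  } else {
    incomp <- tibble::tibble(population = character(), family = character(),
                             individual = character(), locus = character(),
                             allele_a = integer(), allele_b = integer(),
                             m_a = integer(), m_b = integer())
  }
  list(allele_counts = allele_counts, missing_rates = missing_rates,
       incompatibilities = tibble::as_tibble(incomp))
}
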