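# Mixed-mating model with correlated paternity for open-pollinated progeny
# arrays: Mendelian transition probabilities, null-allele-aware phenotype
# likelihoods, EM estimation of outcrossing rates / maternal inbreeding /
# pollen and ovule frequencies, two-stage profile extension allowing t > 1,
# pairwise composite-likelihood estimation of the correlations of paternity
# and of selfing, and bootstrap standard errors over progeny arrays.

# ---- Mendelian primitives ----------------------------------------------------

genotype_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

mask_pair <- function(m, k) {
  # observed phenotype of true allele pair (m, k) under null masking
  if (m == NULL_CODE && k == NULL_CODE) return(c(MISSING_CODE, MISSING_CODE))
  if (k == NULL_CODE) return(c(m, m))
  if (m == NULL_CODE) return(c(k, k))
  sort(c(m, k))
}

#' Offspring genotype probability under selfing
#'
#' Probability of an offspring genotype under self-fertilization of the
#' mother: random union of two maternal gametes. Genotypes are unordered
#' pairs of allele codes (null code -1 allowed); an offspring allele absent
#' from the mother gives probability 0.
#'
#' @param mother,offspring length-2 integer genotype vectors.
#' @return A probability.
#' @export
self_transition_prob <- function(mother, offspring) {
  key <- genotype_key(offspring[1], offspring[2])
  p <- 0
  for (g1 in mother) for (g2 in mother) {
    if (genotype_key(g1, g2) == key) p <- p + 0.25
  }
  p
}

#' Offspring genotype probability under outcrossing
#'
#' Maternal gamete (each maternal allele with probability 1/2) united with a
#' paternal allele drawn from the pollen allele frequencies.
#'
#' @param mother,offspring length-2 integer genotype vectors.
#' @param pollen_freqs named numeric vector of pollen allele frequencies
#'   (names are allele codes) summing to 1.
#' @return A probability.
#' @export
outcross_transition_prob <- function(mother, offspring, pollen_freqs) {
  key <- genotype_key(offspring[1], offspring[2])
  alle <- as.integer(names(pollen_freqs))
  p <- 0
  for (m in mother) {
    hit <- genotype_key(pmin(m, alle), pmax(m, alle)) == key
    p <- p + 0.5 * sum(pollen_freqs[hit])
  }
  p
}

#' Likelihood of an observed phenotype under the mixed-mating model
#'
#' Mixture `t * outcross + (1 - t) * self`, summed over the true genotypes
#' that map to the observed phenotype under null-allele masking: an apparent
#' homozygote (k, k) may be the true (k, k) or (k, null); an untyped
#' phenotype at a null-segregating locus is the true (null, null). `t` may
#' exceed 1 (the likelihood is then no longer a mixture but remains valid
#' while positive).
#'
#' @param observed length-2 integer observed phenotype (0 0 = untyped).
#' @param mother length-2 integer maternal genotype (may carry -1).
#' @param t outcrossing rate.
#' @param pollen_freqs named numeric vector over visible alleles, summing
#'   to 1; internally rescaled by `1 - null_freq` with a null class appended.
#' @param null_freq null-allele frequency in `[0, 1)`.
#' @return A probability (0 when the phenotype is incompatible with the
#'   mother under the model; 1 for an untyped phenotype at a null-free
#'   locus, which carries no information).
#' @export
phenotype_likelihood <- function(observed, mother, t, pollen_freqs,
                                 null_freq = 0) {
  stopifnot(t >= 0, null_freq >= 0, null_freq < 1)
  null_locus <- null_freq > 0
  q <- pollen_freqs * (1 - null_freq)
  if (null_locus) q <- c(q, setNames(null_freq, NULL_CODE))
  genos <- true_genotypes_of_phenotype(observed[1], observed[2], null_locus)
  if (is.null(genos)) return(1)  # untyped at a null-free locus: no information
  tot <- 0
  for (g in genos) {
    tot <- tot + t * outcross_transition_prob(mother, g, q) +
      (1 - t) * self_transition_prob(mother, g)
  }
  tot
}

# all observable phenotypes at a locus (visible unordered pairs + untyped)
enumerate_phenotypes <- function(alleles) {
  alleles <- sort(alleles)
  pairs <- which(upper.tri(diag(length(alleles)), diag = TRUE), arr.ind = TRUE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    c(alleles[pairs[i, 1]], alleles[pairs[i, 2]])
  })
  c(out, list(c(MISSING_CODE, MISSING_CODE)))
}

# maternal genotype prior with inbreeding F (Wright genotype proportions,
# clamped at a small floor since F < 0 can push rare-homozygote terms negative)
genotype_prior <- function(geno, o, fis) {
  a <- as.character(geno[1]); b <- as.character(geno[2])
  pa <- o[a]; pb <- o[b]
  if (is.na(pa) || is.na(pb)) return(1e-12)
  pr <- if (geno[1] == geno[2]) pa^2 + fis * pa * (1 - pa)
        else 2 * pa * pb * (1 - fis)
  max(pr, 1e-12)
}

# ---- EM data preparation -----------------------------------------------------

# candidate maternal genotypes at one locus given the recorded maternal
# phenotype; unknown mothers get all pairs of `support` alleles
mother_candidates <- function(mphen, null_locus, support) {
  if (is.null(mphen) || (mphen[1] == MISSING_CODE && mphen[2] == MISSING_CODE)) {
    alle <- support
    pairs <- which(upper.tri(diag(length(alle)), diag = TRUE), arr.ind = TRUE)
    return(lapply(seq_len(nrow(pairs)), function(i) {
      sort(c(alle[pairs[i, 1]], alle[pairs[i, 2]]))
    }))
  }
  true_genotypes_of_phenotype(mphen[1], mphen[2], null_locus)
}

# per-family, per-locus likelihood blocks:
#  S[gm, class], C[[gm]] (class x K), class_count, off_class (per offspring)
build_family_locus_block <- function(mphen, off_phen, null_locus, alleles) {
  K <- length(alleles)
  akey <- as.character(alleles)
  off_keys <- vapply(off_phen, function(g) paste(g[1], g[2]), "")
  typed <- vapply(off_phen, function(g) {
    !(g[1] == MISSING_CODE && g[2] == MISSING_CODE) || null_locus
  }, TRUE)
  keys <- unique(off_keys[typed])
  off_class <- ifelse(typed, match(off_keys, keys), NA_integer_)
  class_count <- as.numeric(tabulate(off_class[!is.na(off_class)],
                                     nbins = length(keys)))
  support_obs <- sort(unique(unlist(off_phen)))
  support_obs <- support_obs[support_obs > 0]
  # unknown mothers: enumerate the full allele universe at small loci, else
  # restrict to alleles seen in the family (documented truncation)
  support <- if (K <= 12 || !length(support_obs)) alleles
             else unique(c(support_obs, if (null_locus) NULL_CODE))
  gms <- mother_candidates(mphen, null_locus, support)
  nG <- length(gms)
  nC <- length(keys)
  S <- matrix(0, nG, nC)
  Clist <- vector("list", nG)
  class_genos <- lapply(keys, function(k) {
    v <- as.integer(strsplit(k, " ")[[1]])
    true_genotypes_of_phenotype(v[1], v[2], null_locus)
  })
  for (gi in seq_len(nG)) {
    gm <- gms[[gi]]
    Cm <- matrix(0, nC, K)
    for (ci in seq_len(nC)) {
      gset <- class_genos[[ci]]
      if (is.null(gset)) next
      S[gi, ci] <- sum(vapply(gset, function(g) {
        self_transition_prob(gm, g)
      }, 0))
      # a paternal allele k contributes 0.5 per maternal gamete m whenever
      # the true genotype (m, k) masks to this observed class
      for (m in gm) {
        masked <- vapply(alleles, function(k) {
          mp <- mask_pair(m, k)
          paste(mp[1], mp[2])
        }, "")
        Cm[ci, ] <- Cm[ci, ] + 0.5 * (masked == keys[ci])
      }
    }
    Clist[[gi]] <- Cm
  }
  list(gms = gms, S = S, C = Clist, class_count = class_count,
       off_class = off_class, n_classes = nC, n_gms = nG, akey = akey)
}

prep_mating_data <- function(x, population = NULL, null_loci = NULL) {
  pops <- unique(x$genotypes$population)
  population <- population %||% pops[1]
  g <- x$genotypes[x$genotypes$population == population, ]
  if (!nrow(g)) stop("population not found: ", population)
  loci <- x$loci
  if (is.null(null_loci)) null_loci <- loci$locus[loci$has_null]
  fams <- unique(g$family)
  if (length(fams) < 2) stop("need >= 2 families")
  universe <- purrr::map2(loci$alleles, loci$locus %in% null_loci,
                          ~ if (.y) c(.x, NULL_CODE) else .x)
  names(universe) <- loci$locus
  blocks <- vector("list", length(fams))
  names(blocks) <- fams
  off_ids <- list()
  for (f in fams) {
    gf <- g[g$family == f, ]
    mom <- gf[gf$role == "mother", ]
    offs <- gf[gf$role == "offspring", ]
    oid <- unique(offs$individual)
    off_ids[[f]] <- oid
    blocks[[f]] <- purrr::map(loci$locus, function(l) {
      ml <- mom[mom$locus == l, ]
      mphen <- if (nrow(ml)) c(ml$allele_a[1], ml$allele_b[1]) else NULL
      ol <- offs[offs$locus == l, ]
      ol <- ol[match(oid, ol$individual), ]
      off_phen <- purrr::map2(ol$allele_a, ol$allele_b, c)
      build_family_locus_block(mphen, off_phen, l %in% null_loci,
                               universe[[l]])
    })
    names(blocks[[f]]) <- loci$locus
  }
  list(population = population, families = fams, blocks = blocks,
       off_ids = off_ids, loci = loci, universe = universe,
       null_loci = null_loci,
       mothers_geno = g[g$role == "mother", ],
       offspring_geno = g[g$role == "offspring", ])
}

# flatten selected families (bootstrap-friendly) into per-locus arrays
assemble_structs <- function(prep, fam_sel = NULL) {
  fams <- fam_sel %||% prep$families
  loci <- prep$loci$locus
  n_off_per <- vapply(fams, function(f) length(prep$off_ids[[f]]), 0L)
  off_fam <- rep(seq_along(fams), n_off_per)
  n_off <- sum(n_off_per)
  off_offset <- c(0, cumsum(n_off_per))
  per_locus <- purrr::map(seq_along(loci), function(li) {
    K <- length(prep$universe[[li]])
    Cs <- list(); Ss <- list()
    row_gm <- integer(); row_class <- integer()
    gm_fam <- integer(); gm_geno <- list()
    class_fam <- integer(); class_count <- numeric()
    off_class <- rep(NA_integer_, n_off)
    g0 <- 0L; c0 <- 0L
    for (fi in seq_along(fams)) {
      b <- prep$blocks[[fams[fi]]][[li]]
      nG <- b$n_gms; nC <- b$n_classes
      if (nG == 0) next
      gm_fam <- c(gm_fam, rep(fi, nG))
      gm_geno <- c(gm_geno, b$gms)
      if (nC > 0) {
        class_fam <- c(class_fam, rep(fi, nC))
        class_count <- c(class_count, b$class_count)
        for (gi in seq_len(nG)) {
          Cs[[length(Cs) + 1]] <- b$C[[gi]]
          Ss[[length(Ss) + 1]] <- b$S[gi, ]
          row_gm <- c(row_gm, rep(g0 + gi, nC))
          row_class <- c(row_class, c0 + seq_len(nC))
        }
        oc <- b$off_class
        off_class[off_offset[fi] + seq_along(oc)] <-
          ifelse(is.na(oc), NA_integer_, c0 + oc)
      }
      g0 <- g0 + nG; c0 <- c0 + nC
    }
    list(K = K, alleles = prep$universe[[li]],
         C = if (length(Cs)) do.call(rbind, Cs) else matrix(0, 0, K),
         S = unlist(Ss) %||% numeric(),
         row_gm = row_gm, row_class = row_class,
         gm_fam = gm_fam, gm_geno = gm_geno,
         class_fam = class_fam, class_count = class_count,
         off_class = off_class, n_gm = g0, n_class = c0)
  })
  names(per_locus) <- loci
  list(per_locus = per_locus, fams = fams, off_fam = off_fam, n_off = n_off)
}

# ---- EM engine ---------------------------------------------------------------

#' EM fitting options for the mixed-mating model
#'
#' @param tol convergence tolerance on the log composite likelihood.
#' @param max_iter maximum EM iterations.
#' @param pool_pollen_ovule estimate a single shared allele-frequency vector
#'   for pollen and ovules (default `FALSE`: estimated separately).
#' @param constrain_t_to_unit keep outcrossing rates inside `[0, 1]`; the
#'   default `FALSE` allows estimates above 1 via a profile-likelihood
#'   extension after EM convergence.
#' @param t_init,F_init starting values.
#' @param update_freqs,update_F set `FALSE` to freeze allele frequencies or
#'   `F` at their starting values (diagnostics / oracle comparisons).
#' @return A list of options.
#' @export
em_options <- function(tol = 1e-6, max_iter = 500, pool_pollen_ovule = FALSE,
                       constrain_t_to_unit = FALSE, t_init = 0.9, F_init = 0,
                       update_freqs = TRUE, update_F = TRUE) {
  stopifnot(tol > 0, max_iter >= 1)
  list(tol = tol, max_iter = max_iter, pool_pollen_ovule = pool_pollen_ovule,
       constrain_t_to_unit = constrain_t_to_unit, t_init = t_init,
       F_init = F_init, update_freqs = update_freqs, update_F = update_F)
}

init_freqs <- function(prep, kind = c("pollen", "ovule")) {
  kind <- match.arg(kind)
  g <- if (kind == "ovule") prep$mothers_geno else prep$offspring_geno
  purrr::imap(prep$universe, function(alle, l) {
    counts <- rep(0.5, length(alle))
    names(counts) <- alle
    src <- if (!is.null(g) && nrow(g)) g[g$locus == l, ] else NULL
    vals <- if (!is.null(src)) c(src$allele_a, src$allele_b) else integer()
    vals <- vals[vals > 0]
    tb <- table(factor(vals, levels = alle))
    counts <- counts + as.numeric(tb)
    p <- counts / sum(counts)
    if (NULL_CODE %in% alle) {
      p <- p * 0.95 / sum(p[names(p) != as.character(NULL_CODE)])
      p[as.character(NULL_CODE)] <- 0.05
      p <- p / sum(p)
    }
    p
  })
}

logmix <- function(t, logO, logS) {
  a <- if (t > 0) log(t) + logO else rep(-Inf, length(logO))
  b <- if (t < 1) log(1 - t) + logS else rep(-Inf, length(logS))
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

# E-step for one locus at current params: gm posteriors, class-level
# posterior-averaged quantities
locus_estep <- function(ls, p, o, F, t) {
  if (ls$n_class == 0 || nrow(ls$C) == 0) {
    return(list(post_gm = rep(1, ls$n_gm), Sbar = numeric(), Obar = numeric(),
                Cbar = matrix(0, 0, ls$K), O_row = numeric(),
                prior_gm = vapply(ls$gm_geno, genotype_prior, 0, o = o, fis = F)))
  }
  O_row <- as.numeric(ls$C %*% p)
  mix <- t * O_row + (1 - t) * ls$S
  mix[mix < 1e-300] <- 1e-300
  llrow <- ls$class_count[ls$row_class] * log(mix)
  ll_gm <- rep(0, ls$n_gm)
  agg <- rowsum(llrow, ls$row_gm)
  ll_gm[as.integer(rownames(agg))] <- agg[, 1]
  prior_gm <- vapply(ls$gm_geno, genotype_prior, 0, o = o, fis = F)
  lp <- log(prior_gm) + ll_gm
  post_gm <- numeric(ls$n_gm)
  for (fi in unique(ls$gm_fam)) {
    idx <- which(ls$gm_fam == fi)
    z <- lp[idx] - max(lp[idx])
    w <- exp(z); post_gm[idx] <- w / sum(w)
  }
  wrow <- post_gm[ls$row_gm]
  Sbar <- numeric(ls$n_class); Obar <- numeric(ls$n_class)
  aggS <- rowsum(wrow * ls$S, ls$row_class)
  aggO <- rowsum(wrow * O_row, ls$row_class)
  Sbar[as.integer(rownames(aggS))] <- aggS[, 1]
  Obar[as.integer(rownames(aggO))] <- aggO[, 1]
  Cbar <- matrix(0, ls$n_class, ls$K)
  aggC <- rowsum(ls$C * wrow, ls$row_class)
  Cbar[as.integer(rownames(aggC)), ] <- aggC
  list(post_gm = post_gm, Sbar = Sbar, Obar = Obar, Cbar = Cbar,
       O_row = O_row, prior_gm = prior_gm)
}

# per-offspring multilocus log self/outcross likelihoods from E-step results
offspring_loglik <- function(st, es_list) {
  n <- st$n_off
  logS <- rep(0, n); logO <- rep(0, n)
  informative <- rep(FALSE, n)
  for (l in names(st$per_locus)) {
    ls <- st$per_locus[[l]]
    es <- es_list[[l]]
    oc <- ls$off_class
    ok <- !is.na(oc)
    if (!any(ok)) next
    s <- es$Sbar[oc[ok]]; o <- es$Obar[oc[ok]]
    logS[ok] <- logS[ok] + log(pmax(s, 1e-300))
    logO[ok] <- logO[ok] + log(pmax(o, 1e-300))
    informative[ok] <- TRUE
  }
  list(logS = logS, logO = logO, informative = informative)
}

profile_t <- function(logO, logS, constrain, weights = NULL) {
  # maximize sum w * log(t e^logO + (1-t) e^logS) in t
  w <- weights %||% rep(1, length(logO))
  keep <- is.finite(logO) | is.finite(logS)
  logO <- logO[keep]; logS <- logS[keep]; w <- w[keep]
  if (!length(logO)) return(NA_real_)
  obj <- function(t) {
    v <- sum(w * logmix_ext(t, logO, logS))
    if (is.finite(v)) v else -1e300
  }
  upper <- 1
  if (!constrain) {
    d <- logS - logO
    pos <- is.finite(d) & d > 0
    upper <- if (any(pos)) min(1 / (1 - exp(-d[pos])), 2) else 2
    upper <- min(upper, 2) - 1e-9
  }
  op <- optimize(obj, c(0, upper), maximum = TRUE, tol = 1e-9)
  # the optimum may sit at a boundary; compare explicitly
  cand <- c(op$maximum, 0, upper)
  cand[which.max(vapply(cand, obj, 0))]
}

logmix_ext <- function(t, logO, logS) {
  # valid for t outside [0,1] while the mixture stays positive
  if (t >= 0 && t <= 1) return(logmix(t, logO, logS))
  v <- t * exp(logO) + (1 - t) * exp(logS)
  out <- rep(-Inf, length(v))
  out[v > 0] <- log(v[v > 0])
  out
}

em_engine <- function(st, prep, options) {
  pollen <- init_freqs(prep, "pollen")
  ovule <- init_freqs(prep, "ovule")
  t <- min(max(options$t_init, 1e-3), 1 - 1e-3)
  F <- options$F_init
  ovule_prev <- NULL
  loci <- names(st$per_locus)
  trace <- numeric()
  converged <- FALSE
  es_list <- NULL
  for (iter in seq_len(options$max_iter)) {
    es_list <- purrr::map(loci, function(l) {
      locus_estep(st$per_locus[[l]], pollen[[l]], ovule[[l]], F, t)
    })
    names(es_list) <- loci
    ol <- offspring_loglik(st, es_list)
    lm_off <- logmix(t, ol$logO, ol$logS)
    # maternal observation probability under the prior (marginal over the
    # candidate set)
    ll_mom <- sum(purrr::map_dbl(loci, function(l) {
      ls <- st$per_locus[[l]]; es <- es_list[[l]]
      if (!ls$n_gm) return(0)
      sum(log(pmax(rowsum(es$prior_gm, ls$gm_fam)[, 1], 1e-300)))
    }))
    ll <- sum(lm_off[ol$informative]) + ll_mom
    trace <- c(trace, ll)
    # E: posterior selfing per offspring
    d <- ol$logS - ol$logO
    w <- (1 - t) / ((1 - t) + t * exp(-d))
    w[d == -Inf] <- 0
    w[d == Inf] <- 1
    w[!ol$informative] <- NA
    # M: t = mean posterior outcross fraction
    t_new <- mean(1 - w, na.rm = TRUE)
    t_new <- min(max(t_new, 1e-6), 1 - 1e-6)
    # M: frequencies
    if (options$update_freqs) {
      for (l in loci) {
        ls <- st$per_locus[[l]]
        es <- es_list[[l]]
        if (ls$n_class == 0) next
        oc <- ls$off_class
        ok <- !is.na(oc) & ol$informative
        if (!any(ok)) next
        u <- rowsum((1 - w[ok]), oc[ok])
        uc <- numeric(ls$n_class)
        uc[as.integer(rownames(u))] <- u[, 1]
        Obar <- pmax(es$Obar, 1e-300)
        counts <- pollen[[l]] * colSums(es$Cbar * (uc / Obar))
        counts <- pmax(counts, 1e-8)
        pollen[[l]] <- counts / sum(counts)
        # ovule frequencies from expected maternal allele counts
        mom_counts <- rep(1e-8, ls$K)
        names(mom_counts) <- names(pollen[[l]])
        for (gi in seq_len(ls$n_gm)) {
          for (a in ls$gm_geno[[gi]]) {
            ai <- match(as.character(a), as.character(ls$alleles))
            mom_counts[ai] <- mom_counts[ai] + es$post_gm[gi]
          }
        }
        ovule[[l]] <- mom_counts / sum(mom_counts)
        if (options$pool_pollen_ovule) {
          pooled <- counts / sum(counts) + mom_counts / sum(mom_counts)
          pooled <- pooled / sum(pooled)
          pollen[[l]] <- pooled
          ovule[[l]] <- pooled
        }
      }
    }
    # M: F from expected maternal genotype counts; the count-based ovule
    # update is the exact maximizer only at F = 0, so the joint (ovule, F)
    # update is accepted only when it improves the expected maternal term
    if (options$update_F) {
      mat_obj <- function(ov, Fv) {
        sum(purrr::map_dbl(loci, function(l) {
          ls <- st$per_locus[[l]]
          if (!ls$n_gm) return(0)
          es <- es_list[[l]]
          pr <- vapply(ls$gm_geno, genotype_prior, 0, o = ov[[l]], fis = Fv)
          sum(es$post_gm * log(pr))
        }))
      }
      F_new <- optimize(function(Fv) mat_obj(ovule, Fv), c(-0.95, 0.95),
                        maximum = TRUE, tol = 1e-6)$maximum
      if (mat_obj(ovule, F_new) >= mat_obj(ovule_prev %||% ovule, F)) {
        F <- F_new
      } else if (!is.null(ovule_prev)) {
        ovule <- ovule_prev
      }
    }
    ovule_prev <- ovule
    t <- t_new
    if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < options$tol) {
      converged <- TRUE
      break
    }
  }
  # final E-step at converged parameters
  es_list <- purrr::map(loci, function(l) {
    locus_estep(st$per_locus[[l]], pollen[[l]], ovule[[l]], F, t)
  })
  names(es_list) <- loci
  ol <- offspring_loglik(st, es_list)
  # profile maximization of t (multilocus), allowed past 1 if unconstrained
  t_m <- profile_t(ol$logO[ol$informative], ol$logS[ol$informative],
                   options$constrain_t_to_unit)
  # per-locus outcrossing rates with frozen frequencies
  t_by_locus <- purrr::map_dbl(loci, function(l) {
    ls <- st$per_locus[[l]]
    es <- es_list[[l]]
    oc <- ls$off_class
    ok <- !is.na(oc)
    if (!any(ok)) return(NA_real_)
    s <- es$Sbar[oc[ok]]; o <- es$Obar[oc[ok]]
    if (all(abs(s - o) < 1e-12)) return(NA_real_)
    profile_t(log(pmax(o, 1e-300)), log(pmax(s, 1e-300)),
              options$constrain_t_to_unit)
  })
  names(t_by_locus) <- loci
  ll_final <- sum(logmix_ext(min(t_m, 1), ol$logO, ol$logS)[ol$informative])
  list(t_m = t_m, t_by_locus = t_by_locus, F = F,
       pollen = pollen, ovule = ovule, es_list = es_list, ol = ol,
       trace = trace, converged = converged, n_iter = length(trace),
       loglik = ll_final)
}

# ---- correlation estimators --------------------------------------------------

# per-family outcross-pair quantities: for each sib pair, the ratio
# R = P(pair | same father) / P(pair | independent fathers), per locus and
# multilocus, plus posterior outcross weights
pair_ratios <- function(st, fit) {
  loci <- names(st$per_locus)
  d <- fit$ol$logS - fit$ol$logO
  t_m <- min(max(fit$t_m, 1e-6), 1 - 1e-6)
  w_out <- 1 / (1 + (1 - t_m) / t_m * exp(d))
  w_out[d == Inf] <- 0
  w_out[d == -Inf] <- 1
  pairs <- list()
  for (fi in seq_along(st$fams)) {
    off <- which(st$off_fam == fi & fit$ol$informative)
    if (length(off) < 2) next
    cmb <- utils::combn(off, 2)
    Rl <- matrix(NA_real_, ncol(cmb), length(loci))
    for (li in seq_along(loci)) {
      ls <- st$per_locus[[loci[li]]]
      es <- fit$es_list[[loci[li]]]
      p <- fit$pollen[[loci[li]]]
      oc <- ls$off_class
      for (pi in seq_len(ncol(cmb))) {
        i <- cmb[1, pi]; j <- cmb[2, pi]
        ci <- oc[i]; cj <- oc[j]
        if (is.na(ci) || is.na(cj)) next
        Ai <- es$Obar[ci]; Aj <- es$Obar[cj]
        if (Ai <= 0 || Aj <= 0) next
        B <- sum(p * es$Cbar[ci, ] * es$Cbar[cj, ])
        Rl[pi, li] <- (B + Ai * Aj) / (2 * Ai * Aj)
      }
    }
    pairs[[length(pairs) + 1]] <- list(
      Rl = Rl, w = w_out[cmb[1, ]] * w_out[cmb[2, ]],
      d_i = d[cmb[1, ]], d_j = d[cmb[2, ]])
  }
  pairs
}

maximize_rp <- function(R, w) {
  ok <- is.finite(R) & w > 1e-6
  R <- R[ok]; w <- w[ok]
  if (length(R) < 2 || all(abs(R - 1) < 1e-12)) return(NA_real_)
  lo <- -0.999; up <- 0.999
  if (any(R > 1)) lo <- max(lo, -1 / (max(R) - 1) + 1e-6)
  if (any(R < 1)) up <- min(up, 1 / (1 - min(R)) - 1e-6)
  if (lo >= up) return(NA_real_)
  obj <- function(r) sum(w * log(pmax(r * R + 1 - r, 1e-300)))
  op <- optimize(obj, c(lo, up), maximum = TRUE, tol = 1e-8)
  cand <- c(op$maximum, lo, up)
  cand[which.max(vapply(cand, obj, 0))]
}

estimate_paternity_correlation_internal <- function(st, fit) {
  pairs <- pair_ratios(st, fit)
  if (!length(pairs)) {
    return(list(r_p_m = NA_real_, r_p_s = NA_real_,
                r_p_by_locus = setNames(rep(NA_real_,
                                            length(st$per_locus)),
                                        names(st$per_locus))))
  }
  w <- unlist(purrr::map(pairs, "w"))
  Rl <- do.call(rbind, purrr::map(pairs, "Rl"))
  R_m <- apply(Rl, 1, function(r) prod(r[is.finite(r)]))
  n_inf <- apply(Rl, 1, function(r) sum(is.finite(r)))
  keep <- n_inf > 0
  r_p_m <- maximize_rp(R_m[keep], w[keep])
  r_p_by_locus <- apply(Rl, 2, maximize_rp, w = w)
  names(r_p_by_locus) <- names(st$per_locus)
  list(r_p_m = r_p_m, r_p_s = mean(r_p_by_locus, na.rm = TRUE),
       r_p_by_locus = r_p_by_locus)
}

estimate_selfing_correlation_internal <- function(st, fit) {
  s <- 1 - fit$t_m
  if (s <= 1e-6) return(NA_real_)
  d <- fit$ol$logS - fit$ol$logO
  pairs <- list()
  for (fi in seq_along(st$fams)) {
    off <- which(st$off_fam == fi & fit$ol$informative)
    if (length(off) < 2) next
    cmb <- utils::combn(off, 2)
    pairs[[length(pairs) + 1]] <- cbind(d[cmb[1, ]], d[cmb[2, ]])
  }
  if (!length(pairs)) return(NA_real_)
  D <- do.call(rbind, pairs)
  D <- D[is.finite(D[, 1]) & is.finite(D[, 2]), , drop = FALSE]
  if (nrow(D) < 2) return(NA_real_)
  lo <- max(-0.999, -s / (1 - s), -(1 - s) / s) + 1e-6
  obj <- function(r) {
    pss <- s^2 + r * s * (1 - s)
    poo <- (1 - s)^2 + r * s * (1 - s)
    pso <- s * (1 - s) * (1 - r)
    terms <- cbind(log(pmax(pss, 1e-300)) + D[, 1] + D[, 2],
                   log(pmax(pso, 1e-300)) + D[, 1],
                   log(pmax(pso, 1e-300)) + D[, 2],
                   log(pmax(poo, 1e-300)))
    m <- apply(terms, 1, max)
    sum(m + log(rowSums(exp(terms - m))))
  }
  op <- optimize(obj, c(lo, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  cand <- c(op$maximum, lo, 1 - 1e-6)
  cand[which.max(vapply(cand, obj, 0))]
}

selfing_posterior_matrix <- function(st, fit) {
  loci <- names(st$per_locus)
  W <- matrix(NA_real_, st$n_off, length(loci))
  for (li in seq_along(loci)) {
    ls <- st$per_locus[[loci[li]]]
    es <- fit$es_list[[loci[li]]]
    tl <- fit$t_by_locus[[loci[li]]]
    if (is.na(tl)) next
    tl <- min(max(tl, 1e-6), 1 - 1e-6)
    oc <- ls$off_class
    ok <- !is.na(oc)
    s <- es$Sbar[oc[ok]]; o <- es$Obar[oc[ok]]
    W[ok, li] <- (1 - tl) * s / pmax((1 - tl) * s + tl * o, 1e-300)
  }
  colnames(W) <- loci
  W
}

r_loci_from_posteriors <- function(W) {
  nl <- ncol(W)
  if (nl < 2) return(NA_real_)
  vals <- c()
  for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
    ok <- stats::complete.cases(W[, c(i, j)])
    if (sum(ok) < 3) next
    si <- sd(W[ok, i]); sj <- sd(W[ok, j])
    if (is.na(si) || is.na(sj) || si == 0 || sj == 0) next
    vals <- c(vals, cor(W[ok, i], W[ok, j]))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# ---- user-facing fit ---------------------------------------------------------

point_estimates <- function(st, prep, options) {
  fit <- em_engine(st, prep, options)
  rp <- estimate_paternity_correlation_internal(st, fit)
  r_s <- estimate_selfing_correlation_internal(st, fit)
  W <- selfing_posterior_matrix(st, fit)
  r_loci <- r_loci_from_posteriors(W)
  t_s <- mean(fit$t_by_locus, na.rm = TRUE)
  est <- c(t_m = fit$t_m, t_s = t_s, alpha_m = 1 - fit$t_m,
           alpha_s = 1 - t_s, tm_minus_ts = fit$t_m - t_s, F = fit$F,
           r_s = r_s, r_p_m = rp$r_p_m, r_p_s = rp$r_p_s,
           rps_minus_rpm = rp$r_p_s - rp$r_p_m, r_loci = r_loci)
  list(est = est, fit = fit, rp = rp, W = W)
}

#' Fit the mixed-mating model to one population
#'
#' Estimates the multilocus and mean single-locus outcrossing rates, maternal
#' inbreeding, pollen and ovule allele frequencies, and the correlations of
#' paternity and of selfing from a population of open-pollinated families.
#'
#' The fit proceeds in stages: (1) EM for the multilocus mixture (posterior
#' selfed/outcrossed status per offspring; allele-frequency and `F` updates
#' from expected counts), with maternal genotypes integrated over their
#' null-masking-compatible candidates; (2) profile maximization of the exact
#' log-likelihood in `t` with frequencies frozen, which permits estimates
#' above 1 unless `constrain_t_to_unit`; (3) per-locus outcrossing rates the
#' same way; (4) correlations of paternity (`r_p`) and of selfing (`r_s`,
#' `r_loci`) by pairwise composite likelihood over sib pairs; (5) optional
#' bootstrap over families (progeny arrays) for standard errors.
#'
#' @param x a [progeny_data] object.
#' @param population population name (default: the first).
#' @param screen optional screening result from
#'   [screen_genotyping_errors()]; its per-population null flags override the
#'   locus registry's `has_null`.
#' @param options an [em_options()] list.
#' @param n_bootstrap bootstrap replicates (0 = no standard errors).
#' @param seed seed for the bootstrap resampling.
#' @return A `mating_fit` object; see [tidy.mating_fit()] and
#'   [glance.mating_fit()].
#' @export
fit_mating_system <- function(x, population = NULL, screen = NULL,
                              options = em_options(), n_bootstrap = 0,
                              seed = 1) {
  pops <- unique(x$genotypes$population)
  population <- population %||% pops[1]
  null_loci <- NULL
  if (!is.null(screen)) {
    sc <- screen[screen$population == population, ]
    null_loci <- sc$locus[!is.na(sc$null_flag) & sc$null_flag]
  }
  prep <- prep_mating_data(x, population, null_loci)
  poly <- vapply(prep$universe, function(a) sum(a > 0) >= 2, TRUE)
  if (!any(poly)) stop("all loci are monomorphic; cannot estimate")
  st <- assemble_structs(prep)
  pe <- point_estimates(st, prep, options)

  se <- setNames(rep(NA_real_, length(pe$est)), names(pe$est))
  n_failed <- 0L
  boot <- NULL
  if (n_bootstrap > 0) {
    set.seed(seed)
    fams <- prep$families
    boot <- matrix(NA_real_, n_bootstrap, length(pe$est),
                   dimnames = list(NULL, names(pe$est)))
    for (b in seq_len(n_bootstrap)) {
      sel <- sample(fams, length(fams), replace = TRUE)
      res <- tryCatch(
        point_estimates(assemble_structs(prep, sel), prep, options)$est,
        error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L else boot[b, ] <- res
    }
    se <- apply(boot, 2, sd, na.rm = TRUE)
  }

  out <- list(
    population = population,
    estimates = tibble::tibble(term = names(pe$est),
                               estimate = unname(pe$est),
                               se = unname(se[names(pe$est)])),
    t_s_by_locus = pe$fit$t_by_locus,
    r_p_by_locus = pe$rp$r_p_by_locus,
    pollen_freqs = pe$fit$pollen,
    ovule_freqs = pe$fit$ovule,
    loglik = pe$fit$loglik,
    loglik_trace = pe$fit$trace,
    converged = pe$fit$converged,
    n_iter = pe$fit$n_iter,
    n_families = length(prep$families),
    n_offspring = st$n_off,
    n_bootstrap = as.integer(n_bootstrap),
    n_bootstrap_failed = n_failed,
    bootstrap_estimates = boot,
    options = options)
  class(out) <- "mating_fit"
  out
}

#' @export
print.mating_fit <- function(x, ...) {
  cat(sprintf("<mating_fit> population %s: %d families, %d offspring\n",
              x$population, x$n_families, x$n_offspring))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-14s %8.3f%s\n", e$term[i], e$estimate[i],
                if (!is.na(e$se[i])) sprintf(" (%.3f)", e$se[i]) else ""))
  }
  cat(sprintf("  loglik %.3f, %s after %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Derived mating-system quantities
#'
#' Selfing rates `alpha = 1 - t`, the biparental-inbreeding indicator
#' `t_m - t_s`, the pollen-pool substructure indicator `r_p_s - r_p_m`, and
#' the effective number of pollen donors `N_ep = 1 / r_p_m` (reported missing
#' when `r_p_m <= 0`).
#'
#' @param estimates a `mating_fit`, or a named vector/list with `t_m`, `t_s`,
#'   `r_p_m`, `r_p_s`.
#' @return A tibble with columns `term`, `value`.
#' @export
derived_quantities <- function(estimates) {
  e <- if (inherits(estimates, "mating_fit")) {
    setNames(estimates$estimates$estimate, estimates$estimates$term)
  } else unlist(estimates)
  need <- function(k) if (k %in% names(e)) unname(e[k]) else NA_real_
  t_m <- need("t_m"); t_s <- need("t_s")
  r_p_m <- need("r_p_m"); r_p_s <- need("r_p_s")
  tibble::tibble(
    term = c("alpha_m", "alpha_s", "tm_minus_ts", "rps_minus_rpm", "N_ep"),
    value = c(1 - t_m, 1 - t_s, t_m - t_s, r_p_s - r_p_m,
              ifelse(!is.na(r_p_m) && r_p_m > 0, 1 / r_p_m, NA_real_)))
}

#' Equilibrium outcrossing rate from an inbreeding coefficient
#'
#' Under equilibrium between selfing and outcrossing the outcrossing rate is
#' `t = (1 - F_is) / (1 + F_is)`. Values above 1 (negative `F_is`) are
#' returned as-is with a `flagged` marker.
#'
#' @param F_is inbreeding coefficient, > -1.
#' @return A tibble with `t` and `flagged` (TRUE when `t > 1`).
#' @export
equilibrium_outcrossing <- function(F_is) {
  if (any(F_is <= -1)) stop("F_is must be > -1")
  t <- (1 - F_is) / (1 + F_is)
  tibble::tibble(F_is = F_is, t = t, flagged = t > 1)
}

#' Posterior over maternal genotypes from a progeny array
#'
#' For each locus, the posterior over candidate maternal genotypes: a point
#' mass where the recorded maternal genotype is unambiguous, a
#' null-masking-compatible candidate set where it is an apparent homozygote
#' at a null-flagged locus, and (for unrecorded mothers) all genotypes over
#' the alleles seen in the family, weighted by the inbreeding-adjusted prior
#' `prior(genotype | ovule_freqs, F)` times the family likelihood under the
#' mixed-mating model.
#'
#' @param x a [progeny_data] object.
#' @param population,family identifiers.
#' @param t outcrossing rate used in the family likelihood.
#' @param F maternal inbreeding coefficient for the prior.
#' @param ovule_freqs,pollen_freqs optional per-locus named frequency
#'   vectors; defaults are observed-count frequencies.
#' @return A tibble: `locus`, `allele_a`, `allele_b`, `posterior`.
#' @export
infer_maternal_genotypes <- function(x, population = NULL, family,
                                     t = 0.9, F = 0, ovule_freqs = NULL,
                                     pollen_freqs = NULL) {
  population <- population %||% x$populations$population[1]
  prep <- prep_mating_data_family(x, population, family)
  pollen <- pollen_freqs %||% init_freqs(prep, "pollen")
  ovule <- ovule_freqs %||% init_freqs(prep, "ovule")
  out <- purrr::map(names(prep$universe), function(l) {
    b <- prep$blocks[[1]][[l]]
    if (!b$n_gms) return(NULL)
    prior <- vapply(b$gms, genotype_prior, 0, o = ovule[[l]], fis = F)
    ll <- vapply(seq_len(b$n_gms), function(gi) {
      if (!b$n_classes) return(0)
      O <- as.numeric(b$C[[gi]] %*% pollen[[l]])
      mix <- t * O + (1 - t) * b$S[gi, ]
      sum(b$class_count * log(pmax(mix, 1e-300)))
    }, 0)
    lp <- log(prior) + ll
    if (all(!is.finite(lp))) {
      stop("no maternal genotype has positive likelihood at locus ", l,
           " in family ", family)
    }
    post <- exp(lp - max(lp)); post <- post / sum(post)
    tibble::tibble(locus = l,
                   allele_a = purrr::map_int(b$gms, 1),
                   allele_b = purrr::map_int(b$gms, 2),
                   posterior = post)
  })
  dplyr::bind_rows(out)
}

prep_mating_data_family <- function(x, population, family) {
  g <- x$genotypes[x$genotypes$population == population &
                     x$genotypes$family == family, ]
  if (!nrow(g)) stop("family not found: ", family)
  offs <- g[g$role == "offspring", ]
  if (!nrow(offs)) stop("family has no offspring")
  x2 <- x
  x2$genotypes <- x$genotypes[x$genotypes$population == population, ]
  prep <- prep_mating_data_single(x2, population, family)
  prep
}

prep_mating_data_single <- function(x, population, family) {
  loci <- x$loci
  null_loci <- loci$locus[loci$has_null]
  universe <- purrr::map2(loci$alleles, loci$locus %in% null_loci,
                          ~ if (.y) c(.x, NULL_CODE) else .x)
  names(universe) <- loci$locus
  g <- x$genotypes[x$genotypes$population == population, ]
  gf <- g[g$family == family, ]
  mom <- gf[gf$role == "mother", ]
  offs <- gf[gf$role == "offspring", ]
  oid <- unique(offs$individual)
  blocks <- list(purrr::map(loci$locus, function(l) {
    ml <- mom[mom$locus == l, ]
    mphen <- if (nrow(ml)) c(ml$allele_a[1], ml$allele_b[1]) else NULL
    ol <- offs[offs$locus == l, ]
    ol <- ol[match(oid, ol$individual), ]
    build_family_locus_block(mphen, purrr::map2(ol$allele_a, ol$allele_b, c),
                             l %in% null_loci, universe[[l]])
  }))
  names(blocks[[1]]) <- loci$locus
  list(population = population, families = family, blocks = blocks,
       off_ids = setNames(list(oid), family), loci = loci,
       universe = universe, null_loci = null_loci,
       mothers_geno = g[g$role == "mother", ],
       offspring_geno = g[g$role == "offspring", ])
}

#' Bootstrap standard errors over progeny arrays
#'
#' Resamples families (progeny arrays) with replacement, re-runs an
#' estimator, and reports per-parameter standard deviations of the bootstrap
#' estimates. Replicates where the estimator fails are dropped and counted.
#'
#' @param x a [progeny_data] object (one population).
#' @param estimator function taking a [progeny_data] and returning a named
#'   numeric vector.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed (same seed, same resampling).
#' @return A list: `se` (named vector), `estimates` (B x p matrix),
#'   `n_failed`.
#' @export
bootstrap_se <- function(x, estimator, B = 1000, seed = 1) {
  stopifnot(B >= 2)
  g <- x$genotypes
  pop <- unique(g$population)
  stopifnot(length(pop) == 1)
  fams <- unique(g$family)
  set.seed(seed)
  res <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    sel <- sample(fams, length(fams), replace = TRUE)
    pieces <- purrr::imap(sel, function(f, i) {
      gi <- g[g$family == f, ]
      gi$family <- sprintf("bs%03d", i)
      gi$individual <- paste0(gi$individual, "_bs", i)
      gi
    })
    xb <- progeny_data(dplyr::bind_rows(pieces), x$loci, x$populations)
    r <- tryCatch(estimator(xb), error = function(e) NULL)
    if (is.null(r)) n_failed <- n_failed + 1L else res[[b]] <- r
  }
  res <- purrr::compact(res)
  M <- do.call(rbind, res)
  list(se = apply(M, 2, sd), estimates = M, n_failed = n_failed)
}
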