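#' Priors for the pedigree sampler
#'
#' Broad lognormal priors on the number of unsampled candidate parents of
#' each sex, with means in the plausible range for a small re-establishing
#' wolf population (more unsampled males than females, reflecting
#' male-biased long-distance immigration), and beta priors on the two
#' genotyping-error classes.
#'
#' @param male_mu,male_sigma Lognormal parameters for unsampled males
#'   (default `log(7)`, 0.5).
#' @param female_mu,female_sigma Lognormal parameters for unsampled females
#'   (default `log(2)`, 0.5).
#' @param e1_shape,e2_shape Beta shape pairs for the dropout (E1) and
#'   miscall (E2) rates (defaults `c(4, 100)` and `c(2, 100)`).
#' @return A list of class `ped_priors`.
#' @export
ped_priors <- function(male_mu = log(7), male_sigma = 0.5,
                       female_mu = log(2), female_sigma = 0.5,
                       e1_shape = c(4, 100), e2_shape = c(2, 100)) {
  stopifnot(male_sigma > 0, female_sigma > 0,
            all(e1_shape > 0), all(e2_shape > 0))
  structure(list(male_mu = male_mu, male_sigma = male_sigma,
                 female_mu = female_mu, female_sigma = female_sigma,
                 e1_shape = e1_shape, e2_shape = e2_shape),
            class = "ped_priors")
}

#' MCMC settings for the pedigree sampler
#'
#' @param iterations Total sweeps (default 30000).
#' @param burn_in Sweeps discarded (default 3000).
#' @param thinning Keep every `thinning`-th sweep after burn-in (default 2).
#' @param seed Optional RNG seed for a reproducible chain.
#' @param max_mismatch_loci Candidate parents mismatching the offspring at
#'   more than this many loci are excluded (default 4).
#' @param target_accept Acceptance window the size-update step is tuned
#'   into during burn-in (default 0.30--0.50).
#' @param update_sizes Update the unsampled population sizes (`TRUE`) or
#'   hold them fixed at `size_init`.
#' @param size_init Named starting values `c(male = , female = )` for the
#'   unsampled sizes (defaults: the prior medians).
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 30000L, burn_in = 3000L,
                          thinning = 2L, seed = NULL,
                          max_mismatch_loci = 4L,
                          target_accept = c(0.30, 0.50),
                          update_sizes = TRUE,
                          size_init = c(male = 7, female = 2)) {
  stopifnot(burn_in < iterations, thinning >= 1L,
            length(target_accept) == 2L, all(size_init >= 0))
  if (isTRUE(update_sizes) && any(size_init <= 0)) {
    abort("size_init must be positive when update_sizes = TRUE")
  }
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = seed,
                 max_mismatch_loci = as.integer(max_mismatch_loci),
                 target_accept = target_accept,
                 update_sizes = isTRUE(update_sizes),
                 size_init = size_init),
            class = "mcmc_settings")
}

# Build per-offspring candidate sets after the exclusion filter.
# Returns list(dam = list of id vectors, sire = ...).
build_candidates <- function(ids, gt_wide, sexes, cohorts, deaths,
                             max_mismatch_loci, min_breeding_age = 2L,
                             allowed = NULL) {
  n <- length(ids)
  a1 <- gt_wide$a1; a2 <- gt_wide$a2
  dam <- vector("list", n)
  sire <- vector("list", n)
  for (oi in seq_len(n)) {
    keep <- rep(TRUE, n)
    keep[oi] <- FALSE
    if (!is.null(allowed)) keep <- keep & (ids %in% allowed)
    # genotype mismatch count (no allele in common at a typed shared locus)
    sh <- !is.na(a1[oi, ])
    if (any(sh)) {
      for (ci in which(keep)) {
        s2 <- sh & !is.na(a1[ci, ])
        if (!any(s2)) next
        mm <- locus_mismatches(a1[oi, s2], a2[oi, s2], a1[ci, s2],
                               a2[ci, s2])
        if (sum(mm == 2L) > max_mismatch_loci) keep[ci] <- FALSE
      }
    }
    # age / death constraints when cohorts known
    oc <- cohorts[[oi]]
    if (!is.na(oc)) {
      cb <- cohorts
      too_young <- !is.na(cb) & (cb + min_breeding_age > oc)
      dead <- !is.na(deaths) & (deaths < oc)
      keep <- keep & !too_young & !dead
    }
    dam[[oi]] <- ids[keep & (is.na(sexes) | sexes != "M")]
    sire[[oi]] <- ids[keep & (is.na(sexes) | sexes != "F")]
  }
  list(dam = dam, sire = sire)
}

# genotype long table -> aligned character matrices (ids x loci)
genotypes_wide <- function(genotypes, ids, loci) {
  a1 <- matrix(NA_character_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  g <- dplyr::filter(genotypes, !is.na(.data$allele1) &
                       !is.na(.data$allele2) &
                       .data$individual_id %in% ids &
                       .data$locus %in% loci)
  if (nrow(g) > 0L) {
    a1[cbind(g$individual_id, g$locus)] <- pmin(as.character(g$allele1),
                                                as.character(g$allele2))
    a2[cbind(g$individual_id, g$locus)] <- pmax(as.character(g$allele1),
                                                as.character(g$allele2))
  }
  list(a1 = a1, a2 = a2)
}

#' Sample the posterior distribution of pedigrees
#'
#' Gibbs sampling over per-offspring (dam, sire) assignments, with
#' candidate parents enumerated per offspring (after the mismatch, sex,
#' age and survival exclusion filters) plus an UNSAMPLED category whose
#' prior weight scales with the current unsampled population size of that
#' sex. The unsampled male and female sizes are updated by random-walk
#' Metropolis-Hastings under lognormal priors, with the proposal step
#' auto-tuned during burn-in. Pedigree legality is enforced at every
#' iteration by rejecting cycle-creating proposals. Offspring are swept in
#' reverse detection-date order, so later-observed individuals are visited
#' (and hence fitted) as offspring first.
#'
#' @param individuals Tibble with `individual_id` and optionally `sex`,
#'   `first_seen`, `birth_year`, `death_year`, `source_class`.
#' @param genotypes Long consensus genotype table (`individual_id`,
#'   `locus`, `allele1`, `allele2`).
#' @param freqs Allele-frequency table covering all genotype alleles.
#' @param rates Error-rate table (`locus`, `source_class`, `E1`, `E2`).
#' @param priors A [ped_priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @param candidates Optional restriction of candidate parents to a vector
#'   of ids ("possible breeders"); default all individuals.
#' @return An object of class `ped_posterior`: per-offspring posterior
#'   pair frequencies, candidate sets, chains of the unsampled sizes and
#'   log-likelihood, and achieved acceptance rates. A warning is issued if
#'   tuning did not reach the target acceptance window.
#' @export
sample_pedigree <- function(individuals, genotypes, freqs, rates,
                            priors = ped_priors(),
                            settings = mcmc_settings(),
                            candidates = NULL) {
  assert_cols(individuals, "individual_id", "individuals")
  ids <- as.character(individuals$individual_id)
  n <- length(ids)
  if (n == 0L) abort("no individuals")
  freqs <- validate_frequencies(freqs)
  lms <- locus_models(freqs)
  loci <- names(lms)

  sexes <- if ("sex" %in% names(individuals)) {
    s <- as.character(individuals$sex)
    s[s %in% c("UNKNOWN", "")] <- NA
    s
  } else rep(NA_character_, n)
  cohorts <- if ("birth_year" %in% names(individuals)) {
    as.integer(individuals$birth_year)
  } else rep(NA_integer_, n)
  deaths <- if ("death_year" %in% names(individuals)) {
    as.integer(individuals$death_year)
  } else rep(NA_integer_, n)
  class_of <- if ("source_class" %in% names(individuals)) {
    setNames(ifelse(is.na(individuals$source_class), "SCAT",
                    as.character(individuals$source_class)), ids)
  } else setNames(rep("SCAT", n), ids)

  gt_wide <- genotypes_wide(genotypes, ids, loci)
  cand <- build_candidates(ids, gt_wide, sexes, cohorts, deaths,
                           settings$max_mismatch_loci,
                           allowed = candidates)

  gt_idx <- index_genotypes(genotypes, lms)
  pair_ll <- precompute_pair_logliks(ids, gt_idx, lms, rates, class_of,
                                     cand$dam, cand$sire)
  # scale per offspring to avoid underflow; constant factors cancel in the
  # conditional
  pair_lik <- lapply(pair_ll, function(L) exp(L - max(L)))

  # reverse detection order: later-observed first
  sweep_order <- if ("first_seen" %in% names(individuals)) {
    order(individuals$first_seen, decreasing = TRUE) - 1L
  } else seq_len(n) - 1L

  dam_idx <- lapply(cand$dam, function(v) match(v, ids) - 1L)
  sire_idx <- lapply(cand$sire, function(v) match(v, ids) - 1L)

  res <- local_seed(settings$seed,
    gibbs_pedigree_chain(pair_lik, dam_idx, sire_idx,
                         as.integer(sweep_order),
                         priors$female_mu, priors$female_sigma,
                         priors$male_mu, priors$male_sigma,
                         settings$size_init[["female"]],
                         settings$size_init[["male"]],
                         settings$update_sizes,
                         settings$iterations, settings$burn_in,
                         settings$thinning,
                         settings$target_accept[1L],
                         settings$target_accept[2L]))

  if (settings$update_sizes) {
    accs <- c(res$accept_female, res$accept_male)
    lo <- settings$target_accept[1L]; hi <- settings$target_accept[2L]
    if (any(!is.na(accs) & (accs < lo - 0.05 | accs > hi + 0.05))) {
      warn(sprintf(paste0("size-update acceptance outside target window: ",
                          "female %.2f, male %.2f"), accs[1L], accs[2L]))
    }
  }

  n_kept <- length(res$N_female)
  freq <- lapply(seq_len(n), function(i) {
    m <- res$counts[[i]] / n_kept
    dimnames(m) <- list(c(cand$dam[[i]], UNSAMPLED),
                        c(cand$sire[[i]], UNSAMPLED))
    m
  })
  structure(list(
    offspring = ids,
    pair_freq = freq,
    dam_candidates = cand$dam,
    sire_candidates = cand$sire,
    chains = tibble::tibble(sample = seq_len(n_kept),
                            N_unsampled_female = res$N_female,
                            N_unsampled_male = res$N_male,
                            loglik = res$loglik),
    acceptance = c(female = res$accept_female, male = res$accept_male),
    settings = settings, priors = priors),
    class = "ped_posterior")
}

#' @export
print.ped_posterior <- function(x, ...) {
  cat(sprintf(paste0("<ped_posterior> %d offspring, %d kept samples ",
                     "(iterations %d, burn-in %d, thin %d)\n"),
              length(x$offspring), nrow(x$chains),
              x$settings$iterations, x$settings$burn_in,
              x$settings$thinning))
  invisible(x)
}

#' Extract the modal pedigree from a posterior
#'
#' Per offspring, the most frequently sampled (dam, sire) pair. Ties are
#' broken conservatively towards pairs containing UNSAMPLED slots, then
#' lexicographically. If the modal pairs jointly form an illegal pedigree
#' (possible since modes are taken per offspring), a greedy repair walks
#' the offspring of each cycle in decreasing pair probability and replaces
#' assignments by the best legal alternative; repaired rows are flagged.
#'
#' @param posterior A `ped_posterior`.
#' @return A pedigree tibble with `id`, `dam`, `sire`, `dam_prob`,
#'   `sire_prob` (marginal support for the chosen parent), `pair_prob`,
#'   `flag` (`""`, `TIE`, `REPAIRED`).
#' @export
modal_pedigree <- function(posterior) {
  stopifnot(inherits(posterior, "ped_posterior"))
  ids <- posterior$offspring
  pick_best <- function(m, exclude = character(0)) {
    f <- m
    if (length(exclude) > 0L) {
      f[rownames(f) %in% exclude, ] <- -1
      f[, colnames(f) %in% exclude] <- -1
    }
    best <- max(f)
    hits <- which(f == best, arr.ind = TRUE)
    tie <- nrow(hits) > 1L
    if (tie) {
      dn <- rownames(f)[hits[, 1L]]
      sn <- colnames(f)[hits[, 2L]]
      n_uns <- (dn == UNSAMPLED) + (sn == UNSAMPLED)
      o <- order(-n_uns, dn, sn)
      hits <- hits[o[1L], , drop = FALSE]
    }
    list(dam = rownames(f)[hits[1L, 1L]], sire = colnames(f)[hits[1L, 2L]],
         prob = best, tie = tie)
  }
  rows <- lapply(seq_along(ids), function(i) {
    m <- posterior$pair_freq[[i]]
    b <- pick_best(m)
    tibble::tibble(id = ids[i], dam = b$dam, sire = b$sire,
                   dam_prob = sum(m[b$dam, ]), sire_prob = sum(m[, b$sire]),
                   pair_prob = b$prob,
                   flag = if (b$tie) "TIE" else "")
  })
  ped <- dplyr::bind_rows(rows)
  ped$dam[ped$dam == UNSAMPLED] <- UNSAMPLED
  ped$sire[ped$sire == UNSAMPLED] <- UNSAMPLED

  # greedy legality repair
  guard <- 0L
  repeat {
    chk <- is_legal(ped)
    if (chk$legal || guard > length(ids)) break
    guard <- guard + 1L
    cyc <- strsplit(chk$violations$detail[chk$violations$type == "CYCLE"][1L],
                    " -> ", fixed = TRUE)[[1]]
    # reassign the cycle member whose current pair has the lowest support
    probs <- ped$pair_prob[match(cyc, ped$id)]
    victim <- cyc[which.min(probs)]
    vi <- match(victim, ids)
    m <- posterior$pair_freq[[vi]]
    b <- pick_best(m, exclude = setdiff(cyc, victim))
    ri <- match(victim, ped$id)
    ped$dam[ri] <- b$dam; ped$sire[ri] <- b$sire
    ped$pair_prob[ri] <- b$prob
    ped$dam_prob[ri] <- sum(m[b$dam, ])
    ped$sire_prob[ri] <- sum(m[, b$sire])
    ped$flag[ri] <- paste0(ped$flag[ri],
                           if (nzchar(ped$flag[ri])) ";REPAIRED"
                           else "REPAIRED")
  }
  ped
}

#' @export
tidy.ped_posterior <- function(x, ...) {
  purrr::map2_dfr(x$offspring, x$pair_freq, function(id, m) {
    d <- as.data.frame.table(m, responseName = "posterior",
                             stringsAsFactors = FALSE)
    names(d)[1:2] <- c("dam", "sire")
    d$id <- id
    tibble::as_tibble(d[d$posterior > 0, c("id", "dam", "sire",
                                           "posterior")])
  })
}

#' @export
glance.ped_posterior <- function(x, ...) {
  tibble::tibble(
    n_offspring = length(x$offspring),
    n_samples = nrow(x$chains),
    iterations = x$settings$iterations,
    burn_in = x$settings$burn_in,
    thinning = x$settings$thinning,
    accept_female = unname(x$acceptance["female"]),
    accept_male = unname(x$acceptance["male"]),
    mean_N_unsampled_female = mean(x$chains$N_unsampled_female),
    mean_N_unsampled_male = mean(x$chains$N_unsampled_male))
}

#' @export
autoplot.ped_posterior <- function(object, ...) {
  d <- tidyr::pivot_longer(object$chains,
                           cols = c("N_unsampled_female",
                                    "N_unsampled_male"),
                           names_to = "parameter")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "kept sample", y = "unsampled population size")
}
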