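#' Estimate per-locus genotyping error rates from replicates and trios
#'
#' Posterior estimation of the dropout (E1) and miscall (E2) rate per locus
#' by Metropolis-Hastings under beta priors, holding a partial pedigree
#' fixed. The likelihood combines two sources of information: concordance
#' among repeated observations of the same individual (all replicate PCRs
#' of all samples assigned to it share one latent true genotype), and
#' Mendelian consistency with the fixed parent-offspring links, which set
#' the prior over each individual's latent genotype (transmission from the
#' parents' consensus genotypes where both were assigned confidently,
#' Hardy-Weinberg otherwise).
#'
#' @param replicates Replicate observation table (`sample_id`, `locus`,
#'   `replicate`, `allele1`, `allele2`).
#' @param membership Tibble `sample_id`, `individual_id` linking samples to
#'   identified individuals (from [cluster_samples()]).
#' @param freqs Allele-frequency table.
#' @param pedigree Optional fixed pedigree tibble (`id`, `dam`, `sire`) --
#'   typically the high-confidence links of a preliminary fit.
#' @param genotypes Consensus genotypes of the individuals (needed when
#'   `pedigree` is given).
#' @param metadata Optional sample metadata with `source_class`; only
#'   classes in `classes` are used (faecal samples by default, the class
#'   with enough repeats to inform the rates).
#' @param classes Source classes used (default `"SCAT"`).
#' @param priors A [ped_priors()] (its beta shapes are used).
#' @param init Chain starting value for both rates (default 0.1, high but
#'   realistic, so parameter space is explored from above).
#' @param iterations,burn_in Chain length per locus (defaults 4000 / 1000).
#' @param seed Optional RNG seed.
#' @return Tibble per locus: posterior mean and central 95% interval for
#'   `E1` and `E2`, `n_obs` (replicate observations used) and `flag`
#'   (`PRIOR_ONLY` where the locus carried no data).
#' @export
estimate_error_rates <- function(replicates, membership, freqs,
                                 pedigree = NULL, genotypes = NULL,
                                 metadata = NULL, classes = "SCAT",
                                 priors = ped_priors(), init = 0.1,
                                 iterations = 4000L, burn_in = 1000L,
                                 seed = NULL) {
  assert_cols(replicates, c("sample_id", "locus", "allele1", "allele2"),
              "replicates")
  assert_cols(membership, c("sample_id", "individual_id"), "membership")
  freqs <- validate_frequencies(freqs)
  lms <- locus_models(freqs)

  reps <- replicates
  if (!is.null(metadata) && "source_class" %in% names(metadata)) {
    keep <- metadata$sample_id[metadata$source_class %in% classes]
    reps <- dplyr::filter(reps, .data$sample_id %in% keep)
  }
  reps <- reps |>
    dplyr::inner_join(membership, by = "sample_id") |>
    dplyr::filter(!is.na(.data$allele1) & !is.na(.data$allele2))

  ids <- sort(unique(membership$individual_id))
  gt_idx <- if (!is.null(genotypes)) index_genotypes(genotypes, lms)

  ped_map <- NULL
  if (!is.null(pedigree)) {
    ped <- as_pedigree(pedigree)
    ped_map <- list(dam = setNames(ped$dam, ped$id),
                    sire = setNames(ped$sire, ped$id))
  }

  a1 <- priors$e1_shape[1L]; b1 <- priors$e1_shape[2L]
  a2 <- priors$e2_shape[1L]; b2 <- priors$e2_shape[2L]

  local_seed(seed, {
    out <- lapply(names(lms), function(lc) {
      lm <- lms[[lc]]
      d <- reps[reps$locus == lc, ]
      n_obs <- nrow(d)
      if (n_obs == 0L) {
        return(tibble::tibble(
          locus = lc,
          E1_mean = a1 / (a1 + b1), E1_lo = qbeta(0.025, a1, b1),
          E1_hi = qbeta(0.975, a1, b1),
          E2_mean = a2 / (a2 + b2), E2_lo = qbeta(0.025, a2, b2),
          E2_hi = qbeta(0.975, a2, b2),
          n_obs = 0L, flag = "PRIOR_ONLY"))
      }
      og <- gt_index(lm, d$allele1, d$allele2)
      ind <- sort(unique(d$individual_id))
      C <- matrix(0, length(ind), lm$G)
      tab <- table(factor(d$individual_id, ind), factor(og, seq_len(lm$G)))
      C[] <- as.numeric(tab)

      # latent-genotype prior per individual: Mendelian from fixed parents
      # where available, HWE otherwise
      log_prior <- matrix(rep(log(lm$hwe), each = length(ind)),
                          length(ind), lm$G)
      if (!is.null(ped_map) && !is.null(gt_idx)) {
        for (ii in seq_along(ind)) {
          id <- ind[ii]
          dam <- ped_map$dam[id]; sire <- ped_map$sire[id]
          tv <- function(p) {
            if (is.na(p) || !is_sampled_parent(p)) return(lm$f)
            g <- gt_idx[[lc]][p]
            if (is.na(g)) return(lm$f)
            lm$Tr[g, ]
          }
          if (!is.na(dam) || !is.na(sire)) {
            o <- outer(tv(unname(dam)), tv(unname(sire)))
            m <- o + t(o)
            pr <- m[cbind(lm$g1, lm$g2)]
            hom <- lm$g1 == lm$g2
            pr[hom] <- diag(o)[lm$g1[hom]]
            pr[pr <= 0] <- 1e-12
            log_prior[ii, ] <- log(pr)
          }
        }
      }

      loglik <- function(E1, E2) {
        D <- obs_matrix(lm, E1, E2)
        lD <- log(pmax(D, 1e-300))
        sum(row_logsumexp(log_prior + C %*% lD))
      }
      logpost <- function(x) {
        E1 <- stats::plogis(x[1L]); E2 <- stats::plogis(x[2L])
        loglik(E1, E2) +
          dbeta(E1, a1, b1, log = TRUE) + log(E1 * (1 - E1)) +
          dbeta(E2, a2, b2, log = TRUE) + log(E2 * (1 - E2))
      }

      x <- rep(stats::qlogis(init), 2L)
      lp <- logpost(x)
      step <- c(0.4, 0.4)
      keep_mat <- matrix(NA_real_, iterations - burn_in, 2L)
      acc <- c(0L, 0L); tries <- c(0L, 0L)
      for (it in seq_len(iterations)) {
        for (j in 1:2) {
          prop <- x
          prop[j] <- prop[j] + step[j] * rnorm(1)
          lp_new <- logpost(prop)
          tries[j] <- tries[j] + 1L
          if (log(runif(1)) < lp_new - lp) {
            x <- prop; lp <- lp_new; acc[j] <- acc[j] + 1L
          }
        }
        if (it <= burn_in && it %% 100L == 0L) {
          r <- acc / pmax(tries, 1L)
          step <- step * ifelse(r > 0.5, 1.3, ifelse(r < 0.3, 1 / 1.3, 1))
          acc[] <- 0L; tries[] <- 0L
        }
        if (it > burn_in) keep_mat[it - burn_in, ] <- stats::plogis(x)
      }
      tibble::tibble(
        locus = lc,
        E1_mean = mean(keep_mat[, 1L]),
        E1_lo = quantile(keep_mat[, 1L], 0.025, names = FALSE),
        E1_hi = quantile(keep_mat[, 1L], 0.975, names = FALSE),
        E2_mean = mean(keep_mat[, 2L]),
        E2_lo = quantile(keep_mat[, 2L], 0.025, names = FALSE),
        E2_hi = quantile(keep_mat[, 2L], 0.975, names = FALSE),
        n_obs = n_obs, flag = "")
    })
    dplyr::bind_rows(out)
  })
}

#' Convert estimated rates to the per-locus rate table used by the sampler
#'
#' @param estimates Output of [estimate_error_rates()].
#' @param tissue_E1,tissue_E2 Constant rates applied to tissue/secretion
#'   samples (from prior work; such samples are too few to estimate rates).
#' @return Error-rate table with one `SCAT` row per locus (posterior mean)
#'   and one `TISSUE_SECRETION` row per locus.
#' @export
rates_from_estimates <- function(estimates, tissue_E1 = 0.01,
                                 tissue_E2 = 0.005) {
  dplyr::bind_rows(
    tibble::tibble(locus = estimates$locus, source_class = "SCAT",
                   E1 = estimates$E1_mean, E2 = estimates$E2_mean),
    tibble::tibble(locus = estimates$locus,
                   source_class = "TISSUE_SECRETION",
                   E1 = tissue_E1, E2 = tissue_E2))
}
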