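# Mendelian transmission and trio observation likelihoods.
#
# Candidate parents enter the parentage likelihood through the posterior of
# their true genotype given their observed genotype (HWE prior x observation
# density), so sampled and UNSAMPLED candidates are on a common scale:
#   L(pair) = P(obs_offspring | obs_dam, obs_sire)
#           = prod_loci sum_{g_o,g_d,g_s} P(obs_o | g_o) T(g_o | g_d, g_s)
#                         P(g_d | obs_d) P(g_s | obs_s)
# with P(g | obs) ~ HWE(g) D[obs, g] for sampled candidates and HWE(g) for
# UNSAMPLED or untyped loci. Loci at which the offspring is untyped
# contribute a factor of 1.

#' Mendelian transmission probability
#'
#' Probability of an offspring genotype given two parental genotypes under
#' autosomal Mendelian segregation. An `"UNSAMPLED"` parent contributes an
#' allele drawn from population frequencies (Hardy-Weinberg).
#'
#' @param offspring Length-2 character vector of allele labels.
#' @param dam,sire Length-2 allele vectors, or the string `"UNSAMPLED"`.
#' @param locus_freqs Allele-frequency rows for the locus.
#' @return A probability.
#' @examples
#' lf <- tibble::tibble(allele = c("A", "B"), frequency = c(0.7, 0.3))
#' mendelian_transmission(c("A", "B"), c("A", "A"), "UNSAMPLED", lf)
#' @export
mendelian_transmission <- function(offspring, dam, sire, locus_freqs) {
  o <- order(locus_freqs$allele)
  lm <- locus_model(as.character(locus_freqs$allele)[o],
                    locus_freqs$frequency[o])
  tvec <- function(p) {
    if (identical(p, UNSAMPLED)) return(lm$f)
    i <- match(as.character(p), lm$alleles)
    if (anyNA(i)) abort("parent allele not in locus allele set")
    v <- rep(0, lm$k)
    v[i[1L]] <- v[i[1L]] + 0.5
    v[i[2L]] <- v[i[2L]] + 0.5
    v
  }
  td <- tvec(dam); ts <- tvec(sire)
  oi <- match(as.character(offspring), lm$alleles)
  if (anyNA(oi)) abort("offspring allele not in locus allele set")
  if (oi[1L] == oi[2L]) td[oi[1L]] * ts[oi[2L]]
  else td[oi[1L]] * ts[oi[2L]] + td[oi[2L]] * ts[oi[1L]]
}

# ---- internal: per-individual genotype-state weights -------------------

# For one locus model and observation matrix D, the column vector over true
# genotypes used for a candidate parent (posterior given its observation)
# or for the UNSAMPLED category (HWE).
parent_state_weights <- function(lm, D, obs_g) {
  if (is.na(obs_g)) return(lm$hwe)
  w <- lm$hwe * D[obs_g, ]
  s <- sum(w)
  if (s <= 0) return(lm$hwe)  # observation impossible under model: fall back
  w / s
}

# Genotype tables to indexed per-locus observation structure.
# genotypes: individual_id, locus, allele1, allele2 (consensus calls).
index_genotypes <- function(genotypes, lms) {
  g <- dplyr::filter(genotypes, !is.na(.data$allele1) &
                       !is.na(.data$allele2))
  out <- list()
  for (lc in names(lms)) {
    d <- g[g$locus == lc, ]
    if (nrow(d) == 0L) {
      out[[lc]] <- setNames(integer(0), character(0))
    } else {
      out[[lc]] <- setNames(gt_index(lms[[lc]], d$allele1, d$allele2),
                            d$individual_id)
    }
  }
  out
}

#' Parent-pair observation likelihood
#'
#' Log-likelihood of an offspring's observed multilocus genotype given the
#' observed genotypes of a candidate parent pair, integrating over true
#' genotypes under the dropout/miscall error model (see the model notes
#' above). `"UNSAMPLED"` parents are integrated over Hardy-Weinberg
#' genotype frequencies. Loci untyped in the offspring contribute 1.
#'
#' @param offspring,dam,sire Long genotype tables (`locus`, `allele1`,
#'   `allele2`), or `"UNSAMPLED"` for either parent.
#' @param freqs Allele-frequency table.
#' @param rates Error-rate table ([error_rates()]); one row per locus. When
#'   per-class rates differ, pass the class-appropriate subset per
#'   individual via `dam_rates`/`sire_rates`.
#' @param dam_rates,sire_rates Optional class-specific rate tables for the
#'   candidate parents (default: same as `rates`).
#' @return Log-likelihood (a scalar).
#' @export
parent_pair_likelihood <- function(offspring, dam, sire, freqs, rates,
                                   dam_rates = rates, sire_rates = rates) {
  lms <- locus_models(freqs)
  rate_row <- function(r, lc) {
    x <- r[r$locus == lc, ]
    if (nrow(x) == 0L) abort(paste0("no error rates for locus ", lc))
    x[1L, ]
  }
  gt_of <- function(tbl, lc) {
    if (identical(tbl, UNSAMPLED)) return(NA_integer_)
    d <- tbl[tbl$locus == lc & !is.na(tbl$allele1) & !is.na(tbl$allele2), ]
    if (nrow(d) == 0L) return(NA_integer_)
    gt_index(lms[[lc]], d$allele1[1L], d$allele2[1L])
  }
  ll <- 0
  for (lc in names(lms)) {
    lm <- lms[[lc]]
    og <- gt_of(offspring, lc)
    if (is.na(og)) next
    ro <- rate_row(rates, lc)
    Do <- obs_matrix(lm, ro$E1, ro$E2)
    rd <- rate_row(dam_rates, lc)
    rs <- rate_row(sire_rates, lc)
    wd <- parent_state_weights(lm, obs_matrix(lm, rd$E1, rd$E2),
                               gt_of(dam, lc))
    ws <- parent_state_weights(lm, obs_matrix(lm, rs$E1, rs$E2),
                               gt_of(sire, lc))
    # B[a, b] = P(obs_o | true offspring formed from alleles a, b)
    B <- matrix(Do[og, lm$pair_to_g], lm$k, lm$k)
    M <- lm$Tr %*% B %*% t(lm$Tr)     # G x G over (dam, sire) true genotypes
    ll <- ll + log(drop(wd %*% M %*% ws))
  }
  ll
}

#' Candidate-parent exclusion filter
#'
#' A candidate is retained as a potential parent of an offspring unless it
#' mismatches the offspring (no allele in common) at more than
#' `max_mismatch_loci` shared typed loci, is of the wrong sex for the role,
#' is known to have died before the offspring's conception, or was younger
#' than the minimum breeding age in the offspring's cohort (when cohorts are
#' known).
#'
#' @param offspring_gt,candidate_gt Long genotype tables (`locus`,
#'   `allele1`, `allele2`).
#' @param max_mismatch_loci Opposing-homozygote style mismatch tolerance
#'   (default 4).
#' @param role `"dam"` or `"sire"`, checked against `candidate_sex` when
#'   given.
#' @param candidate_sex `"M"`, `"F"` or `NA`.
#' @param offspring_cohort,candidate_birth Optional years for the age check.
#' @param candidate_death Optional death year; a candidate dead strictly
#'   before the offspring's birth year is excluded.
#' @param min_breeding_age Minimum age at reproduction (default 2).
#' @return `TRUE` if the candidate is retained.
#' @export
exclusion_filter <- function(offspring_gt, candidate_gt,
                             max_mismatch_loci = 4L, role = NULL,
                             candidate_sex = NA,
                             offspring_cohort = NA, candidate_birth = NA,
                             candidate_death = NA, min_breeding_age = 2L) {
  if (!is.null(role) && !is.na(candidate_sex)) {
    if (role == "dam" && candidate_sex == "M") return(FALSE)
    if (role == "sire" && candidate_sex == "F") return(FALSE)
  }
  if (!is.na(offspring_cohort)) {
    if (!is.na(candidate_birth) &&
        candidate_birth + min_breeding_age > offspring_cohort) return(FALSE)
    if (!is.na(candidate_death) && candidate_death < offspring_cohort) {
      return(FALSE)
    }
  }
  m <- dplyr::inner_join(
    dplyr::filter(offspring_gt, !is.na(.data$allele1)),
    dplyr::filter(candidate_gt, !is.na(.data$allele1)),
    by = "locus", suffix = c("_o", "_c"))
  if (nrow(m) == 0L) return(TRUE)
  mm <- locus_mismatches(as.character(m$allele1_o), as.character(m$allele2_o),
                         as.character(m$allele1_c), as.character(m$allele2_c))
  sum(mm == 2L) <= max_mismatch_loci
}

# ---- internal: bulk pair log-likelihood precomputation -----------------

# Precompute, for every offspring, the matrix of pair log-likelihoods over
# (dam candidates + UNSAMPLED) x (sire candidates + UNSAMPLED). Inputs are
# indexed structures; class_of maps individual -> source class for rate
# lookup. Returns list(pair_ll = list of matrices, dam_ids, sire_ids).
precompute_pair_logliks <- function(ids, gt_idx, lms, rates, class_of,
                                    dam_cand, sire_cand) {
  n <- length(ids)
  classes <- unique(class_of)
  # observation matrices per locus x class
  Dlist <- lapply(names(lms), function(lc) {
    out <- list()
    for (cl in classes) {
      r <- rates[rates$locus == lc & rates$source_class == cl, ]
      if (nrow(r) == 0L) r <- rates[rates$locus == lc, ][1L, ]
      out[[cl]] <- obs_matrix(lms[[lc]], r$E1[1L], r$E2[1L])
    }
    out
  })
  names(Dlist) <- names(lms)

  # per-locus matrix of candidate state weights (rows = individuals + UNS)
  state_w <- lapply(names(lms), function(lc) {
    lm <- lms[[lc]]
    W <- matrix(0, n + 1L, lm$G)
    for (i in seq_len(n)) {
      D <- Dlist[[lc]][[class_of[[ids[i]]]]]
      og <- gt_idx[[lc]][ids[i]]
      W[i, ] <- parent_state_weights(lm, D, unname(og))
    }
    W[n + 1L, ] <- lm$hwe
    rownames(W) <- c(ids, UNSAMPLED)
    W
  })
  names(state_w) <- names(lms)

  pair_ll <- vector("list", n)
  for (oi in seq_len(n)) {
    dc <- c(dam_cand[[oi]], UNSAMPLED)
    sc <- c(sire_cand[[oi]], UNSAMPLED)
    L <- matrix(0, length(dc), length(sc), dimnames = list(dc, sc))
    for (lc in names(lms)) {
      lm <- lms[[lc]]
      og <- gt_idx[[lc]][ids[oi]]
      if (is.na(og)) next
      Do <- Dlist[[lc]][[class_of[[ids[oi]]]]]
      B <- matrix(Do[og, lm$pair_to_g], lm$k, lm$k)
      M <- lm$Tr %*% B %*% t(lm$Tr)
      Wd <- state_w[[lc]][dc, , drop = FALSE]
      Ws <- state_w[[lc]][sc, , drop = FALSE]
      contrib <- Wd %*% M %*% t(Ws)
      contrib[contrib <= 0] <- 1e-300
      L <- L + log(contrib)
    }
    pair_ll[[oi]] <- L
  }
  pair_ll
}
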