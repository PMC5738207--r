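# Two-stage generative genotyping-error model.
#
# Stage 1 (allelic dropout, rate E1): for a true heterozygote, with
# probability E1 one of the two alleles -- chosen uniformly -- fails to
# amplify and the sample presents as an apparent homozygote. Homozygotes are
# unaffected by dropout.
# Stage 2 (stochastic miscall, rate E2): each apparent allele copy is
# independently misread with probability E2; the misread value is drawn from
# the other alleles of the locus, by default proportional to their population
# frequency.

#' Build a per-locus, per-source-class error-rate table
#'
#' @param loci Character vector of locus ids.
#' @param E1 Allelic dropout probability (recycled per locus).
#' @param E2 Per-allele miscall probability (recycled per locus).
#' @param source_class Sample class the rates apply to (`"SCAT"` or
#'   `"TISSUE_SECRETION"`).
#' @return Tibble `locus`, `source_class`, `E1`, `E2`.
#' @export
error_rates <- function(loci, E1 = 0.04, E2 = 0.022,
                        source_class = "SCAT") {
  stopifnot(all(E1 >= 0 & E1 < 1), all(E2 >= 0 & E2 < 1))
  tidyr::expand_grid(locus = loci, source_class = source_class) |>
    dplyr::mutate(E1 = rep_len(E1, dplyr::n()),
                  E2 = rep_len(E2, dplyr::n()))
}

# ---- internal locus machinery -----------------------------------------

# A "locus model": allele labels, frequencies, the unordered genotype table
# and lookups used throughout the likelihood code.
locus_model <- function(alleles, f) {
  k <- length(alleles)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  # row = allele1 index (<= allele2 index)
  g1 <- idx[, 1L]
  g2 <- idx[, 2L]
  G <- length(g1)
  key <- paste0(alleles[g1], "/", alleles[g2])
  pair_to_g <- matrix(0L, k, k)
  pair_to_g[cbind(g1, g2)] <- seq_len(G)
  pair_to_g[cbind(g2, g1)] <- seq_len(G)
  hwe <- ifelse(g1 == g2, f[g1]^2, 2 * f[g1] * f[g2])
  # transmission matrix: P(transmit allele a | genotype g)
  Tr <- matrix(0, G, k)
  Tr[cbind(seq_len(G), g1)] <- Tr[cbind(seq_len(G), g1)] + 0.5
  Tr[cbind(seq_len(G), g2)] <- Tr[cbind(seq_len(G), g2)] + 0.5
  list(alleles = alleles, f = f, k = k, G = G, g1 = g1, g2 = g2,
       key = key, pair_to_g = pair_to_g, hwe = hwe, Tr = Tr)
}

locus_models <- function(freqs) {
  freqs <- validate_frequencies(freqs)
  lapply(split(freqs, freqs$locus), function(d) {
    o <- order(d$allele)
    locus_model(d$allele[o], d$frequency[o])
  })
}

# Observation density matrix D[obs_g, true_g] for one locus under (E1, E2).
obs_matrix <- function(lm, E1, E2, miscall = c("frequency", "uniform")) {
  miscall <- match.arg(miscall)
  k <- lm$k; G <- lm$G
  # per-copy read distribution: C[true_allele, read_allele]
  if (k == 1L) {
    C <- matrix(1, 1L, 1L)
  } else {
    w <- if (miscall == "frequency") lm$f else rep(1, k)
    C <- matrix(rep(w, each = k), k, k)
    diag(C) <- 0
    C <- C / rowSums(C) * E2
    diag(C) <- 1 - E2
  }
  # apparent genotype -> observed genotype matrix: A[app_g, obs_g]
  A <- matrix(0, G, G)
  for (g in seq_len(G)) {
    p <- C[lm$g1[g], ]
    q <- C[lm$g2[g], ]
    o <- outer(p, q)
    m <- o + t(o)
    probs <- m[cbind(lm$g1, lm$g2)]
    probs[lm$g1 == lm$g2] <- diag(o)[lm$g1[lm$g1 == lm$g2]]
    A[g, ] <- probs
  }
  # true genotype -> apparent genotype (dropout stage)
  D <- matrix(0, G, G, dimnames = list(lm$key, lm$key))
  for (g in seq_len(G)) {
    if (lm$g1[g] == lm$g2[g]) {
      app <- A[g, ]
    } else {
      h1 <- lm$pair_to_g[lm$g1[g], lm$g1[g]]
      h2 <- lm$pair_to_g[lm$g2[g], lm$g2[g]]
      app <- (1 - E1) * A[g, ] + (E1 / 2) * A[h1, ] + (E1 / 2) * A[h2, ]
    }
    D[, g] <- app  # column = true genotype, row = observed genotype
  }
  D
}

# resolve a genotype (character allele pair) to a genotype index
gt_index <- function(lm, a1, a2) {
  i <- match(as.character(a1), lm$alleles)
  j <- match(as.character(a2), lm$alleles)
  if (anyNA(c(i, j))) {
    abort(paste0("allele not in locus allele set: ",
                 paste(setdiff(c(a1, a2), lm$alleles), collapse = ", ")))
  }
  lm$pair_to_g[cbind(i, j)]
}

# ---- exported operations ----------------------------------------------

#' Distribution of observed genotypes given a true genotype
#'
#' @param true_genotype Length-2 character vector of allele labels.
#' @param locus_freqs Allele-frequency rows for the locus (`allele`,
#'   `frequency`), defining the locus allele set.
#' @param E1 Allelic dropout probability.
#' @param E2 Per-allele miscall probability.
#' @param miscall `"frequency"` (default) draws the misread allele
#'   proportional to population frequency among the other alleles;
#'   `"uniform"` draws it uniformly.
#' @return Tibble of unordered observed genotypes with `allele1`, `allele2`,
#'   `prob`; probabilities sum to 1.
#' @examples
#' lf <- tibble::tibble(allele = c("A", "B"), frequency = c(0.5, 0.5))
#' observation_distribution(c("A", "B"), lf, E1 = 0.1, E2 = 0)
#' @export
observation_distribution <- function(true_genotype, locus_freqs,
                                     E1, E2, miscall = "frequency") {
  stopifnot(length(true_genotype) == 2L, E1 >= 0, E1 < 1, E2 >= 0, E2 < 1)
  o <- order(locus_freqs$allele)
  lm <- locus_model(as.character(locus_freqs$allele)[o],
                    locus_freqs$frequency[o])
  D <- obs_matrix(lm, E1, E2, miscall)
  g <- gt_index(lm, true_genotype[1L], true_genotype[2L])
  tibble::tibble(allele1 = lm$alleles[lm$g1], allele2 = lm$alleles[lm$g2],
                 prob = unname(D[, g])) |>
    dplyr::filter(.data$prob > 0)
}

#' Simulate observed genotypes under the error model
#'
#' Draws one observed genotype per row of `genotypes` from
#' [observation_distribution()], optionally preceded by a Bernoulli
#' missingness event. Seeded runs are reproducible.
#'
#' @param genotypes Long true-genotype table: `individual_id` (or
#'   `sample_id`), `locus`, `allele1`, `allele2`.
#' @param freqs Allele-frequency table.
#' @param rates Error-rate table from [error_rates()]; if several source
#'   classes are present, `genotypes` must carry a `source_class` column.
#' @param missing_prob Per-observation probability of a failed amplification
#'   (default 0).
#' @param miscall Miscall target weighting, see
#'   [observation_distribution()].
#' @param seed Optional RNG seed.
#' @return The input table with `allele1`/`allele2` replaced by observed
#'   values (`NA` for missing observations).
#' @export
simulate_observations <- function(genotypes, freqs, rates,
                                  missing_prob = 0, miscall = "frequency",
                                  seed = NULL) {
  assert_cols(genotypes, c("locus", "allele1", "allele2"), "genotypes")
  lms <- locus_models(freqs)
  if (!"source_class" %in% names(genotypes)) {
    if (length(unique(rates$source_class)) > 1L) {
      abort("rates carry several source classes; genotypes need source_class")
    }
    genotypes$source_class <- rates$source_class[1L]
  }
  local_seed(seed, {
    out <- genotypes
    out$.row <- seq_len(nrow(out))
    grp <- split(out, list(out$locus, out$source_class), drop = TRUE)
    for (d in grp) {
      lc <- d$locus[1L]
      lm <- lms[[lc]]
      if (is.null(lm)) abort(paste0("locus absent from freqs: ", lc))
      r <- rates[rates$locus == lc & rates$source_class ==
                   d$source_class[1L], ]
      if (nrow(r) != 1L) {
        abort(paste0("need exactly one error-rate row for locus ", lc,
                     " class ", d$source_class[1L]))
      }
      D <- obs_matrix(lm, r$E1, r$E2, miscall)
      g <- gt_index(lm, d$allele1, d$allele2)
      for (i in seq_len(nrow(d))) {
        row <- d$.row[i]
        if (missing_prob > 0 && runif(1) < missing_prob) {
          out$allele1[row] <- NA_character_
          out$allele2[row] <- NA_character_
        } else {
          og <- sample.int(lm$G, 1L, prob = D[, g[i]])
          out$allele1[row] <- lm$alleles[lm$g1[og]]
          out$allele2[row] <- lm$alleles[lm$g2[og]]
        }
      }
    }
    out$.row <- NULL
    out
  })
}

#' @rdname simulate_observations
#' @param true_genotype,locus_freqs,E1,E2 As in
#'   [observation_distribution()].
#' @export
simulate_observation <- function(true_genotype, locus_freqs, E1, E2,
                                 missing_prob = 0, miscall = "frequency",
                                 seed = NULL) {
  local_seed(seed, {
    if (missing_prob > 0 && runif(1) < missing_prob) {
      return(c(NA_character_, NA_character_))
    }
    d <- observation_distribution(true_genotype, locus_freqs, E1, E2,
                                  miscall)
    i <- sample.int(nrow(d), 1L, prob = d$prob)
    c(d$allele1[i], d$allele2[i])
  })
}
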