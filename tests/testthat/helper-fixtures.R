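# Shared in-code fixtures for the test suite.

tbl_gt <- function(id, ...) {
  # tbl_gt("X", L1 = c("A","B"), L2 = c("A","A"))
  g <- list(...)
  tibble::tibble(individual_id = id, locus = names(g),
                 allele1 = vapply(g, `[`, character(1), 1L),
                 allele2 = vapply(g, `[`, character(1), 2L))
}

biallelic_freqs <- function(loci, p = 0.5) {
  tibble::tibble(locus = rep(loci, each = 2L),
                 allele = rep(c("A", "B"), length(loci)),
                 frequency = rep(c(p, 1 - p), length(loci)))
}

rep_rows <- function(sample_id, locus, pairs, start = 1L) {
  # pairs: list of c(a1, a2) or NA for a failed replicate
  tibble::tibble(
    sample_id = sample_id, locus = locus,
    replicate = seq.int(start, start + length(pairs) - 1L),
    allele1 = vapply(pairs, function(p) p[1L], character(1)),
    allele2 = vapply(pairs, function(p) if (length(p) > 1L) p[2L] else
      p[1L], character(1)))
}

# a three-generation outbred family used across pedigree tests:
# founders GF + GM -> P; P + Q -> D; D's mate unrelated
family_ped <- function() {
  tibble::tibble(
    id = c("GF", "GM", "Q", "P", "D"),
    dam = c(NA, NA, NA, "GM", "Q"),
    sire = c(NA, NA, NA, "GF", "P"))
}

# Independent tabular (additive-relationship) kinship oracle: processes
# individuals in pedigree order and fills the kinship matrix row by row.
# Kept deliberately separate from the package's memoised recursion.
tabular_kinship <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  dam <- match(ped$dam, ids)
  sire <- match(ped$sire, ids)
  dam[!is.na(ped$dam) & ped$dam == "UNSAMPLED"] <- NA
  sire[!is.na(ped$sire) & ped$sire == "UNSAMPLED"] <- NA
  # order so parents precede offspring
  ord <- integer(0)
  left <- seq_len(n)
  while (length(left) > 0L) {
    ready <- left[vapply(left, function(i) {
      (is.na(dam[i]) || dam[i] %in% ord) &&
        (is.na(sire[i]) || sire[i] %in% ord)
    }, logical(1))]
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    fi <- if (!is.na(dam[i]) && !is.na(sire[i])) K[dam[i], sire[i]] else 0
    K[i, i] <- 0.5 * (1 + fi)
    for (j in ord) {
      if (j == i) break
      kij <- 0
      if (!is.na(dam[i])) kij <- kij + 0.5 * K[dam[i], j]
      if (!is.na(sire[i])) kij <- kij + 0.5 * K[sire[i], j]
      K[i, j] <- K[j, i] <- kij
    }
  }
  K
}

# random legal pedigree generator for property tests
random_pedigree <- function(n, p_parent = 0.7) {
  ids <- sprintf("I%02d", seq_len(n))
  dam <- rep(NA_character_, n)
  sire <- rep(NA_character_, n)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (i > 2L && runif(1) < p_parent) {
      fem <- which(sex[seq_len(i - 1L)] == "F")
      mal <- which(sex[seq_len(i - 1L)] == "M")
      if (length(fem) > 0L) dam[i] <- ids[sample(fem, 1L)]
      if (length(mal) > 0L) sire[i] <- ids[sample(mal, 1L)]
    }
  }
  list(ped = tibble::tibble(id = ids, dam = dam, sire = sire), sex = sex)
}
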