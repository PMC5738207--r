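test_that("consensus calling implements the triplicate reliability rules", {
  cases <- list(
    # heterozygote: both alleles in >= 2 of the 3 replicates
    list(pairs = list(c("A", "B"), c("A", "B"), c("A", "A")),
         status = "RELIABLE_HET", gt = c("A", "B")),
    # homozygote: identical in all three
    list(pairs = list(c("A", "A"), c("A", "A"), c("A", "A")),
         status = "RELIABLE_HOM", gt = c("A", "A")),
    # two informative replicates cannot satisfy the all-three rule
    list(pairs = list(c("A", "A"), c("A", "A"), NA_character_),
         status = "UNRESOLVED", gt = c(NA_character_, NA_character_)),
    # one allele short of the het rule, not all-identical for the hom rule
    list(pairs = list(c("A", "A"), c("A", "A"), c("A", "B")),
         status = "UNRESOLVED", gt = c(NA_character_, NA_character_)),
    # het confirmed with a failed third replicate
    list(pairs = list(c("A", "B"), c("A", "B"), NA_character_),
         status = "RELIABLE_HET", gt = c("A", "B")))
  for (cs in cases) {
    out <- call_consensus(rep_rows("s", "L1", cs$pairs))
    expect_equal(out$status, cs$status)
    expect_equal(c(out$allele1, out$allele2), cs$gt,
                 ignore_attr = TRUE)
  }
})

test_that("an unresolved second triplicate after six replicates is MISSING", {
  reps <- dplyr::bind_rows(
    rep_rows("s", "L1", list(c("A", "A"), c("A", "B"), c("B", "B"))),
    rep_rows("s", "L1", list(c("A", "A"), c("A", "B"), c("B", "B")),
             start = 4L))
  out <- call_consensus(reps)
  expect_equal(out$status, "MISSING")
  expect_equal(out$replicates_used, 6L)
  # but a clean second triplicate rescues the locus
  reps2 <- dplyr::bind_rows(
    rep_rows("s", "L1", list(c("A", "A"), c("A", "B"), c("B", "B"))),
    rep_rows("s", "L1", list(c("A", "A"), c("A", "A"), c("A", "A")),
             start = 4L))
  expect_equal(call_consensus(reps2)$status, "RELIABLE_HOM")
})

test_that("consensus calls are invariant to replicate order and reject bad input", {
  pairs <- list(c("A", "B"), c("A", "A"), c("A", "B"))
  base <- rep_rows("s", "L1", pairs)
  shuffled <- base[c(3, 1, 2), ]
  expect_equal(call_consensus(base)[-1], call_consensus(shuffled)[-1])

  expect_error(call_consensus(dplyr::bind_rows(base, base)), "duplicate")
  seven <- dplyr::bind_rows(base,
                            rep_rows("s", "L1", pairs, start = 4L),
                            rep_rows("s", "L1", pairs[1], start = 7L))
  expect_error(call_consensus(seven), "more than 6")
})

test_that("genotype matching counts mismatching alleles per locus", {
  g_base <- tbl_gt("a", L1 = c("A", "B"), L2 = c("A", "A"),
                   L3 = c("B", "B"), L4 = c("A", "B"), L5 = c("A", "A"),
                   L6 = c("A", "B"), L7 = c("B", "B"), L8 = c("A", "A"))
  expect_equal(match_genotypes(g_base, g_base),
               tibble::tibble(is_match = TRUE, mismatching_alleles = 0L,
                              loci_compared = 8L))

  # one allele at each of two loci: still a match
  g2 <- g_base
  g2$allele2[g2$locus == "L1"] <- "C"
  g2$allele2[g2$locus == "L3"] <- "C"
  r <- match_genotypes(g_base, g2)
  expect_true(r$is_match)
  expect_equal(r$mismatching_alleles, 2L)

  # two mismatches concentrated at one locus (A/B vs C/D): no match
  g3 <- g_base
  g3$allele1[g3$locus == "L1"] <- "C"
  g3$allele2[g3$locus == "L1"] <- "D"
  r3 <- match_genotypes(g_base, g3)
  expect_false(r3$is_match)
  expect_equal(r3$mismatching_alleles, 2L)
  # ... but matches under the plain total-count rule
  expect_true(match_genotypes(g_base, g3,
                              match_rule(per_locus_cap = FALSE))$is_match)

  # three single-allele mismatches: over the cap
  g4 <- g_base
  for (lc in c("L1", "L3", "L7")) g4$allele2[g4$locus == lc] <- "C"
  r4 <- match_genotypes(g_base, g4)
  expect_false(r4$is_match)
  expect_equal(r4$mismatching_alleles, 3L)

  # insufficient overlap is a NO_CALL, not a mismatch
  g5 <- g_base[1:5, ]
  expect_true(is.na(match_genotypes(g_base, g5)$is_match))
})

test_that("genotype matching is symmetric", {
  set.seed(41)
  for (i in 1:20) {
    mk <- function() {
      tibble::tibble(locus = sprintf("L%d", 1:10),
                     allele1 = sample(c("A", "B", "C", NA), 10, TRUE),
                     allele2 = sample(c("A", "B", "C"), 10, TRUE)) |>
        dplyr::mutate(allele2 = ifelse(is.na(.data$allele1), NA,
                                       .data$allele2))
    }
    g1 <- mk(); g2 <- mk()
    expect_equal(match_genotypes(g1, g2), match_genotypes(g2, g1))
  }
})

test_that("clustering groups matching samples and flags transitive conflicts", {
  loci <- sprintf("L%02d", 1:12)
  mk_sample <- function(sid, alleles1, alleles2) {
    tibble::tibble(sample_id = sid, locus = loci, allele1 = alleles1,
                   allele2 = alleles2)
  }
  base1 <- rep("A", 12); base2 <- rep("B", 12)
  s1 <- mk_sample("s1", base1, base2)
  s2 <- mk_sample("s2", base1, base2)
  s3 <- mk_sample("s3", base1, base2)
  out <- cluster_samples(dplyr::bind_rows(s1, s2, s3),
                         min_loci_consensus = 11L)
  expect_equal(nrow(out$individuals), 1L)
  expect_equal(out$individuals$n_samples, 3L)
  expect_equal(out$individuals$flag, "OK")

  # s1-s2 match, s2-s3 match, but s1-s3 differ at 3 alleles: one component,
  # flagged for review
  a1 <- base1
  s2b <- mk_sample("s2", replace(base1, 1:2, "C"), base2)   # 2 mm to s1
  s3b <- mk_sample("s3", replace(base1, 1:3, "C"), base2)
  r12 <- match_genotypes(s1[-1], s2b[-1]); r23 <- match_genotypes(s2b[-1], s3b[-1])
  r13 <- match_genotypes(s1[-1], s3b[-1])
  expect_true(r12$is_match && r23$is_match && !r13$is_match)
  out2 <- cluster_samples(dplyr::bind_rows(s1, s2b, s3b),
                          min_loci_consensus = 11L)
  expect_equal(nrow(out2$individuals), 1L)
  expect_match(out2$individuals$flag, "AMBIGUOUS")
})

test_that("expected heterozygosity matches the gene-diversity formula", {
  f <- tibble::tibble(locus = c("L1", "L1", "L2", "L2", "L2", "L3"),
                      allele = c("A", "B", "A", "B", "C", "A"),
                      frequency = c(0.5, 0.5, 0.2, 0.3, 0.5, 1))
  he <- expected_heterozygosity(f)
  expect_equal(he$He[he$locus == "L1"], 0.5)
  expect_equal(he$He[he$locus == "L2"], 0.62)
  expect_equal(he$He[he$locus == "L3"], 0)   # monomorphic
  expect_equal(attr(he, "panel_mean"), mean(he$He))
  expect_error(expected_heterozygosity(f[0, ]), "empty")
})

test_that("H_E is bounded by 1 - 1/k with equality at uniform frequencies", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(2:9, 1)
    x <- rgamma(k, 1); x <- x / sum(x)
    f <- tibble::tibble(locus = "L", allele = as.character(seq_len(k)),
                        frequency = x)
    he <- expected_heterozygosity(f)$He
    expect_gte(he, 0)
    expect_lte(he, 1 - 1 / k + 1e-12)
  }
  unif <- tibble::tibble(locus = "L", allele = as.character(1:5),
                         frequency = rep(0.2, 5))
  expect_equal(expected_heterozygosity(unif)$He, 1 - 1 / 5)
})

test_that("augment_frequencies adds novel alleles at epsilon and renormalises", {
  base <- tibble::tibble(locus = "L1", allele = c("A", "B"),
                         frequency = c(0.6, 0.4))
  out <- augment_frequencies(base, tibble::tibble(locus = "L1",
                                                  allele = "C"),
                             epsilon = 0.005)
  expect_equal(out$frequency[out$allele == "C"], 0.005 / 1.005)
  expect_equal(out$frequency[out$allele == "A"], 0.6 / 1.005)
  expect_equal(sum(out$frequency), 1)

  # no novel alleles: unchanged
  same <- augment_frequencies(base, tibble::tibble(locus = "L1",
                                                   allele = "A"))
  expect_equal(dplyr::arrange(same, .data$allele), base)

  # two novel alleles both enter at epsilon pre-normalisation
  out2 <- augment_frequencies(base,
                              tibble::tibble(locus = "L1",
                                             allele = c("C", "D")),
                              epsilon = 0.01)
  expect_equal(out2$frequency[out2$allele == "C"],
               out2$frequency[out2$allele == "D"])
  expect_equal(sum(out2$frequency), 1)
})

test_that("augmented tables always sum to one per locus", {
  set.seed(11)
  for (i in 1:20) {
    ft <- make_frequency_table(n_loci = 3L, seed = i)
    obs <- tibble::tibble(locus = sample(unique(ft$locus), 4, TRUE),
                          allele = as.character(sample(900:999, 4)))
    out <- augment_frequencies(ft, obs)
    sums <- tapply(out$frequency, out$locus, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("ML inbreeding estimator recovers boundary and simulated values", {
  # all-heterozygous individual: likelihood decreasing in F
  f <- biallelic_freqs(sprintf("L%d", 1:5))
  het <- tbl_gt("h", L1 = c("A", "B"), L2 = c("A", "B"), L3 = c("A", "B"),
                L4 = c("A", "B"), L5 = c("A", "B"))
  expect_equal(inbreeding_mle(het, f)$F_hat, 0)

  # single homozygous locus at p = 0.5: P = 0.25 + 0.75 F, maximised at 1
  hom <- tbl_gt("x", L1 = c("A", "A"))
  expect_equal(inbreeding_mle(hom, biallelic_freqs("L1"))$F_hat, 1)

  # simulation recovery at F = 0.2 with 30 loci, 200 individuals
  set.seed(202)
  loci <- sprintf("L%02d", 1:30)
  f30 <- biallelic_freqs(loci, p = 0.4)
  Ftrue <- 0.2
  sim <- purrr::map_dfr(1:200, function(i) {
    ibd <- runif(30) < Ftrue
    a1 <- ifelse(runif(30) < 0.4, "A", "B")
    a2 <- ifelse(ibd, a1, ifelse(runif(30) < 0.4, "A", "B"))
    tibble::tibble(individual_id = sprintf("i%03d", i), locus = loci,
                   allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
  })
  est <- inbreeding_mle(sim, f30)
  expect_lt(abs(mean(est$F_hat) - Ftrue), 0.05)

  # individuals with no typed loci are excluded with a warning
  empty <- tibble::tibble(individual_id = "z", locus = "L1",
                          allele1 = NA_character_, allele2 = NA_character_)
  expect_warning(inbreeding_mle(dplyr::bind_rows(hom, empty),
                                biallelic_freqs("L1")), "excluded")
})
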