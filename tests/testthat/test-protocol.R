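mk_modal <- function(id, dam, sire, prob) {
  tibble::tibble(id = id, dam = dam, sire = sire,
                 dam_prob = prob, sire_prob = prob, pair_prob = prob,
                 flag = "")
}

test_that("step-5 averaging weighs pairs by mean support across runs", {
  # a pair absent from a run contributes 0 for that run: modal in 10/20
  # runs at 0.9 averages to 0.45 and beats a pair modal in the other 10
  # at 0.5 (mean 0.25); rarely-modal-but-strong loses to often-modal once
  # the frequencies differ enough
  mixed <- c(lapply(1:10, function(i) mk_modal("X", "d1", "s1", 0.9)),
             lapply(1:10, function(i) mk_modal("X", "d2", "s2", 0.5)))
  out <- step5_average(mixed)
  expect_equal(out$dam, "d1")
  expect_equal(out$confidence, 0.9 * 10 / 20)
  few_strong <- c(lapply(1:4, function(i) mk_modal("X", "d1", "s1", 0.9)),
                  lapply(1:16, function(i) mk_modal("X", "d2", "s2", 0.5)))
  out_f <- step5_average(few_strong)
  expect_equal(out_f$dam, "d2")
  expect_equal(out_f$confidence, 0.5 * 16 / 20)

  # plain dominance
  out2 <- step5_average(list(mk_modal("X", "d1", "s1", 0.8),
                             mk_modal("X", "d1", "s1", 0.8),
                             mk_modal("X", "d2", "s2", 0.3)))
  expect_equal(out2$dam, "d1")
  expect_equal(out2$confidence, 0.8 * 2 / 3)

  # idempotence on identical runs
  same <- lapply(1:5, function(i) mk_modal(c("X", "Y"),
                                           c("d1", "UNSAMPLED"),
                                           c("s1", "s2"), c(0.9, 0.6)))
  out3 <- step5_average(same)
  expect_equal(out3$confidence, c(0.9, 0.6))
  expect_equal(out3$dam, c("d1", "UNSAMPLED"))

  # the present-only alternative divides by runs where the pair appeared
  alt <- step5_average(mixed, absent = "present_only")
  expect_equal(alt$dam, "d1")
  expect_equal(alt$confidence, 0.9)
})

test_that("prior-only loci return the beta prior in step-2 estimation", {
  membership <- tibble::tibble(sample_id = "s1", individual_id = "i1")
  reps <- tibble::tibble(sample_id = "s1", locus = "L1", replicate = 1:2,
                         allele1 = c("A", "A"), allele2 = c("A", "A"))
  freqs <- biallelic_freqs(c("L1", "L2"))
  est <- estimate_error_rates(reps, membership, freqs, iterations = 300L,
                              burn_in = 100L, seed = 2)
  prior_row <- est[est$locus == "L2", ]
  expect_equal(prior_row$flag, "PRIOR_ONLY")
  expect_equal(prior_row$E1_mean, 4 / 104)
  expect_equal(prior_row$E2_mean, 2 / 102)
})

test_that("abundant concordant replicates shrink error rates below prior", {
  set.seed(8)
  n_ind <- 40L
  membership <- tibble::tibble(sample_id = sprintf("s%02d", 1:n_ind),
                               individual_id = sprintf("i%02d", 1:n_ind))
  # 4 identical heterozygous replicates per individual: no discordance
  reps <- tidyr::expand_grid(sample_id = membership$sample_id,
                             replicate = 1:4) |>
    dplyr::mutate(locus = "L1", allele1 = "A", allele2 = "B")
  freqs <- biallelic_freqs("L1")
  est <- estimate_error_rates(reps, membership, freqs,
                              iterations = 1500L, burn_in = 500L,
                              seed = 5)
  expect_lt(est$E1_mean, 4 / 104)
  expect_lt(est$E1_hi, 0.04)
})

test_that("step-6 flags anachronisms and single-offspring pairs", {
  cfg <- protocol_config()
  ped <- tibble::tibble(
    id = c("gp", "p", "q", "kid", "x", "y", "lone"),
    dam = c(NA, "gp", NA, "p", NA, NA, "x"),
    sire = c(NA, NA, NA, "q", NA, NA, "y"),
    confidence = c(0.99, 0.99, 0.99, 0.95, 0.9, 0.9, 0.75))
  # p is a litter member first seen 2014, so her cohort is 2014; her
  # offspring appearing in 2015 would make her a one-year-old mother
  det <- tibble::tibble(
    individual_id = c("gp", "p", "q", "kid", "x", "y", "lone"),
    first_seen = c(2010L, 2014L, 2014L, 2015L, 2010L, 2010L, 2015L))
  rep <- step6_consistency(ped, det, config = cfg)
  expect_true(any(rep$flags$flag == "ANACHRONISM" &
                    rep$flags$id == "kid"))
  expect_true(any(rep$flags$flag == "SINGLE_OFFSPRING_PAIR" &
                    rep$flags$id == "lone"))
  # assignment counts partition the individuals
  s <- rep$assignment_summary
  expect_equal(s$both + s$only_mother + s$only_father + s$neither,
               s$n_individuals)
})

test_that("step-6 is quiet on a clean pedigree and counts categories", {
  cfg <- protocol_config()
  ped <- tibble::tibble(
    id = c("m", "f", "a", "b", "c"),
    dam = c(NA, NA, "m", "m", NA),
    sire = c(NA, NA, "f", "f", "f"),
    dam_prob = c(0, 0, 0.95, 0.85, 0.2),
    sire_prob = c(0, 0, 0.96, 0.5, 0.9),
    confidence = c(0, 0, 0.95, 0.5, 0.2))
  det <- tibble::tibble(individual_id = c("m", "f", "a", "b", "c"),
                        first_seen = c(2010L, 2010L, 2013L, 2013L, 2014L))
  rep <- step6_consistency(ped, det, config = cfg)
  expect_equal(nrow(rep$flags), 0L)
  s <- rep$assignment_summary
  expect_equal(s$both, 1L)          # a
  expect_equal(s$only_mother, 1L)   # b
  expect_equal(s$only_father, 1L)   # c
  expect_equal(s$neither, 2L)       # the founders
})

test_that("territory conflicts are flagged when two pairs share a territory-year", {
  cfg <- protocol_config()
  ped <- tibble::tibble(
    id = c("m1", "f1", "m2", "f2", "k1", "k2"),
    dam = c(NA, NA, NA, NA, "f1", "f2"),
    sire = c(NA, NA, NA, NA, "m1", "m2"),
    confidence = c(0, 0, 0, 0, 0.95, 0.95))
  det <- tibble::tibble(
    individual_id = ped$id,
    first_seen = c(2010L, 2010L, 2010L, 2010L, 2014L, 2014L))
  terr <- tibble::tibble(individual_id = c("k1", "k2"),
                         territory = c("T1", "T1"))
  rep <- step6_consistency(ped, det, territories = terr, config = cfg)
  expect_true(any(rep$flags$flag == "TERRITORY_CONFLICT"))
})

test_that("corrections ledger edits are applied, logged and legality-checked", {
  ped <- tibble::tibble(id = c("gp", "p", "kid", "d2", "s2"),
                        dam = c(NA, "gp", "p", NA, NA),
                        sire = c(NA, NA, NA, NA, NA))
  # empty ledger: unchanged
  out0 <- apply_corrections(ped, tibble::tibble())
  expect_equal(out0$pedigree, ped)

  ledger <- tibble::tibble(
    offspring = c("kid", "kid", "p"),
    field = c("dam", "sire", "dam"),
    new_value = c("d2", "s2", "gp"),
    reason = c("ANACHRONISM", "SINGLE_OFFSPRING_PAIR", "CONFIRMED"),
    note = "test")
  out <- apply_corrections(ped, ledger)
  expect_equal(out$pedigree$dam[out$pedigree$id == "kid"], "d2")
  expect_equal(out$pedigree$sire[out$pedigree$id == "kid"], "s2")
  expect_equal(sum(out$log$applied), 2L)
  expect_equal(out$log$message[3], "confirmed, unchanged")

  # an edit that would make an individual its own grandparent is rejected
  bad <- tibble::tibble(offspring = "gp", field = "dam",
                        new_value = "kid", reason = "ANACHRONISM",
                        note = "")
  out2 <- apply_corrections(ped, bad)
  expect_false(out2$log$applied[1])
  expect_match(out2$log$message[1], "rejected")
  expect_equal(out2$pedigree, ped)
})

test_that("possible-breeder aggregation pools assignment counts over runs", {
  ind <- tibble::tibble(individual_id = c("a", "b", "c", "d"))
  peds <- c(
    lapply(1:3, function(i)
      mk_modal(c("a", "b", "c", "d"),
               c(NA, NA, "a", "a"), c(NA, NA, "b", "b"),
               c(0, 0, 0.9, 0.9))),
    lapply(1:1, function(i)
      mk_modal(c("a", "b", "c", "d"),
               c(NA, NA, "a", "d"), c(NA, NA, "b", "b"),
               c(0, 0, 0.9, 0.9))))
  counts <- vapply(peds, function(p) {
    pr <- c(p$dam, p$sire)
    table(factor(pr[!is.na(pr) & pr != "UNSAMPLED"],
                 levels = ind$individual_id))
  }, numeric(4))
  share <- rowSums(counts) / (8 * 4)
  # a appears 7 times, b 8, d once: with a 5% threshold a, b qualify
  expect_gte(share[["a"]], 0.05)
  expect_lt(share[["d"]], 0.05)
})
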