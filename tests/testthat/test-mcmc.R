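# Independent brute-force oracle for the trio observation likelihood:
# enumerate all true-genotype triples per locus under the same model
# definition (HWE-posterior parent weights, error-model observation
# densities, Mendelian transmission) with plain loops.
brute_pair_loglik <- function(off, dam, sire, freqs, rates) {
  tot <- 0
  for (lc in unique(freqs$locus)) {
    lf <- freqs[freqs$locus == lc, ]
    k <- nrow(lf)
    als <- lf$allele
    gts <- list()
    for (i in seq_len(k)) for (j in i:k) gts <- c(gts, list(c(i, j)))
    hwe <- vapply(gts, function(g) {
      if (g[1] == g[2]) lf$frequency[g[1]]^2 else
        2 * lf$frequency[g[1]] * lf$frequency[g[2]]
    }, numeric(1))
    r <- rates[rates$locus == lc, ][1, ]
    dens <- function(obs, tru) {
      d <- observation_distribution(als[tru], lf, r$E1, r$E2)
      key <- paste0(d$allele1, "/", d$allele2)
      p <- unname(d$prob[key == paste0(min(als[obs]), "/",
                                       max(als[obs]))])
      if (length(p) == 0) 0 else p
    }
    get_gt <- function(tbl) {
      if (identical(tbl, "UNSAMPLED")) return(NULL)
      row <- tbl[tbl$locus == lc & !is.na(tbl$allele1), ]
      if (nrow(row) == 0) return(NULL)
      c(match(row$allele1[1], als), match(row$allele2[1], als))
    }
    og <- get_gt(off)
    if (is.null(og)) next
    dens_pair <- function(obs, tru_idx) dens(obs, gts[[tru_idx]])
    wvec <- function(tbl) {
      g <- get_gt(tbl)
      if (is.null(g)) return(hwe)
      w <- vapply(seq_along(gts), function(t) dens(g, gts[[t]]),
                  numeric(1)) * hwe
      w / sum(w)
    }
    wd <- wvec(dam); ws <- wvec(sire)
    trans <- function(go, gd, gs) {
      p <- 0
      for (a in gts[[gd]]) for (b in gts[[gs]]) {
        if (setequal(sort(c(a, b)), sort(go)) &&
            all(sort(c(a, b)) == sort(go))) p <- p + 0.25
      }
      p
    }
    lik <- 0
    for (gd in seq_along(gts)) for (gs in seq_along(gts)) {
      for (got in seq_along(gts)) {
        po <- dens_pair(og, got)
        if (po == 0) next
        lik <- lik + wd[gd] * ws[gs] * po *
          trans(gts[[got]], gd, gs)
      }
    }
    tot <- tot + log(unname(lik))
  }
  tot
}

test_that("Mendelian transmission covers Punnett and unsampled cases", {
  lf <- tibble::tibble(allele = c("A", "B"), frequency = c(0.7, 0.3))
  expect_equal(mendelian_transmission(c("A", "A"), c("A", "A"),
                                      c("A", "A"), lf), 1)
  expect_equal(mendelian_transmission(c("A", "A"), c("A", "B"),
                                      c("A", "B"), lf), 0.25)
  expect_equal(mendelian_transmission(c("A", "B"), c("A", "B"),
                                      c("A", "B"), lf), 0.5)
  expect_equal(mendelian_transmission(c("B", "B"), c("A", "B"),
                                      c("A", "B"), lf), 0.25)
  expect_equal(mendelian_transmission(c("A", "B"), c("A", "A"),
                                      "UNSAMPLED", lf), 0.3)
  expect_equal(mendelian_transmission(c("A", "B"), "UNSAMPLED",
                                      "UNSAMPLED", lf), 2 * 0.7 * 0.3)
})

test_that("pair likelihood collapses to Mendelian products at zero error", {
  freqs <- biallelic_freqs(c("L1", "L2"), p = 0.6)
  rates <- error_rates(c("L1", "L2"), 0, 0)
  off <- tbl_gt("o", L1 = c("A", "B"), L2 = c("A", "A"))[-1]
  dam <- tbl_gt("d", L1 = c("A", "A"), L2 = c("A", "B"))[-1]
  sire <- tbl_gt("s", L1 = c("B", "B"), L2 = c("A", "A"))[-1]
  ll <- parent_pair_likelihood(off, dam, sire, freqs, rates)
  exp_ll <- log(mendelian_transmission(c("A", "B"), c("A", "A"),
                                       c("B", "B"),
                                       freqs[freqs$locus == "L1", ])) +
    log(mendelian_transmission(c("A", "A"), c("A", "B"), c("A", "A"),
                               freqs[freqs$locus == "L2", ]))
  expect_equal(ll, exp_ll)

  # Mendelian exclusion: offspring allele absent from both parents
  bad_sire <- tbl_gt("s", L1 = c("A", "A"), L2 = c("A", "A"))[-1]
  bad_dam <- tbl_gt("d", L1 = c("A", "A"), L2 = c("A", "A"))[-1]
  off2 <- tbl_gt("o", L1 = c("B", "B"), L2 = c("A", "A"))[-1]
  expect_equal(parent_pair_likelihood(off2, bad_dam, bad_sire, freqs,
                                      rates), -Inf)
})

test_that("pair likelihood equals exhaustive enumeration with errors", {
  set.seed(31)
  freqs <- dplyr::bind_rows(
    biallelic_freqs("L1", p = 0.6),
    tibble::tibble(locus = "L2", allele = c("A", "B", "C"),
                   frequency = c(0.5, 0.3, 0.2)))
  rates <- error_rates(c("L1", "L2"), E1 = 0.1, E2 = 0.05)
  combos <- list(
    list(o = list(L1 = c("A", "B"), L2 = c("A", "C")),
         d = list(L1 = c("A", "A"), L2 = c("C", "C")),
         s = list(L1 = c("B", "B"), L2 = c("A", "B"))),
    list(o = list(L1 = c("A", "A"), L2 = c("B", "B")),
         d = "UNSAMPLED",
         s = list(L1 = c("A", "B"), L2 = c("B", "C"))),
    list(o = list(L1 = c("B", "B"), L2 = c("A", "A")),
         d = "UNSAMPLED", s = "UNSAMPLED"))
  for (cb in combos) {
    as_tbl <- function(x) {
      if (identical(x, "UNSAMPLED")) return("UNSAMPLED")
      do.call(tbl_gt, c(list("x"), x))[-1]
    }
    got <- parent_pair_likelihood(as_tbl(cb$o), as_tbl(cb$d),
                                  as_tbl(cb$s), freqs, rates)
    want <- brute_pair_loglik(as_tbl(cb$o), as_tbl(cb$d), as_tbl(cb$s),
                              freqs, rates)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("exclusion filter applies mismatch, sex, age and death rules", {
  loci <- sprintf("L%d", 1:6)
  off <- tibble::tibble(locus = loci, allele1 = "A", allele2 = "A")
  share_all <- tibble::tibble(locus = loci, allele1 = "A", allele2 = "B")
  expect_true(exclusion_filter(off, share_all))

  opp5 <- tibble::tibble(locus = loci,
                         allele1 = c(rep("B", 5), "A"),
                         allele2 = c(rep("B", 5), "A"))
  expect_false(exclusion_filter(off, opp5))           # 5 opposing loci
  expect_true(exclusion_filter(off, opp5, max_mismatch_loci = 5L))

  expect_false(exclusion_filter(off, share_all, role = "dam",
                                candidate_sex = "M"))
  # dead at age 1: excluded once cohorts known
  expect_false(exclusion_filter(off, share_all, offspring_cohort = 2014,
                                candidate_birth = 2013,
                                candidate_death = 2014))
  expect_false(exclusion_filter(off, share_all, offspring_cohort = 2014,
                                candidate_birth = 2010,
                                candidate_death = 2012))
  expect_true(exclusion_filter(off, share_all, offspring_cohort = 2014,
                               candidate_birth = 2010,
                               candidate_death = 2014))
})

test_that("posterior matches full-joint brute force on a toy instance", {
  # 4 individuals; every one is an offspring slot; legality couples them.
  freqs <- biallelic_freqs(c("L1", "L2"))
  genos <- dplyr::bind_rows(
    tbl_gt("O", L1 = c("A", "B"), L2 = c("A", "A")),
    tbl_gt("D", L1 = c("A", "A"), L2 = c("A", "A")),
    tbl_gt("S1", L1 = c("B", "B"), L2 = c("A", "A")),
    tbl_gt("S2", L1 = c("A", "B"), L2 = c("A", "B")))
  ind <- tibble::tibble(
    individual_id = c("O", "D", "S1", "S2"),
    sex = c("F", "F", "M", "M"),
    first_seen = as.Date(c("2015-01-01", "2010-01-01", "2010-01-01",
                           "2010-06-01")))
  rates <- error_rates(c("L1", "L2"), 0, 0)
  Nf <- 1; Nm <- 1
  post <- sample_pedigree(
    ind, genos, freqs, rates,
    settings = mcmc_settings(iterations = 102000, burn_in = 2000,
                             thinning = 2, seed = 7,
                             update_sizes = FALSE,
                             size_init = c(male = Nm, female = Nf)))
  n_kept <- nrow(post$chains)
  expect_equal(n_kept, 50000L)

  # exact joint enumeration over all legal configurations
  ids <- ind$individual_id
  sex <- setNames(ind$sex, ids)
  gtab <- function(id) if (id == "UNSAMPLED") "UNSAMPLED" else
    genos[genos$individual_id == id, ]
  dams <- lapply(ids, function(o) c(setdiff(ids[sex == "F"], o),
                                    "UNSAMPLED"))
  sires <- lapply(ids, function(o) c(setdiff(ids[sex == "M"], o),
                                     "UNSAMPLED"))
  names(dams) <- names(sires) <- ids
  pw <- function(cands, chosen, N) {
    n <- length(cands) - 1
    if (chosen == "UNSAMPLED") N / (n + N) else 1 / (n + N)
  }
  grids <- lapply(ids, function(o)
    expand.grid(d = dams[[o]], s = sires[[o]], stringsAsFactors = FALSE))
  wcache <- lapply(seq_along(ids), function(j) {
    o <- ids[j]; g <- grids[[j]]
    vapply(seq_len(nrow(g)), function(r) {
      exp(parent_pair_likelihood(gtab(o), gtab(g$d[r]), gtab(g$s[r]),
                                 freqs, rates)) *
        pw(dams[[o]], g$d[r], Nf) * pw(sires[[o]], g$s[r], Nm)
    }, numeric(1))
  })
  idx <- expand.grid(lapply(grids, function(g) seq_len(nrow(g))))
  tot <- 0
  marg <- matrix(0, length(dams[["O"]]), length(sires[["O"]]),
                 dimnames = list(dams[["O"]], sires[["O"]]))
  for (r in seq_len(nrow(idx))) {
    w <- 1
    ped <- tibble::tibble(id = ids, dam = NA_character_,
                          sire = NA_character_)
    for (j in seq_along(ids)) {
      g <- grids[[j]]; k <- idx[r, j]
      ped$dam[j] <- g$d[k]; ped$sire[j] <- g$s[k]
      w <- w * wcache[[j]][k]
    }
    if (w > 0 && is_legal(ped)$legal) {
      tot <- tot + w
      k <- idx[r, 1]
      marg[grids[[1]]$d[k], grids[[1]]$s[k]] <-
        marg[grids[[1]]$d[k], grids[[1]]$s[k]] + w
    }
  }
  exact <- marg / tot
  got <- post$pair_freq[[match("O", post$offspring)]]
  for (d in rownames(exact)) {
    for (s in colnames(exact)) {
      mc_se <- sqrt(exact[d, s] * (1 - exact[d, s]) / n_kept)
      expect_lt(abs(got[d, s] - exact[d, s]), 3 * mc_se + 1e-4)
    }
  }
  # per-offspring pair frequencies are a distribution
  for (m in post$pair_freq) expect_equal(sum(m), 1, tolerance = 1e-12)
})

test_that("seeded chains are exactly reproducible", {
  freqs <- biallelic_freqs(c("L1", "L2"))
  genos <- dplyr::bind_rows(
    tbl_gt("A", L1 = c("A", "B"), L2 = c("A", "A")),
    tbl_gt("B", L1 = c("A", "A"), L2 = c("A", "B")),
    tbl_gt("C", L1 = c("B", "B"), L2 = c("A", "B")))
  ind <- tibble::tibble(individual_id = c("A", "B", "C"),
                        sex = c("F", "M", "F"),
                        first_seen = as.Date("2014-01-01") + 0:2)
  rates <- error_rates(c("L1", "L2"), 0.04, 0.022)
  st <- mcmc_settings(iterations = 2000, burn_in = 200, seed = 13)
  p1 <- sample_pedigree(ind, genos, freqs, rates, settings = st)
  p2 <- sample_pedigree(ind, genos, freqs, rates, settings = st)
  expect_identical(p1$chains, p2$chains)
  expect_identical(p1$pair_freq, p2$pair_freq)
})

test_that("with zero error and unique compatible parents the pair is certain", {
  loci <- sprintf("L%d", 1:8)
  freqs <- dplyr::bind_rows(lapply(loci, function(lc)
    tibble::tibble(locus = lc, allele = c("A", "B", "C", "D"),
                   frequency = rep(0.25, 4))))
  rates <- error_rates(loci, 0, 0)
  mk <- function(id, a) do.call(tbl_gt, c(list(id),
                                          setNames(rep(list(a), 8), loci)))
  genos <- dplyr::bind_rows(mk("KID", c("A", "B")), mk("MUM", c("A", "A")),
                            mk("DAD", c("B", "B")), mk("AUNT", c("C", "C")),
                            mk("UNCLE", c("D", "D")))
  ind <- tibble::tibble(
    individual_id = c("KID", "MUM", "DAD", "AUNT", "UNCLE"),
    sex = c("F", "F", "M", "F", "M"),
    first_seen = as.Date(c("2015-06-01", rep("2010-01-01", 4))))
  post <- sample_pedigree(
    ind, genos, freqs, rates,
    settings = mcmc_settings(iterations = 4000, burn_in = 500, seed = 3,
                             update_sizes = FALSE,
                             size_init = c(male = 0, female = 0)))
  m <- post$pair_freq[[match("KID", post$offspring)]]
  expect_equal(m["MUM", "DAD"], 1)
})

test_that("size chains recover the lognormal prior when likelihood is flat", {
  # a single offspring with no typed loci: every pair likelihood is 1, so
  # the unsampled-size chain must reproduce its prior
  genos <- tibble::tibble(individual_id = "X", locus = "L1",
                          allele1 = NA_character_, allele2 = NA_character_)
  ind <- tibble::tibble(individual_id = "X", sex = "F",
                        first_seen = as.Date("2015-01-01"))
  post <- sample_pedigree(
    ind, genos, biallelic_freqs("L1"), error_rates("L1", 0, 0),
    priors = ped_priors(),
    settings = mcmc_settings(iterations = 22000, burn_in = 2000,
                             thinning = 2, seed = 11))
  # subsample the kept chain so the KS test sees near-independent draws
  pick <- seq(1L, nrow(post$chains), by = 25L)
  ks_m <- stats::ks.test(post$chains$N_unsampled_male[pick],
                         stats::plnorm, meanlog = log(7), sdlog = 0.5)
  ks_f <- stats::ks.test(post$chains$N_unsampled_female[pick],
                         stats::plnorm, meanlog = log(2), sdlog = 0.5)
  expect_gt(ks_m$p.value, 0.01)
  expect_gt(ks_f$p.value, 0.01)
})

test_that("modal pedigree breaks ties to UNSAMPLED and repairs cycles", {
  mk_post <- function(freq_list, ids, dam_cands, sire_cands) {
    structure(list(offspring = ids, pair_freq = freq_list,
                   dam_candidates = dam_cands, sire_candidates = sire_cands,
                   chains = tibble::tibble(sample = 1L),
                   acceptance = c(female = NA, male = NA),
                   settings = mcmc_settings(iterations = 10,
                                            burn_in = 1)),
              class = "ped_posterior")
  }
  # exact tie between a sampled pair and the unsampled pair
  m <- matrix(c(0.5, 0, 0, 0.5), 2, 2,
              dimnames = list(c("d1", "UNSAMPLED"),
                              c("s1", "UNSAMPLED")))
  post <- mk_post(list(m), "X", list("d1"), list("s1"))
  ped <- modal_pedigree(post)
  expect_equal(ped$dam, "UNSAMPLED")
  expect_equal(ped$sire, "UNSAMPLED")
  expect_match(ped$flag, "TIE")

  # adversarial posterior whose per-offspring modes form a 2-cycle
  mA <- matrix(c(0.6, 0.4), 1, 2,
               dimnames = list("UNSAMPLED", c("B", "UNSAMPLED")))
  mB <- matrix(c(0.9, 0.1), 1, 2,
               dimnames = list("UNSAMPLED", c("A", "UNSAMPLED")))
  post2 <- mk_post(list(mA, mB), c("A", "B"), list(character(0)),
                   list("B"))
  post2$dam_candidates <- list(character(0), character(0))
  post2$sire_candidates <- list("B", "A")
  ped2 <- modal_pedigree(post2)
  expect_true(is_legal(ped2[c("id", "dam", "sire")])$legal)
  expect_true(any(grepl("REPAIRED", ped2$flag)))
})
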