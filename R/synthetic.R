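# Synthetic wolf-population generator with known ground truth.
#
# Emulates the data-generating structure of territorial wolf monitoring:
# a handful of pack territories, each held by a single breeding (alpha)
# pair producing at most one litter per year; vacancies after breeder
# deaths are filled by inheritance from within the pack, local dispersal
# (female-biased) or immigration from outside the study area (male-biased;
# immigrants carry UNSAMPLED parents); parent-offspring pairings never
# form. A detection/sampling layer then generates dated, geolocated
# samples and triplicate PCR replicate observations corrupted by the
# dropout/miscall error model, with the second-triplicate escalation rule.

#' Demographic configuration for the synthetic population
#'
#' @param n_packs Number of pack territories (default 4).
#' @param years Breeding years simulated (default 7).
#' @param start_year First breeding year (default 2009).
#' @param establishment_lags Years after `start_year` at which each
#'   territory becomes available (default `c(0, 1, 2, 3)`, recycled),
#'   mirroring the gradual settlement of a re-colonising population.
#' @param litter_mean Poisson mean litter size (default 4).
#' @param breeder_mortality Annual death probability of any adult
#'   (default 0.15).
#' @param inherit_prob Probability a vacancy is filled from within the
#'   natal pack (default 0.3).
#' @param female_dispersal Probability a remaining female vacancy is
#'   filled by a local disperser from another pack (default 0.3).
#' @param male_immigration Probability a remaining male vacancy is filled
#'   by an immigrant with unsampled parents (default 0.5).
#' @param cross_rate Probability of the minority route (male local
#'   dispersal, female immigration) for still-open vacancies
#'   (default 0.15).
#' @param min_breeding_age Minimum age at first reproduction (default 2).
#' @param territory_spread SD (in km) of sample scatter around the pack
#'   centre (default 8).
#' @return List of class `population_config`.
#' @export
population_config <- function(n_packs = 4L, years = 7L, start_year = 2009L,
                              establishment_lags = c(0L, 1L, 2L, 3L),
                              litter_mean = 4, breeder_mortality = 0.15,
                              inherit_prob = 0.3, female_dispersal = 0.3,
                              male_immigration = 0.5, cross_rate = 0.15,
                              min_breeding_age = 2L,
                              territory_spread = 8) {
  stopifnot(litter_mean > 0, n_packs >= 1L, years >= 0L)
  probs <- c(breeder_mortality, inherit_prob, female_dispersal,
             male_immigration, cross_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(as.list(environment()), class = "population_config")
}

#' Sampling-process configuration
#'
#' @param detection_prob Per-individual, per-year detection probability
#'   (default 0.7).
#' @param samples_mean,samples_size Negative-binomial parameters for the
#'   number of samples per detected individual (mean 4, size 5; truncated
#'   at 1).
#' @param replicate_missing Per-replicate, per-locus amplification failure
#'   probability (default 0.05).
#' @param scat_fraction Fraction of samples that are faecal (default
#'   0.93; the remainder are tissue/secretion).
#' @param n_collectors Distinct volunteer collectors (default 30).
#' @return List of class `sampling_config`.
#' @export
sampling_config <- function(detection_prob = 0.7, samples_mean = 4,
                            samples_size = 5, replicate_missing = 0.05,
                            scat_fraction = 0.93, n_collectors = 30L) {
  stopifnot(detection_prob >= 0, detection_prob <= 1,
            replicate_missing >= 0, replicate_missing < 1,
            scat_fraction >= 0, scat_fraction <= 1)
  structure(as.list(environment()), class = "sampling_config")
}

#' Generate an allele-frequency table with a target diversity profile
#'
#' Builds a microsatellite-like panel: per-locus allele counts between 2
#' and 9, Dirichlet-drawn frequencies accepted when the locus expected
#' heterozygosity hits a per-locus target; the targets span roughly
#' 0.2--0.78 with a panel mean matching `target_mean_he` to within 0.03.
#'
#' @param n_loci Number of loci (default 17).
#' @param target_mean_he Target panel-mean expected heterozygosity in
#'   (0, 0.9) (default 0.58).
#' @param seed Optional RNG seed.
#' @return Allele-frequency tibble (`locus`, `allele`, `frequency`).
#' @export
make_frequency_table <- function(n_loci = 17L, target_mean_he = 0.58,
                                 seed = NULL) {
  if (target_mean_he <= 0 || target_mean_he >= 0.9) {
    abort("target_mean_he must lie in (0, 0.9)")
  }
  # reference diversity profile (mean ~0.58), shifted to the target mean
  base <- c(0.20, 0.35, 0.45, 0.50, 0.53, 0.55, 0.57, 0.58, 0.60, 0.62,
            0.63, 0.65, 0.67, 0.70, 0.72, 0.75, 0.78)
  prof <- stats::approx(seq_along(base), base,
                        xout = seq(1, length(base),
                                   length.out = n_loci))$y
  prof <- prof + (target_mean_he - mean(prof))
  prof <- pmin(pmax(prof, 0.05), 0.88)

  local_seed(seed, {
    rows <- lapply(seq_len(n_loci), function(i) {
      t <- prof[i]
      k <- max(2L, min(9L, ceiling(1 / (1 - t)) + 2L))
      f <- NULL
      for (try in seq_len(2000L)) {
        x <- rgamma(k, 1)
        cand <- x / sum(x)
        if (abs(1 - sum(cand^2) - t) < 0.02) { f <- cand; break }
      }
      if (is.null(f)) {
        # deterministic fallback: mix a uniform with a point mass so the
        # locus He is exactly attainable, then renormalise
        he_mix <- function(l) {
          p <- rep(l / k, k); p[1] <- p[1] + 1 - l
          1 - sum(p^2)
        }
        lo <- 0; hi <- 1
        for (b in 1:60) {
          mid <- (lo + hi) / 2
          if (he_mix(mid) < t) lo <- mid else hi <- mid
        }
        f <- rep(lo / k, k); f[1] <- f[1] + 1 - lo
      }
      tibble::tibble(locus = sprintf("L%02d", i),
                     allele = sprintf("%d", 100L + 4L * seq_len(k)),
                     frequency = f / sum(f))
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate the pedigree and demography of a territorial wolf population
#'
#' Year-by-year: breeder mortality, vacancy filling (inheritance, local
#' dispersal, immigration), then one litter per occupied territory whose
#' pair satisfies the age minimum and is not a parent-offspring pairing.
#'
#' @param config A [population_config()].
#' @param seed Optional RNG seed.
#' @return List of class `wolfped_population`: `individuals` (id, sex,
#'   birth_year, death_year, pack, immigrant), `pedigree` (id, dam, sire;
#'   immigrants and founders carry UNSAMPLED parents), `events` (log of
#'   demographic events), `config`.
#' @export
simulate_population <- function(config = population_config(),
                                seed = NULL) {
  cfg <- config
  local_seed(seed, {
    nid <- 0L
    ind <- list()
    events <- list()
    new_ind <- function(sex, birth, pack, dam, sire, immigrant) {
      nid <<- nid + 1L
      id <- sprintf("W%03d", nid)
      ind[[id]] <<- list(id = id, sex = sex, birth = birth,
                         death = NA_integer_, pack = pack,
                         natal_pack = pack, dam = dam,
                         sire = sire, immigrant = immigrant)
      id
    }
    log_event <- function(year, pack, type, id) {
      events[[length(events) + 1L]] <<-
        tibble::tibble(year = year, pack = pack, type = type, id = id)
    }

    packs <- sprintf("P%d", seq_len(cfg$n_packs))
    open_year <- setNames(cfg$start_year +
                            rep_len(cfg$establishment_lags, cfg$n_packs),
                          packs)
    breeders <- setNames(rep(list(list(F = NA_character_,
                                       M = NA_character_)), cfg$n_packs),
                         packs)
    found_pack <- function(p, year) {
      fa <- year - cfg$min_breeding_age - sample.int(2L, 1L) + 1L
      ma <- year - cfg$min_breeding_age - sample.int(2L, 1L) + 1L
      breeders[[p]]$F <<- new_ind("F", fa, p, UNSAMPLED, UNSAMPLED, TRUE)
      breeders[[p]]$M <<- new_ind("M", ma, p, UNSAMPLED, UNSAMPLED, TRUE)
      log_event(year, p, "FOUNDING_PAIR", breeders[[p]]$F)
    }
    for (p in packs) if (open_year[[p]] <= cfg$start_year) {
      found_pack(p, cfg$start_year)
    }

    alive <- function(id, year) {
      x <- ind[[id]]
      is.na(x$death) || x$death >= year
    }
    is_parent_offspring <- function(a, b) {
      xa <- ind[[a]]; xb <- ind[[b]]
      (xa$dam %in% b) || (xa$sire %in% b) ||
        (xb$dam %in% a) || (xb$sire %in% a)
    }
    eligible <- function(year, sex, exclude_pack = NULL, same_pack = NULL) {
      cur <- unlist(lapply(breeders, function(b) c(b$F, b$M)))
      ok <- vapply(ind, function(x) {
        x$sex == sex && is.na(x$death) &&
          (year - x$birth) >= cfg$min_breeding_age &&
          !(x$id %in% cur) &&
          (is.null(same_pack) || x$pack == same_pack) &&
          (is.null(exclude_pack) || x$pack != exclude_pack)
      }, logical(1))
      names(ind)[ok]
    }

    if (cfg$years > 0L) {
      for (year in seq(cfg$start_year, cfg$start_year + cfg$years - 1L)) {
        # mortality of all adults (age >= 1)
        for (id in names(ind)) {
          x <- ind[[id]]
          if (is.na(x$death) && year > x$birth &&
              runif(1) < cfg$breeder_mortality) {
            ind[[id]]$death <- year - 1L
            log_event(year, x$pack, "DEATH", id)
          }
        }
        # newly opened territories are settled by an immigrant pair
        for (p in packs) {
          if (open_year[[p]] == year && is.na(breeders[[p]]$F)) {
            found_pack(p, year)
          }
        }
        # vacancies
        for (p in packs) {
          if (open_year[[p]] > year) next
          for (role in c("F", "M")) {
            cur <- breeders[[p]][[role]]
            if (!is.na(cur) && alive(cur, year)) next
            breeders[[p]][[role]] <- NA_character_
            partner <- breeders[[p]][[setdiff(c("F", "M"), role)]]
            ok_with_partner <- function(id) {
              is.na(partner) || !alive(partner, year) ||
                !is_parent_offspring(id, partner)
            }
            filled <- FALSE
            if (runif(1) < cfg$inherit_prob) {
              cand <- Filter(ok_with_partner,
                             eligible(year, role, same_pack = p))
              if (length(cand) > 0L) {
                heir <- sample(cand, 1L)
                breeders[[p]][[role]] <- heir
                log_event(year, p, "INHERIT", heir)
                filled <- TRUE
              }
            }
            if (!filled) {
              main_rate <- if (role == "F") cfg$female_dispersal else
                cfg$male_immigration
              if (runif(1) < main_rate) {
                if (role == "F") {   # local dispersal between packs
                  cand <- Filter(ok_with_partner,
                                 eligible(year, role, exclude_pack = p))
                  if (length(cand) > 0L) {
                    mover <- sample(cand, 1L)
                    ind[[mover]]$pack <- p
                    breeders[[p]][[role]] <- mover
                    log_event(year, p, "DISPERSE_IN", mover)
                    filled <- TRUE
                  }
                } else {             # immigration from outside
                  im <- new_ind("M", year - cfg$min_breeding_age, p,
                                UNSAMPLED, UNSAMPLED, TRUE)
                  breeders[[p]][[role]] <- im
                  log_event(year, p, "IMMIGRATE", im)
                  filled <- TRUE
                }
              }
            }
            if (!filled && runif(1) < cfg$cross_rate) {
              if (role == "F") {
                im <- new_ind("F", year - cfg$min_breeding_age, p,
                              UNSAMPLED, UNSAMPLED, TRUE)
                breeders[[p]][[role]] <- im
                log_event(year, p, "IMMIGRATE", im)
              } else {
                cand <- Filter(ok_with_partner,
                               eligible(year, role, exclude_pack = p))
                if (length(cand) > 0L) {
                  mover <- sample(cand, 1L)
                  ind[[mover]]$pack <- p
                  breeders[[p]][[role]] <- mover
                  log_event(year, p, "DISPERSE_IN", mover)
                }
              }
            }
          }
        }
        # litters: one per occupied territory with a legal pair
        for (p in packs) {
          if (open_year[[p]] > year) next
          f <- breeders[[p]]$F; m <- breeders[[p]]$M
          if (is.na(f) || is.na(m)) next
          if (!alive(f, year) || !alive(m, year)) next
          if ((year - ind[[f]]$birth) < cfg$min_breeding_age ||
              (year - ind[[m]]$birth) < cfg$min_breeding_age) next
          if (is_parent_offspring(f, m)) next
          n_cubs <- rpois(1L, cfg$litter_mean)
          if (n_cubs == 0L) next
          for (ci in seq_len(n_cubs)) {
            cub <- new_ind(sample(c("F", "M"), 1L), year, p, f, m, FALSE)
            log_event(year, p, "BIRTH", cub)
          }
        }
      }
    }

    individuals <- purrr::map_dfr(ind, function(x) {
      tibble::tibble(individual_id = x$id, sex = x$sex,
                     birth_year = x$birth, death_year = x$death,
                     pack = x$pack, natal_pack = x$natal_pack,
                     immigrant = x$immigrant)
    })
    pedigree <- purrr::map_dfr(ind, function(x) {
      tibble::tibble(id = x$id, dam = x$dam, sire = x$sire)
    })
    structure(list(individuals = individuals, pedigree = pedigree,
                   events = if (length(events) > 0L)
                     dplyr::bind_rows(events) else
                       tibble::tibble(year = integer(), pack = character(),
                                      type = character(), id = character()),
                   config = cfg),
              class = "wolfped_population")
  })
}

#' Simulate the detection, sampling and replicate-genotyping process
#'
#' Applies a detection layer to a simulated population (per-individual,
#' per-year detection), draws dated, geolocated samples per detection
#' (negative-binomial counts, faecal-dominated source mix), simulates true
#' genotypes down the pedigree and produces triplicate PCR replicate
#' observations through the dropout/miscall error model, escalating to a
#' second triplicate where the first fails the consensus rule.
#'
#' @param population A [simulate_population()] result.
#' @param config A [sampling_config()].
#' @param freqs Allele-frequency table (e.g. [make_frequency_table()]).
#' @param rates Error-rate table with `SCAT` and `TISSUE_SECRETION` rows
#'   per locus.
#' @param seed Optional RNG seed.
#' @return A list of class `wolfped_truth` (the truth package): `pedigree`
#'   and `individuals` restricted to detected individuals (plus the full
#'   versions under `population`), `true_genotypes`, `samples` (metadata),
#'   `replicates`, `membership`, `freqs`, `rates`, the configs and seed.
#' @export
simulate_sampling <- function(population, config = sampling_config(),
                              freqs, rates, seed = NULL) {
  stopifnot(inherits(population, "wolfped_population"))
  cfg <- config
  pop_cfg <- population$config
  freqs <- validate_frequencies(freqs)
  seeds <- derive_seeds(seed, 3L)

  # true genotypes for everyone ever alive
  sim <- simulate_genotypes_on_pedigree(population$pedigree, freqs,
                                        error_rates(unique(freqs$locus),
                                                    0, 0),
                                        seed = seeds[[1L]])
  true_gt <- sim$true

  years <- seq(pop_cfg$start_year,
               pop_cfg$start_year + max(pop_cfg$years, 1L) - 1L)
  centres <- tibble::tibble(
    pack = sprintf("P%d", seq_len(pop_cfg$n_packs)),
    cx = 60 * seq_len(pop_cfg$n_packs), cy = 40 * (seq_len(pop_cfg$n_packs) %% 3))

  local_seed(seeds[[2L]], {
    ind <- population$individuals
    samples <- list()
    sn <- 0L
    for (i in seq_len(nrow(ind))) {
      row <- ind[i, ]
      yrs <- years[years >= row$birth_year &
                     (is.na(row$death_year) | years <= row$death_year)]
      if (length(yrs) == 0L) next
      det <- yrs[runif(length(yrs)) < cfg$detection_prob]
      if (length(det) == 0L) next
      n_samp <- max(1L, rnbinom(1L, size = cfg$samples_size,
                                mu = cfg$samples_mean))
      yr_pick <- sample(det, n_samp, replace = TRUE)
      ctr <- centres[centres$pack == row$pack, ]
      for (y in yr_pick) {
        sn <- sn + 1L
        samples[[sn]] <- tibble::tibble(
          sample_id = sprintf("S%04d", sn),
          individual_id = row$individual_id,
          date = as.Date(sprintf("%d-01-01", y)) +
            sample.int(365L, 1L) - 1L,
          x = ctr$cx + rnorm(1, 0, pop_cfg$territory_spread),
          y = ctr$cy + rnorm(1, 0, pop_cfg$territory_spread),
          source_class = if (runif(1) < cfg$scat_fraction) "SCAT" else
            "TISSUE_SECRETION",
          collector = sprintf("C%02d", sample.int(cfg$n_collectors, 1L)),
          species_flag = "WOLF",
          sex = row$sex)
      }
    }
    samples <- dplyr::bind_rows(samples)
    if (nrow(samples) == 0L) {
      samples <- tibble::tibble(sample_id = character(),
                                individual_id = character(),
                                date = as.Date(character()),
                                x = numeric(), y = numeric(),
                                source_class = character(),
                                collector = character(),
                                species_flag = character(),
                                sex = character())
    }
    samples
  })

  # replicate observations: triplicate, escalate on failure
  replicates <- local_seed(seeds[[3L]], {
    gt_by_id <- split(true_gt, true_gt$individual_id)
    out <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      s <- samples[i, ]
      g <- gt_by_id[[s$individual_id]]
      g$source_class <- s$source_class
      trip1 <- dplyr::bind_rows(
        lapply(1:3, function(r) {
          o <- simulate_observations(g, freqs, rates,
                                     missing_prob = cfg$replicate_missing)
          tibble::tibble(sample_id = s$sample_id, locus = o$locus,
                         replicate = r, allele1 = o$allele1,
                         allele2 = o$allele2)
        }))
      cc <- call_consensus(trip1)
      unresolved <- cc$locus[cc$status == "UNRESOLVED"]
      if (length(unresolved) > 0L) {
        g2 <- g[g$locus %in% unresolved, ]
        trip2 <- dplyr::bind_rows(
          lapply(4:6, function(r) {
            o <- simulate_observations(g2, freqs, rates,
                                       missing_prob = cfg$replicate_missing)
            tibble::tibble(sample_id = s$sample_id, locus = o$locus,
                           replicate = r, allele1 = o$allele1,
                           allele2 = o$allele2)
          }))
        trip1 <- dplyr::bind_rows(trip1, trip2)
      }
      out[[i]] <- trip1
    }
    dplyr::bind_rows(out)
  })

  detected <- unique(samples$individual_id)
  ped_det <- population$pedigree |>
    dplyr::filter(.data$id %in% detected) |>
    dplyr::mutate(
      dam = ifelse(is.na(.data$dam) | .data$dam %in% detected,
                   .data$dam, UNSAMPLED),
      sire = ifelse(is.na(.data$sire) | .data$sire %in% detected,
                    .data$sire, UNSAMPLED))
  structure(list(
    pedigree = ped_det,
    individuals = dplyr::filter(population$individuals,
                                .data$individual_id %in% detected),
    population = population,
    true_genotypes = true_gt,
    samples = dplyr::select(samples, -"individual_id", -"sex"),
    membership = dplyr::select(samples, "sample_id", "individual_id"),
    sample_meta_full = samples,
    replicates = replicates,
    freqs = freqs, rates = rates,
    sampling_config = cfg, seed = seed),
    class = "wolfped_truth")
}

#' @export
print.wolfped_truth <- function(x, ...) {
  cat(sprintf(paste0("<wolfped_truth> %d detected individuals (of %d), ",
                     "%d samples, %d replicate rows\n"),
              nrow(x$individuals), nrow(x$population$individuals),
              nrow(x$samples), nrow(x$replicates)))
  invisible(x)
}

#' One-call synthetic study: population, frequencies, sampling
#'
#' Convenience wrapper producing a complete truth package under the
#' default study conditions (4 packs, 7 years, 17 loci at panel
#' diversity ~0.58, dropout 0.04 and miscall 0.022 on faecal samples).
#'
#' @param pop_config,samp_config,n_loci,target_mean_he,E1,E2 Overrides of
#'   the default conditions.
#' @param seed RNG seed.
#' @return A `wolfped_truth` object (see [simulate_sampling()]).
#' @export
simulate_truth <- function(pop_config = population_config(),
                           samp_config = sampling_config(),
                           n_loci = 17L, target_mean_he = 0.58,
                           E1 = 0.04, E2 = 0.022, seed = NULL) {
  seeds <- derive_seeds(seed, 3L)
  freqs <- make_frequency_table(n_loci, target_mean_he, seed = seeds[[1L]])
  loci <- unique(freqs$locus)
  rates <- dplyr::bind_rows(error_rates(loci, E1, E2, "SCAT"),
                            error_rates(loci, 0.01, 0.005,
                                        "TISSUE_SECRETION"))
  pop <- simulate_population(pop_config, seed = seeds[[2L]])
  simulate_sampling(pop, samp_config, freqs, rates, seed = seeds[[3L]])
}

#' Build analysis-ready inputs from a truth package
#'
#' Runs the laboratory-side pipeline on the simulated replicate data --
#' consensus calling and individual identification -- and then labels each
#' recovered cluster with the generating individual's id (by majority over
#' its member samples' true origins) so that downstream pedigree fits can
#' be scored against the truth. Clusters that merge several generating
#' individuals or split one across clusters are reported.
#'
#' @param truth A `wolfped_truth` object.
#' @param rules,rule Consensus and matching rules.
#' @return List: `individuals` (id, sex, first_seen, last_seen,
#'   source_class), `genotypes` (consensus, keyed by true ids),
#'   `detections` (for birth-year inference), `mapping`
#'   (cluster -> true id), `clean` (TRUE when the identification was a
#'   bijection onto the detected individuals).
#' @export
truth_to_inputs <- function(truth, rules = consensus_rules(),
                            rule = match_rule()) {
  stopifnot(inherits(truth, "wolfped_truth"))
  cc <- call_consensus(truth$replicates, rules)
  meta <- truth$sample_meta_full[c("sample_id", "date", "source_class",
                                   "sex")]
  cl <- cluster_samples(cc, metadata = meta, rule = rule)

  mapping <- cl$membership |>
    dplyr::inner_join(truth$membership, by = "sample_id",
                      suffix = c("_cluster", "_true")) |>
    dplyr::count(.data$individual_id_cluster, .data$individual_id_true) |>
    dplyr::group_by(.data$individual_id_cluster) |>
    dplyr::mutate(n_true = dplyr::n()) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  clean <- all(mapping$n_true == 1L) &&
    !anyDuplicated(mapping$individual_id_true)

  relabel <- setNames(mapping$individual_id_true,
                      mapping$individual_id_cluster)
  genotypes <- cl$genotypes |>
    dplyr::mutate(individual_id = unname(relabel[.data$individual_id])) |>
    dplyr::filter(!is.na(.data$individual_id))
  individuals <- cl$individuals |>
    dplyr::mutate(individual_id = unname(relabel[.data$individual_id])) |>
    dplyr::filter(!is.na(.data$individual_id)) |>
    dplyr::left_join(truth$individuals[c("individual_id", "death_year")],
                     by = "individual_id")
  detections <- individuals |>
    dplyr::transmute(.data$individual_id, first_seen = .data$first_seen)
  membership <- cl$membership |>
    dplyr::mutate(individual_id = unname(relabel[.data$individual_id])) |>
    dplyr::filter(!is.na(.data$individual_id))
  list(individuals = individuals, genotypes = genotypes,
       detections = detections, membership = membership,
       mapping = mapping, clean = clean)
}
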