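#' Configuration for the staged pedigree-estimation protocol
#'
#' Defaults follow the staged analysis the package implements: a
#' preliminary fit at fixed literature error rates, per-locus error-rate
#' estimation against the confident part of that pedigree, identification
#' of possible breeders from 20 replicate fits, 20 replicate main fits
#' restricted to those breeders, averaging of the modal pedigrees, and
#' biological consistency checks.
#'
#' @param step1 Preliminary fit: iterations, burn-in, fixed `E1`, `E2`.
#' @param step2 Error estimation: chain init, confidence cutoff selecting
#'   the input pedigree links, iterations, burn-in.
#' @param step3 Breeder identification: number of runs, iterations,
#'   burn-in, the assignment-share threshold for entering the possible-
#'   breeder set, and the aggregation rule (`"pooled"` counts assignments
#'   over all runs jointly; `"per_run"` admits anyone passing the
#'   threshold in a single run).
#' @param step4 Main fit: number of runs, iterations, burn-in.
#' @param step5 Averaging rule for pairs absent from a run's modal
#'   pedigree: `"zero"` (contribute 0 for that run) or `"present_only"`.
#' @param thresholds Confidence vocabulary: `confident` (> 0.80), `high`
#'   (> 0.90), `very_high` (> 0.95), `medium` band (0.70--0.80).
#' @param thinning Chain thinning (every 2 iterations).
#' @param min_breeding_age Minimum parental age in years (default 2).
#' @param tissue_E1,tissue_E2 Constant error rates for tissue/secretion
#'   samples.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(
    step1 = list(iterations = 20000L, burn_in = 2000L, E1 = 0.04,
                 E2 = 0.022),
    step2 = list(init = 0.1, conf_cutoff = 0.90, iterations = 4000L,
                 burn_in = 1000L),
    step3 = list(runs = 20L, iterations = 25000L, burn_in = 1000L,
                 breeder_threshold = 0.05, aggregation = "pooled"),
    step4 = list(runs = 20L, iterations = 30000L, burn_in = 3000L),
    step5 = list(absent = "zero"),
    thresholds = list(confident = 0.80, high = 0.90, very_high = 0.95,
                      medium = c(0.70, 0.80)),
    thinning = 2L, min_breeding_age = 2L,
    tissue_E1 = 0.01, tissue_E2 = 0.005) {
  stopifnot(step3$runs >= 1L, step4$runs >= 1L,
            thresholds$confident > 0, thresholds$confident < 1)
  structure(list(step1 = step1, step2 = step2, step3 = step3,
                 step4 = step4, step5 = step5, thresholds = thresholds,
                 thinning = as.integer(thinning),
                 min_breeding_age = as.integer(min_breeding_age),
                 tissue_E1 = tissue_E1, tissue_E2 = tissue_E2),
            class = "protocol_config")
}

settings_for <- function(step, config, seed, ...) {
  mcmc_settings(iterations = step$iterations, burn_in = step$burn_in,
                thinning = config$thinning, seed = seed, ...)
}

#' Step 1: preliminary pedigree at fixed error rates
#'
#' A single chain at literature error rates; its modal pedigree provides
#' the high-confidence links used as the fixed input pedigree for error
#' estimation.
#'
#' @inheritParams sample_pedigree
#' @param config A [protocol_config()].
#' @param seed RNG seed.
#' @return List: `pedigree` (modal, with confidences), `posterior`,
#'   `high_confidence` (links above the step-2 cutoff), `rates` used.
#' @export
step1_preliminary <- function(individuals, genotypes, freqs,
                              config = protocol_config(), seed = NULL) {
  loci <- unique(validate_frequencies(freqs)$locus)
  rates <- dplyr::bind_rows(
    error_rates(loci, config$step1$E1, config$step1$E2, "SCAT"),
    error_rates(loci, config$tissue_E1, config$tissue_E2,
                "TISSUE_SECRETION"))
  post <- sample_pedigree(individuals, genotypes, freqs, rates,
                          settings = settings_for(config$step1, config,
                                                  seed))
  ped <- modal_pedigree(post)
  cutoff <- config$step2$conf_cutoff
  high <- ped |>
    dplyr::mutate(dam = ifelse(.data$dam_prob > cutoff, .data$dam,
                               NA_character_),
                  sire = ifelse(.data$sire_prob > cutoff, .data$sire,
                                NA_character_))
  list(pedigree = ped, posterior = post,
       high_confidence = high[c("id", "dam", "sire")], rates = rates)
}

#' Step 3: identify possible breeders from replicate modal pedigrees
#'
#' Runs the sampler `runs` times at the estimated error rates; an
#' individual assigned as a parent in at least `breeder_threshold` of
#' parentages across the pooled modal pedigrees becomes a "possible
#' breeder" for the main fit. An individual can occupy at most one
#' parental role per offspring, so the denominator is the offspring count
#' per role per run (maternities for a dam, paternities for a sire); the
#' `"per_run"` aggregation admits anyone passing the threshold within a
#' single run.
#'
#' @inheritParams step1_preliminary
#' @param rates Error-rate table (typically from [rates_from_estimates()]).
#' @return List: `breeders` (character vector), `share` (per-individual
#'   assignment share), `pedigrees` (list of modal pedigrees).
#' @export
step3_possible_breeders <- function(individuals, genotypes, freqs, rates,
                                    config = protocol_config(),
                                    seed = NULL) {
  runs <- config$step3$runs
  seeds <- derive_seeds(seed, runs)
  peds <- lapply(seq_len(runs), function(r) {
    post <- sample_pedigree(individuals, genotypes, freqs, rates,
                            settings = settings_for(config$step3, config,
                                                    seeds[[r]]))
    modal_pedigree(post)
  })
  n_off <- nrow(individuals)
  count_in <- function(ped) {
    p <- c(ped$dam, ped$sire)
    table(factor(p[is_sampled_parent(p)],
                 levels = individuals$individual_id))
  }
  counts <- vapply(peds, count_in, numeric(nrow(individuals)))
  thr <- config$step3$breeder_threshold
  if (identical(config$step3$aggregation, "per_run")) {
    share <- apply(counts / n_off, 1L, max)
  } else {
    share <- rowSums(counts) / (n_off * runs)
  }
  breeders <- names(share)[share >= thr]
  list(breeders = breeders,
       share = tibble::tibble(individual_id = names(share),
                              share = unname(share)),
       pedigrees = peds)
}

#' Step 4: replicate main fits restricted to possible breeders
#'
#' @inheritParams step3_possible_breeders
#' @param breeders Possible-breeder ids from [step3_possible_breeders()].
#' @return List of modal pedigrees (length `config$step4$runs`).
#' @export
step4_main_fit <- function(individuals, genotypes, freqs, rates, breeders,
                           config = protocol_config(), seed = NULL) {
  runs <- config$step4$runs
  seeds <- derive_seeds(seed, runs)
  lapply(seq_len(runs), function(r) {
    post <- sample_pedigree(individuals, genotypes, freqs, rates,
                            settings = settings_for(config$step4, config,
                                                    seeds[[r]]),
                            candidates = breeders)
    modal_pedigree(post)
  })
}

#' Step 5: average modal pedigrees into the main pedigree
#'
#' Per offspring, every parent pair appearing in any run's modal pedigree
#' receives its mean support across runs (a run where the pair is not the
#' mode contributes 0 under the default rule); the pair with the highest
#' mean wins, ties broken towards UNSAMPLED then lexicographically.
#'
#' @param pedigrees List of modal pedigrees from [step4_main_fit()].
#' @param absent `"zero"` (default) or `"present_only"`.
#' @return Pedigree tibble `id`, `dam`, `sire`, `confidence` (mean support
#'   of the winning pair), `n_runs` (runs in which it was modal), `flag`.
#' @export
step5_average <- function(pedigrees, absent = "zero") {
  stopifnot(length(pedigrees) >= 1L)
  runs <- length(pedigrees)
  all <- dplyr::bind_rows(pedigrees, .id = "run")
  agg <- all |>
    dplyr::group_by(.data$id, .data$dam, .data$sire) |>
    dplyr::summarise(total = sum(.data$pair_prob), n_runs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(confidence = if (identical(absent, "present_only"))
      .data$total / .data$n_runs else .data$total / runs)
  agg |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(dplyr::desc(.data$confidence),
                   dplyr::desc((.data$dam == UNSAMPLED) +
                                 (.data$sire == UNSAMPLED)),
                   .data$dam, .data$sire, .by_group = TRUE) |>
    dplyr::mutate(flag = ifelse(dplyr::n() > 1L &&
                                  isTRUE(all.equal(.data$confidence[1L],
                                                   .data$confidence[2L])),
                                "TIE", "")) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("id", "dam", "sire", "confidence", "n_runs", "flag")
}

#' Step 6: biological consistency checks and assignment summary
#'
#' Flags assignments that conflict with the biology of the system:
#' `ANACHRONISM` when inferred birth years leave a parent younger than the
#' minimum breeding age; `SINGLE_OFFSPRING_PAIR` for medium-confidence
#' (0.70--0.80) parent pairs represented by a single offspring (wolf pairs
#' produce litters of several cubs, so such assignments are suspect);
#' `TERRITORY_CONFLICT` when two distinct pairs are assigned litters in
#' one territory-year. Also tabulates, at the confident threshold, how
#' many individuals have both parents, only a mother, only a father, or
#' neither assigned.
#'
#' @param pedigree Main pedigree from [step5_average()] (columns `id`,
#'   `dam`, `sire`, `confidence`; or `dam_prob`/`sire_prob` per slot).
#' @param detections Detection table for [infer_birth_years()].
#' @param territories Optional tibble `individual_id`, `territory` (natal
#'   territory of each offspring).
#' @param config A [protocol_config()].
#' @return List: `flags` (tibble `id`, `flag`, `detail`),
#'   `assignment_summary` (both / only_mother / only_father / neither),
#'   `birth_years`.
#' @export
step6_consistency <- function(pedigree, detections = NULL,
                              territories = NULL,
                              config = protocol_config()) {
  ped <- tibble::as_tibble(pedigree)
  thr <- config$thresholds
  dam_conf <- if ("dam_prob" %in% names(ped)) ped$dam_prob else
    ped$confidence
  sire_conf <- if ("sire_prob" %in% names(ped)) ped$sire_prob else
    ped$confidence
  pair_conf <- if ("confidence" %in% names(ped)) ped$confidence else
    pmin(dam_conf, sire_conf)

  flags <- list()
  by <- NULL
  if (!is.null(detections)) {
    by <- infer_birth_years(ped[c("id", "dam", "sire")], detections,
                            config$min_breeding_age)
    yr <- setNames(by$birth_year, by$individual_id)
    for (i in seq_len(nrow(ped))) {
      for (col in c("dam", "sire")) {
        p <- ped[[col]][i]
        if (!is_sampled_parent(p)) next
        yo <- yr[[ped$id[i]]]; yp <- yr[[p]]
        if (!is.na(yo) && !is.na(yp) &&
            yp + config$min_breeding_age > yo) {
          flags <- c(flags, list(tibble::tibble(
            id = ped$id[i], flag = "ANACHRONISM",
            detail = sprintf("%s %s born %d, offspring born %d (min age %d)",
                             col, p, yp, yo, config$min_breeding_age))))
        }
      }
    }
    # also conflicts surfaced by the propagation itself
    conf <- by$individual_id[by$status == "CONFLICT"]
    for (id in conf) {
      flags <- c(flags, list(tibble::tibble(
        id = id, flag = "ANACHRONISM",
        detail = "birth-year constraints admit no solution")))
    }
  }

  # medium-confidence single-offspring pairs
  pairs <- ped |>
    dplyr::mutate(pair_conf = pair_conf) |>
    dplyr::filter(is_sampled_parent(.data$dam) &
                    is_sampled_parent(.data$sire)) |>
    dplyr::group_by(.data$dam, .data$sire) |>
    dplyr::summarise(n_offspring = dplyr::n(),
                     ids = list(.data$id),
                     max_conf = max(.data$pair_conf), .groups = "drop")
  med <- pairs |>
    dplyr::filter(.data$n_offspring == 1L &
                    .data$max_conf >= thr$medium[1L] &
                    .data$max_conf <= thr$medium[2L])
  for (i in seq_len(nrow(med))) {
    flags <- c(flags, list(tibble::tibble(
      id = med$ids[[i]][1L], flag = "SINGLE_OFFSPRING_PAIR",
      detail = sprintf("pair (%s, %s) at confidence %.2f has one offspring",
                       med$dam[i], med$sire[i], med$max_conf[i]))))
  }

  if (!is.null(territories) && !is.null(by)) {
    yr <- setNames(by$birth_year, by$individual_id)
    terr <- setNames(territories$territory, territories$individual_id)
    litters <- ped |>
      dplyr::filter(is_sampled_parent(.data$dam) |
                      is_sampled_parent(.data$sire)) |>
      dplyr::mutate(year = unname(yr[.data$id]),
                    territory = unname(terr[.data$id])) |>
      dplyr::filter(!is.na(.data$year) & !is.na(.data$territory)) |>
      dplyr::distinct(.data$territory, .data$year, .data$dam, .data$sire)
    dup <- litters |>
      dplyr::count(.data$territory, .data$year) |>
      dplyr::filter(.data$n > 1L)
    for (i in seq_len(nrow(dup))) {
      flags <- c(flags, list(tibble::tibble(
        id = NA_character_, flag = "TERRITORY_CONFLICT",
        detail = sprintf("%d litters in territory %s in %d",
                         dup$n[i], dup$territory[i], dup$year[i]))))
    }
  }

  conf_dam <- is_sampled_parent(ped$dam) | ped$dam %in% UNSAMPLED
  conf_dam <- conf_dam & dam_conf > thr$confident
  conf_sire <- is_sampled_parent(ped$sire) | ped$sire %in% UNSAMPLED
  conf_sire <- conf_sire & sire_conf > thr$confident
  summary <- tibble::tibble(
    both = sum(conf_dam & conf_sire),
    only_mother = sum(conf_dam & !conf_sire),
    only_father = sum(!conf_dam & conf_sire),
    neither = sum(!conf_dam & !conf_sire),
    n_individuals = nrow(ped))

  list(flags = if (length(flags) > 0L) dplyr::bind_rows(flags) else
    tibble::tibble(id = character(), flag = character(),
                   detail = character()),
    assignment_summary = summary,
    birth_years = by)
}

#' Run the full staged protocol
#'
#' Orchestrates steps 1--6. When replicate-level data are unavailable,
#' step 2 is skipped and the step-1 literature rates are carried through
#' (flagged in the result).
#'
#' @inheritParams step1_preliminary
#' @param replicates,membership,metadata Per-sample replicate data for
#'   step 2 (optional).
#' @param detections,territories Step-6 inputs (optional).
#' @param seed RNG seed governing all stages.
#' @return An object of class `wolfped_protocol` with elements `step1`,
#'   `error_estimates`, `rates`, `breeders`, `main_runs`, `main_pedigree`,
#'   `report`, `config`, `seed`.
#' @export
run_protocol <- function(individuals, genotypes, freqs,
                         replicates = NULL, membership = NULL,
                         metadata = NULL, detections = NULL,
                         territories = NULL,
                         config = protocol_config(), seed = NULL) {
  seeds <- derive_seeds(seed, 4L)
  s1 <- step1_preliminary(individuals, genotypes, freqs, config,
                          seed = seeds[[1L]])
  if (!is.null(replicates) && !is.null(membership)) {
    est <- estimate_error_rates(replicates, membership, freqs,
                                pedigree = s1$high_confidence,
                                genotypes = genotypes,
                                metadata = metadata,
                                init = config$step2$init,
                                iterations = config$step2$iterations,
                                burn_in = config$step2$burn_in,
                                seed = seeds[[2L]])
    rates <- rates_from_estimates(est, config$tissue_E1, config$tissue_E2)
  } else {
    est <- NULL
    rates <- s1$rates
  }
  s3 <- step3_possible_breeders(individuals, genotypes, freqs, rates,
                                config, seed = seeds[[3L]])
  s4 <- step4_main_fit(individuals, genotypes, freqs, rates, s3$breeders,
                       config, seed = seeds[[4L]])
  main <- step5_average(s4, absent = config$step5$absent)
  report <- step6_consistency(main, detections, territories, config)
  structure(list(step1 = s1, error_estimates = est, rates = rates,
                 breeders = s3$breeders, breeder_share = s3$share,
                 main_runs = s4, main_pedigree = main, report = report,
                 config = config, seed = seed),
            class = "wolfped_protocol")
}

#' @export
print.wolfped_protocol <- function(x, ...) {
  cat("<wolfped_protocol>\n")
  cat(sprintf("  %d individuals, %d possible breeders\n",
              nrow(x$main_pedigree), length(x$breeders)))
  print(x$report$assignment_summary)
  invisible(x)
}

#' @export
tidy.wolfped_protocol <- function(x, ...) {
  x$main_pedigree
}

#' @export
glance.wolfped_protocol <- function(x, ...) {
  dplyr::bind_cols(
    x$report$assignment_summary,
    tibble::tibble(n_breeders = length(x$breeders),
                   n_flags = nrow(x$report$flags)))
}

#' @export
autoplot.wolfped_protocol <- function(object, ...) {
  d <- object$main_pedigree
  ggplot2::ggplot(d, ggplot2::aes(x = .data$confidence)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$config$thresholds$confident,
                        linetype = 2) +
    ggplot2::labs(x = "parent-pair confidence", y = "offspring")
}
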