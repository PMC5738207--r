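#' Subsample a marker panel for the power experiment
#'
#' Panels up to the full panel size are drawn without replacement; larger
#' panels (up to twice the panel) take every real locus once plus a second
#' group drawn without replacement, so duplicated loci occur only across
#' groups. Duplicates are treated downstream as independent markers sharing
#' the source locus' allele frequencies.
#'
#' @param loci Character vector of available locus ids.
#' @param size Target panel size (1 to `2 * length(loci)`).
#' @param seed Optional RNG seed.
#' @return A tibble `locus` (instance id, `<locus>.2` for duplicates),
#'   `source` (the real locus).
#' @export
subsample_panel <- function(loci, size, seed = NULL) {
  n <- length(loci)
  stopifnot(size >= 1L)
  if (size > 2L * n) {
    abort(sprintf("panel size %d exceeds the design ceiling %d (twice the panel)",
                  size, 2L * n))
  }
  local_seed(seed, {
    if (size <= n) {
      src <- sample(loci, size)
      tibble::tibble(locus = src, source = src)
    } else {
      extra <- sample(loci, size - n)
      tibble::tibble(locus = c(loci, paste0(extra, ".2")),
                     source = c(loci, extra))
    }
  })
}

#' Simulate genotypes for all pedigree members and their observations
#'
#' Founders (individuals with no sampled parents) draw genotypes from
#' Hardy-Weinberg at the supplied frequencies; descendants receive alleles
#' by Mendelian segregation in pedigree order, with UNSAMPLED parental
#' slots contributing population alleles. Observed genotypes are then
#' produced through the dropout/miscall error model.
#'
#' @param pedigree True pedigree tibble (`id`, `dam`, `sire`).
#' @param freqs Allele-frequency table.
#' @param rates Error-rate table.
#' @param panel Optional panel from [subsample_panel()]; default all loci
#'   once. Duplicated instances are simulated as independent loci with the
#'   source locus' frequencies.
#' @param individuals Optional individuals tibble carrying `source_class`
#'   per id for rate lookup.
#' @param seed Optional RNG seed.
#' @return List: `true` and `observed` long genotype tables, and
#'   `panel_freqs` (the frequency table over panel instances, for fitting).
#' @export
simulate_genotypes_on_pedigree <- function(pedigree, freqs, rates,
                                           panel = NULL,
                                           individuals = NULL,
                                           seed = NULL) {
  ped <- as_pedigree(pedigree)
  chk <- is_legal(ped)
  if (!chk$legal) abort(paste0("illegal pedigree: ",
                               chk$violations$detail[1L]))
  freqs <- validate_frequencies(freqs)
  if (is.null(panel)) {
    panel <- tibble::tibble(locus = unique(freqs$locus),
                            source = unique(freqs$locus))
  }
  panel_freqs <- panel |>
    dplyr::left_join(freqs, by = c("source" = "locus"),
                     relationship = "many-to-many") |>
    dplyr::select("locus", "allele", "frequency")
  panel_rates <- panel |>
    dplyr::left_join(rates, by = c("source" = "locus"),
                     relationship = "many-to-many") |>
    dplyr::select("locus", "source_class", "E1", "E2")
  lms <- locus_models(panel_freqs)

  # topological order: parents before offspring
  order_ids <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0L) {
    ready <- !is_sampled_parent(remaining$dam) |
      remaining$dam %in% order_ids
    ready <- ready & (!is_sampled_parent(remaining$sire) |
                        remaining$sire %in% order_ids)
    order_ids <- c(order_ids, remaining$id[ready])
    remaining <- remaining[!ready, ]
  }

  local_seed(seed, {
    true <- list()
    geno <- list()  # per id: named list locus -> c(a1, a2)
    dam_of <- setNames(ped$dam, ped$id)
    sire_of <- setNames(ped$sire, ped$id)
    for (id in order_ids) {
      g <- vector("list", length(lms))
      names(g) <- names(lms)
      for (lc in names(lms)) {
        lm <- lms[[lc]]
        draw_from <- function(p) {
          if (!is_sampled_parent(p)) {
            sample(lm$alleles, 1L, prob = lm$f)
          } else {
            pg <- geno[[p]][[lc]]
            pg[sample.int(2L, 1L)]
          }
        }
        g[[lc]] <- c(draw_from(dam_of[[id]]), draw_from(sire_of[[id]]))
      }
      geno[[id]] <- g
    }
    true_tbl <- purrr::map_dfr(order_ids, function(id) {
      tibble::tibble(individual_id = id, locus = names(geno[[id]]),
                     allele1 = vapply(geno[[id]], function(x)
                       min(x), character(1)),
                     allele2 = vapply(geno[[id]], function(x)
                       max(x), character(1)))
    })
    if (!is.null(individuals) && "source_class" %in% names(individuals)) {
      cls <- setNames(individuals$source_class,
                      individuals$individual_id)
      true_tbl$source_class <- ifelse(is.na(cls[true_tbl$individual_id]),
                                      "SCAT",
                                      cls[true_tbl$individual_id])
    }
    obs <- simulate_observations(true_tbl, panel_freqs, panel_rates)
    list(true = true_tbl, observed = obs, panel_freqs = panel_freqs,
         panel_rates = panel_rates)
  })
}

#' Score a fitted pedigree against the truth
#'
#' An assignment (a dam or sire slot) is confident when its support
#' exceeds `threshold`, and correct when it names the true parent; an
#' UNSAMPLED assignment is correct only when the true parent is itself
#' outside the sampled set.
#'
#' @param fitted Pedigree tibble with per-slot or per-pair confidences
#'   (`dam_prob`/`sire_prob`, or `confidence` applied to both slots).
#' @param truth True pedigree tibble over the same individuals.
#' @param threshold Confidence threshold (default 0.80).
#' @return One-row tibble: `n_assignable` (2 x individuals),
#'   `n_confident`, `n_confident_correct`, `n_correct`, `fp_fraction`
#'   (incorrect fraction among confident assignments).
#' @export
evaluate_assignments <- function(fitted, truth, threshold = 0.80) {
  f <- tibble::as_tibble(fitted)
  t <- as_pedigree(truth)
  if (!setequal(f$id, t$id)) {
    abort("fitted and true pedigrees cover different individuals")
  }
  m <- dplyr::left_join(f, t, by = "id", suffix = c("", "_true"))
  dam_conf <- if ("dam_prob" %in% names(m)) m$dam_prob else m$confidence
  sire_conf <- if ("sire_prob" %in% names(m)) m$sire_prob else
    m$confidence

  slot_correct <- function(assigned, true_parent) {
    ifelse(is.na(assigned), FALSE,
           ifelse(assigned == UNSAMPLED, !is_sampled_parent(true_parent),
                  !is.na(true_parent) & assigned == true_parent))
  }
  dam_ok <- slot_correct(m$dam, m$dam_true)
  sire_ok <- slot_correct(m$sire, m$sire_true)
  dam_confident <- !is.na(m$dam) & dam_conf > threshold
  sire_confident <- !is.na(m$sire) & sire_conf > threshold

  n_conf <- sum(dam_confident) + sum(sire_confident)
  n_conf_ok <- sum(dam_confident & dam_ok) + sum(sire_confident & sire_ok)
  tibble::tibble(
    n_assignable = 2L * nrow(m),
    n_confident = n_conf,
    n_confident_correct = n_conf_ok,
    n_correct = sum(dam_ok) + sum(sire_ok),
    fp_fraction = ifelse(n_conf > 0, (n_conf - n_conf_ok) / n_conf, 0))
}

#' Marker-panel power experiment
#'
#' For each panel size and replicate: subsample the panel, simulate
#' genotypes on the true pedigree through the error model, refit the
#' pedigree (protocol steps 3--5: breeder identification, replicated main
#' fits, averaging) and score the result against the truth. Reports the
#' per-replicate scores, per-size means with standard errors, and linear
#' trends of the correct-confident count on panel size for the
#' full-panel-to-plus-three contrast and for the extended range, in both
#' per-marker and per-contrast form.
#'
#' @param truth True pedigree tibble.
#' @param individuals Individuals table (sex, detection dates) used for
#'   fitting.
#' @param freqs Base allele-frequency table (the real panel).
#' @param rates Error-rate table.
#' @param sizes Panel sizes (default `c(5, 10, 17, 20, 25, 30, 34)`).
#' @param reps Simulated genotype sets per size (default 10).
#' @param breeders Optional possible-parent set reused across all fits
#'   (the study design: the power simulations use the same set of
#'   possible parents as the main analysis). Default `NULL` re-runs the
#'   breeder identification (step 3) on every simulated data set.
#' @param config Protocol configuration used for the fits.
#' @param threshold Confidence threshold (default 0.80).
#' @param seed RNG seed.
#' @return Object of class `wolfped_power`: `scores`, `summary`, `slopes`.
#' @export
panel_power_experiment <- function(truth, individuals, freqs, rates,
                                   sizes = c(5, 10, 17, 20, 25, 30, 34),
                                   reps = 10L, breeders = NULL,
                                   config = protocol_config(),
                                   threshold = 0.80, seed = NULL) {
  loci <- unique(validate_frequencies(freqs)$locus)
  grid <- tidyr::expand_grid(size = as.integer(sizes),
                             replicate = seq_len(reps))
  seeds <- derive_seeds(seed, nrow(grid) * 3L)
  scores <- purrr::pmap_dfr(grid, function(size, replicate) {
    i <- (match(size, sizes) - 1L) * reps + replicate
    panel <- subsample_panel(loci, size, seed = seeds[[3L * i - 2L]])
    sim <- simulate_genotypes_on_pedigree(truth, freqs, rates, panel,
                                          individuals = individuals,
                                          seed = seeds[[3L * i - 1L]])
    fit_seed <- seeds[[3L * i]]
    fit_seeds <- derive_seeds(fit_seed, 2L)
    br <- breeders
    if (is.null(br)) {
      s3 <- step3_possible_breeders(individuals, sim$observed,
                                    sim$panel_freqs, sim$panel_rates,
                                    config, seed = fit_seeds[[1L]])
      br <- s3$breeders
    }
    s4 <- step4_main_fit(individuals, sim$observed, sim$panel_freqs,
                         sim$panel_rates, br, config,
                         seed = fit_seeds[[2L]])
    main <- step5_average(s4, absent = config$step5$absent)
    dplyr::bind_cols(tibble::tibble(size = size, replicate = replicate),
                     evaluate_assignments(main, truth, threshold))
  })
  summ <- scores |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      mean_confident = mean(.data$n_confident),
      se_confident = se_of(.data$n_confident),
      mean_correct = mean(.data$n_confident_correct),
      se_correct = se_of(.data$n_confident_correct),
      mean_fp = mean(.data$fp_fraction), .groups = "drop")

  slope_tbl <- function(sub, label) {
    if (length(unique(sub$size)) < 2L) return(NULL)
    fit <- lm(n_confident_correct ~ size, data = sub)
    tibble::tibble(range = label,
                   slope_per_marker = coef(fit)[["size"]],
                   se = sqrt(diag(stats::vcov(fit)))[["size"]])
  }
  full <- length(loci)
  slopes <- dplyr::bind_rows(
    slope_tbl(dplyr::filter(scores, .data$size %in% c(full, full + 3L)),
              sprintf("%d-%d", full, full + 3L)),
    slope_tbl(dplyr::filter(scores, .data$size > full),
              sprintf(">%d", full)))
  contrast <- summ$mean_correct[match(full + 3L, summ$size)] -
    summ$mean_correct[match(full, summ$size)]

  structure(list(scores = scores, summary = summ, slopes = slopes,
                 contrast_full_plus3 = contrast,
                 threshold = threshold, seed = seed),
            class = "wolfped_power")
}

#' @export
print.wolfped_power <- function(x, ...) {
  cat("<wolfped_power> panel-size power experiment\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.wolfped_power <- function(x, ...) x$scores

#' @export
glance.wolfped_power <- function(x, ...) {
  tibble::tibble(n_sizes = length(unique(x$scores$size)),
                 reps = max(x$scores$replicate),
                 threshold = x$threshold)
}

#' @export
autoplot.wolfped_power <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$summary,
    cols = c("mean_confident", "mean_correct"),
    names_to = "measure", values_to = "mean")
  d$se <- ifelse(d$measure == "mean_confident",
                 object$summary$se_confident[match(d$size,
                                                   object$summary$size)],
                 object$summary$se_correct[match(d$size,
                                                 object$summary$size)])
  d$measure <- ifelse(d$measure == "mean_confident", "confident",
                      "confident & correct")
  max_slots <- max(object$scores$n_assignable)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$mean,
                                  colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = max_slots, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             position = ggplot2::position_dodge(0.6)) +
    ggplot2::scale_colour_manual(values = c("black", "grey55")) +
    ggplot2::labs(x = "panel size (loci)", y = "assignments",
                  colour = NULL)
}
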