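#' Rules for declaring two multilocus genotypes the same individual
#'
#' Because non-invasive DNA is error-prone, two genotypes are allowed a small
#' number of mismatching alleles and still treated as one individual. The
#' default permits at most two mismatching alleles in total, at most one at
#' any single locus (so a two-allele discrepancy concentrated at one locus,
#' e.g. A/B vs C/D, is not a match), and requires at least `min_overlap` loci
#' typed in both genotypes before any call is made.
#'
#' @param max_mismatch Total mismatching alleles tolerated (default 2).
#' @param per_locus_cap If `TRUE` (default) no single locus may contribute
#'   two mismatches; `FALSE` gives a plain total-count rule.
#' @param min_overlap Minimum shared typed loci for a comparison (default 8);
#'   below this the comparison returns `NO_CALL` (`is_match = NA`).
#' @return A list of class `match_rule`.
#' @export
match_rule <- function(max_mismatch = 2L, per_locus_cap = TRUE,
                       min_overlap = 8L) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 per_locus_cap = isTRUE(per_locus_cap),
                 min_overlap = as.integer(min_overlap)),
            class = "match_rule")
}

# Per-locus mismatching alleles: 2 - |multiset intersection of allele pairs|.
# Inputs are equal-length allele vectors for the shared loci.
locus_mismatches <- function(a1, a2, b1, b2) {
  # order within pair first so exact equality catches 0-mismatch cases
  lo_a <- pmin(a1, a2); hi_a <- pmax(a1, a2)
  lo_b <- pmin(b1, b2); hi_b <- pmax(b1, b2)
  exact <- lo_a == lo_b & hi_a == hi_b
  shared <- lo_a == lo_b | lo_a == hi_b | hi_a == lo_b | hi_a == hi_b
  ifelse(exact, 0L, ifelse(shared, 1L, 2L))
}

#' Compare two multilocus genotypes under a matching rule
#'
#' @param g1,g2 Data frames with columns `locus`, `allele1`, `allele2`
#'   (`NA` alleles = locus untyped).
#' @param rule A [match_rule()].
#' @return A one-row tibble: `is_match` (`NA` when fewer than
#'   `min_overlap` loci are typed in both), `mismatching_alleles`,
#'   `loci_compared`.
#' @export
match_genotypes <- function(g1, g2, rule = match_rule()) {
  assert_cols(g1, c("locus", "allele1", "allele2"), "g1")
  assert_cols(g2, c("locus", "allele1", "allele2"), "g2")
  m <- dplyr::inner_join(
    dplyr::filter(g1, !is.na(.data$allele1) & !is.na(.data$allele2)),
    dplyr::filter(g2, !is.na(.data$allele1) & !is.na(.data$allele2)),
    by = "locus", suffix = c("_1", "_2"))
  n <- nrow(m)
  if (n < rule$min_overlap) {
    return(tibble::tibble(is_match = NA, mismatching_alleles = NA_integer_,
                          loci_compared = n))
  }
  mm <- locus_mismatches(as.character(m$allele1_1), as.character(m$allele2_1),
                         as.character(m$allele1_2), as.character(m$allele2_2))
  total <- sum(mm)
  ok <- total <= rule$max_mismatch &&
    (!rule$per_locus_cap || all(mm < 2L))
  tibble::tibble(is_match = ok, mismatching_alleles = as.integer(total),
                 loci_compared = n)
}

#' Cluster samples into individuals by multilocus genotype matching
#'
#' Builds a graph whose vertices are samples and whose edges are pairwise
#' genotype matches under `rule`; connected components are taken as
#' individuals. A component in which some internal pair fails the matching
#' rule (match by transitivity only) is flagged `AMBIGUOUS` for review
#' rather than split. The individual consensus genotype is the per-locus
#' majority over member samples.
#'
#' @param consensus Output of [call_consensus()] (or any table with
#'   `sample_id`, `locus`, `allele1`, `allele2`).
#' @param metadata Optional sample metadata with `sample_id` and any of
#'   `date`, `source_class`, `sex`, `species_flag`. Samples flagged
#'   `NON_WOLF` are dropped before clustering.
#' @param rule A [match_rule()].
#' @param min_loci_sample Samples typed at fewer loci are set aside
#'   (default 10).
#' @param min_loci_consensus Individuals whose consensus genotype covers
#'   fewer loci are flagged `LOW_LOCI` (default 11).
#' @param id_prefix Prefix for generated individual ids.
#' @return A list of class `wolfped_individuals`:
#'   `individuals` (one row per individual: id, sex, n_samples,
#'   first_seen, last_seen, loci_typed, flag), `genotypes` (long consensus
#'   genotype table), `membership` (sample_id -> individual_id), and
#'   `excluded_samples`.
#' @export
cluster_samples <- function(consensus, metadata = NULL, rule = match_rule(),
                            min_loci_sample = 10L, min_loci_consensus = 11L,
                            id_prefix = "IND") {
  assert_cols(consensus, c("sample_id", "locus", "allele1", "allele2"),
              "consensus")
  consensus <- dplyr::mutate(consensus,
                             allele1 = as.character(.data$allele1),
                             allele2 = as.character(.data$allele2))
  if (!is.null(metadata) && "species_flag" %in% names(metadata)) {
    bad <- metadata$sample_id[metadata$species_flag %in% "NON_WOLF"]
    consensus <- dplyr::filter(consensus, !(.data$sample_id %in% bad))
  }

  typed <- dplyr::filter(consensus,
                         !is.na(.data$allele1) & !is.na(.data$allele2))
  loci_per_sample <- dplyr::count(typed, .data$sample_id, name = "n_loci")
  keep <- loci_per_sample$sample_id[loci_per_sample$n_loci >= min_loci_sample]
  excluded <- setdiff(unique(consensus$sample_id), keep)
  typed <- dplyr::filter(typed, .data$sample_id %in% keep)
  if (nrow(typed) == 0L) {
    abort("no samples pass the minimum-loci filter")
  }

  samples <- sort(unique(typed$sample_id))
  loci <- sort(unique(typed$locus))
  a1 <- matrix(NA_character_, length(samples), length(loci),
               dimnames = list(samples, loci))
  a2 <- a1
  a1[cbind(typed$sample_id, typed$locus)] <- pmin(typed$allele1, typed$allele2)
  a2[cbind(typed$sample_id, typed$locus)] <- pmax(typed$allele1, typed$allele2)

  n <- length(samples)
  edges <- integer(0)
  ambiguous_pairs <- matrix(integer(0), ncol = 2L)
  if (n > 1L) {
    pair_res <- vector("list", n * (n - 1L) / 2L)
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        k <- k + 1L
        sh <- which(!is.na(a1[i, ]) & !is.na(a1[j, ]))
        if (length(sh) < rule$min_overlap) {
          pair_res[[k]] <- c(i, j, NA_integer_)
          next
        }
        mm <- locus_mismatches(a1[i, sh], a2[i, sh], a1[j, sh], a2[j, sh])
        ok <- sum(mm) <= rule$max_mismatch &&
          (!rule$per_locus_cap || all(mm < 2L))
        pair_res[[k]] <- c(i, j, as.integer(ok))
      }
    }
    pr <- do.call(rbind, pair_res)
    edges <- t(pr[!is.na(pr[, 3L]) & pr[, 3L] == 1L, 1:2, drop = FALSE])
    ambiguous_pairs <- pr[!is.na(pr[, 3L]) & pr[, 3L] == 0L, 1:2,
                          drop = FALSE]
  }

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership

  # flag components containing an internal explicit non-match
  ambiguous_comp <- unique(comp[ambiguous_pairs[, 1L]][
    comp[ambiguous_pairs[, 1L]] == comp[ambiguous_pairs[, 2L]]])

  ord <- order(match(comp, unique(comp)))
  comp_ids <- setNames(sprintf("%s_%03d", id_prefix,
                               seq_along(unique(comp))),
                       unique(comp))
  membership <- tibble::tibble(sample_id = samples,
                               individual_id = comp_ids[as.character(comp)])

  geno <- typed |>
    dplyr::left_join(membership, by = "sample_id") |>
    dplyr::mutate(key = gt_key(.data$allele1, .data$allele2)) |>
    dplyr::count(.data$individual_id, .data$locus, .data$key) |>
    dplyr::group_by(.data$individual_id, .data$locus) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = TRUE) |>
    dplyr::arrange(.data$key, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    tidyr::separate_wider_delim("key", "/", names = c("allele1", "allele2")) |>
    dplyr::select("individual_id", "locus", "allele1", "allele2")

  loci_typed <- dplyr::count(geno, .data$individual_id, name = "loci_typed")

  ind <- membership |>
    dplyr::count(.data$individual_id, name = "n_samples") |>
    dplyr::left_join(loci_typed, by = "individual_id")
  flags <- setNames(rep("OK", nrow(ind)), ind$individual_id)
  flags[comp_ids[as.character(ambiguous_comp)]] <- "AMBIGUOUS"
  low <- ind$individual_id[ind$loci_typed < min_loci_consensus]
  flags[low] <- ifelse(flags[low] == "OK", "LOW_LOCI",
                       paste(flags[low], "LOW_LOCI", sep = ";"))
  ind$flag <- unname(flags[ind$individual_id])

  if (!is.null(metadata)) {
    md <- dplyr::left_join(membership, metadata, by = "sample_id")
    if ("date" %in% names(metadata)) {
      dates <- md |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::summarise(first_seen = min(.data$date, na.rm = TRUE),
                         last_seen = max(.data$date, na.rm = TRUE))
      ind <- dplyr::left_join(ind, dates, by = "individual_id")
    }
    if ("sex" %in% names(metadata)) {
      sx <- md |>
        dplyr::filter(!is.na(.data$sex)) |>
        dplyr::count(.data$individual_id, .data$sex) |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::select("individual_id", "sex")
      ind <- dplyr::left_join(ind, sx, by = "individual_id")
    }
    if ("source_class" %in% names(metadata)) {
      sc <- md |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::summarise(source_class = if (all(.data$source_class %in%
                                                "SCAT")) "SCAT"
                         else "TISSUE_SECRETION")
      ind <- dplyr::left_join(ind, sc, by = "individual_id")
    }
  }

  structure(list(individuals = dplyr::arrange(ind, .data$individual_id),
                 genotypes = geno,
                 membership = membership,
                 excluded_samples = excluded),
            class = "wolfped_individuals")
}

#' @export
print.wolfped_individuals <- function(x, ...) {
  cat(sprintf("<wolfped_individuals> %d individuals from %d samples",
              nrow(x$individuals), nrow(x$membership)), "\n")
  amb <- sum(grepl("AMBIGUOUS", x$individuals$flag))
  if (amb > 0L) cat(sprintf("  %d component(s) flagged AMBIGUOUS\n", amb))
  print(x$individuals, ...)
  invisible(x)
}
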