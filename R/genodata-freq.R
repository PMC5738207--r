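#' Validate an allele-frequency table
#'
#' @param freqs Data frame with columns `locus`, `allele`, `frequency`.
#' @param tol Tolerance on per-locus frequency sums (default 1e-9).
#' @return The table as a tibble, invisibly checked: per-locus frequencies
#'   sum to one within `tol`, all frequencies strictly positive, alleles
#'   unique within locus.
#' @export
validate_frequencies <- function(freqs, tol = 1e-9) {
  assert_cols(freqs, c("locus", "allele", "frequency"), "freqs")
  freqs <- dplyr::mutate(tibble::as_tibble(freqs),
                         allele = as.character(.data$allele))
  if (nrow(freqs) == 0L) abort("empty allele-frequency table")
  if (any(freqs$frequency <= 0)) {
    abort("all allele frequencies must be > 0")
  }
  dup <- duplicated(freqs[c("locus", "allele")])
  if (any(dup)) {
    abort(paste0("duplicated locus/allele rows: ",
                 paste(unique(paste(freqs$locus[dup], freqs$allele[dup])),
                       collapse = ", ")))
  }
  sums <- tapply(freqs$frequency, freqs$locus, sum)
  off <- names(sums)[abs(sums - 1) > tol]
  if (length(off) > 0L) {
    abort(paste0("allele frequencies do not sum to 1 at: ",
                 paste(off, collapse = ", ")))
  }
  freqs
}

#' Expected heterozygosity per locus
#'
#' Nei's gene diversity `H_E = 1 - sum(p^2)` per locus, with the panel mean
#' and its standard error over loci attached as attributes (`panel_mean`,
#' `panel_se`). An unbiased small-sample correction `n/(n-1)` can be applied
#' when the per-locus sample size is supplied.
#'
#' @param freqs Allele-frequency table (`locus`, `allele`, `frequency`).
#' @param n Optional named vector of per-locus sample sizes (individuals)
#'   for the unbiased `2n/(2n-1)` correction; default none.
#' @return Tibble with `locus`, `n_alleles`, `He`.
#' @export
expected_heterozygosity <- function(freqs, n = NULL) {
  freqs <- validate_frequencies(freqs)
  out <- freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n_alleles = dplyr::n(),
                     He = 1 - sum(.data$frequency^2)) |>
    dplyr::ungroup()
  if (!is.null(n)) {
    nn <- n[out$locus]
    out$He <- out$He * (2 * nn) / (2 * nn - 1)
  }
  attr(out, "panel_mean") <- mean(out$He)
  attr(out, "panel_se") <- se_of(out$He)
  out
}

#' Add observed-but-absent alleles to a frequency table at low frequency
#'
#' Reference allele frequencies estimated from a wider population may lack
#' alleles observed locally; these are added at a small frequency `epsilon`
#' and the locus renormalised.
#'
#' @param freqs Base allele-frequency table.
#' @param observed Data frame of observed alleles: either `locus`, `allele`
#'   rows, or a long genotype table with `locus`, `allele1`, `allele2`.
#' @param epsilon Frequency assigned to each novel allele before
#'   renormalisation, in (0, 0.05] (default 0.005).
#' @return Renormalised frequency table (per-locus sums exactly 1).
#' @export
augment_frequencies <- function(freqs, observed, epsilon = 0.005) {
  stopifnot(epsilon > 0, epsilon <= 0.05)
  freqs <- validate_frequencies(freqs)
  if (all(c("allele1", "allele2") %in% names(observed))) {
    observed <- tidyr::pivot_longer(observed[c("locus", "allele1", "allele2")],
                                    cols = c("allele1", "allele2"),
                                    values_to = "allele")[c("locus", "allele")]
  }
  assert_cols(observed, c("locus", "allele"), "observed")
  observed <- dplyr::distinct(
    dplyr::filter(observed, !is.na(.data$allele) &
                    .data$locus %in% freqs$locus),
    .data$locus, allele = as.character(.data$allele))
  novel <- dplyr::anti_join(observed, freqs, by = c("locus", "allele"))
  if (nrow(novel) > 0L) {
    freqs <- dplyr::bind_rows(freqs,
                              dplyr::mutate(novel, frequency = epsilon))
  }
  freqs |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$locus, .data$allele)
}

#' Maximum-likelihood individual inbreeding from allele frequencies
#'
#' For each individual, maximises the genotype likelihood over
#' `F` in \[0, 1\] under the inbreeding model
#' `P(aa | F) = p_a^2 (1 - F) + p_a F`, `P(ab | F) = 2 p_a p_b (1 - F)`,
#' multiplying over typed loci. Individuals with no typed loci are excluded
#' with a warning. The population mean and its standard error are attached
#' as attributes (`mean_F`, `se_F`).
#'
#' @param genotypes Long genotype table: `individual_id`, `locus`,
#'   `allele1`, `allele2`.
#' @param freqs Allele-frequency table covering the genotype alleles.
#' @param tol Optimisation tolerance (default 1e-6).
#' @return Tibble with `individual_id`, `F_hat`, `n_loci`.
#' @export
inbreeding_mle <- function(genotypes, freqs, tol = 1e-6) {
  assert_cols(genotypes, c("individual_id", "locus", "allele1", "allele2"),
              "genotypes")
  freqs <- validate_frequencies(freqs)
  fmap <- setNames(freqs$frequency, paste(freqs$locus, freqs$allele))
  g <- dplyr::filter(genotypes,
                     !is.na(.data$allele1) & !is.na(.data$allele2))
  all_ids <- unique(genotypes$individual_id)
  dropped <- setdiff(all_ids, unique(g$individual_id))
  if (length(dropped) > 0L) {
    warn(paste0("individuals with no typed loci excluded: ",
                paste(dropped, collapse = ", ")))
  }
  pa <- fmap[paste(g$locus, g$allele1)]
  pb <- fmap[paste(g$locus, g$allele2)]
  if (anyNA(pa) || anyNA(pb)) {
    abort("genotype contains alleles absent from the frequency table; ",
          "augment_frequencies() first")
  }
  het <- g$allele1 != g$allele2

  out <- vapply(split(seq_len(nrow(g)), g$individual_id), function(idx) {
    h <- het[idx]; a <- pa[idx]; b <- pb[idx]
    nll <- function(f) {
      -sum(log(ifelse(h, 2 * a * b * (1 - f), a^2 * (1 - f) + a * f)))
    }
    # all-heterozygous likelihood is decreasing in F: check the boundary
    # explicitly since optimize() never returns an exact endpoint
    cand <- optimize(nll, c(0, 1), tol = tol)$minimum
    vals <- c(0, cand, 1)
    c(F_hat = vals[which.min(vapply(vals, nll, numeric(1)))],
      n_loci = length(idx))
  }, numeric(2))

  res <- tibble::tibble(individual_id = colnames(out),
                        F_hat = out["F_hat", ],
                        n_loci = as.integer(out["n_loci", ]))
  attr(res, "mean_F") <- mean(res$F_hat)
  attr(res, "se_F") <- se_of(res$F_hat)
  res
}
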