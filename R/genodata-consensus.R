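#' Consensus-calling rules for replicate PCR genotypes
#'
#' Replicated PCR is the standard safeguard against genotyping error in
#' low-quantity DNA (scats, hairs, urine). Each sample is first amplified in
#' three independent replicates; a heterozygote is accepted when both of its
#' alleles are observed together in at least two replicates of the
#' triplicate, a homozygote only
#' when all three replicates show the identical homozygous genotype. A locus
#' failing both rules triggers a second triplicate; a locus still unresolved
#' after six replicates is treated as missing data.
#'
#' @param min_het_replicates Replicates in which each allele of a
#'   heterozygote must appear (default 2).
#' @param max_replicates Hard ceiling on replicates per sample-locus
#'   (default 6, i.e. two triplicates).
#' @param pooled If `TRUE`, evaluate all available replicates as one pool
#'   instead of triplicate-by-triplicate. The default mirrors the sequential
#'   lab workflow: the second triplicate is judged on its own.
#' @return A list of class `consensus_rules`.
#' @export
consensus_rules <- function(min_het_replicates = 2L, max_replicates = 6L,
                            pooled = FALSE) {
  stopifnot(min_het_replicates >= 1L, max_replicates >= 3L)
  structure(list(min_het_replicates = as.integer(min_het_replicates),
                 max_replicates = as.integer(max_replicates),
                 pooled = isTRUE(pooled)),
            class = "consensus_rules")
}

# Apply the reliability rule to one block of replicate calls.
# a1, a2: allele vectors (NA pair = failed replicate).
# Returns list(genotype = c(a1, a2) or NULL, status)
call_block <- function(a1, a2, rules, full_block = 3L) {
  ok <- !is.na(a1) & !is.na(a2)
  n_inf <- sum(ok)
  if (n_inf > 0L) {
    # heterozygote: both alleles observed together (the same heterozygous
    # genotype) in >= min_het_replicates replicates of the block
    keys <- gt_key(a1[ok], a2[ok])
    het_keys <- keys[a1[ok] != a2[ok]]
    if (length(het_keys) > 0L) {
      tab <- table(het_keys)
      hits <- names(tab)[tab >= rules$min_het_replicates]
      if (length(hits) == 1L) {
        return(list(genotype = strsplit(hits, "/", fixed = TRUE)[[1L]],
                    status = "RELIABLE_HET"))
      }
      if (length(hits) > 1L) {
        return(list(genotype = NULL, status = "UNRESOLVED"))
      }
    }
    # homozygote: every replicate of the block present and identical hom
    if (length(a1) >= full_block && n_inf == length(a1) &&
        all(a1 == a2) && length(unique(a1)) == 1L) {
      return(list(genotype = c(a1[1L], a1[1L]), status = "RELIABLE_HOM"))
    }
  }
  list(genotype = NULL, status = "UNRESOLVED")
}

call_one_consensus <- function(rep_idx, a1, a2, rules) {
  if (length(rep_idx) > rules$max_replicates) {
    abort(sprintf("more than %d replicates supplied for one sample/locus",
                  rules$max_replicates))
  }
  o <- order(rep_idx)
  rep_idx <- rep_idx[o]; a1 <- a1[o]; a2 <- a2[o]
  n <- length(rep_idx)

  if (rules$pooled) {
    res <- call_block(a1, a2, rules, full_block = n)
  } else {
    first <- rep_idx <= 3L
    res <- call_block(a1[first], a2[first], rules)
    if (res$status == "UNRESOLVED" && any(!first)) {
      res <- call_block(a1[!first], a2[!first], rules)
    }
  }
  if (res$status == "UNRESOLVED" && n >= rules$max_replicates) {
    res$status <- "MISSING"
  }
  list(a1 = res$genotype[1L] %||% NA_character_,
       a2 = res$genotype[2L] %||% NA_character_,
       status = res$status, replicates_used = n)
}

#' Call consensus genotypes from replicate observations
#'
#' @param replicates A data frame with columns `sample_id`, `locus`,
#'   `replicate`, `allele1`, `allele2` (both alleles `NA` for a failed
#'   replicate). Replicates 1--3 form the first triplicate, 4--6 the second.
#' @param rules A [consensus_rules()] object.
#' @return A tibble with one row per sample x locus: `sample_id`, `locus`,
#'   `allele1`, `allele2`, `status` (`RELIABLE_HET`, `RELIABLE_HOM`,
#'   `UNRESOLVED` -- a further triplicate is required -- or `MISSING`), and
#'   `replicates_used`.
#' @examples
#' reps <- tibble::tibble(
#'   sample_id = "s1", locus = "L1", replicate = 1:3,
#'   allele1 = c("120", "120", "120"), allele2 = c("124", "124", "120"))
#' call_consensus(reps)
#' @export
call_consensus <- function(replicates, rules = consensus_rules()) {
  assert_cols(replicates, c("sample_id", "locus", "replicate",
                            "allele1", "allele2"), "replicates")
  replicates <- dplyr::mutate(replicates,
                              allele1 = as.character(.data$allele1),
                              allele2 = as.character(.data$allele2))
  # a half-called replicate is treated as failed
  half <- xor(is.na(replicates$allele1), is.na(replicates$allele2))
  if (any(half)) {
    replicates$allele1[half] <- NA_character_
    replicates$allele2[half] <- NA_character_
  }
  key <- paste(replicates$sample_id, replicates$locus, replicates$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (sample, locus, replicate) rows: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  replicates |>
    dplyr::group_by(.data$sample_id, .data$locus) |>
    dplyr::group_modify(function(d, g) {
      tibble::as_tibble(call_one_consensus(d$replicate, d$allele1,
                                           d$allele2, rules))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(allele1 = "a1", allele2 = "a2")
}
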