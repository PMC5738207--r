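# Readers and writers for the package's plain-text formats. All data files
# are UTF-8 CSV with explicit headers (tab-separated for pedigrees and
# reports); dates are ISO-8601 and coordinates are carried verbatim.

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

#' Read a long replicate genotype table
#'
#' Expected header: `sample_id,locus,replicate,allele1,allele2`; empty
#' allele cells denote a failed replicate. Duplicate
#' (sample, locus, replicate) keys are an error naming the offenders.
#'
#' @param path CSV file path.
#' @return Tibble of replicate observations.
#' @export
read_genotype_table <- function(path) {
  d <- read_csv_quiet(path, readr::cols(sample_id = "c", locus = "c",
                                        replicate = "i", allele1 = "c",
                                        allele2 = "c"))
  assert_cols(d, c("sample_id", "locus", "replicate", "allele1",
                   "allele2"), "genotype table")
  if (any(is.na(d$replicate))) {
    abort("non-numeric or missing replicate index")
  }
  key <- paste(d$sample_id, d$locus, d$replicate, sep = "/")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate replicate keys: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  d
}

#' Read sample metadata
#'
#' Header: `sample_id,date,x,y,source_class,collector,species_flag`
#' (ISO-8601 dates).
#'
#' @param path CSV file path.
#' @return Tibble of sample records.
#' @export
read_sample_metadata <- function(path) {
  d <- read_csv_quiet(path, readr::cols(sample_id = "c", date = "D",
                                        x = "d", y = "d",
                                        source_class = "c",
                                        collector = "c",
                                        species_flag = "c"))
  assert_cols(d, c("sample_id", "date", "source_class"), "sample metadata")
  d
}

#' Read / write an allele-frequency table
#'
#' CSV with header `locus,allele,frequency`.
#'
#' @param path CSV file path.
#' @return [read_frequency_table()]: validated tibble.
#' @export
read_frequency_table <- function(path) {
  d <- read_csv_quiet(path, readr::cols(locus = "c", allele = "c",
                                        frequency = "d"))
  validate_frequencies(d)
}

#' @rdname read_frequency_table
#' @param freqs Frequency tibble to write.
#' @export
write_frequency_table <- function(freqs, path) {
  readr::write_csv(freqs, path)
  invisible(path)
}

#' Read / write an error-rate table
#'
#' CSV with header `locus,source_class,E1,E2`.
#'
#' @param path CSV file path.
#' @export
read_error_rates <- function(path) {
  d <- read_csv_quiet(path, readr::cols(locus = "c", source_class = "c",
                                        E1 = "d", E2 = "d"))
  assert_cols(d, c("locus", "source_class", "E1", "E2"), "error rates")
  d
}

#' @rdname read_error_rates
#' @param rates Rate tibble to write.
#' @export
write_error_rates <- function(rates, path) {
  readr::write_csv(rates, path)
  invisible(path)
}

#' Read / write a pedigree
#'
#' Tab-separated with header `id,dam,sire[,dam_prob,sire_prob]` and
#' literal tokens `UNSAMPLED` and `UNKNOWN`; the round trip is lossless
#' (`UNKNOWN` maps to `NA` in memory).
#'
#' @param path TSV file path.
#' @export
read_pedigree <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", dam = "c", sire = "c", .default = "d"),
    progress = FALSE, na = "NA")
  assert_cols(d, c("id", "dam", "sire"), "pedigree file")
  d$dam[d$dam %in% "UNKNOWN"] <- NA_character_
  d$sire[d$sire %in% "UNKNOWN"] <- NA_character_
  as_pedigree(d)
}

#' @rdname read_pedigree
#' @param pedigree Pedigree tibble to write.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- tibble::as_tibble(pedigree)
  out$dam[is.na(out$dam)] <- "UNKNOWN"
  out$sire[is.na(out$sire)] <- "UNKNOWN"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the individuals table with one allele-pair column per locus
#'
#' Columns: `individual_id,sex,n_samples,first_seen,last_seen,loci_typed`,
#' then `<locus>_1`, `<locus>_2` per locus.
#'
#' @param individuals,genotypes As returned by [cluster_samples()].
#' @param path CSV output path.
#' @export
write_individuals <- function(individuals, genotypes, path) {
  wide <- genotypes |>
    tidyr::pivot_wider(names_from = "locus",
                       values_from = c("allele1", "allele2"),
                       names_glue = "{locus}_{ifelse(.value == 'allele1', 1, 2)}")
  keep <- intersect(c("individual_id", "sex", "n_samples", "first_seen",
                      "last_seen", "loci_typed"), names(individuals))
  out <- dplyr::left_join(individuals[keep], wide, by = "individual_id")
  readr::write_csv(out, path)
  invisible(path)
}
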