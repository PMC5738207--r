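#' Apply a ledger of documented manual corrections to a pedigree
#'
#' Statistically estimated parentages sometimes conflict with biological
#' understanding (temporally impossible generations, implausible
#' single-offspring pairs). Such edits are applied only through an explicit
#' ledger so every change is documented; edits that would make the pedigree
#' illegal are rejected, not silently dropped.
#'
#' @param pedigree Pedigree tibble (`id`, `dam`, `sire`, ...).
#' @param ledger Tibble with columns `offspring`, `field` (`"dam"` or
#'   `"sire"`), `new_value` (an id, `"UNSAMPLED"`, or `NA`), `reason`
#'   (one of `ANACHRONISM`, `SINGLE_OFFSPRING_PAIR`, `TERRITORY_CONFLICT`,
#'   `CONFIRMED`), `note` (free text).
#' @return A list of class `wolfped_corrections`: `pedigree` (edited),
#'   `log` (one row per ledger entry with `applied`, `old_value`,
#'   `message`). `CONFIRMED` entries change nothing but are logged.
#' @export
apply_corrections <- function(pedigree, ledger) {
  ped <- tibble::as_tibble(pedigree)
  if (nrow(ledger) == 0L) {
    return(structure(list(pedigree = ped,
                          log = tibble::tibble(offspring = character(),
                                               field = character(),
                                               old_value = character(),
                                               new_value = character(),
                                               reason = character(),
                                               applied = logical(),
                                               message = character())),
                     class = "wolfped_corrections"))
  }
  assert_cols(ledger, c("offspring", "field", "new_value", "reason"),
              "ledger")
  valid_reasons <- c("ANACHRONISM", "SINGLE_OFFSPRING_PAIR",
                     "TERRITORY_CONFLICT", "CONFIRMED")
  if (!all(ledger$reason %in% valid_reasons)) {
    abort(paste0("unknown reason code(s): ",
                 paste(setdiff(ledger$reason, valid_reasons),
                       collapse = ", ")))
  }
  logs <- vector("list", nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    e <- ledger[i, ]
    row <- match(e$offspring, ped$id)
    if (is.na(row)) {
      abort(paste0("ledger references unknown offspring: ", e$offspring))
    }
    if (!e$field %in% c("dam", "sire")) {
      abort(paste0("ledger field must be dam or sire, got: ", e$field))
    }
    old <- ped[[e$field]][row]
    if (e$reason == "CONFIRMED") {
      logs[[i]] <- tibble::tibble(offspring = e$offspring, field = e$field,
                                  old_value = old, new_value = old,
                                  reason = e$reason, applied = FALSE,
                                  message = "confirmed, unchanged")
      next
    }
    trial <- ped
    trial[[e$field]][row] <- e$new_value
    chk <- is_legal(trial[c("id", "dam", "sire")])
    if (!chk$legal) {
      logs[[i]] <- tibble::tibble(offspring = e$offspring, field = e$field,
                                  old_value = old,
                                  new_value = as.character(e$new_value),
                                  reason = e$reason, applied = FALSE,
                                  message = paste0("rejected: ",
                                                   chk$violations$detail[1L]))
      next
    }
    ped <- trial
    logs[[i]] <- tibble::tibble(offspring = e$offspring, field = e$field,
                                old_value = old,
                                new_value = as.character(e$new_value),
                                reason = e$reason, applied = TRUE,
                                message = "applied")
  }
  structure(list(pedigree = ped, log = dplyr::bind_rows(logs)),
            class = "wolfped_corrections")
}

#' @export
print.wolfped_corrections <- function(x, ...) {
  n_app <- sum(x$log$applied)
  cat(sprintf("<wolfped_corrections> %d entries, %d applied, %d rejected\n",
              nrow(x$log), n_app,
              sum(!x$log$applied & x$log$reason != "CONFIRMED")))
  invisible(x)
}
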