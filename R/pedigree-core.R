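#' Construct / validate a pedigree table
#'
#' A pedigree is a tibble with one row per individual: `id`, `dam`, `sire`,
#' optionally `dam_prob`, `sire_prob`. Parent fields hold an individual id,
#' the literal token `"UNSAMPLED"` (an anonymous parent outside the genotyped
#' set; treated as a distinct unrelated founder per offspring), or `NA`
#' (unknown / unassigned).
#'
#' @param df Data frame with at least `id`, `dam`, `sire`.
#' @return The validated tibble (ids unique, sampled parents present in
#'   `id`).
#' @export
as_pedigree <- function(df) {
  assert_cols(df, c("id", "dam", "sire"), "pedigree")
  df <- dplyr::mutate(tibble::as_tibble(df),
                      id = as.character(.data$id),
                      dam = as.character(.data$dam),
                      sire = as.character(.data$sire))
  if (anyDuplicated(df$id)) {
    abort(paste0("duplicated pedigree ids: ",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  for (col in c("dam", "sire")) {
    p <- df[[col]]
    bad <- setdiff(p[is_sampled_parent(p)], df$id)
    if (length(bad) > 0L) {
      abort(paste0(col, " references unknown id(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  df
}

#' Check pedigree legality
#'
#' A pedigree is legal when the parent relation is acyclic (no individual is
#' its own ancestor) and, if sexes are supplied, every dam is female or of
#' unknown sex and every sire male or unknown.
#'
#' @param pedigree Pedigree table (see [as_pedigree()]).
#' @param sexes Optional tibble `individual_id`, `sex` (`"M"`, `"F"`, or
#'   `NA`/`"UNKNOWN"`).
#' @return A list: `legal` (logical) and `violations` (tibble with `type`
#'   -- `CYCLE` or `SEX` -- and `detail` naming the offending link or
#'   cycle). The first violation found is always reported.
#' @export
is_legal <- function(pedigree, sexes = NULL) {
  ped <- as_pedigree(pedigree)
  viol <- list()

  # Kahn-style elimination: repeatedly strip individuals all of whose
  # parents are already stripped; anything left over sits on/below a cycle.
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  dam_i <- ifelse(is_sampled_parent(ped$dam), idx[ped$dam], NA_integer_)
  sire_i <- ifelse(is_sampled_parent(ped$sire), idx[ped$sire], NA_integer_)
  done <- rep(FALSE, nrow(ped))
  repeat {
    ready <- !done &
      (is.na(dam_i) | done[pmax(dam_i, 1L)]) &
      (is.na(sire_i) | done[pmax(sire_i, 1L)])
    if (!any(ready)) break
    done[ready] <- TRUE
  }
  if (!all(done)) {
    # walk parent links inside the leftover set until a repeat: that loop
    # is a genuine cycle
    left <- which(!done)
    cur <- left[1L]
    path <- integer(0)
    while (!(cur %in% path)) {
      path <- c(path, cur)
      nxt <- c(dam_i[cur], sire_i[cur])
      nxt <- nxt[!is.na(nxt) & !done[pmax(nxt, 1L)]]
      cur <- nxt[1L]
    }
    cyc <- path[which(path == cur)[1L]:length(path)]
    viol <- c(viol, list(tibble::tibble(
      type = "CYCLE",
      detail = paste(ped$id[cyc], collapse = " -> "))))
  }
  if (!is.null(sexes)) {
    sx <- setNames(as.character(sexes$sex), sexes$individual_id)
    dam_sex <- sx[ped$dam[is_sampled_parent(ped$dam)]]
    sire_sex <- sx[ped$sire[is_sampled_parent(ped$sire)]]
    bad_dam <- names(dam_sex)[dam_sex %in% "M"]
    bad_sire <- names(sire_sex)[sire_sex %in% "F"]
    if (length(bad_dam) > 0L) {
      viol <- c(viol, list(tibble::tibble(
        type = "SEX", detail = paste0("male assigned as dam: ",
                                      paste(unique(bad_dam), collapse = ", ")))))
    }
    if (length(bad_sire) > 0L) {
      viol <- c(viol, list(tibble::tibble(
        type = "SEX", detail = paste0("female assigned as sire: ",
                                      paste(unique(bad_sire), collapse = ", ")))))
    }
  }
  violations <- if (length(viol) > 0L) dplyr::bind_rows(viol) else
    tibble::tibble(type = character(), detail = character())
  list(legal = nrow(violations) == 0L, violations = violations)
}

# Build a memoised kinship environment for a pedigree. UNSAMPLED/NA parents
# are unrelated founders. Uses the standard recursion
#   phi(x, x) = (1 + F_x) / 2,   F_x = phi(dam_x, sire_x)
#   phi(a, b) = (phi(dam_a, b) + phi(sire_a, b)) / 2
# recursing on whichever of a, b sits deeper in the pedigree.
kinship_env <- function(ped) {
  dam <- setNames(ped$dam, ped$id)
  sire <- setNames(ped$sire, ped$id)
  dam[!is_sampled_parent(dam)] <- NA
  sire[!is_sampled_parent(sire)] <- NA

  depth <- setNames(rep(NA_integer_, nrow(ped)), ped$id)
  depth_of <- function(i) {
    if (!is.na(depth[[i]])) return(depth[[i]])
    d <- 0L
    for (p in c(dam[[i]], sire[[i]])) {
      if (!is.na(p)) d <- max(d, depth_of(p) + 1L)
    }
    depth[[i]] <<- d
    d
  }
  for (i in ped$id) depth_of(i)

  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (a <= b) paste0(a, "\r", b) else paste0(b, "\r", a)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      0.5 * (1 + phi(dam[[a]], sire[[a]]))
    } else {
      # recurse on the deeper individual; it cannot be an ancestor of the
      # shallower one
      if (depth[[a]] < depth[[b]]) { t <- a; a <- b; b <- t }
      0.5 * (phi(dam[[a]], b) + phi(sire[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  phi
}

#' Pedigree kinship coefficient
#'
#' The probability that alleles drawn at random from `a` and `b` are
#' identical by descent, computed by the classical recursion with
#' unsampled/unknown parents as unrelated founders.
#'
#' @param pedigree Pedigree table.
#' @param a,b Individual ids. If both are `NULL` the full kinship matrix is
#'   returned.
#' @return A number, or a named matrix when `a` and `b` are `NULL`.
#' @export
kinship <- function(pedigree, a = NULL, b = NULL) {
  ped <- as_pedigree(pedigree)
  chk <- is_legal(ped)
  if (!chk$legal) {
    abort(paste0("illegal pedigree: ", chk$violations$detail[1L]))
  }
  phi <- kinship_env(ped)
  if (is.null(a) && is.null(b)) {
    n <- nrow(ped)
    M <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
    for (i in seq_len(n)) {
      for (j in i:n) {
        M[i, j] <- M[j, i] <- phi(ped$id[i], ped$id[j])
      }
    }
    return(M)
  }
  stopifnot(a %in% ped$id, b %in% ped$id)
  phi(a, b)
}

#' Pedigree inbreeding coefficient
#'
#' `F_x` is the kinship between the parents of `x`; zero when either parent
#' is unsampled or unknown.
#'
#' @param pedigree Pedigree table.
#' @param x Individual id, or `NULL` for all individuals.
#' @return A number, or a tibble `individual_id`, `F` for all.
#' @export
inbreeding_coefficient <- function(pedigree, x = NULL) {
  ped <- as_pedigree(pedigree)
  phi <- kinship_env(ped)
  f_one <- function(id) {
    r <- ped[ped$id == id, ]
    if (!is_sampled_parent(r$dam) || !is_sampled_parent(r$sire)) return(0)
    phi(r$dam, r$sire)
  }
  if (!is.null(x)) return(f_one(x))
  tibble::tibble(individual_id = ped$id,
                 F = unname(vapply(ped$id, f_one, numeric(1))))
}

#' Pedigree relatedness coefficient
#'
#' `r = 2 phi(a, b) / sqrt((1 + F_a)(1 + F_b))`; reduces to `2 phi` for
#' outbred pairs (0.5 full sibs or parent-offspring, 0.25
#' grandparent-grandchild).
#'
#' @inheritParams kinship
#' @return A number.
#' @export
relatedness <- function(pedigree, a, b) {
  ped <- as_pedigree(pedigree)
  phi <- kinship_env(ped)
  fa <- inbreeding_coefficient(ped, a)
  fb <- inbreeding_coefficient(ped, b)
  2 * phi(a, b) / sqrt((1 + fa) * (1 + fb))
}

#' Merge two unsampled parental slots into one anonymous individual
#'
#' By default every UNSAMPLED slot is a distinct anonymous founder. When
#' field knowledge indicates that several offspring share the same unsampled
#' parent (e.g. one unsampled breeding male fathered a whole litter), this
#' curation step replaces the token with a shared placeholder id added to
#' the pedigree as a founder.
#'
#' @param pedigree Pedigree table.
#' @param offspring Ids whose `field` slot should point at one shared parent.
#' @param field `"dam"` or `"sire"`.
#' @param parent_id Placeholder id for the shared anonymous parent.
#' @return The edited pedigree (with the placeholder appended as a founder).
#' @export
merge_unsampled_parents <- function(pedigree, offspring, field, parent_id) {
  stopifnot(field %in% c("dam", "sire"))
  ped <- as_pedigree(pedigree)
  if (parent_id %in% ped$id) {
    abort("parent_id already exists in the pedigree")
  }
  rows <- match(offspring, ped$id)
  if (anyNA(rows)) abort("offspring not all present in pedigree")
  if (!all(ped[[field]][rows] == UNSAMPLED)) {
    abort("all targeted slots must currently be UNSAMPLED")
  }
  ped[[field]][rows] <- parent_id
  dplyr::bind_rows(ped, tibble::tibble(id = parent_id, dam = NA_character_,
                                       sire = NA_character_))
}
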