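#' Infer birth years from detection dates and pedigree structure
#'
#' Non-invasive monitoring yields detection dates, not ages, so cohorts
#' must be reconstructed from the joint appearance of sibling groups.
#' Working assumption: an individual assigned at least one parent belongs
#' to a monitored litter and is first detected in its birth year, so its
#' point estimate is its first-detection year; founders (no assigned
#' parents) have unknown birth years unless a known age at death pins them
#' exactly. Around the point estimates, bounds are propagated through the
#' pedigree: an individual is born no later than its first detection and
#' no later than `min_breeding_age` years before any of its offspring;
#' it is born no earlier than `min_breeding_age` years after its parents'
#' (latest possible) birth. A point estimate violating its bounds marks a
#' temporal impossibility (`CONFLICT`) -- the raw material of the
#' anachronism checks.
#'
#' @param pedigree Pedigree table.
#' @param detections Tibble `individual_id`, `first_seen` (Date or year),
#'   optionally `death_year` and `known_age_at_death`.
#' @param min_breeding_age Minimum parental age at reproduction in years
#'   (default 2).
#' @return Tibble `individual_id`, `birth_ub`, `birth_lb`, `birth_year`
#'   (point estimate, `NA` when undetermined), `status` (`OK`,
#'   `UNDETERMINED`, `CONFLICT`).
#' @export
infer_birth_years <- function(pedigree, detections, min_breeding_age = 2L) {
  ped <- as_pedigree(pedigree)
  assert_cols(detections, c("individual_id", "first_seen"), "detections")
  det <- detections
  yr <- det$first_seen
  if (inherits(yr, "Date")) yr <- as.integer(format(yr, "%Y"))
  det$year <- as.integer(yr)

  seen <- setNames(det$year[match(ped$id, det$individual_id)], ped$id)
  ub <- seen
  # exact birth years from known age at death
  if (all(c("death_year", "known_age_at_death") %in% names(det))) {
    exact <- !is.na(det$death_year) & !is.na(det$known_age_at_death)
    fixed <- setNames(det$death_year[exact] - det$known_age_at_death[exact],
                      det$individual_id[exact])
  } else {
    fixed <- setNames(integer(0), character(0))
  }
  ub[names(fixed)] <- pmin(ub[names(fixed)], fixed, na.rm = TRUE)

  dam <- setNames(ped$dam, ped$id)
  sire <- setNames(ped$sire, ped$id)
  # upper bounds cascade upwards: a parent is born no later than its
  # earliest offspring's upper bound minus the generation gap
  repeat {
    changed <- FALSE
    for (i in ped$id) {
      for (p in c(dam[[i]], sire[[i]])) {
        if (!is_sampled_parent(p) || is.na(ub[[i]])) next
        cap <- ub[[i]] - min_breeding_age
        if (is.na(ub[[p]]) || ub[[p]] > cap) {
          ub[[p]] <- cap
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  # point estimates: litter members appear in their birth year
  has_parent <- is_sampled_parent(dam) | is_sampled_parent(sire)
  est <- ifelse(has_parent, seen, NA_integer_)
  est[names(fixed)] <- fixed

  # lower bounds from the parents' birth estimates (their latest possible
  # birth year when no point estimate exists)
  lb <- setNames(rep(NA_integer_, nrow(ped)), ped$id)
  for (i in ped$id) {
    bounds <- integer(0)
    for (p in c(dam[[i]], sire[[i]])) {
      if (!is_sampled_parent(p)) next
      pb <- if (!is.na(est[[p]])) est[[p]] else ub[[p]]
      if (!is.na(pb)) bounds <- c(bounds, pb + min_breeding_age)
    }
    if (length(bounds) > 0L) lb[[i]] <- max(bounds)
  }

  conflict <- (!is.na(est) & !is.na(ub) & est > ub) |
    (!is.na(est) & !is.na(lb) & est < lb) |
    (!is.na(lb) & !is.na(ub) & lb > ub)
  status <- ifelse(conflict, "CONFLICT",
                   ifelse(is.na(est), "UNDETERMINED", "OK"))
  tibble::tibble(individual_id = ped$id,
                 birth_ub = unname(ub), birth_lb = unname(lb),
                 birth_year = as.integer(unname(est)),
                 status = unname(status))
}
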