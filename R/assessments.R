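#' Define one psychometric assessment
#'
#' An assessment is one instrument subscale (or single query) contributing
#' a score trajectory to the clustering: who reports it, how many items it
#' has, the item and total-score ranges, and at which waves it was
#' administered. Summed scales satisfy `score_max = n_items * item_max`.
#'
#' @param name assessment identifier (snake_case).
#' @param informant `"self"` or `"caregiver"`.
#' @param n_items number of items (>= 1).
#' @param item_min,item_max integer item response bounds.
#' @param waves_administered character subset of `c("T1","T2","T3","T4")`.
#' @param binary logical; `TRUE` for single yes/no queries such as
#'   self-harm, which are generated as one Bernoulli item.
#' @return an object of class `assessment_spec`.
#' @export
assessment_spec <- function(name, informant, n_items, item_min, item_max,
                            waves_administered = c("T1", "T2", "T3", "T4"),
                            binary = FALSE) {
  if (!informant %in% c("self", "caregiver"))
    stop_field("informant", "must be 'self' or 'caregiver'")
  if (n_items < 1) stop_field("n_items", "must be >= 1")
  if (item_max <= item_min) stop_field("item_max", "must exceed item_min")
  bad <- setdiff(waves_administered, c("T1", "T2", "T3", "T4"))
  if (length(bad)) stop_field("waves_administered", paste(bad, collapse = ", "))
  structure(list(
    name = name, informant = informant,
    n_items = as.integer(n_items),
    item_min = as.integer(item_min), item_max = as.integer(item_max),
    score_min = as.integer(n_items * item_min),
    score_max = as.integer(n_items * item_max),
    waves_administered = waves_administered,
    binary = isTRUE(binary)
  ), class = "assessment_spec")
}

#' Default 14-assessment catalog
#'
#' The instrument set used for trajectory clustering: depression (SMFQ,
#' self, 0-26), depression/anxiety (SDQ emotional, caregiver, 0-10),
#' psychotic-like experiences by both informants, caregiver-reported
#' obsession/compulsion, dissociation, sociality problems,
#' hyperactivity/inattention, conduct problems, somatic symptoms and
#' withdrawal, and self-reported desire for slimness, self-harm (0-1) and
#' suicidal ideation. CBCL-derived subscales were not administered at T3;
#' the self-harm and suicidal-ideation queries were not asked at T1.
#' Waves T1-T4 correspond to ages 10, 12, 14 and 16.
#'
#' @return named list of [assessment_spec()] objects, length 14.
#' @export
default_assessments <- function() {
  all_w <- c("T1", "T2", "T3", "T4")
  no_t3 <- c("T1", "T2", "T4")
  no_t1 <- c("T2", "T3", "T4")
  specs <- list(
    assessment_spec("depression_self",        "self",      13, 0, 2, all_w),
    assessment_spec("emotional_caregiver",    "caregiver",  5, 0, 2, all_w),
    assessment_spec("ple_self",               "self",       5, 0, 2, all_w),
    assessment_spec("ple_caregiver",          "caregiver",  4, 0, 2, no_t3),
    assessment_spec("obsession_caregiver",    "caregiver",  2, 0, 2, no_t3),
    assessment_spec("dissociation_caregiver", "caregiver",  3, 0, 2, all_w),
    assessment_spec("sociality_caregiver",    "caregiver",  5, 0, 2, all_w),
    assessment_spec("hyperactivity_caregiver","caregiver",  5, 0, 2, all_w),
    assessment_spec("conduct_caregiver",      "caregiver",  5, 0, 2, all_w),
    assessment_spec("somatic_caregiver",      "caregiver",  9, 0, 2, no_t3),
    assessment_spec("withdrawal_caregiver",   "caregiver",  9, 0, 2, no_t3),
    assessment_spec("slimness_self",          "self",       1, 0, 3, all_w),
    assessment_spec("selfharm_self",          "self",       1, 0, 1, no_t1, binary = TRUE),
    assessment_spec("suicidal_self",          "self",       1, 0, 3, no_t1)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @export
print.assessment_spec <- function(x, ...) {
  cat(sprintf("<assessment_spec> %s (%s): %d item(s) %d-%d, score %d-%d, waves %s\n",
              x$name, x$informant, x$n_items, x$item_min, x$item_max,
              x$score_min, x$score_max,
              paste(x$waves_administered, collapse = ",")))
  invisible(x)
}
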