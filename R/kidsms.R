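## Kid-Short Marfan Score: pre-test probability stratification.

KIDSMS_CATEGORIES <- c("negative", "moderate", "high", "very_high")

## Rule table in published row order; the reported primary profile of a
## patient is the first matched rule in this order.
KIDSMS_RULES <- data.frame(
  label = c("SV+EL", "SV+MVP+TVP", "SV+PA", "SV+3Skel",
            "EL+MVP+TVP", "EL+PA", "FH", "SV"),
  category = c("very_high", "high", "high", "high",
               "high", "high", "moderate", "moderate"),
  stringsAsFactors = FALSE
)

#' Count present skeletal features
#'
#' Counts the *number* of present items (not Ghent points) among the
#' skeletal subset of the systemic checklist: pectus carinatum, pectus
#' excavatum/chest asymmetry, segment-ratio/armspan combination,
#' characteristic face, wrist sign, thumb sign, scoliosis/kyphosis, reduced
#' elbow extension, pes planus, hindfoot deformity, protrusio acetabulae
#' (11 items).  Non-skeletal rows (myopia, MVP, pneumothorax, striae, dural
#' ectasia) are excluded.
#'
#' @param items Named logical vector from [systemic_items()] or a cohort
#'   data.frame (vectorized).
#' @return Integer count(s) in `[0, 11]`.
#' @export
count_skeletal_features <- function(items) {
  if (is.data.frame(items)) {
    sys <- sys_matrix(items, context = "skeletal feature count")
    return(as.integer(rowSums(sys[, SKELETAL_ITEMS, drop = FALSE])))
  }
  stopifnot(setequal(names(items), SYS_ITEMS))
  if (anyNA(items[SKELETAL_ITEMS])) {
    stop("skeletal feature count is not computable: item(s) not stated",
         call. = FALSE)
  }
  as.integer(sum(items[SKELETAL_ITEMS]))
}

## Core rule engine on resolved feature flags; all inputs logical vectors of
## equal length plus the integer skeletal count.
kidsms_rules_matrix <- function(sv, el, mvp, tvp, pa, fh, skel) {
  cbind(
    `SV+EL` = sv & el,
    `SV+MVP+TVP` = sv & mvp & tvp,
    `SV+PA` = sv & pa,
    `SV+3Skel` = sv & (skel >= 3L),
    `EL+MVP+TVP` = el & mvp & tvp,
    `EL+PA` = el & pa,
    `FH` = fh,
    `SV` = sv
  )
}

kidsms_category_from_rules <- function(matched) {
  ## matched: logical matrix, columns in KIDSMS_RULES order
  cat_idx <- match(KIDSMS_RULES$category, KIDSMS_CATEGORIES)
  best <- apply(matched, 1, function(r) if (any(r)) max(cat_idx[r]) else 1L)
  factor(KIDSMS_CATEGORIES[best], levels = KIDSMS_CATEGORIES, ordered = TRUE)
}

#' Kid-SMS risk stratification for a single record
#'
#' Evaluates the eight Kid-SMS rules -- very high risk: SV dilatation +
#' ectopia lentis; high risk: SV + MVP + TVP, SV + PA dilatation, SV +
#' \eqn{\ge 3} skeletal features, EL + MVP + TVP, EL + PA; moderate risk:
#' family history alone, SV dilatation alone -- and returns the highest
#' matched category with every matched rule recorded in published row
#' order.  The moderate FH and SV rules are recorded even when dominated by
#' a higher rule.  Aortic dissection does not enter Kid-SMS.
#'
#' @param record One-row cohort data.frame.
#' @param sv_dilated,pa_dilated Logical dilatation flags; if `NULL`,
#'   resolved from the record (direct flag, else nomogram) via
#'   [resolve_dilation()].
#' @param sv_nomogram,pa_nomogram,threshold Passed to [resolve_dilation()].
#' @return Object of class `kidsms_result`: list with `category` (ordered
#'   factor negative < moderate < high < very_high), `matched_rules`
#'   (character vector) and `skeletal_feature_count`.
#' @export
kidsms_stratify <- function(record, sv_dilated = NULL, pa_dilated = NULL,
                            sv_nomogram = NULL, pa_nomogram = NULL,
                            threshold = 2) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (is.null(sv_dilated)) {
    sv_dilated <- resolve_dilation(record, "sv", nomogram = sv_nomogram,
                                   threshold = threshold)
  }
  if (is.null(pa_dilated)) {
    pa_dilated <- resolve_dilation(record, "pa", nomogram = pa_nomogram,
                                   threshold = threshold)
  }
  stopifnot(!is.na(sv_dilated), !is.na(pa_dilated))
  require_stated(record, c("ectopia_lentis", "mitral_valve_prolapse",
                           "tricuspid_valve_prolapse", "family_history_mfs"),
                 "Kid-SMS stratification")
  skel <- count_skeletal_features(record)
  matched <- kidsms_rules_matrix(sv_dilated, record$ectopia_lentis,
                                 record$mitral_valve_prolapse,
                                 record$tricuspid_valve_prolapse,
                                 pa_dilated, record$family_history_mfs, skel)
  structure(
    list(category = kidsms_category_from_rules(matched)[1],
         matched_rules = KIDSMS_RULES$label[matched[1, ]],
         skeletal_feature_count = skel),
    class = "kidsms_result"
  )
}

#' @export
print.kidsms_result <- function(x, ...) {
  cat("Kid-SMS risk category:", as.character(x$category), "\n")
  if (length(x$matched_rules)) {
    cat("  matched rules:", paste(x$matched_rules, collapse = ", "), "\n")
  }
  cat("  skeletal features present:", x$skeletal_feature_count, "\n")
  invisible(x)
}

#' Primary risk profile of a stratification result
#'
#' Reduces a [kidsms_stratify()] result to the single profile label used to
#' partition a cohort (one row per patient): the first matched rule in
#' published row order, so a patient matching both FH and isolated SV
#' reports `"FH"`, and any higher-risk rule dominates both.
#'
#' @param result A `kidsms_result`, or a character vector of matched rule
#'   labels.
#' @return A single profile label, or `"negative"` when no rule matched.
#' @export
primary_profile <- function(result) {
  rules <- if (inherits(result, "kidsms_result")) result$matched_rules
           else as.character(result)
  if (length(rules) == 0) return("negative")
  idx <- match(rules, KIDSMS_RULES$label)
  stopifnot(!anyNA(idx))
  KIDSMS_RULES$label[min(idx)]
}

#' Kid-SMS stratification for a whole cohort
#'
#' Vectorized [kidsms_stratify()]; dilatation flags are resolved per record
#' (direct flag, else nomogram from diameter and BSA; unresolvable records
#' raise an error).
#'
#' @inheritParams kidsms_stratify
#' @param cohort Cohort data.frame.
#' @return data.frame with `category` (ordered factor), `primary_profile`,
#'   `matched_rules` (`";"`-joined) and `skeletal_feature_count`.
#' @export
kidsms_cohort <- function(cohort, sv_nomogram = NULL, pa_nomogram = NULL,
                          threshold = 2) {
  sv <- resolve_dilation(cohort, "sv", nomogram = sv_nomogram,
                         threshold = threshold)
  pa <- resolve_dilation(cohort, "pa", nomogram = pa_nomogram,
                         threshold = threshold)
  require_stated(cohort, c("ectopia_lentis", "mitral_valve_prolapse",
                           "tricuspid_valve_prolapse", "family_history_mfs"),
                 "Kid-SMS stratification")
  skel <- count_skeletal_features(cohort)
  matched <- kidsms_rules_matrix(sv, cohort$ectopia_lentis,
                                 cohort$mitral_valve_prolapse,
                                 cohort$tricuspid_valve_prolapse,
                                 pa, cohort$family_history_mfs, skel)
  data.frame(
    patient_id = cohort$patient_id,
    category = kidsms_category_from_rules(matched),
    primary_profile = apply(matched, 1, function(r) {
      if (any(r)) KIDSMS_RULES$label[which(r)[1]] else "negative"
    }),
    matched_rules = apply(matched, 1, function(r) {
      paste(KIDSMS_RULES$label[r], collapse = ";")
    }),
    skeletal_feature_count = skel,
    stringsAsFactors = FALSE
  )
}
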