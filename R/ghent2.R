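## Revised Ghent (Ghent-2) systemic score and confirmed-MFS pathways.

## Point weights of the 20-point systemic checklist.  Two exclusivity rules
## keep the maximum reachable total at exactly 20:
##   - pectus carinatum (2) suppresses pectus excavatum / chest asymmetry (1);
##   - hindfoot deformity (2) suppresses *plain* pes planus (1).
## Wrist/thumb contributes exactly one of {0, 1, 3}: both signs award 3,
## exactly one sign awards 1, never 3 + 1 = 4.
SYS_WEIGHTS <- c(
  pectus_carinatum = 2L,
  pectus_excavatum_or_chest_asymmetry = 1L,
  reduced_us_ls_and_increased_armspan_no_scoliosis = 1L,
  characteristic_face = 1L,
  wrist_sign = 1L,          # wrist OR thumb (exclusive); both -> 3 combined
  thumb_sign = 1L,
  scoliosis_or_kyphosis = 1L,
  reduced_elbow_extension = 1L,
  pes_planus = 1L,
  hindfoot_deformity = 2L,
  protrusio_acetabulae = 2L,
  myopia_gt3_diopters = 1L,
  mitral_valve_prolapse = 1L,
  spontaneous_pneumothorax = 2L,
  striae_atrophicae = 1L,
  dural_ectasia = 2L
)

GHENT2_PATHWAYS <- c("aorta+EL", "aorta+systemic", "aorta+FBN1",
                     "FH+aorta", "FH+EL", "FH+systemic")

## Vectorized awarded-points matrix: one row per record, one column per item.
sys_points_matrix <- function(sys) {
  p <- matrix(0L, nrow = nrow(sys), ncol = length(SYS_ITEMS),
              dimnames = list(NULL, SYS_ITEMS))
  for (it in SYS_ITEMS) p[, it] <- as.integer(sys[[it]]) * SYS_WEIGHTS[[it]]
  ## exclusivities
  p[, "pectus_excavatum_or_chest_asymmetry"] <-
    ifelse(sys$pectus_carinatum, 0L,
           p[, "pectus_excavatum_or_chest_asymmetry"])
  p[, "pes_planus"] <- ifelse(sys$hindfoot_deformity, 0L, p[, "pes_planus"])
  ## wrist/thumb: both -> 3 awarded on the wrist row, 0 on the thumb row
  both <- sys$wrist_sign & sys$thumb_sign
  p[, "wrist_sign"] <- ifelse(both, 3L, p[, "wrist_sign"])
  p[, "thumb_sign"] <- ifelse(both, 0L, p[, "thumb_sign"])
  p
}

#' Systemic-score totals for a cohort
#'
#' Vectorized total of the 20-point systemic checklist for every record.
#'
#' @param cohort A cohort data.frame (all 16 `sys_*` items must be stated).
#' @return Integer vector of totals in `[0, 20]`.
#' @export
systemic_points <- function(cohort) {
  sys <- sys_matrix(cohort)
  as.integer(rowSums(sys_points_matrix(sys)))
}

#' Ghent-2 systemic involvement score
#'
#' Awards points per the 20-point checklist (pectus carinatum 2, hindfoot
#' deformity 2, protrusio acetabulae 2, pneumothorax 2, dural ectasia 2,
#' wrist AND thumb 3, wrist OR thumb 1, all other items 1) with the
#' exclusivity rules documented in the package vignette, and applies the
#' \eqn{\ge 7/20} positivity threshold.
#'
#' @param items Named logical vector from [systemic_items()], or a one-row
#'   cohort data.frame.
#' @return An object of class `systemic_score`: list with `total_points`
#'   (0--20), `item_points` (named integer vector of awarded points) and
#'   `positive` (`total_points >= 7`).
#' @export
systemic_score <- function(items) {
  if (is.data.frame(items)) {
    stopifnot(nrow(items) == 1)
    sys <- sys_matrix(items)
  } else {
    stopifnot(setequal(names(items), SYS_ITEMS))
    if (anyNA(items)) {
      stop("systemic score is not computable: item(s) not stated: ",
           paste(names(items)[is.na(items)], collapse = ", "), call. = FALSE)
    }
    sys <- as.data.frame(as.list(items[SYS_ITEMS]))
    names(sys) <- SYS_ITEMS
  }
  pts <- sys_points_matrix(sys)[1, ]
  total <- as.integer(sum(pts))
  structure(
    list(total_points = total, item_points = pts, positive = total >= 7L),
    class = "systemic_score"
  )
}

#' @export
print.systemic_score <- function(x, ...) {
  cat("Ghent-2 systemic score:", x$total_points, "/ 20 points",
      if (x$positive) "(positive, >= 7)" else "(negative, < 7)", "\n")
  awarded <- x$item_points[x$item_points > 0]
  if (length(awarded)) {
    for (nm in names(awarded)) cat("  ", nm, ": ", awarded[[nm]], "\n",
                                   sep = "")
  }
  invisible(x)
}

require_stated <- function(cohort, fields, context) {
  for (nm in fields) {
    if (anyNA(cohort[[nm]])) {
      stop(context, " is not computable: '", nm,
           "' not stated for row(s) ",
           paste(which(is.na(cohort[[nm]])), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

ghent2_eval <- function(cohort, aorta_dilated) {
  require_stated(cohort, c("aortic_dissection", "ectopia_lentis",
                           "family_history_mfs", "fbn1_status"),
                 "Ghent-2 diagnosis")
  stopifnot(length(aorta_dilated) == nrow(cohort), !anyNA(aorta_dilated))
  sysp <- systemic_points(cohort)
  aorta <- aorta_dilated | cohort$aortic_dissection
  el <- cohort$ectopia_lentis
  fh <- cohort$family_history_mfs
  fbn1 <- cohort$fbn1_status == "positive"   # not_tested counts as non-positive
  systemic <- sysp >= 7L
  paths <- cbind(
    `aorta+EL` = aorta & el,
    `aorta+systemic` = aorta & systemic,
    `aorta+FBN1` = aorta & fbn1,
    `FH+aorta` = fh & aorta,
    `FH+EL` = fh & el,
    `FH+systemic` = fh & systemic
  )
  list(diagnosis = rowSums(paths) > 0, pathways = paths,
       systemic_points = sysp, systemic_positive = systemic)
}

#' Ghent-2 diagnosis for a single record
#'
#' Evaluates the six confirmed-MFS pathway conjunctions: aortic
#' dilatation/dissection combined with ectopia lentis, systemic involvement
#' (\eqn{\ge 7} points) or an FBN1 mutation; and family history of MFS
#' combined with aortic dilatation/dissection, ectopia lentis or systemic
#' involvement.  `fbn1_status = "not_tested"` disables (does not fail) the
#' FBN1 pathway.
#'
#' @param record One-row cohort data.frame.
#' @param aorta_dilated Logical: aortic (sinus of Valsalva) dilatation,
#'   precomputed via a direct flag or nomogram.  If `NULL`, resolved from
#'   the record with [resolve_dilation()].
#' @param nomogram,threshold Passed to [resolve_dilation()] when
#'   `aorta_dilated` is `NULL`.
#' @return An object of class `ghent2_result`: list with `diagnosis`
#'   (logical), `pathways` (character vector of matched pathway labels) and
#'   `systemic` (a [systemic_score()] result).  `diagnosis` is `TRUE` iff
#'   `pathways` is non-empty.
#' @export
ghent2_diagnose <- function(record, aorta_dilated = NULL, nomogram = NULL,
                            threshold = 2) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (is.null(aorta_dilated)) {
    aorta_dilated <- resolve_dilation(record, "sv", nomogram = nomogram,
                                      threshold = threshold)
  }
  ev <- ghent2_eval(record, aorta_dilated)
  structure(
    list(diagnosis = ev$diagnosis[1],
         pathways = GHENT2_PATHWAYS[ev$pathways[1, ]],
         systemic = systemic_score(record)),
    class = "ghent2_result"
  )
}

#' @export
print.ghent2_result <- function(x, ...) {
  cat("Ghent-2:", if (x$diagnosis) "MFS confirmed" else "MFS not confirmed",
      "\n")
  if (length(x$pathways)) {
    cat("  pathways:", paste(x$pathways, collapse = ", "), "\n")
  }
  cat("  systemic score:", x$systemic$total_points, "/ 20\n")
  invisible(x)
}

#' Ghent-2 diagnosis for a whole cohort
#'
#' Vectorized [ghent2_diagnose()].  Aortic dilatation is resolved per
#' record from the direct `sv_dilated` flag, or the SV nomogram when only a
#' diameter and BSA are recorded.
#'
#' @param cohort Cohort data.frame.
#' @param nomogram SV nomogram (default [default_sv_nomogram()]).
#' @param threshold Z-score dilatation threshold (default 2, inclusive).
#' @return data.frame with `diagnosis`, `pathways` (`";"`-joined labels),
#'   `systemic_points`, `systemic_positive`.
#' @export
ghent2_cohort <- function(cohort, nomogram = NULL, threshold = 2) {
  aorta <- resolve_dilation(cohort, "sv", nomogram = nomogram,
                            threshold = threshold)
  ev <- ghent2_eval(cohort, aorta)
  data.frame(
    patient_id = cohort$patient_id,
    diagnosis = ev$diagnosis,
    pathways = apply(ev$pathways, 1, function(r) {
      paste(GHENT2_PATHWAYS[r], collapse = ";")
    }),
    systemic_points = ev$systemic_points,
    systemic_positive = ev$systemic_positive,
    stringsAsFactors = FALSE
  )
}
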