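## Synthetic validation cohort.
##
## fixture_cohort() deterministically reconstructs a 106-patient cohort
## whose Kid-SMS profile x outcome cells, baseline and follow-up fourfold
## tables, and age-at-first-presentation bins match the published
## validation study; random_cohort() draws randomized cohorts for property
## testing.  Each fixture record is a minimal realization: it carries
## exactly the manifestations its profile requires plus the minimum extras
## needed to force its assigned Ghent-2 status.

AGE_BIN_BREAKS <- c(0, 1, 6, 13, 18, Inf)
AGE_BIN_LABELS <- c("0-1", "1-6", "6-13", "13-18", ">18")
## deterministic within-bin representatives used by the fixture
AGE_BIN_MIDPOINTS <- c(0.5, 3.5, 9.5, 15.5, 19)

#' Age-at-first-presentation bins
#'
#' Bins ages into the presentation-age classes 0--1, 1--6, 6--13, 13--18
#' and >18 years (right-closed).
#'
#' @param age_years Numeric ages.
#' @return Factor with the five bin labels.
#' @export
age_bins <- function(age_years) {
  cut(age_years, breaks = AGE_BIN_BREAKS, labels = AGE_BIN_LABELS,
      right = TRUE, include.lowest = TRUE)
}

## One fixture patient: profile features at follow-up, optional reduced
## systemic items at baseline (the follow-up conversions), final MFS
## outcome, and the deterministic baseline age.
fixture_plan <- function() {
  pt <- function(group, sv = FALSE, pa = FALSE, el = FALSE, mvp = FALSE,
                 tvp = FALSE, fh = FALSE, fbn1 = "not_tested",
                 sys = character(), sys_baseline = NULL, final = FALSE,
                 age = 9.5) {
    list(group = group, sv = sv, pa = pa, el = el, mvp = mvp, tvp = tvp,
         fh = fh, fbn1 = fbn1, sys = sys,
         sys_baseline = if (is.null(sys_baseline)) sys else sys_baseline,
         final = final, age = age)
  }
  sys7_skel <- c("wrist_sign", "thumb_sign", "pectus_carinatum",
                 "hindfoot_deformity")                       # 3+2+2 = 7
  sys3_skel <- c("scoliosis_or_kyphosis", "pes_planus",
                 "pectus_excavatum_or_chest_asymmetry")      # 1+1+1 = 3
  sys7_mvp <- c("mitral_valve_prolapse", "spontaneous_pneumothorax",
                "dural_ectasia", "striae_atrophicae",
                "myopia_gt3_diopters")                       # 1+2+2+1+1 = 7
  sys6_mvp <- setdiff(sys7_mvp, "myopia_gt3_diopters")       # 6 points
  sys7_pa <- c("spontaneous_pneumothorax", "dural_ectasia",
               "striae_atrophicae", "myopia_gt3_diopters",
               "wrist_sign")                                 # 2+2+1+1+1 = 7
  plan <- c(
    ## very high risk, SV + EL: confirmed via aorta + EL
    rep(list(pt("SV+EL", sv = TRUE, el = TRUE, final = TRUE)), 2),
    ## high risk, SV + 3Skel, confirmed via aorta + systemic (7 points from
    ## 4 skeletal items); the first two convert between visits: at baseline
    ## they lack hindfoot deformity (5 points, still 3 skeletal features)
    rep(list(pt("SV+3Skel", sv = TRUE, sys = sys7_skel,
                sys_baseline = setdiff(sys7_skel, "hindfoot_deformity"),
                final = TRUE)), 2),
    rep(list(pt("SV+3Skel", sv = TRUE, sys = sys7_skel, final = TRUE)), 6),
    ## high risk, SV + 3Skel, never confirmed (3 low-weight skeletal items)
    rep(list(pt("SV+3Skel", sv = TRUE, sys = sys3_skel, age = 0.5)), 2),
    ## high risk, SV + MVP + TVP, confirmed via aorta + systemic (7
    ## non-skeletal points); the first converts: no dural ectasia at
    ## baseline (5 points)
    list(pt("SV+MVP+TVP", sv = TRUE, mvp = TRUE, tvp = TRUE, sys = sys7_mvp,
            sys_baseline = setdiff(sys7_mvp, "dural_ectasia"),
            final = TRUE)),
    rep(list(pt("SV+MVP+TVP", sv = TRUE, mvp = TRUE, tvp = TRUE,
                sys = sys7_mvp, final = TRUE)), 6),
    ## high risk, SV + PA, confirmed via aorta + systemic
    rep(list(pt("SV+PA", sv = TRUE, pa = TRUE, sys = sys7_pa,
                final = TRUE)), 3),
    ## high risk, EL + PA, confirmed via family history + EL
    rep(list(pt("EL+PA", el = TRUE, pa = TRUE, fh = TRUE, final = TRUE)), 2),
    ## moderate risk, FH: one confirmed via FH + systemic; one diagnosed
    ## only after the follow-up evaluation (6 points at both visits)
    list(pt("FH", fh = TRUE, mvp = TRUE, sys = sys7_mvp, final = TRUE)),
    list(pt("FH", fh = TRUE, mvp = TRUE, sys = sys6_mvp, final = TRUE,
            age = 3.5)),
    ## moderate risk, FH with FBN1 mutation, no diagnosis
    rep(list(pt("FH", fh = TRUE, fbn1 = "positive", age = 3.5)), 2),
    ## moderate risk, FH, FBN1 negative
    rep(list(pt("FH", fh = TRUE, fbn1 = "negative", age = 3.5)), 7),
    ## moderate risk, SV: one confirmed via aorta + systemic; two diagnosed
    ## only after the follow-up evaluation
    list(pt("SV", sv = TRUE, mvp = TRUE, sys = sys7_mvp, final = TRUE)),
    rep(list(pt("SV", sv = TRUE, mvp = TRUE, sys = sys6_mvp, final = TRUE,
                age = 3.5)), 2),
    ## moderate risk, SV alone, never confirmed
    rep(list(pt("SV", sv = TRUE, age = 3.5)), 2),
    rep(list(pt("SV", sv = TRUE, age = 9.5)), 3),
    ## Kid-SMS negative with FBN1 mutation: isolated MVP + TVP, and two
    ## with a positive systemic score but no vascular involvement
    list(pt("negative", mvp = TRUE, tvp = TRUE, fbn1 = "positive",
            sys = "mitral_valve_prolapse")),
    rep(list(pt("negative", fbn1 = "positive", sys = sys7_skel)), 2),
    ## Kid-SMS negative, no manifestations
    rep(list(pt("negative", age = 9.5)), 3),
    rep(list(pt("negative", age = 15.5)), 53),
    rep(list(pt("negative", age = 19)), 4)
  )
  plan
}

fixture_record <- function(p, i, visit) {
  sys_names <- if (visit == "baseline") p$sys_baseline else p$sys
  sys <- systemic_items_none()
  sys[sys_names] <- TRUE
  age <- if (visit == "baseline") p$age else p$age + 2
  phenotype_record(
    patient_id = sprintf("P%03d", i),
    age_years = age,
    sex = if (i <= 39) "female" else "male",
    visit = visit,
    sv_dilated = p$sv, pa_dilated = p$pa,
    aortic_dissection = FALSE,
    ectopia_lentis = p$el,
    mitral_valve_prolapse = p$mvp,
    tricuspid_valve_prolapse = p$tvp,
    family_history_mfs = p$fh,
    fbn1_status = p$fbn1,
    systemic = sys
  )
}

#' Deterministic 106-patient validation fixture
#'
#' Reconstructs, without randomness, a 106-patient cohort realizing the
#' published validation counts: the nine Kid-SMS profile rows crossed with
#' the final outcome (27 eventually diagnosed; 5 FBN1-positive without
#' diagnosis; 74 neither), a baseline fourfold of (21, 22, 0, 63) and a
#' follow-up fourfold of (24, 19, 0, 63) against computed Ghent-2 status
#' (three patients convert from Ghent-2-negative to positive between
#' visits while already stratified at risk, and three further patients are
#' diagnosed only after the follow-up evaluation), 43 children stratified
#' at risk, and age-at-first-presentation bins of 2/14/33/53/4.  Ages sit
#' at deterministic bin representatives; the follow-up visit is 2 years
#' after baseline.
#'
#' The returned cohort carries one fixture-only extra column, `mfs_final`:
#' the final-surveillance outcome used for the profile-by-outcome summary
#' (see [table5_summary()]), which for three late-diagnosed patients is
#' `TRUE` although [ghent2_cohort()] is still negative at the follow-up
#' visit.
#'
#' @param visit `"follow_up"` (default) or `"baseline"`.
#' @return Cohort data.frame of 106 records plus the `mfs_final` column.
#' @export
fixture_cohort <- function(visit = c("follow_up", "baseline")) {
  visit <- match.arg(visit)
  plan <- fixture_plan()
  recs <- lapply(seq_along(plan), function(i) {
    fixture_record(plan[[i]], i, visit)
  })
  cohort <- do.call(rbind, recs)
  cohort$mfs_final <- vapply(plan, function(p) p$final, logical(1))
  cohort <- as_cohort(cohort, allow_extra = "mfs_final")
  stopifnot(nrow(cohort) == 106, sum(cohort$mfs_final) == 27,
            sum(cohort$fbn1_status == "positive" & !cohort$mfs_final) == 5)
  cohort
}

#' Profile-by-outcome summary of a cohort
#'
#' Cross-tabulates the computed Kid-SMS primary profile of every record
#' against a three-way outcome grouping: eventually diagnosed with MFS;
#' not diagnosed but FBN1-positive; neither.
#'
#' @param cohort Cohort data.frame.
#' @param mfs_final Logical vector of final diagnosis outcomes; defaults to
#'   the cohort's `mfs_final` column.
#' @param ... Passed to [kidsms_cohort()].
#' @return Integer matrix, nine profile rows by the three outcome columns.
#' @export
table5_summary <- function(cohort, mfs_final = cohort$mfs_final, ...) {
  stopifnot(is.logical(mfs_final), length(mfs_final) == nrow(cohort))
  profile <- kidsms_cohort(cohort, ...)$primary_profile
  outcome <- ifelse(mfs_final, "mfs",
                    ifelse(cohort$fbn1_status == "positive",
                           "fbn1_pos", "fbn1_neg"))
  rows <- c(KIDSMS_RULES$label, "negative")
  cols <- c("mfs", "fbn1_pos", "fbn1_neg")
  out <- matrix(0L, length(rows), length(cols),
                dimnames = list(profile = rows, outcome = cols))
  tab <- table(factor(profile, levels = rows),
               factor(outcome, levels = cols))
  out[] <- as.integer(tab)
  out
}

#' Event series of the fixture cohort
#'
#' Builds the age-at-stratification and age-at-diagnosis [event_series()]
#' from both visits of [fixture_cohort()] via [endpoint_series()].  The
#' three patients diagnosed only after the follow-up evaluation are
#' censored, as they never reach the Ghent-2 endpoint within surveillance.
#'
#' @return List with `kidsms` and `ghent2` event series.
#' @export
fixture_event_series <- function() {
  schema <- cohort_columns()$name
  both <- rbind(fixture_cohort("baseline")[, schema],
                fixture_cohort("follow_up")[, schema])
  endpoint_series(both)
}

#' Empirical fixture profile weights
#'
#' The nine Kid-SMS profile frequencies of the fixture cohort
#' (2, 10, 7, 3, 0, 2, 11, 8, 63 out of 106), usable as
#' `profile_weights` for [random_cohort()].
#'
#' @return Named numeric vector summing to 1.
#' @export
fixture_profile_weights <- function() {
  counts <- c(`SV+EL` = 2, `SV+MVP+TVP` = 7, `SV+PA` = 3, `SV+3Skel` = 10,
              `EL+MVP+TVP` = 0, `EL+PA` = 2, FH = 11, SV = 8,
              negative = 63)
  counts / sum(counts)
}

#' Empirical fixture age-bin weights
#'
#' Age-at-first-presentation bin frequencies (2, 14, 33, 53, 4 out of 106).
#'
#' @return Named numeric vector over the five bins, summing to 1.
#' @export
fixture_age_bin_weights <- function() {
  counts <- stats::setNames(c(2, 14, 33, 53, 4), AGE_BIN_LABELS)
  counts / sum(counts)
}

## Minimal phenotype per profile for randomly generated records.
profile_features <- function(profile) {
  sys <- systemic_items_none()
  f <- list(sv = FALSE, pa = FALSE, el = FALSE, mvp = FALSE, tvp = FALSE,
            fh = FALSE)
  switch(profile,
    "SV+EL" = { f$sv <- TRUE; f$el <- TRUE },
    "SV+MVP+TVP" = {
      f$sv <- TRUE; f$mvp <- TRUE; f$tvp <- TRUE
      sys["mitral_valve_prolapse"] <- TRUE
    },
    "SV+PA" = { f$sv <- TRUE; f$pa <- TRUE },
    "SV+3Skel" = {
      f$sv <- TRUE
      sys[c("scoliosis_or_kyphosis", "pes_planus",
            "pectus_excavatum_or_chest_asymmetry")] <- TRUE
    },
    "EL+MVP+TVP" = {
      f$el <- TRUE; f$mvp <- TRUE; f$tvp <- TRUE
      sys["mitral_valve_prolapse"] <- TRUE
    },
    "EL+PA" = { f$el <- TRUE; f$pa <- TRUE },
    "FH" = { f$fh <- TRUE },
    "SV" = { f$sv <- TRUE },
    "negative" = { },
    stop("unknown profile: ", profile)
  )
  f$sys <- sys
  f
}

## Run code with a private RNG stream (no global random state disturbed).
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random cohort generator
#'
#' Draws `n` records i.i.d. over Kid-SMS profiles with the given weights;
#' each record carries the minimal phenotype of its profile.  Ages are
#' drawn from the presentation-age bins (uniform within a bin; the open
#' top bin is drawn on 18--20 years).  Fully reproducible under a fixed
#' seed, with no global RNG state disturbed.
#'
#' @param n Number of records (>= 1).
#' @param profile_weights Named probabilities over the nine profiles
#'   (default [fixture_profile_weights()]); must sum to 1.
#' @param age_bin_weights Named probabilities over the five age bins
#'   (default [fixture_age_bin_weights()]); must sum to 1.
#' @param seed Integer seed governing the whole draw.
#' @return Cohort data.frame of `n` records.
#' @export
random_cohort <- function(n, profile_weights = fixture_profile_weights(),
                          age_bin_weights = fixture_age_bin_weights(),
                          seed = 1) {
  stopifnot(n >= 1)
  check_weights <- function(w, names_expected, what) {
    if (is.null(names(w)) || !setequal(names(w), names_expected) ||
        any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop(what, " must be named over {",
           paste(names_expected, collapse = ", "),
           "}, non-negative, and sum to 1", call. = FALSE)
    }
    w[names_expected]
  }
  profiles <- c(KIDSMS_RULES$label, "negative")
  pw <- check_weights(profile_weights, profiles, "profile_weights")
  aw <- check_weights(age_bin_weights, AGE_BIN_LABELS, "age_bin_weights")
  with_local_seed(seed, {
    prof <- sample(profiles, n, replace = TRUE, prob = pw)
    bin <- sample(seq_along(AGE_BIN_LABELS), n, replace = TRUE, prob = aw)
    lo <- AGE_BIN_BREAKS[bin]
    hi <- ifelse(is.finite(AGE_BIN_BREAKS[bin + 1]),
                 AGE_BIN_BREAKS[bin + 1], 20)
    age <- stats::runif(n, lo, hi)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    recs <- lapply(seq_len(n), function(i) {
      f <- profile_features(prof[i])
      phenotype_record(
        patient_id = sprintf("S%05d", i),
        age_years = age[i], sex = sex[i], visit = "baseline",
        sv_dilated = f$sv, pa_dilated = f$pa,
        aortic_dissection = FALSE,
        ectopia_lentis = f$el, mitral_valve_prolapse = f$mvp,
        tricuspid_valve_prolapse = f$tvp, family_history_mfs = f$fh,
        fbn1_status = "not_tested", systemic = f$sys
      )
    })
    do.call(rbind, recs)
  })
}
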