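## Independent brute-force oracles and record-building shorthands.
## The oracles are written as literal scalar transcriptions of the
## published rules, deliberately structured differently from the package's
## vectorized engines.

## Scalar systemic-score oracle: explicit if-chains over the 20-point
## checklist with the two exclusive pairs and the wrist/thumb 3-or-1 rule.
oracle_systemic_total <- function(v) {
  pts <- 0L
  if (v[["pectus_carinatum"]]) {
    pts <- pts + 2L
  } else if (v[["pectus_excavatum_or_chest_asymmetry"]]) {
    pts <- pts + 1L
  }
  if (v[["reduced_us_ls_and_increased_armspan_no_scoliosis"]]) pts <- pts + 1L
  if (v[["characteristic_face"]]) pts <- pts + 1L
  if (v[["wrist_sign"]] && v[["thumb_sign"]]) {
    pts <- pts + 3L
  } else if (v[["wrist_sign"]] || v[["thumb_sign"]]) {
    pts <- pts + 1L
  }
  if (v[["scoliosis_or_kyphosis"]]) pts <- pts + 1L
  if (v[["reduced_elbow_extension"]]) pts <- pts + 1L
  if (v[["hindfoot_deformity"]]) {
    pts <- pts + 2L
  } else if (v[["pes_planus"]]) {
    pts <- pts + 1L
  }
  if (v[["protrusio_acetabulae"]]) pts <- pts + 2L
  if (v[["myopia_gt3_diopters"]]) pts <- pts + 1L
  if (v[["mitral_valve_prolapse"]]) pts <- pts + 1L
  if (v[["spontaneous_pneumothorax"]]) pts <- pts + 2L
  if (v[["striae_atrophicae"]]) pts <- pts + 1L
  if (v[["dural_ectasia"]]) pts <- pts + 2L
  pts
}

## Scalar Kid-SMS category oracle over resolved feature flags.
oracle_kidsms_category <- function(sv, el, mvp, tvp, pa, fh, skel3) {
  if (sv && el) return("very_high")
  if ((sv && mvp && tvp) || (sv && pa) || (sv && skel3) ||
      (el && mvp && tvp) || (el && pa)) {
    return("high")
  }
  if (fh || sv) return("moderate")
  "negative"
}

## Exhaustive fixed-margins Fisher oracle: enumerate every table with the
## observed margins, score each by its exact hypergeometric probability
## computed from binomial coefficients, and sum the probabilities of
## tables no more probable than the observed one.
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

## A minimal scoring-ready record with every feature resolved and stated.
rec <- function(sv = FALSE, pa = FALSE, el = FALSE, mvp = FALSE,
                tvp = FALSE, fh = FALSE, fbn1 = "not_tested",
                dissection = FALSE, sys = systemic_items_none(),
                age = 10, id = "T001", visit = "baseline") {
  phenotype_record(
    patient_id = id, age_years = age, sex = "unknown", visit = visit,
    sv_dilated = sv, pa_dilated = pa, aortic_dissection = dissection,
    ectopia_lentis = el, mitral_valve_prolapse = mvp,
    tricuspid_valve_prolapse = tvp, family_history_mfs = fh,
    fbn1_status = fbn1, systemic = sys
  )
}

## Systemic-item vector with the named items present.
sys_with <- function(...) {
  v <- systemic_items_none()
  v[c(...)] <- TRUE
  v
}

## An n-row scoring-ready cohort whose sys_* columns are taken from a
## logical matrix (columns named by item); built columnwise so the 2^16
## sweep stays cheap.
sys_cohort <- function(sysmat) {
  n <- nrow(sysmat)
  df <- data.frame(
    patient_id = sprintf("C%05d", seq_len(n)), visit = "baseline",
    age_years = 10, sex = "unknown", bsa_m2 = NA_real_,
    sv_diameter_mm = NA_real_, sv_dilated = FALSE,
    aortic_dissection = FALSE, pa_diameter_mm = NA_real_,
    pa_dilated = FALSE, ectopia_lentis = FALSE,
    mitral_valve_prolapse = FALSE, tricuspid_valve_prolapse = FALSE,
    family_history_mfs = FALSE, fbn1_status = "not_tested",
    stringsAsFactors = FALSE
  )
  for (it in colnames(sysmat)) df[[paste0("sys_", it)]] <- sysmat[, it]
  as_cohort(df)
}
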