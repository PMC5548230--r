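test_that("skeletal features are counted as items, not points", {
  expect_equal(count_skeletal_features(
    sys_with("scoliosis_or_kyphosis", "pes_planus",
             "pectus_excavatum_or_chest_asymmetry")), 3)
  expect_equal(count_skeletal_features(systemic_items_none()), 0)
  ## the full skeletal subset has 11 items; non-skeletal rows are excluded
  all_items <- stats::setNames(rep(TRUE, 16),
                               names(systemic_items_none()))
  expect_equal(count_skeletal_features(
    do.call(systemic_items, as.list(all_items))), 11)
  ## wrist + thumb is two features even though it scores 3 points
  expect_equal(count_skeletal_features(sys_with("wrist_sign", "thumb_sign")),
               2)
})

test_that("the eight stratification rules assign the published categories", {
  ## SV + EL: very high risk
  r <- kidsms_stratify(rec(sv = TRUE, el = TRUE))
  expect_equal(as.character(r$category), "very_high")
  expect_equal(r$matched_rules[1], "SV+EL")

  ## family history alone: moderate, matched rules exactly [FH]
  r2 <- kidsms_stratify(rec(fh = TRUE))
  expect_equal(as.character(r2$category), "moderate")
  expect_equal(r2$matched_rules, "FH")

  ## no manifestations: negative
  r3 <- kidsms_stratify(rec())
  expect_equal(as.character(r3$category), "negative")
  expect_length(r3$matched_rules, 0)

  ## SV + MVP + TVP with 3 skeletal features: high, dominated SV recorded
  r4 <- kidsms_stratify(rec(sv = TRUE, mvp = TRUE, tvp = TRUE,
                            sys = sys_with("scoliosis_or_kyphosis",
                                           "pes_planus", "wrist_sign")))
  expect_equal(as.character(r4$category), "high")
  expect_equal(r4$matched_rules, c("SV+MVP+TVP", "SV+3Skel", "SV"))

  ## aortic dissection does not enter Kid-SMS
  r5 <- kidsms_stratify(rec(dissection = TRUE))
  expect_equal(as.character(r5$category), "negative")
})

test_that("stratification agrees with the brute-force rule oracle on all 2^7 feature combinations", {
  grid <- expand.grid(sv = c(FALSE, TRUE), el = c(FALSE, TRUE),
                      mvp = c(FALSE, TRUE), tvp = c(FALSE, TRUE),
                      pa = c(FALSE, TRUE), fh = c(FALSE, TRUE),
                      skel3 = c(FALSE, TRUE))
  three_skel <- sys_with("scoliosis_or_kyphosis", "pes_planus",
                         "reduced_elbow_extension")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- kidsms_stratify(rec(sv = g$sv, el = g$el, mvp = g$mvp, tvp = g$tvp,
                             pa = g$pa, fh = g$fh,
                             sys = if (g$skel3) three_skel
                                   else systemic_items_none()))
    want <- oracle_kidsms_category(g$sv, g$el, g$mvp, g$tvp, g$pa, g$fh,
                                   g$skel3)
    expect_equal(as.character(r$category), want,
                 info = paste(unlist(g), collapse = ","))
    ## negative iff no rule matched
    expect_identical(length(r$matched_rules) == 0, want == "negative")
  }
})

test_that("adding any manifestation never lowers the category", {
  grid <- expand.grid(sv = c(FALSE, TRUE), el = c(FALSE, TRUE),
                      mvp = c(FALSE, TRUE), tvp = c(FALSE, TRUE),
                      pa = c(FALSE, TRUE), fh = c(FALSE, TRUE),
                      skel3 = c(FALSE, TRUE))
  cat_of <- function(g) {
    factor(oracle_kidsms_category(g$sv, g$el, g$mvp, g$tvp, g$pa, g$fh,
                                  g$skel3),
           levels = c("negative", "moderate", "high", "very_high"),
           ordered = TRUE)
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    base <- cat_of(g)
    for (f in names(grid)) {
      g2 <- g
      g2[[f]] <- TRUE
      expect_true(cat_of(g2) >= base, info = f)
    }
  }
})

test_that("primary profile is the first matched rule in published row order", {
  expect_equal(primary_profile(c("SV+EL", "SV")), "SV+EL")
  expect_equal(primary_profile(c("FH", "SV")), "FH")
  expect_equal(primary_profile(character(0)), "negative")
  r <- kidsms_stratify(rec(fh = TRUE, sv = TRUE))
  expect_equal(primary_profile(r), "FH")
  expect_equal(as.character(r$category), "moderate")
})

test_that("unresolved dilatation makes stratification fail loudly", {
  r <- rec()
  r$sv_dilated <- NA
  expect_error(kidsms_stratify(r), "SV dilatation unresolvable")
  r2 <- rec()
  r2$pa_dilated <- NA
  expect_error(kidsms_stratify(r2), "PA dilatation unresolvable")
})

test_that("every very-high record in fixture and random cohorts satisfies Ghent-2", {
  for (cohort in list(fixture_cohort("follow_up"),
                      fixture_cohort("baseline"),
                      random_cohort(400, seed = 99))) {
    kid <- kidsms_cohort(cohort)
    g2 <- ghent2_cohort(cohort)
    vh <- kid$category == "very_high"
    if (any(vh)) expect_true(all(g2$diagnosis[vh]))
  }
})
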