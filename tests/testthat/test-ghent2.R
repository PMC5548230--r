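test_that("systemic score awards the published point values", {
  ## wrist+thumb (3) + pectus carinatum (2) + hindfoot (2) = 7, positive
  s <- systemic_score(sys_with("wrist_sign", "thumb_sign",
                               "pectus_carinatum", "hindfoot_deformity"))
  expect_equal(s$total_points, 7)
  expect_true(s$positive)
  expect_equal(sum(s$item_points), s$total_points)

  ## no items: 0, negative
  s0 <- systemic_score(systemic_items_none())
  expect_equal(s0$total_points, 0)
  expect_false(s0$positive)

  ## all items: exactly 20 under the exclusivity rules (wrist/thumb once as
  ## 3; carinatum suppresses excavatum; hindfoot suppresses plain pes planus)
  items <- stats::setNames(rep(TRUE, 16), names(systemic_items_none()))
  s20 <- systemic_score(do.call(systemic_items, as.list(items)))
  expect_equal(s20$total_points, 20)
  expect_true(s20$positive)
})

test_that("wrist/thumb contributes exactly one of {0, 1, 3}", {
  expect_equal(systemic_score(sys_with("wrist_sign"))$total_points, 1)
  expect_equal(systemic_score(sys_with("thumb_sign"))$total_points, 1)
  expect_equal(systemic_score(sys_with("wrist_sign",
                                       "thumb_sign"))$total_points, 3)
})

test_that("systemic totals match the brute-force oracle on sampled item vectors", {
  set.seed(41)
  m <- matrix(sample(c(TRUE, FALSE), 500 * 16, replace = TRUE), 500, 16,
              dimnames = list(NULL, names(systemic_items_none())))
  cohort <- sys_cohort(m)
  got <- systemic_points(cohort)
  want <- apply(m, 1, oracle_systemic_total)
  expect_equal(got, as.integer(want))
})

test_that("raising any single item never decreases the total", {
  set.seed(42)
  items <- names(systemic_items_none())
  m <- matrix(sample(c(TRUE, FALSE), 200 * 16, replace = TRUE), 200, 16,
              dimnames = list(NULL, items))
  base <- systemic_points(sys_cohort(m))
  for (it in items) {
    m2 <- m
    m2[, it] <- TRUE
    expect_true(all(systemic_points(sys_cohort(m2)) >= base), info = it)
  }
})

test_that("Ghent-2 pathways combine aorta, EL, systemic, FBN1 and FH as published", {
  ## aortic dilatation + ectopia lentis, FBN1 untested
  r1 <- ghent2_diagnose(rec(sv = TRUE, el = TRUE))
  expect_true(r1$diagnosis)
  expect_equal(r1$pathways, "aorta+EL")

  ## family history + systemic involvement at exactly 7 points
  r2 <- ghent2_diagnose(rec(fh = TRUE,
                            sys = sys_with("wrist_sign", "thumb_sign",
                                           "pectus_carinatum",
                                           "hindfoot_deformity")))
  expect_true(r2$diagnosis)
  expect_equal(r2$pathways, "FH+systemic")

  ## FBN1 mutation alone with sub-threshold systemic score: no diagnosis
  r3 <- ghent2_diagnose(rec(fbn1 = "positive",
                            sys = sys_with("scoliosis_or_kyphosis",
                                           "pes_planus", "wrist_sign")))
  expect_false(r3$diagnosis)
  expect_length(r3$pathways, 0)

  ## aortic dissection counts as the aorta criterion
  r4 <- ghent2_diagnose(rec(dissection = TRUE, fbn1 = "positive"))
  expect_true(r4$diagnosis)
  expect_equal(r4$pathways, "aorta+FBN1")

  ## not_tested disables, not fails, the FBN1 pathway
  r5 <- ghent2_diagnose(rec(sv = TRUE, fbn1 = "not_tested"))
  expect_false(r5$diagnosis)

  ## diagnosis is true iff pathways non-empty, on a batch of random records
  set.seed(7)
  for (i in 1:50) {
    r <- rec(sv = runif(1) < 0.5, el = runif(1) < 0.5, fh = runif(1) < 0.5,
             fbn1 = sample(c("positive", "negative", "not_tested"), 1),
             sys = sys_with(sample(names(systemic_items_none()),
                                   sample(0:8, 1))))
    out <- ghent2_diagnose(r)
    expect_identical(out$diagnosis, length(out$pathways) > 0)
  }
})

test_that("adding a manifestation never revokes a Ghent-2 diagnosis", {
  set.seed(11)
  flip_up <- function(r, field) { r[[field]] <- TRUE; r }
  fields <- c("ectopia_lentis", "family_history_mfs", "aortic_dissection",
              "sv_dilated")
  for (i in 1:40) {
    r <- rec(sv = runif(1) < 0.5, el = runif(1) < 0.5, fh = runif(1) < 0.5,
             fbn1 = sample(c("positive", "not_tested"), 1),
             sys = sys_with(sample(names(systemic_items_none()),
                                   sample(0:10, 1))))
    base <- ghent2_diagnose(r)$diagnosis
    for (f in fields) {
      expect_true(ghent2_diagnose(flip_up(r, f))$diagnosis >= base,
                  info = f)
    }
  }
})

test_that("ghent2 fails loudly on unstated clinical features", {
  r <- rec(sv = TRUE)
  r$ectopia_lentis <- NA
  expect_error(ghent2_diagnose(r), "ectopia_lentis")
  r2 <- rec(sv = TRUE, sys = NA)
  expect_error(ghent2_diagnose(r2), "not stated")
})
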