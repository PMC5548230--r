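test_that("fourfold tables cross-tabulate index vs reference", {
  cohort <- fixture_cohort("follow_up")
  kid <- kidsms_cohort(cohort)
  g2 <- ghent2_cohort(cohort)
  ff <- build_fourfold(cohort, kid$category >= "moderate", g2$diagnosis)
  expect_equal(unlist(ff[c("tp", "fp", "fn", "tn")]),
               c(tp = 24, fp = 19, fn = 0, tn = 63))
  ## identical predicates give a diagonal table
  ff2 <- build_fourfold(cohort, g2$diagnosis, g2$diagnosis)
  expect_equal(ff2$fp, 0)
  expect_equal(ff2$fn, 0)
  ## predicates can be functions of the cohort
  ff3 <- build_fourfold(cohort,
                        function(co) kidsms_cohort(co)$category >= "moderate",
                        function(co) ghent2_cohort(co)$diagnosis)
  expect_equal(unlist(ff3), unlist(ff))
  expect_error(build_fourfold(cohort[0, ], TRUE, TRUE), "empty")
  expect_error(fourfold(0, 0, 0, 0), "positive total")
})

test_that("Clopper-Pearson intervals match closed forms and binom.test", {
  ## numerator = denominator: lower bound solves (alpha/2)^(1/n)
  ci24 <- clopper_pearson_ci(24, 24)
  expect_equal(ci24$ci_low, 0.025^(1 / 24))
  expect_equal(ci24$ci_high, 1)
  ci63 <- clopper_pearson_ci(63, 63)
  expect_equal(ci63$ci_low, 0.025^(1 / 63))
  ## zero numerator: lower bound 0
  ci0 <- clopper_pearson_ci(0, 10)
  expect_equal(ci0$ci_low, 0)
  expect_equal(ci0$ci_high, 1 - 0.025^(1 / 10))
  ## cross-check against stats::binom.test on assorted cases
  for (case in list(c(24, 43), c(63, 82), c(5, 10), c(1, 50), c(17, 20))) {
    got <- clopper_pearson_ci(case[1], case[2])
    want <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(want),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson_ci(1, 0), "denominator")
})

test_that("exact intervals hold nominal coverage at n = 50", {
  set.seed(314)
  for (p in c(0.05, 0.5, 0.95)) {
    x <- rbinom(10000, 50, p)
    lo <- ifelse(x == 0, 0, qbeta(0.025, x, 50 - x + 1))
    hi <- ifelse(x == 50, 1, qbeta(0.975, x + 1, 50 - x))
    ## same closed form as the implementation; verify equality on a sample
    idx <- sample(length(x), 25)
    for (i in idx) {
      ci <- clopper_pearson_ci(x[i], 50)
      expect_equal(c(ci$ci_low, ci$ci_high), c(lo[i], hi[i]))
    }
    coverage <- mean(lo <= p & p <= hi)
    ## exact intervals are conservative; allow 3 SE of Monte-Carlo error
    expect_gte(coverage, 0.95 - 3 * sqrt(0.95 * 0.05 / 10000))
  }
})

test_that("performance reproduces the published follow-up statistics", {
  perf <- performance(fourfold(24, 19, 0, 63))
  expect_equal(round(100 * perf$sensitivity$estimate), 100)
  expect_equal(round(100 * perf$specificity$estimate), 77)
  expect_equal(round(100 * perf$ppv$estimate), 56)
  expect_equal(round(100 * perf$npv$estimate), 100)
  expect_equal(round(perf$positive_lr, 1), 4.3)
  expect_equal(perf$positive_lr, (24 / 24) / (1 - 63 / 82))
  ## printed CI bounds at 2 decimals
  expect_equal(round(c(perf$sensitivity$ci_low, perf$sensitivity$ci_high), 2),
               c(0.86, 1.00))
  expect_equal(round(c(perf$specificity$ci_low, perf$specificity$ci_high), 2),
               c(0.66, 0.85))
  expect_equal(round(c(perf$ppv$ci_low, perf$ppv$ci_high), 2), c(0.40, 0.71))
  expect_equal(round(c(perf$npv$ci_low, perf$npv$ci_high), 2), c(0.94, 1.00))
  expect_lt(perf$fisher_p, 0.05)
})

test_that("degenerate margins are flagged undefined, not NaN-propagated", {
  perf <- performance(fourfold(1, 0, 0, 1))
  expect_equal(perf$sensitivity$estimate, 1)
  expect_equal(perf$specificity$estimate, 1)
  expect_identical(perf$positive_lr, Inf)
  expect_length(perf$undefined, 0)

  perf2 <- performance(fourfold(0, 0, 1, 1))
  expect_null(perf2$ppv)
  expect_equal(perf2$undefined, "ppv")
  expect_false(any(vapply(list(perf2$sensitivity, perf2$specificity,
                               perf2$npv), is.null, logical(1))))
})

test_that("Fisher p matches fisher.test and the fixed-margins oracle", {
  cases <- list(c(24, 19, 0, 63), c(3, 1, 2, 5), c(10, 0, 0, 10),
                c(0, 5, 5, 0), c(2, 2, 2, 2), c(7, 0, 3, 4))
  for (cs in cases) {
    got <- fisher_exact(fourfold(cs[1], cs[2], cs[3], cs[4]))
    want_r <- stats::fisher.test(matrix(c(cs[1], cs[3], cs[2], cs[4]),
                                        2))$p.value
    want_o <- oracle_fisher_two_sided(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got, want_r, tolerance = 1e-10)
    expect_equal(got, want_o, tolerance = 1e-10)
  }
  ## all-zero row: single-point support, p = 1
  expect_equal(fisher_exact(fourfold(0, 0, 3, 4)), 1)
  expect_equal(fisher_exact(fourfold(2, 3, 0, 0)), 1)
})

test_that("the key-value report round-trips the unrounded statistics", {
  perf <- performance(fourfold(24, 19, 0, 63))
  path <- withr::local_tempfile(fileext = ".kv")
  performance_report(perf, path)
  kv <- read.dcf(textConnection(gsub("=", ": ", readLines(path))))
  expect_equal(as.numeric(kv[, "sensitivity"]), 1)
  expect_equal(as.numeric(kv[, "specificity"]), 63 / 82, tolerance = 1e-12)
  expect_equal(as.numeric(kv[, "positive_lr"]), 82 / 19, tolerance = 1e-12)
  expect_equal(as.numeric(kv[, "tp"]), 24)
})

test_that("the unpaired t test wrapper reports the classical statistic", {
  x <- c(10.1, 11.2, 9.8, 10.6)
  y <- c(12.0, 12.5, 11.7, 12.3)
  got <- cohort_t_test(x, y)
  want <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$p.value, want$p.value)
})
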