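test_that("the embedded accuracy table matches its published cells", {
  tab <- load_table3()
  expect_equal(dim(tab$values), c(9L, 4L))
  expect_equal(tab$values["Subject 1", "tACS"], 98.75)
  expect_equal(tab$values["Subject 8", "tACS"], 75.11)
  expect_equal(tab$values["Subject 2", "tDCS"], 97.50)
  expect_equal(tab$condition_names[1], "pre-stimulation")
})

test_that("column summaries reproduce the published mean +/- SD row", {
  cs <- column_summary(load_table3())
  # the published tDCS mean (88.71) is truncated from 88.7156, so that cell
  # gets one unit in the last printed digit; the others are rounded values
  expect_true(all(abs(cs$mean - c(82.07, 82.66, 87.07, 88.71)) <=
                    c(0.005, 0.005, 0.005, 0.01)))
  expect_true(all(abs(cs$sd - c(5.67, 7.25, 7.63, 6.88)) <= 0.005))
  const <- study_table(matrix(80, 3, 2))
  expect_equal(column_summary(const)$mean, c(80, 80))
  expect_equal(column_summary(const)$sd, c(0, 0))
})

test_that("repeated-measures ANOVA matches hand-worked and degenerate fixtures", {
  hand <- study_table(matrix(c(1, 2, 2, 4, 3, 3), nrow = 3, byrow = TRUE))
  an <- rm_anova(hand)
  expect_equal(an$ss_condition, 1.5, tolerance = 1e-12)
  expect_equal(an$ss_subject, 3.0, tolerance = 1e-12)
  expect_equal(an$ss_error, 1.0, tolerance = 1e-12)
  expect_equal(an$F, 3.0, tolerance = 1e-12)
  expect_equal(c(an$df_between, an$df_error), c(1L, 2L))

  flat <- study_table(matrix(c(10, 10, 20, 20, 30, 30), 3, 2, byrow = TRUE))
  an0 <- rm_anova(flat)
  expect_equal(an0$ss_condition, 0)
  expect_equal(an0$F, 0)
})

test_that("the published F statistic is recovered from the table", {
  an <- rm_anova(load_table3())
  expect_equal(an$F, 10.436, tolerance = 0.02)
  expect_equal(c(an$df_between, an$df_error), c(3L, 24L))
  expect_lt(an$p, 0.05)
})

test_that("the decomposition matches brute-force and aov oracles on random tables", {
  set.seed(202)
  for (i in 1:10) {
    x <- matrix(runif(12, 40, 95), 4, 3)
    tab <- study_table(x)
    an <- rm_anova(tab)
    # identity: components add to the total
    expect_equal(an$ss_condition + an$ss_subject + an$ss_error,
                 sum((x - mean(x))^2), tolerance = 1e-9)
    br <- brute_rm_anova(x)
    expect_equal(an$ss_condition, br$ss_condition, tolerance = 1e-9)
    expect_equal(an$ss_error, br$ss_error, tolerance = 1e-9)
    expect_equal(an$F, br$F, tolerance = 1e-9)
    # independent route: base R aov with a subject error stratum
    df <- data.frame(y = as.vector(x),
                     cond = factor(rep(seq_len(3), each = 4)),
                     subj = factor(rep(seq_len(4), 3)))
    s <- summary(stats::aov(y ~ cond + Error(subj), data = df))
    f_aov <- s[["Error: Within"]][[1]]["cond", "F value"]
    expect_equal(an$F, f_aov, tolerance = 1e-8)
  }
})

test_that("shifting all cells or single subjects moves only the right components", {
  set.seed(7)
  x <- matrix(runif(12, 50, 90), 4, 3)
  a0 <- rm_anova(study_table(x))
  a1 <- rm_anova(study_table(x + 5))
  expect_equal(a1$F, a0$F, tolerance = 1e-9)
  expect_equal(a1$ss_condition, a0$ss_condition, tolerance = 1e-9)
  xs <- x; xs[2, ] <- xs[2, ] + 4          # per-subject constant
  a2 <- rm_anova(study_table(xs))
  expect_equal(a2$ss_condition, a0$ss_condition, tolerance = 1e-9)
  expect_equal(a2$ss_error, a0$ss_error, tolerance = 1e-9)
  expect_gt(a2$ss_subject, a0$ss_subject)
})

test_that("Greenhouse-Geisser correction yields a valid epsilon and larger p", {
  an <- rm_anova(load_table3(), gg_correction = TRUE)
  expect_gt(an$gg_epsilon, 1 / 3)          # lower bound 1/(c-1)
  expect_lte(an$gg_epsilon, 1 + 1e-12)
  expect_gte(an$p, rm_anova(load_table3())$p)
})

test_that("pairwise comparisons behave like paired t-tests with the tie rule", {
  tab <- load_table3()
  res <- pairwise_comparisons(tab)
  expect_equal(nrow(res), 6L)
  expect_match(attr(res, "note"), "exploratory")
  # tDCS vs pre-stimulation: significant, matching the published direction
  row <- res[res$condition_a == "pre-stimulation" & res$condition_b == "tDCS", ]
  expect_lt(row$p, 0.05)
  # self-comparison: zero statistic, p = 1
  self_tab <- study_table(cbind(tab$values[, 1], tab$values[, 1]))
  self <- pairwise_comparisons(self_tab)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  # swapping columns flips the sign, not the p-value
  sw <- study_table(tab$values[, c(2, 1, 3, 4)],
                    condition_names = tab$condition_names[c(2, 1, 3, 4)])
  res_sw <- pairwise_comparisons(sw)
  a <- res[res$condition_a == "pre-stimulation" &
             res$condition_b == "pseudo-stimulation", ]
  b <- res_sw[res_sw$condition_a == "pseudo-stimulation" &
                res_sw$condition_b == "pre-stimulation", ]
  expect_equal(b$statistic, -a$statistic, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("the reproduction report checks pass at the printed precision", {
  rep <- reproduce_report()
  expect_true(rep$all_pass)
  path <- file.path(withr::local_tempdir(), "report.json")
  rep2 <- reproduce_report(json_path = path)
  expect_true(file.exists(path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(j$all_pass)
  # zero tolerance: rounding-level failures are reported, never raised
  strict <- reproduce_report(mean_sd_tol = 0, f_tol = 0)
  expect_false(strict$all_pass)
  expect_s3_class(strict, "reproduce_report")
})
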