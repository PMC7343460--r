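md_for <- function(ages, ids = sprintf("p%02d", seq_along(ages))) {
  tibble::tibble(subject_id = ids, chron_age = ages)
}

test_that("order_phases sorts clusters by median age with tie rules", {
  # four clusters with medians 50, 30, 70, 40 -> relabeled 3, 1, 4, 2
  ages <- c(49, 50, 51, 29, 30, 31, 69, 70, 71, 39, 40, 41)
  labels <- setNames(rep(1:4, each = 3), sprintf("p%02d", 1:12))
  ph <- order_phases(labels, md_for(ages))
  expect_equal(unname(phase_vector(ph)[sprintf("p%02d", c(1, 4, 7, 10))]),
               c(3, 1, 4, 2))

  # already ordered input keeps identity
  ord <- order_phases(setNames(rep(1:2, each = 3), sprintf("p%02d", 1:6)),
                      md_for(c(20, 21, 22, 60, 61, 62)))
  expect_equal(unname(phase_vector(ord)), rep(1:2, each = 3))

  # equal medians 40/40, means 38/42: lower mean gets the lower phase
  ages2 <- c(34, 40, 40, 40, 40, 46)
  lab2 <- setNames(c(2, 2, 2, 1, 1, 1), sprintf("p%02d", 1:6))
  ph2 <- order_phases(lab2, md_for(ages2))
  expect_equal(unname(phase_vector(ph2)), c(1, 1, 1, 2, 2, 2))
})

test_that("association_test handles degenerate and separated groups", {
  grp <- rep(c("a", "b"), each = 3)
  flat <- association_test(rep(5, 6), grp)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  strong <- association_test(c(1, 2, 3, 101, 102, 103), grp)
  expect_lt(strong$p_value, 0.001)
  # matches the closed-form two-group F computed via lm directly
  oracle <- anova(lm(c(1, 2, 3, 101, 102, 103) ~ factor(grp)))
  expect_equal(strong$statistic, oracle$`F value`[1])

  kw <- association_test(c(1, 2, 3, 101, 102, 103), grp, method = "kruskal")
  expect_lt(kw$p_value, 0.06)
  expect_error(association_test(c(1, 2, 3), c("a", "a", "b")), ">= 2 members")
})

test_that("linear clocks apply the affine prediction with missing features", {
  om <- toy_matrix(matrix(c(5, 1, 2, 3), 2, 2), kind = "methylation",
                   scale = "m_value", features = c("cg1", "cg2"))
  flat <- clock_model(c(cg1 = 0, cg2 = 1e-12), intercept = 50)
  expect_equal(apply_linear_clock(om, flat)$predicted_age, c(50, 50),
               tolerance = 1e-9)

  cl <- clock_model(c(cg1 = 2), intercept = 10, input_scale = "m_value")
  expect_equal(apply_linear_clock(om, cl)$predicted_age, c(20, 14))

  cl2 <- clock_model(c(cg1 = 2, cgX = 5), intercept = 10)
  expect_warning(pred <- apply_linear_clock(om, cl2), "1 of 2")
  expect_equal(pred$predicted_age, c(20, 14))

  clX <- clock_model(c(cgX = 1), intercept = 0)
  expect_error(apply_linear_clock(om, clX), "none of the clock features")
  expect_error(apply_linear_clock(toy_matrix(matrix(1:4, 2, 2)), cl), "scale")
})

test_that("clock recovers biological age on a synthetic cohort", {
  co <- small_cohort(seed = 13)
  pred <- apply_linear_clock(co$meth, co$clock)
  err <- median(abs(pred$predicted_age - co$truth$bio_age))
  expect_lt(err, 2 * 4)  # well within twice the biological-age SD
})

test_that("outlier rule reproduces hand-computed quartile cases", {
  # ages [30,32,34,36,38,60]: Q1 = 32.5, Q3 = 37.5, IQR = 5
  ages <- c(30, 32, 34, 36, 38, 60)
  ph <- as_phase_assignment(setNames(rep(1, 6), sprintf("p%02d", 1:6)),
                            md_for(ages))
  out <- classify_age_outliers(ph)
  expect_equal(out$q1[1], 32.5)
  expect_equal(out$q3[1], 37.5)
  expect_identical(as.character(out$status[out$chron_age == 60]), "young_like")
  # 30 sits 2.5 below Q1, beyond the IQR/3 = 1.67 margin, so it is old_like;
  # the remaining four subjects are inside the fences
  expect_identical(as.character(out$status[out$chron_age == 30]), "old_like")
  expect_identical(unique(as.character(out$status[!out$chron_age %in% c(30, 60)])),
                   "none")

  # symmetric [20,30,40,50,60]: Q1 = 30, Q3 = 50, IQR = 20, excess 10 >= 6.67
  ages2 <- c(20, 30, 40, 50, 60)
  ph2 <- as_phase_assignment(setNames(rep(1, 5), sprintf("p%02d", 1:5)),
                             md_for(ages2))
  out2 <- classify_age_outliers(ph2)
  expect_identical(as.character(out2$status[out2$chron_age == 20]), "old_like")
  expect_identical(as.character(out2$status[out2$chron_age == 60]), "young_like")

  # all equal ages: IQR 0 and no strict exceedance, so no outliers
  ph3 <- as_phase_assignment(setNames(rep(1, 5), sprintf("p%02d", 1:5)),
                             md_for(rep(40, 5)))
  expect_identical(unique(as.character(classify_age_outliers(ph3)$status)), "none")

  # phases smaller than 4 subjects are refused
  ph4 <- as_phase_assignment(setNames(c(1, 1, 1, 2, 2, 2, 2), sprintf("p%02d", 1:7)),
                             md_for(c(30, 31, 32, 50, 51, 52, 53)))
  expect_error(classify_age_outliers(ph4), "phase 1")
})

test_that("outlier labels do not depend on subject order", {
  ages <- c(30, 32, 34, 36, 38, 60, 20, 41)
  ids <- sprintf("p%02d", 1:8)
  ph <- as_phase_assignment(setNames(rep(1, 8), ids), md_for(ages, ids))
  out1 <- classify_age_outliers(ph)
  perm <- sample(8)
  ph2 <- as_phase_assignment(setNames(rep(1, 8), ids[perm]),
                             md_for(ages[perm], ids[perm]))
  out2 <- classify_age_outliers(ph2)
  expect_equal(out2$status[match(ids, out2$subject_id)],
               out1$status[match(ids, out1$subject_id)])
})

test_that("pairwise group tests match exact references", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b"), each = 3)
  # exact rank-sum p for {1,2,3} vs {4,5,6}: 2 of the 20 arrangements
  wx <- group_difference_tests(vals, grp, method = "wilcoxon_two_sided")
  expect_equal(wx$p_value, 0.1)

  tt <- group_difference_tests(rep(c(2, 2, 2, 2), 2), rep(c("a", "b"), 4),
                               method = "t_pairwise")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # BH step-up on (0.01, 0.02, 0.03) -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  three <- group_difference_tests(c(1, 2, 10, 11, 20, 21, 30, 31),
                                  rep(c("a", "b", "c", "d"), each = 2),
                                  method = "t_pairwise", adjust = "BH")
  expect_equal(three$p_adjusted, p.adjust(three$p_value, "BH"))

  expect_warning(
    skipped <- group_difference_tests(c(1, 2, 3, 9), c("a", "a", "a", "b"),
                                      method = "t_pairwise"),
    "skipping"
  )
  expect_equal(nrow(skipped), 0)
})

test_that("logistic association flags degeneracies and finds real effects", {
  set.seed(1)
  n <- 200
  age <- runif(n, 20, 80)
  expos <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * expos + 0.01 * age))
  df <- data.frame(outcome = y, exposure = expos, chron_age = age)
  fit <- logistic_association(df, "outcome", "exposure")
  expect_lt(fit$p_value, 1e-6)
  expect_gt(fit$odds_ratio, 1)
  expect_true(fit$reliable)

  df$outcome <- 1
  expect_error(logistic_association(df, "outcome", "exposure"), "constant")

  sep <- data.frame(outcome = rep(0:1, each = 10),
                    exposure = c(rnorm(10, -5), rnorm(10, 5)),
                    chron_age = runif(20, 20, 80))
  expect_warning(res <- logistic_association(sep, "outcome", "exposure"),
                 "separation")
  expect_false(res$reliable)
})

test_that("true phases explain age better than random groupings", {
  hits <- sapply(1:100, function(s) {
    co <- small_cohort(seed = s)
    ages <- co$truth$chron_age
    p_truth <- association_test(ages, co$truth$phase)$p_value
    rand <- sample(co$truth$phase)
    p_rand <- association_test(ages, rand)$p_value
    p_truth < p_rand
  })
  expect_gte(mean(hits), 0.95)
})

test_that("chronological age groups are near-equal quantile bins", {
  g <- chronological_age_groups(1:100, 4)
  expect_equal(sort(unique(g)), 1:4)
  expect_true(max(table(g)) - min(table(g)) <= 1)
})
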