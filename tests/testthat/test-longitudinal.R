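test_that("differential selection ranks a large shift first", {
  set.seed(1)
  n <- 30
  phase <- rep(1:2, each = n / 2)
  vals <- matrix(rnorm(50 * n), 50, n)
  vals[7, phase == 2] <- vals[7, phase == 2] + 10  # ten-SD shift
  om <- toy_matrix(vals, subjects = sprintf("s%02d", 1:n))
  md <- tibble::tibble(subject_id = subject_ids(om), chron_age = 20 + phase * 10)
  ph <- as_phase_assignment(setNames(phase, subject_ids(om)), md)
  sel <- differential_top_features(om, ph, top_k = 5)
  tab <- attr(sel, "contrasts")[["1_vs_2"]]
  expect_identical(tab$feature_id[1], "f07")
  expect_true("f07" %in% sel)
})

test_that("top_k larger than the feature count returns everything", {
  toyn <- 10
  om <- toy_matrix(matrix(rnorm(5 * toyn), 5, toyn))
  phase <- rep(1:2, each = 5)
  md <- tibble::tibble(subject_id = subject_ids(om), chron_age = 20 + phase)
  ph <- as_phase_assignment(setNames(phase, subject_ids(om)), md)
  sel <- differential_top_features(om, ph, top_k = 100)
  expect_setequal(sel, feature_ids(om))
})

test_that("selection under exchangeable phases is deterministic by tie rule", {
  om <- toy_matrix(matrix(rep(1, 40), 4, 10))
  phase <- rep(1:2, each = 5)
  md <- tibble::tibble(subject_id = subject_ids(om), chron_age = 20 + phase)
  ph <- as_phase_assignment(setNames(phase, subject_ids(om)), md)
  sel <- differential_top_features(om, ph, top_k = 2)
  expect_identical(sort(sel), c("f01", "f02"))  # all tied, id order decides
})

test_that("multiclass AUC matches brute-force pair counting on a toy table", {
  # 6 subjects, 3 classes, fixed score table
  scores <- rbind(
    c(0.6, 0.3, 0.1), c(0.5, 0.2, 0.3),   # class a
    c(0.3, 0.4, 0.3), c(0.2, 0.5, 0.3),   # class b
    c(0.1, 0.2, 0.7), c(0.3, 0.3, 0.4)    # class c
  )
  colnames(scores) <- c("a", "b", "c")
  labels <- rep(c("a", "b", "c"), each = 2)
  # independent oracle: enumerate concordant/discordant pairs
  pair_auc <- function(ci, cj) {
    si <- scores[labels == ci, ci]; sj <- scores[labels == cj, ci]
    a_ij <- mean(outer(si, sj, function(x, y) (x > y) + 0.5 * (x == y)))
    si2 <- scores[labels == cj, cj]; sj2 <- scores[labels == ci, cj]
    a_ji <- mean(outer(si2, sj2, function(x, y) (x > y) + 0.5 * (x == y)))
    (a_ij + a_ji) / 2
  }
  oracle <- mean(c(pair_auc("a", "b"), pair_auc("a", "c"), pair_auc("b", "c")))
  expect_equal(multiclass_auc(scores, labels), oracle)

  # perfectly separating scores give AUC 1
  perfect <- diag(3)[rep(1:3, each = 2), ]
  colnames(perfect) <- c("a", "b", "c")
  expect_equal(multiclass_auc(perfect, labels), 1)
})

test_that("our multiclass AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(3)
  n <- 60
  labels <- sample(c("a", "b", "c"), n, replace = TRUE)
  raw <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  idx <- cbind(1:n, match(labels, colnames(raw)))
  raw[idx] <- raw[idx] + 0.4
  scores <- raw / rowSums(raw)
  ref <- suppressMessages(as.numeric(pROC::multiclass.roc(labels, as.data.frame(scores))$auc))
  expect_equal(multiclass_auc(scores, labels), ref, tolerance = 1e-10)
})

test_that("null scores give AUC near one half", {
  set.seed(5)
  n <- 200
  labels <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
  scores <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_lt(abs(multiclass_auc(scores, labels) - 0.5), 0.08)
})

test_that("classifier trains, predicts deterministically, beats chance", {
  co <- small_cohort(seed = 20)
  tr <- truth_assignment(co)
  clf <- train_phase_classifier(co$expr, co$meth, tr, top_k = 10,
                                ntree = 200, seed = 3)
  pred1 <- predict(clf, co$expr, co$meth)
  pred2 <- predict(clf, co$expr, co$meth)
  expect_identical(pred1, pred2)
  acc <- mean(pred1$phase == co$truth$phase)
  expect_gt(acc, 0.25)

  # missing features in the application matrices are an error
  sub <- toy_matrix(co$expr$values[1:5, ], features = feature_ids(co$expr)[1:5],
                    subjects = subject_ids(co$expr))
  expect_error(predict(clf, sub, co$meth), "missing")
})

test_that("cross-validated AUC is high on a default-strength cohort", {
  co <- small_cohort(seed = 21)
  tr <- truth_assignment(co)
  res <- evaluate_classifier_auc(co$expr, co$meth, tr, folds = 5, repeats = 1,
                                 top_k = 10, ntree = 200, seed = 2)
  expect_gte(res$auc, 0.9)
})

test_that("transition summaries count movers and directions", {
  ids <- sprintf("p%02d", 1:6)
  t1 <- setNames(c(1, 2, 2, 3, 3, 4), ids)
  ident <- phase_transition_summary(t1, t1)
  expect_equal(sum(ident$counts) - sum(diag(ident$counts)), 0)
  expect_equal(ident$stability, 1)

  t2 <- t1; t2["p02"] <- 3; t2["p04"] <- 4
  ts <- phase_transition_summary(t1, t2)
  expect_equal(nrow(ts$movers), 2)
  expect_true(all(ts$movers$direction == "forward"))
  expect_equal(ts$counts["2", "3"], 1)
  expect_equal(ts$counts["3", "4"], 1)

  t3 <- t1; t3["p06"] <- 1
  expect_warning(back <- phase_transition_summary(t1, t3), "backward")
  expect_equal(glance(back)$backward, 1)

  # invariance to subject order
  perm <- sample(6)
  ts2 <- phase_transition_summary(t1[perm], t2)
  expect_equal(ts2$counts, ts$counts)
  expect_error(phase_transition_summary(t1, setNames(1, "zz")), "no shared")
})

test_that("in-fold feature selection does not exceed leaky selection", {
  aucs <- sapply(1:4, function(s) {
    co <- small_cohort(seed = s)
    tr <- truth_assignment(co)
    honest <- evaluate_classifier_auc(co$expr, co$meth, tr, folds = 4, repeats = 1,
                                      top_k = 8, ntree = 150, seed = s)$auc
    leaky <- evaluate_classifier_auc(co$expr, co$meth, tr, folds = 4, repeats = 1,
                                     top_k = 8, ntree = 150, seed = s,
                                     leak_features = TRUE)$auc
    c(honest, leaky)
  })
  expect_lte(mean(aucs[1, ]), mean(aucs[2, ]) + 0.01)
})
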