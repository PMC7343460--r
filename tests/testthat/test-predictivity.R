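# Fast CV settings for unit tests; the full 5x5 design is exercised in the
# acceptance suite.
fast <- list(n_reps = 2, folds = 3, repeats = 1, ntree = 100)

balanced_toy <- function(n_per = 9, k = 4, n_genes = 6, signal = 0, seed = 1) {
  set.seed(seed)
  n <- n_per * k
  phase <- rep(seq_len(k), each = n_per)
  vals <- matrix(rnorm(n_genes * n), n_genes, n)
  if (signal > 0) vals[1, ] <- phase * signal + rnorm(n, 0, 0.05)
  om <- toy_matrix(vals, subjects = sprintf("s%02d", 1:n))
  md <- tibble::tibble(subject_id = subject_ids(om), chron_age = 20 + phase * 10 + rnorm(n))
  list(expr = om, assign = as_phase_assignment(setNames(phase, subject_ids(om)), md))
}

test_that("predictivity is deterministic given the seed", {
  toy <- balanced_toy()
  a <- do.call(pathway_predictivity,
               c(list(toy$expr, list(s = c("f01", "f02")), toy$assign, seed = 5), fast))
  b <- do.call(pathway_predictivity,
               c(list(toy$expr, list(s = c("f01", "f02")), toy$assign, seed = 5), fast))
  expect_identical(a$accuracy, b$accuracy)
  c <- do.call(pathway_predictivity,
               c(list(toy$expr, list(s = c("f01", "f02")), toy$assign, seed = 6), fast))
  expect_false(identical(a$accuracy, c$accuracy))
})

test_that("a separable gene drives accuracy to the ceiling", {
  toy <- balanced_toy(signal = 5)
  pr <- do.call(pathway_predictivity,
                c(list(toy$expr, list(s = c("f01", "f02")), toy$assign, seed = 1), fast))
  expect_gte(mean(pr$accuracy), 0.95)
})

test_that("label permutation null sits at chance", {
  toy <- balanced_toy(signal = 5)
  pr <- pathway_predictivity(toy$expr, list(s = c("f01", "f02")), toy$assign,
                             n_reps = 6, folds = 3, repeats = 1, ntree = 100,
                             seed = 2, null = "permute_labels")
  expect_lt(mean(pr$accuracy), 0.5)
})

test_that("input contracts: missing genes, small phases, singletons", {
  toy <- balanced_toy()
  expect_error(
    do.call(pathway_predictivity, c(list(toy$expr, list(s = "nope"), toy$assign), fast)),
    "no genes"
  )
  tiny <- toy
  tiny$assign$phase[1:9] <- seq_len(9) + 10  # shatter phase 1
  expect_error(
    do.call(pathway_predictivity, c(list(toy$expr, list(s = "f01"), tiny$assign), fast)),
    "fewer members"
  )
  expect_warning(
    do.call(pathway_predictivity, c(list(toy$expr, list(s = "f01"), toy$assign), fast)),
    "single gene"
  )
})

test_that("one-vs-all profiles cover every phase with chance baselines", {
  toy <- balanced_toy()
  pr <- do.call(phase_stratified_predictivity,
                c(list(toy$expr, list(s = c("f01", "f02")), toy$assign, seed = 3), fast))
  s <- tidy(pr)
  expect_setequal(s$phase, 1:4)
  expect_equal(unname(attr(pr, "chance")), rep(0.75, 4))
  expect_equal(nrow(s), 4)
})

test_that("succession clustering recovers groups and applies the tie rule", {
  profs <- rbind(a1 = c(0.3, 0.6, 0.6, 0.4), a2 = c(0.32, 0.61, 0.58, 0.41),
                 b1 = c(0.6, 0.4, 0.3, 0.3), b2 = c(0.59, 0.42, 0.28, 0.33),
                 c1 = c(0.3, 0.3, 0.4, 0.7), c2 = c(0.28, 0.33, 0.42, 0.69))
  colnames(profs) <- 1:4
  sc <- succession_clustering(profs, n_groups = 3)
  expect_equal(adjusted_rand_index(sc$groups, rep(1:3, each = 2)), 1)
  expect_equal(unname(sc$peak_phase[["a1"]]), 2)  # tie 0.6/0.6 -> earliest
  expect_equal(unname(sc$peak_phase[["b1"]]), 1)
  expect_equal(unname(sc$peak_phase[["c1"]]), 4)

  # identical profiles collapse into one effective cluster
  same <- rbind(x = c(0.1, 0.2, 0.3, 0.2), y = c(0.1, 0.2, 0.3, 0.2))
  colnames(same) <- 1:4
  sc2 <- succession_clustering(same, n_groups = 2)
  expect_equal(max(sc2$tree$height), 0)

  flat <- rbind(x = c(0.5, 0.5, 0.5, 0.5), y = c(0.1, 0.2, 0.3, 0.2))
  colnames(flat) <- 1:4
  expect_warning(succession_clustering(flat, 2), "constant profile")
})

test_that("phase contrast enumerates the exact signed-rank null", {
  mk <- function(deltas) {
    tibble::tibble(
      set = rep(sprintf("S%d", seq_along(deltas)), 2),
      mode = "one_vs_all",
      phase = rep(c(3, 4), each = length(deltas)),
      mean_accuracy = c(rep(0.8, length(deltas)), 0.8 + deltas)
    )
  }
  # six equal decreases: only the all-negative sign assignment is as extreme
  res <- predictivity_phase_contrast(mk(rep(-0.1, 6)), 3, 4)
  expect_equal(res$p_value, 1 / 64)
  expect_match(res$method, "exact")

  # all-zero deltas: no decrease, p = 1
  res0 <- predictivity_phase_contrast(mk(rep(0, 6)), 3, 4)
  expect_equal(res0$p_value, 1)

  # all increases: wrong direction
  resw <- predictivity_phase_contrast(mk(rep(0.1, 6)), 3, 4)
  expect_equal(resw$p_value, 1)

  expect_warning(predictivity_phase_contrast(mk(rep(-0.1, 3)), 3, 4), "low power")
})

test_that("exact signed-rank enumeration matches wilcox.test without ties", {
  set.seed(4)
  d <- round(rnorm(8), 3)
  ours <- agephase:::exact_signed_rank_p(d)
  ref <- wilcox.test(d, alternative = "less", exact = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-12)
})
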