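block_affinity <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  w <- matrix(between, n, n)
  w[outer(lab, lab, `==`)] <- within
  dimnames(w) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  similarity_network(w, "affinity")
}

test_that("pairwise distances reproduce simple geometry", {
  om <- toy_matrix(matrix(c(0, 0, 3, 4, 0, 0), 2, 3))
  d <- pairwise_distance(om, standardize = FALSE)
  expect_equal(d["s01", "s02"], 5)       # 3-4-5 triangle
  expect_equal(d["s01", "s03"], 0)       # identical columns
  expect_equal(diag(unclass(d)), rep(0, 3), ignore_attr = TRUE)

  om1 <- toy_matrix(matrix(c(0, 3, 1), 1, 3))
  d1 <- pairwise_distance(om1, standardize = FALSE)
  expect_equal(d1["s01", "s02"], 3)      # single feature: |0 - 3|

  zv <- toy_matrix(rbind(c(1, 1, 1), c(1, 2, 3)))
  expect_warning(pairwise_distance(zv), "zero-variance")
})

test_that("affinity kernel matches its formula evaluated by hand", {
  # three points on a line at 0, 1, 3: d12 = 1, d23 = 2, d13 = 3
  om <- toy_matrix(matrix(c(0, 1, 3), 1, 3))
  d <- pairwise_distance(om, standardize = FALSE)
  w <- affinity_matrix(d, k = 1, alpha = 0.5)
  dm <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3)
  knn <- c(1, 1, 2)                      # nearest-other distance per point
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    eps <- (knn[i] + knn[j] + dm[i, j]) / 3
    expect_equal(unclass(w)[i, j], exp(-dm[i, j]^2 / (0.5 * eps)),
                 tolerance = 1e-12)
  }
  # d = 0 with positive local scale gives weight 1
  om0 <- toy_matrix(matrix(c(0, 0, 5), 1, 3))
  w0 <- affinity_matrix(pairwise_distance(om0, standardize = FALSE), k = 1)
  expect_equal(unclass(w0)[1, 2], 1)
  # all-zero distances stay defined through the floor
  omz <- toy_matrix(matrix(0, 1, 4))
  wz <- affinity_matrix(pairwise_distance(omz, standardize = FALSE), k = 2)
  expect_false(anyNA(unclass(wz)))
})

test_that("affinity decreases with distance at fixed local scale", {
  om <- toy_matrix(matrix(c(0, 1, 2, 10), 1, 4))
  w <- unclass(affinity_matrix(pairwise_distance(om, standardize = FALSE), k = 3))
  expect_gt(w[1, 2], w[1, 3])
  expect_gt(w[1, 3], w[1, 4])
})

test_that("zero-iteration fusion returns the average initial status matrix", {
  a <- block_affinity(c(4, 4), within = 1, between = 0.2)
  b <- block_affinity(c(4, 4), within = 0.8, between = 0.1)
  fused <- snf_fuse(list(a, b), k = 3, t = 0)
  # independent status-matrix oracle
  status_oracle <- function(w) {
    w <- unclass(w); diag(w) <- 0
    p <- w / (2 * rowSums(w)); diag(p) <- 0.5
    p
  }
  expected <- (status_oracle(a) + status_oracle(b)) / 2
  expected <- (expected + t(expected)) / 2
  expect_equal(unclass(fused), expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion normalization invariants hold", {
  co <- small_cohort(seed = 6)
  ae <- affinity_matrix(pairwise_distance(suppressWarnings(preprocess_omics(co$expr))))
  am <- affinity_matrix(pairwise_distance(suppressWarnings(preprocess_omics(co$meth))))
  fused <- snf_fuse(list(ae, am), k = 10, t = 5)
  for (p in attr(fused, "status")) {
    expect_lt(max(abs(rowSums(p) - 1)), 1e-8)
  }
  expect_lt(max(abs(unclass(fused) - t(unclass(fused)))), 1e-10)
  expect_gte(min(unclass(fused)), 0)
})

test_that("fusion preserves block structure and ignores view order", {
  a <- block_affinity(c(4, 4), within = 1, between = 0.05)
  fused <- snf_fuse(list(a, a), k = 3, t = 10)
  m <- unclass(fused); diag(m) <- NA
  within <- mean(c(m[1:4, 1:4], m[5:8, 5:8]), na.rm = TRUE)
  between <- mean(m[1:4, 5:8])
  expect_gt(within, between)

  b <- block_affinity(c(4, 4), within = 0.9, between = 0.1)
  expect_equal(unclass(snf_fuse(list(a, b), k = 3, t = 5)),
               unclass(snf_fuse(list(b, a), k = 3, t = 5)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("spectral clustering recovers exact blocks and is equivariant", {
  w <- block_affinity(c(5, 6), within = 1, between = 0)
  lab <- suppressWarnings(spectral_cluster(w, 2, seed = 1))
  expect_equal(adjusted_rand_index(lab, rep(1:2, c(5, 6))), 1)

  perm <- sample(11)
  wp <- similarity_network(unclass(w)[perm, perm], "affinity")
  labp <- suppressWarnings(spectral_cluster(wp, 2, seed = 1))
  expect_equal(adjusted_rand_index(labp, lab[rownames(wp)]), 1)

  expect_identical(suppressWarnings(spectral_cluster(w, 2, seed = 7)),
                   suppressWarnings(spectral_cluster(w, 2, seed = 7)))
})

test_that("eigen-gap recovers the block count for 2 to 5 blocks", {
  for (m in 2:5) {
    w <- block_affinity(rep(6, m), within = 1, between = 0.02)
    sel <- select_cluster_number(w, k_range = 2:8)
    expect_identical(attr(sel, "chosen_k"), as.integer(m))
    expect_identical(sel$k, 2:8)
  }
})

test_that("cluster selection respects the candidate range", {
  w <- block_affinity(c(6, 6, 6), within = 1, between = 0.05)
  sel <- select_cluster_number(w, k_range = 4:6)
  expect_true(attr(sel, "chosen_k") %in% 4:6)
  expect_error(select_cluster_number(w, k_range = 1:3), "k_range")
})
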