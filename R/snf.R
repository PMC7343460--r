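#' Similarity networks over subjects
#'
#' A `similarity_network` is a symmetric subjects x subjects matrix with a
#' `role`: `"distance"` (zero diagonal), `"affinity"` (nonnegative kernel
#' weights), or `"fused"` (output of cross-diffusion).
#'
#' @param m symmetric numeric matrix with subject ids as dimnames.
#' @param role `"distance"`, `"affinity"` or `"fused"`.
#' @return A `similarity_network` (matrix subclass).
#' @export
similarity_network <- function(m, role = c("distance", "affinity", "fused")) {
  role <- match.arg(role)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("subject ids required as dimnames.")
  if (max(abs(m - t(m))) > 1e-10) stop("network matrix must be symmetric.")
  if (role != "distance" && min(m) < 0) stop("affinity/fused networks must be nonnegative.")
  structure(m, role = role, class = c("similarity_network", class(m)))
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network:%s> %d subjects\n", attr(x, "role"), nrow(x)))
  invisible(x)
}

#' Euclidean subject-subject distances
#'
#' Distances between subject columns, optionally after per-feature
#' standardization (mean 0, sd 1 across subjects). Zero-variance features are
#' dropped with a warning when standardizing.
#'
#' @param x an `omics_matrix` with at least 3 subjects.
#' @param standardize standardize features first (default `TRUE`).
#' @return A `similarity_network` with role `"distance"`.
#' @export
pairwise_distance <- function(x, standardize = TRUE) {
  stopifnot(inherits(x, "omics_matrix"))
  if (ncol(x$values) < 3) abort("need at least 3 subjects.")
  v <- x$values
  if (standardize) {
    sds <- apply(v, 1, sd)
    if (any(sds == 0)) {
      warn(sprintf("dropping %d zero-variance feature(s) before standardization.",
                   sum(sds == 0)))
      v <- v[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    v <- (v - rowMeans(v)) / sds
  }
  d <- as.matrix(dist(t(v)))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  similarity_network(d, "distance")
}

#' Scaled-exponential affinity kernel
#'
#' Converts distances to affinities with a locally adaptive Gaussian kernel:
#' `W(i,j) = exp(-d(i,j)^2 / (alpha * eps(i,j)))` where
#' `eps(i,j) = (mean kNN distance of i + mean kNN distance of j + d(i,j)) / 3`,
#' floored at a small positive constant so all-zero distances stay defined.
#'
#' @param d a `similarity_network` with role `"distance"`.
#' @param k number of nearest neighbours for the local scale (default 10).
#' @param alpha kernel bandwidth hyperparameter (default 0.5).
#' @param eps_floor lower bound for the local scale (default 1e-12).
#' @return A `similarity_network` with role `"affinity"`.
#' @export
affinity_matrix <- function(d, k = 10, alpha = 0.5, eps_floor = 1e-12) {
  stopifnot(inherits(d, "similarity_network"), attr(d, "role") == "distance")
  n <- nrow(d)
  if (k < 1 || k >= n) abort("`k` must satisfy 1 <= k < n_subjects.")
  dm <- unclass(d)
  # mean distance to the k nearest other subjects
  knn_mean <- vapply(seq_len(n), function(i) {
    mean(sort(dm[i, -i])[seq_len(k)])
  }, numeric(1))
  eps <- (outer(knn_mean, knn_mean, `+`) + dm) / 3
  eps[eps < eps_floor] <- eps_floor
  w <- exp(-dm^2 / (alpha * eps))
  w <- (w + t(w)) / 2
  similarity_network(w, "affinity")
}

# Full-kernel status matrix: off-diagonal rows normalized to sum 1/2,
# diagonal 1/2, so every row sums to exactly 1.
status_matrix <- function(w) {
  n <- nrow(w)
  p <- unclass(w)
  diag(p) <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / (2 * rs)
  diag(p) <- 0.5
  p
}

# kNN-masked row-stochastic local kernel: keep each row's k strongest
# off-diagonal affinities, renormalize rows to 1.
local_kernel <- function(w, k) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  wm <- unclass(w)
  for (i in seq_len(n)) {
    ord <- order(wm[i, -i], decreasing = TRUE)
    nb <- seq_len(n)[-i][ord[seq_len(k)]]
    s[i, nb] <- wm[i, nb]
  }
  rs <- rowSums(s)
  rs[rs == 0] <- 1
  s / rs
}

#' Similarity network fusion by cross-diffusion
#'
#' Fuses per-omics affinity networks into one network: each view's full-kernel
#' status matrix is iteratively diffused through its k-nearest-neighbour local
#' kernel against the average status of the other views,
#' `P_v <- S_v %*% mean(P_others) %*% t(S_v)`, for `t` iterations. After each
#' update the matrix is symmetrized with a small ridge on the diagonal
#' (`eta = 1/n`) and renormalized to the status form (rows sum to 1). The
#' fused network is the symmetrized view average. With `t = 0` this returns
#' the average of the initial status matrices.
#'
#' @param affinities list of `similarity_network`s (role `"affinity"`) over
#'   identical subject sets.
#' @param k neighbours for the local kernel (default 10).
#' @param t number of diffusion iterations (default 20).
#' @return A `similarity_network` with role `"fused"`. The per-view status
#'   matrices after the final iteration are attached as attribute `"status"`.
#' @export
snf_fuse <- function(affinities, k = 10, t = 20) {
  if (inherits(affinities, "similarity_network")) affinities <- list(affinities)
  stopifnot(length(affinities) >= 1)
  ids <- lapply(affinities, rownames)
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    abort("all views must share the same subjects in the same order.")
  }
  n <- nrow(affinities[[1]])
  eta <- 1 / n
  p <- lapply(affinities, status_matrix)
  s <- lapply(affinities, local_kernel, k = k)
  nv <- length(p)
  if (t > 0) {
    for (iter in seq_len(t)) {
      p_new <- vector("list", nv)
      for (v in seq_len(nv)) {
        others <- if (nv == 1) p[[v]] else Reduce(`+`, p[-v]) / (nv - 1)
        q <- s[[v]] %*% others %*% t(s[[v]])
        q <- (q + t(q)) / 2 + diag(eta, n)
        p_new[[v]] <- status_matrix(q)
      }
      p <- p_new
    }
  }
  fused <- Reduce(`+`, p) / nv
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(unclass(affinities[[1]]))
  out <- similarity_network(fused, "fused")
  attr(out, "status") <- p
  out
}

# Symmetric normalized Laplacian eigen-decomposition, eigenvalues ascending.
laplacian_eigen <- function(w) {
  wm <- unclass(w)
  diag(wm) <- 0
  deg <- rowSums(wm)
  deg[deg == 0] <- .Machine$double.eps
  dinv <- 1 / sqrt(deg)
  lsym <- diag(nrow(wm)) - (dinv * wm) %*% diag(dinv)
  lsym <- (lsym + t(lsym)) / 2
  e <- eigen(lsym, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors)))])
}

#' Spectral clustering on a fused network
#'
#' Normalized-cut spectral clustering: take the eigenvectors of the symmetric
#' normalized Laplacian for the `K` smallest eigenvalues, row-normalize, and
#' run k-means with a fixed seed and many restarts, so labels are
#' deterministic given the seed.
#'
#' @param fused a `similarity_network` (role `"affinity"` or `"fused"`).
#' @param K number of clusters, `2 <= K < n`.
#' @param seed RNG seed for k-means.
#' @param nstart k-means restarts (default 50).
#' @return Integer cluster labels `1..K` named by subject id.
#' @export
spectral_cluster <- function(fused, K, seed = 1, nstart = 50) {
  stopifnot(inherits(fused, "similarity_network"))
  n <- nrow(fused)
  if (K < 2 || K >= n) abort("`K` must satisfy 2 <= K < n.")
  e <- laplacian_eigen(fused)
  if (sum(e$values < 1e-10) > K) {
    warn("graph has more connected components than K; proceeding anyway.")
  }
  u <- e$vectors[, seq_len(K), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  km <- with_local_seed(seed, kmeans(u, centers = K, nstart = nstart, iter.max = 100))
  setNames(as.integer(km$cluster), rownames(fused))
}

# Yu & Shi (2003) style discretisation of spectral embeddings; returns the
# rotation (alignment) cost 2*(n_rows - sum of singular values).
rotation_cost <- function(u) {
  n <- nrow(u)
  k <- ncol(u)
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  # deterministic farthest-point initialization of the rotation
  r <- matrix(0, k, k)
  r[, 1] <- u[which.max(rowSums(u^2)), ]
  c_acc <- rep(0, n)
  if (k > 1) {
    for (j in 2:k) {
      c_acc <- c_acc + abs(u %*% r[, j - 1, drop = FALSE])
      r[, j] <- u[which.min(c_acc), ]
    }
  }
  last_obj <- 0
  for (iter in 1:30) {
    x <- u %*% r
    lab <- max.col(x, ties.method = "first")
    xd <- matrix(0, n, k)
    xd[cbind(seq_len(n), lab)] <- 1
    sv <- svd(t(xd) %*% u)
    obj <- 2 * (n - sum(sv$d))
    r <- sv$v %*% t(sv$u)
    if (abs(obj - last_obj) < 1e-10) break
    last_obj <- obj
  }
  obj
}

#' Select the number of clusters on a fused network
#'
#' Ranks candidate cluster numbers by the eigen-gap statistic (difference of
#' consecutive eigenvalues of the normalized Laplacian at index K) and reports
#' a rotation-cost criterion (alignment cost of the first K Laplacian
#' eigenvectors to a discrete cluster indicator). The chosen K maximizes the
#' eigen-gap; exact ties are broken by smaller rotation cost.
#'
#' @param fused a `similarity_network`.
#' @param k_range candidate cluster numbers (default `2:8`).
#' @return A `cluster_selection` tibble with columns `k`, `eigengap`,
#'   `rotation_cost`, and the chosen K as attribute `chosen_k` (also via
#'   [glance()]).
#' @export
select_cluster_number <- function(fused, k_range = 2:8) {
  stopifnot(inherits(fused, "similarity_network"))
  n <- nrow(fused)
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    abort("`k_range` must lie within [2, n - 1].")
  }
  e <- laplacian_eigen(fused)
  # normalized eigen-gap: the raw gap weighted by (1 - lambda_K)/(1 - lambda_{K+1}),
  # which damps spurious gaps high in the spectrum
  gap <- vapply(k_range, function(k) {
    (e$values[k + 1] - e$values[k]) *
      (1 - e$values[k]) / max(1 - e$values[k + 1], .Machine$double.eps)
  }, numeric(1))
  rot <- vapply(k_range, function(k) {
    rotation_cost(e$vectors[, seq_len(k), drop = FALSE])
  }, numeric(1))
  ord <- order(-gap, rot, k_range)
  out <- tibble::tibble(k = as.integer(k_range), eigengap = gap,
                        rotation_cost = rot)
  attr(out, "chosen_k") <- as.integer(k_range[ord[1]])
  class(out) <- c("cluster_selection", class(out))
  out
}

#' @export
glance.cluster_selection <- function(x, ...) {
  tibble::tibble(chosen_k = attr(x, "chosen_k"),
                 max_eigengap = max(x$eigengap))
}

#' @export
autoplot.cluster_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$eigengap)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"), linetype = 2) +
    ggplot2::labs(x = "number of clusters K", y = "eigen-gap",
                  title = "Eigen-gap cluster-number selection")
}
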