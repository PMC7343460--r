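# Stratified fold assignment: within each class, samples are shuffled and
# dealt to folds round-robin, so class proportions are as even as possible.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

# One repeated stratified CV run of a random forest restricted to the given
# feature matrix; returns the accuracy (fraction of correct held-out
# predictions, pooled within a repeat, averaged over repeats).
rf_cv_accuracy <- function(x, y, folds = 5, repeats = 5, ntree = 1000) {
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    correct <- logical(length(y))
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- randomForest::randomForest(
        x = x[!test, , drop = FALSE], y = droplevels(y[!test]),
        ntree = ntree, mtry = ncol(x)
      )
      pred <- predict(fit, x[test, , drop = FALSE])
      correct[test] <- as.character(pred) == as.character(y[test])
    }
    acc[r] <- mean(correct)
  }
  mean(acc)
}

prepare_predictivity_input <- function(expr, sets, labels, folds) {
  stopifnot(inherits(expr, "omics_matrix"))
  sets <- as_gene_list(sets)
  y <- if (inherits(labels, "phase_assignment")) phase_vector(labels) else labels
  if (!is.null(names(y))) {
    if (!all(subject_ids(expr) %in% names(y))) {
      abort("every subject in `expr` needs a phase label.")
    }
    y <- y[subject_ids(expr)]
  } else if (length(y) != ncol(expr$values)) {
    abort("`labels` must cover the subjects of `expr`.")
  }
  y <- factor(y)
  if (any(table(y) < folds)) {
    abort(sprintf(
      "phase '%s' has fewer members than the %d folds; reduce `folds`.",
      names(which(table(y) < folds))[1], folds
    ))
  }
  matched <- lapply(sets, function(g) intersect(g, feature_ids(expr)))
  empty <- lengths(matched) == 0
  if (any(empty)) {
    abort(sprintf("no genes of set '%s' are present in the matrix.",
                  names(sets)[empty][1]))
  }
  if (any(lengths(matched) == 1)) {
    warn(sprintf("%d set(s) match a single gene; predictivity is computed but fragile.",
                 sum(lengths(matched) == 1)))
  }
  list(genes = matched, y = y)
}

new_predictivity_result <- function(df, chance, n_reps, folds, repeats, ntree, seed) {
  structure(df, class = c("predictivity_result", class(df)),
            chance = chance, n_reps = n_reps, folds = folds,
            repeats = repeats, ntree = ntree, seed = seed)
}

#' Gene-set predictivity of the aging phases
#'
#' The core scoring procedure: for each gene set, a random forest is trained
#' on that set's genes only (mtry = set size, i.e. bagged trees; ntree
#' configurable, default 1000) to predict the phase of every subject, and its
#' predictivity is the accuracy under stratified `folds x repeats` repeated
#' cross-validation. Each of the `n_reps` replicates repeats the whole CV with
#' a fresh fold seed; with `null = "permute_labels"` each replicate instead
#' permutes the phase labels first, giving an explicit chance baseline.
#'
#' @param expr an `omics_matrix` (expression).
#' @param sets a `gene_sets` collection, named list, or character vector of
#'   gene ids (treated as one set).
#' @param labels a `phase_assignment` or named phase vector; every phase needs
#'   at least `folds` members.
#' @param n_reps replicates (default 100).
#' @param folds,repeats CV design (default 5 x 5).
#' @param ntree trees per forest (default 1000).
#' @param seed master seed; replicate seeds are derived from it.
#' @param null `"none"` or `"permute_labels"`.
#' @return A `predictivity_result` tibble: `set`, `mode`, `phase` (`NA` for
#'   the overall multiclass mode), `replicate`, `accuracy`; summaries via
#'   [tidy()]. The chance level (majority-class proportion) is stored in the
#'   `"chance"` attribute.
#' @export
pathway_predictivity <- function(expr, sets, labels, n_reps = 100, folds = 5,
                                 repeats = 5, ntree = 1000, seed = 1,
                                 null = c("none", "permute_labels")) {
  null <- match.arg(null)
  if (is.character(sets) && is.null(names(sets)) && !is.list(sets)) {
    sets <- list(set = sets)
  }
  inp <- prepare_predictivity_input(expr, sets, labels, folds)
  xall <- t(expr$values)
  seeds <- matrix(derive_seeds(seed, n_reps * length(inp$genes)),
                  nrow = n_reps)
  rows <- purrr::imap(inp$genes, function(genes, set_name) {
    j <- match(set_name, names(inp$genes))
    x <- xall[, genes, drop = FALSE]
    acc <- vapply(seq_len(n_reps), function(r) {
      with_local_seed(seeds[r, j], {
        y <- inp$y
        if (null == "permute_labels") y <- y[sample.int(length(y))]
        rf_cv_accuracy(x, y, folds, repeats, ntree)
      })
    }, numeric(1))
    tibble::tibble(set = set_name, mode = "overall_multiclass",
                   phase = NA_integer_, replicate = seq_len(n_reps),
                   accuracy = acc)
  })
  chance <- max(table(inp$y)) / length(inp$y)
  new_predictivity_result(dplyr::bind_rows(rows), chance = chance,
                          n_reps = n_reps, folds = folds, repeats = repeats,
                          ntree = ntree, seed = seed)
}

#' Per-phase (one-against-all) gene-set predictivity
#'
#' For every phase, the multiclass problem is recast as that phase versus all
#' others and scored exactly like [pathway_predictivity()]. The per-phase
#' accuracies form each set's predictivity profile along the phases; the
#' majority-class proportion per phase is reported as the chance baseline.
#'
#' @inheritParams pathway_predictivity
#' @return A `predictivity_result` tibble with `mode = "one_vs_all"` and one
#'   profile entry per phase; `"chance"` attribute is named by phase.
#' @export
phase_stratified_predictivity <- function(expr, sets, labels, n_reps = 100,
                                          folds = 5, repeats = 5, ntree = 1000,
                                          seed = 1) {
  if (is.character(sets) && is.null(names(sets)) && !is.list(sets)) {
    sets <- list(set = sets)
  }
  inp <- prepare_predictivity_input(expr, sets, labels, folds)
  xall <- t(expr$values)
  phases <- sort(unique(as.character(inp$y)))
  seeds <- array(derive_seeds(seed, n_reps * length(inp$genes) * length(phases)),
                 dim = c(n_reps, length(inp$genes), length(phases)))
  rows <- list()
  for (pi in seq_along(phases)) {
    yb <- factor(ifelse(as.character(inp$y) == phases[pi], "target", "rest"),
                 levels = c("target", "rest"))
    for (j in seq_along(inp$genes)) {
      x <- xall[, inp$genes[[j]], drop = FALSE]
      acc <- vapply(seq_len(n_reps), function(r) {
        with_local_seed(seeds[r, j, pi],
                        rf_cv_accuracy(x, yb, folds, repeats, ntree))
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble::tibble(
        set = names(inp$genes)[j], mode = "one_vs_all",
        phase = as.integer(phases[pi]), replicate = seq_len(n_reps),
        accuracy = acc
      )
    }
  }
  chance <- vapply(phases, function(p) {
    max(mean(inp$y == p), 1 - mean(inp$y == p))
  }, numeric(1))
  new_predictivity_result(dplyr::bind_rows(rows), chance = chance,
                          n_reps = n_reps, folds = folds, repeats = repeats,
                          ntree = ntree, seed = seed)
}

#' @export
tidy.predictivity_result <- function(x, ...) {
  chance <- attr(x, "chance")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$set, .data$mode, .data$phase),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = sd(.data$accuracy),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  out$chance <- if (length(chance) > 1) {
    unname(chance[as.character(out$phase)])
  } else {
    chance
  }
  out
}

#' @export
autoplot.predictivity_result <- function(object, ...) {
  s <- tidy(object)
  if (all(is.na(s$phase))) {
    ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$set, .data$mean_accuracy),
                                    y = .data$mean_accuracy)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = s$chance[1], linetype = 2) +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "predictivity (CV accuracy)",
                    title = "Gene-set predictivity (dashed = chance)")
  } else {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$phase, y = .data$mean_accuracy,
                                    colour = .data$set)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "aging phase", y = "one-vs-all predictivity",
                    title = "Per-phase predictivity profiles")
  }
}

#' Hierarchical grouping of gene sets by their predictivity profiles
#'
#' Profiles (per-phase mean predictivity) are z-scaled per set, clustered
#' hierarchically (average linkage, Euclidean distance) and cut into
#' `n_groups` groups — the succession analysis that recovers
#' primary/secondary/integrative hallmark constellations. Each set's peak
#' phase is the argmax of its profile (earliest phase on ties); when a
#' per-phase chance level is available (a one-vs-all `predictivity_result`,
#' or supplied via `chance`), the argmax is taken on accuracy *in excess of
#' chance* — with unbalanced phases, raw one-vs-all accuracy is inflated for
#' phases with a large majority-class baseline, which would otherwise pull
#' every weak profile's peak toward the smallest phase.
#'
#' @param profiles a one-vs-all `predictivity_result`, a tidied profile tibble
#'   (`set`, `phase`, `mean_accuracy`), or a sets x phases matrix.
#' @param n_groups number of groups to cut the tree into (default 3).
#' @param chance optional per-phase chance levels (named by phase) subtracted
#'   before locating peaks; taken from the result's attributes when present.
#' @return A `succession_summary`: list with `profiles` (matrix), `tree`
#'   (hclust), `groups` and `peak_phase` (named integer vectors); tibble via
#'   [tidy()].
#' @export
succession_clustering <- function(profiles, n_groups = 3, chance = NULL) {
  if (inherits(profiles, "predictivity_result")) {
    chance <- chance %||% attr(profiles, "chance")
    profiles <- tidy(profiles)
    profiles <- profiles[profiles$mode == "one_vs_all", ]
  }
  if (is.data.frame(profiles)) {
    wide <- tidyr::pivot_wider(profiles[, c("set", "phase", "mean_accuracy")],
                               names_from = "phase", values_from = "mean_accuracy")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$set
  } else {
    m <- as.matrix(profiles)
  }
  if (nrow(m) < 2) abort("need at least 2 sets to cluster.")
  z <- m
  for (i in seq_len(nrow(z))) {
    s <- sd(z[i, ])
    if (s == 0) {
      warn(sprintf("set '%s' has a constant profile; z-scaling skipped.",
                   rownames(z)[i]))
      z[i, ] <- 0
    } else {
      z[i, ] <- (z[i, ] - mean(z[i, ])) / s
    }
  }
  tree <- hclust(dist(z), method = "average")
  groups <- cutree(tree, k = min(n_groups, nrow(m)))
  peak_base <- m
  if (!is.null(chance) && length(chance) > 1) {
    ch <- if (!is.null(names(chance))) chance[colnames(m)] else chance
    peak_base <- sweep(m, 2, as.numeric(ch))
  }
  peaks <- apply(peak_base, 1, which.max)  # earliest phase on ties
  structure(
    list(profiles = m, tree = tree, groups = groups,
         peak_phase = setNames(as.integer(peaks), rownames(m))),
    class = "succession_summary"
  )
}

#' @export
tidy.succession_summary <- function(x, ...) {
  tibble::tibble(
    set = rownames(x$profiles),
    group = unname(x$groups[rownames(x$profiles)]),
    peak_phase = unname(x$peak_phase[rownames(x$profiles)])
  )
}

#' @export
print.succession_summary <- function(x, ...) {
  cat(sprintf("<succession_summary> %d sets in %d groups\n",
              nrow(x$profiles), length(unique(x$groups))))
  print(tidy(x))
  invisible(x)
}

# Exact one-sided signed-rank p-value by sign-flip enumeration (midranks for
# tied |deltas|, zeros dropped): Pr(T <= T_obs) where T is the sum of ranks of
# positive deltas under independent random signs.
exact_signed_rank_p <- function(deltas) {
  d <- deltas[deltas != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  t_all <- as.vector(signs %*% r)
  mean(t_all <= t_obs + 1e-12)
}

#' Test for a predictivity drop between two phases
#'
#' Paired per-set comparison of one-vs-all mean predictivity between two
#' phases, with a one-sided signed-rank test for a decrease from `phase_a` to
#' `phase_b`. With 14 or fewer sets the p-value is computed exactly by
#' enumerating all sign assignments (midranks handle ties); above that, the
#' normal-approximation Wilcoxon signed-rank test is used. Fewer than 5 sets
#' is flagged as low power.
#'
#' @param result a one-vs-all `predictivity_result` covering both phases.
#' @param phase_a,phase_b the phases compared (direction: `phase_b` lower).
#' @return A `phase_contrast` list: `deltas` (per-set tibble), `p_value`,
#'   `method`, `low_power`; one-row summary via [glance()].
#' @export
predictivity_phase_contrast <- function(result, phase_a = 3, phase_b = 4) {
  s <- if (inherits(result, "predictivity_result")) tidy(result) else result
  s <- s[s$mode == "one_vs_all" & s$phase %in% c(phase_a, phase_b), ]
  wide <- tidyr::pivot_wider(s[, c("set", "phase", "mean_accuracy")],
                             names_from = "phase", values_from = "mean_accuracy")
  if (anyNA(wide)) abort("both phases must be scored for every set.")
  a <- wide[[as.character(phase_a)]]
  b <- wide[[as.character(phase_b)]]
  deltas <- b - a
  low_power <- nrow(wide) < 5
  if (low_power) warn("fewer than 5 sets: the contrast has low power.")
  if (length(deltas) <= 14) {
    p <- exact_signed_rank_p(deltas)
    method <- "exact sign-flip signed-rank"
  } else {
    p <- suppressWarnings(
      wilcox.test(b, a, paired = TRUE, alternative = "less", exact = FALSE)$p.value
    )
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  structure(
    list(
      deltas = tibble::tibble(set = wide$set, mean_a = a, mean_b = b,
                              delta = deltas),
      phase_a = phase_a, phase_b = phase_b,
      p_value = p, method = method, low_power = low_power
    ),
    class = "phase_contrast"
  )
}

#' @export
glance.phase_contrast <- function(x, ...) {
  tibble::tibble(
    phase_a = x$phase_a, phase_b = x$phase_b,
    n_sets = nrow(x$deltas), median_delta = median(x$deltas$delta),
    p_value = x$p_value, method = x$method, low_power = x$low_power
  )
}

#' @export
print.phase_contrast <- function(x, ...) {
  cat(sprintf(
    "<phase_contrast> phase %s -> %s over %d sets: median delta %.3f, one-sided p = %.3g (%s)\n",
    x$phase_a, x$phase_b, nrow(x$deltas), median(x$deltas$delta), x$p_value,
    x$method
  ))
  invisible(x)
}
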