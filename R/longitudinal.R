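# Vectorized per-feature Welch t-test between two groups of columns.
# Returns a tibble of t, p ordered as the input features.
welch_t_rows <- function(m, idx1, idx2) {
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 == 0, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)),
              (m1 - m2) / sqrt(se2))
  df <- ifelse(se2 == 0, n1 + n2 - 2,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df))
  p[t == 0] <- 1
  list(t = t, p = p)
}

#' Select top differential features between phases
#'
#' For every pairwise phase contrast, a per-feature Welch t-test on the
#' working scale (log2-TPM or M-values); the `top_k` features with smallest
#' p (ties broken by larger |t|, then feature id) are taken per contrast, and
#' the union over contrasts is returned. Contrasts where a phase has fewer
#' than 2 subjects are skipped with a warning.
#'
#' @param x an `omics_matrix`.
#' @param assignment a `phase_assignment` covering the subjects.
#' @param top_k features per contrast (default 50).
#' @return Character vector of selected feature ids; the per-contrast ranking
#'   tables are attached as attribute `"contrasts"`.
#' @export
differential_top_features <- function(x, assignment, top_k = 50) {
  stopifnot(inherits(x, "omics_matrix"))
  pv <- phase_vector(assignment)[subject_ids(x)]
  if (anyNA(pv)) abort("every subject in the matrix needs a phase.")
  phases <- sort(unique(pv))
  if (length(phases) < 2) abort("need at least two phases.")
  fid <- feature_ids(x)
  selected <- character(0)
  tables <- list()
  for (pair in utils::combn(phases, 2, simplify = FALSE)) {
    i1 <- which(pv == pair[1]); i2 <- which(pv == pair[2])
    if (length(i1) < 2 || length(i2) < 2) {
      warn(sprintf("contrast %s vs %s skipped: a phase has < 2 subjects.",
                   pair[1], pair[2]))
      next
    }
    res <- welch_t_rows(x$values, i1, i2)
    ord <- order(res$p, -abs(res$t), fid)
    take <- fid[ord[seq_len(min(top_k, length(fid)))]]
    selected <- union(selected, take)
    tables[[paste(pair, collapse = "_vs_")]] <- tibble::tibble(
      feature_id = fid[ord], t = res$t[ord], p_value = res$p[ord]
    )
  }
  if (length(tables) == 0) abort("no testable phase contrast.")
  structure(selected, contrasts = tables)
}

#' Train the aging-phase classifier on combined omics features
#'
#' Selects the top differential features per pairwise phase contrast from each
#' omics layer, concatenates them, and trains a random forest (ntree
#' configurable, default 1000; mtry = number of selected features) to predict
#' the phase. Fully reproducible from the seed.
#'
#' @param expr,meth `omics_matrix` objects over the same subjects.
#' @param assignment a `phase_assignment`.
#' @param top_k differential features per contrast and omics layer.
#' @param ntree trees (default 1000).
#' @param seed RNG seed.
#' @return A `phase_classifier` with a [predict()] method taking new `expr`
#'   and `meth` matrices.
#' @export
train_phase_classifier <- function(expr, meth, assignment, top_k = 50,
                                   ntree = 1000, seed = 1) {
  stopifnot(identical(subject_ids(expr), subject_ids(meth)))
  y <- factor(phase_vector(assignment)[subject_ids(expr)])
  if (anyNA(y)) abort("every subject needs a phase.")
  feats <- list(expr = differential_top_features(expr, assignment, top_k),
                meth = differential_top_features(meth, assignment, top_k))
  x <- cbind(t(expr$values[feats$expr, , drop = FALSE]),
             t(meth$values[feats$meth, , drop = FALSE]))
  fit <- with_local_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = ncol(x)
  ))
  structure(
    list(forest = fit, features = lapply(feats, as.character),
         classes = levels(y), top_k = top_k, ntree = ntree, seed = seed),
    class = "phase_classifier"
  )
}

#' @export
print.phase_classifier <- function(x, ...) {
  cat(sprintf(
    "<phase_classifier> %d expression + %d methylation features, classes: %s\n",
    length(x$features$expr), length(x$features$meth),
    paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' @export
#' @param object a `phase_classifier`.
#' @param expr,meth new omics matrices containing the trained features.
#' @param ... unused.
#' @rdname train_phase_classifier
predict.phase_classifier <- function(object, expr, meth, ...) {
  miss <- c(setdiff(object$features$expr, feature_ids(expr)),
            setdiff(object$features$meth, feature_ids(meth)))
  if (length(miss) > 0) {
    abort(sprintf("%d trained feature(s) missing from the new matrices.",
                  length(miss)))
  }
  stopifnot(identical(subject_ids(expr), subject_ids(meth)))
  x <- cbind(t(expr$values[object$features$expr, , drop = FALSE]),
             t(meth$values[object$features$meth, , drop = FALSE]))
  pred <- predict(object$forest, x)
  tibble::tibble(subject_id = subject_ids(expr),
                 phase = as.integer(as.character(pred)))
}

#' Multiclass AUC by the mean-of-pairwise (Hand-Till) construction
#'
#' For every unordered class pair (i, j), the two-class AUC of the class-i
#' membership score on samples of classes i and j is computed by ranks (and
#' likewise with the class-j score); the pair's value is their average, and
#' the multiclass AUC is the mean over pairs.
#'
#' @param scores numeric matrix, samples x classes, of class-membership scores
#'   (columns named by class).
#' @param labels true class labels.
#' @return A single number in \[0, 1\].
#' @export
multiclass_auc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (!all(classes %in% colnames(scores))) {
    abort("`scores` must have one named column per class.")
  }
  a_given <- function(i, j) {
    si <- scores[labels == i, i]
    sj <- scores[labels == j, i]
    r <- rank(c(si, sj))
    (sum(r[seq_along(si)]) - length(si) * (length(si) + 1) / 2) /
      (length(si) * length(sj))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  vals <- vapply(pairs, function(pr) {
    (a_given(pr[1], pr[2]) + a_given(pr[2], pr[1])) / 2
  }, numeric(1))
  mean(vals)
}

#' Cross-validated multiclass AUC of the phase classifier
#'
#' Stratified repeated cross-validation in which the differential feature
#' selection is re-run inside every training fold (guarding against selection
#' leakage); held-out class-membership votes feed the Hand-Till multiclass
#' AUC, averaged over repeats.
#'
#' @inheritParams train_phase_classifier
#' @param folds,repeats CV design (default 5 x 5).
#' @param leak_features if `TRUE`, select features once on the full data
#'   (deliberately leaky baseline for comparison; default `FALSE`).
#' @return A `classifier_auc` list: `auc` (mean over repeats), `per_repeat`
#'   tibble; one-row summary via [glance()].
#' @export
evaluate_classifier_auc <- function(expr, meth, assignment, folds = 5,
                                    repeats = 5, top_k = 50, ntree = 1000,
                                    seed = 1, leak_features = FALSE) {
  stopifnot(identical(subject_ids(expr), subject_ids(meth)))
  y <- factor(phase_vector(assignment)[subject_ids(expr)])
  if (any(table(y) < folds)) abort("every phase needs at least `folds` members.")
  classes <- levels(y)
  n <- length(y)
  md <- tibble::as_tibble(assignment)
  aucs <- with_local_seed(seed, {
    vapply(seq_len(repeats), function(rep_i) {
      fold <- stratified_folds(y, folds)
      scores <- matrix(NA_real_, n, length(classes),
                       dimnames = list(subject_ids(expr), classes))
      for (f in seq_len(folds)) {
        test <- fold == f
        tr_ids <- subject_ids(expr)[!test]
        sub_assign <- as_phase_assignment(
          setNames(as.integer(as.character(y[!test])), tr_ids),
          md[md$subject_id %in% tr_ids, ]
        )
        subset_cols <- function(om, ids) replace_values(om, om$values[, ids, drop = FALSE])
        expr_tr <- subset_cols(expr, tr_ids)
        meth_tr <- subset_cols(meth, tr_ids)
        sel_src <- if (leak_features) list(expr, meth) else list(expr_tr, meth_tr)
        sel_assign <- if (leak_features) {
          as_phase_assignment(setNames(as.integer(as.character(y)),
                                       subject_ids(expr)), md)
        } else {
          sub_assign
        }
        fe <- differential_top_features(sel_src[[1]], sel_assign, top_k)
        fm <- differential_top_features(sel_src[[2]], sel_assign, top_k)
        xtr <- cbind(t(expr_tr$values[fe, , drop = FALSE]),
                     t(meth_tr$values[fm, , drop = FALSE]))
        xte <- cbind(t(expr$values[fe, test, drop = FALSE]),
                     t(meth$values[fm, test, drop = FALSE]))
        fit <- randomForest::randomForest(x = xtr, y = droplevels(y[!test]),
                                          ntree = ntree, mtry = ncol(xtr))
        pr <- predict(fit, xte, type = "prob")
        scores[test, colnames(pr)] <- pr
      }
      multiclass_auc(scores, as.character(y))
    }, numeric(1))
  })
  structure(
    list(auc = mean(aucs),
         per_repeat = tibble::tibble(rep = seq_len(repeats), auc = aucs),
         folds = folds, repeats = repeats, top_k = top_k, seed = seed,
         leak_features = leak_features),
    class = "classifier_auc"
  )
}

#' @export
glance.classifier_auc <- function(x, ...) {
  tibble::tibble(auc = x$auc, folds = x$folds, repeats = x$repeats,
                 top_k = x$top_k, leak_features = x$leak_features)
}

#' @export
print.classifier_auc <- function(x, ...) {
  cat(sprintf("<classifier_auc> multiclass AUC = %.3f (%dx%d-fold CV)\n",
              x$auc, x$repeats, x$folds))
  invisible(x)
}

#' Summarize phase transitions between two timepoints
#'
#' Cross-tabulates phases of the shared subjects at the two timepoints,
#' lists movers with their direction (forward = higher phase at follow-up),
#' and reports the fraction of stable subjects. Backward transitions are
#' flagged prominently with a warning, since slow biological-age drift should
#' only move subjects forward.
#'
#' @param t1,t2 `phase_assignment`s (or named phase vectors) sharing subjects.
#' @return A `transition_summary`: `counts` matrix (t1 phases x t2 phases),
#'   `movers` tibble, `stability` fraction; overview via [glance()].
#' @export
phase_transition_summary <- function(t1, t2) {
  v1 <- if (inherits(t1, "phase_assignment")) phase_vector(t1) else t1
  v2 <- if (inherits(t2, "phase_assignment")) phase_vector(t2) else t2
  shared <- intersect(names(v1), names(v2))
  if (length(shared) == 0) abort("no shared subjects between timepoints.")
  v1 <- v1[shared]; v2 <- v2[shared]
  lev <- sort(unique(c(v1, v2)))
  counts <- table(factor(v1, levels = lev), factor(v2, levels = lev))
  dimnames(counts) <- list(phase_t1 = lev, phase_t2 = lev)
  moved <- shared[v1 != v2]
  movers <- tibble::tibble(
    subject_id = moved,
    from = as.integer(v1[moved]), to = as.integer(v2[moved]),
    direction = ifelse(v2[moved] > v1[moved], "forward", "backward")
  )
  if (any(movers$direction == "backward")) {
    warn(sprintf("%d backward phase transition(s) detected.",
                 sum(movers$direction == "backward")))
  }
  structure(
    list(counts = as.matrix(unclass(counts)), movers = movers,
         stability = mean(v1 == v2), n = length(shared)),
    class = "transition_summary"
  )
}

#' @export
glance.transition_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n, stable = sum(diag(x$counts)), stability = x$stability,
    forward = sum(x$movers$direction == "forward"),
    backward = sum(x$movers$direction == "backward")
  )
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %d subjects, %.0f%% stable, %d forward / %d backward\n",
              x$n, 100 * x$stability,
              sum(x$movers$direction == "forward"),
              sum(x$movers$direction == "backward")))
  print(x$counts)
  invisible(x)
}
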