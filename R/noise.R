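#' Pairwise inter-subject profile correlations by phase
#'
#' Pearson correlation over all features between every pair of subject
#' profiles, either restricted to pairs within the same phase
#' (`scope = "within_phase"`) or over all pairs pooled. Pairs involving a
#' zero-variance profile are dropped with a warning. Computed on full
#' (unfiltered) matrices by convention — the transcriptional-noise readout is
#' the whole profile, not the high-variance subset.
#'
#' @param x an `omics_matrix`.
#' @param assignment a `phase_assignment` covering the subjects.
#' @param scope `"within_phase"` or `"all_pairs"`.
#' @return A `similarity_by_phase` tibble: `phase` (`NA` for pooled scope),
#'   `subject_a`, `subject_b`, `correlation`; per-phase summaries via
#'   [tidy()].
#' @export
pairwise_similarity_by_phase <- function(x, assignment,
                                         scope = c("within_phase", "all_pairs")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "omics_matrix"), inherits(assignment, "phase_assignment"))
  pv <- phase_vector(assignment)
  if (!all(subject_ids(x) %in% names(pv))) {
    abort("every subject in the matrix needs a phase.")
  }
  v <- x$values
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance subject profile(s).", sum(sds == 0)))
    v <- v[, sds > 0, drop = FALSE]
  }
  subjects <- colnames(v)
  pv <- pv[subjects]
  cm <- cor(v)
  pair_tbl <- function(ids, phase) {
    if (length(ids) < 2) return(NULL)
    idx <- utils::combn(ids, 2)
    tibble::tibble(phase = phase, subject_a = idx[1, ], subject_b = idx[2, ],
                   correlation = cm[cbind(idx[1, ], idx[2, ])])
  }
  out <- if (scope == "within_phase") {
    dplyr::bind_rows(lapply(sort(unique(pv)), function(p) {
      pair_tbl(subjects[pv == p], as.integer(p))
    }))
  } else {
    pair_tbl(subjects, NA_integer_)
  }
  structure(out, class = c("similarity_by_phase", class(out)),
            kind = x$kind, scope = scope,
            phases = setNames(as.integer(pv), subjects),
            cor_matrix = cm)
}

#' @export
tidy.similarity_by_phase <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$phase),
    n_pairs = dplyr::n(),
    mean_correlation = mean(.data$correlation),
    median_correlation = median(.data$correlation),
    .groups = "drop"
  )
}

#' @export
autoplot.similarity_by_phase <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$phase), y = .data$correlation)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "aging phase", y = "pairwise Pearson correlation",
                  title = sprintf("Inter-subject %s profile similarity",
                                  attr(object, "kind") %||% "omics"))
}

#' Contrast within-phase profile similarity between two phases
#'
#' Tests whether inter-subject correlations are lower in `phase_b` than in
#' `phase_a` (rising transcriptional noise) at three levels:
#' \describe{
#'   \item{pairwise}{one-sided Wilcoxon rank-sum over the within-phase pair
#'     correlations. Pairs share subjects, so this p-value is
#'     anti-conservative under the null; it is reported because it is the
#'     conventional readout.}
#'   \item{subject}{each subject summarized by the median correlation to
#'     same-phase peers, then the same one-sided rank-sum — a partial guard
#'     against pair dependence.}
#'   \item{permutation}{the difference in within-phase mean correlation,
#'     referenced against its null distribution under random reassignment of
#'     the subjects of the two phases (pairs recomputed per permutation).
#'     Permuting subjects respects the dependence structure, so this p-value
#'     is calibrated and is the recommended inferential readout.}
#' }
#'
#' @param similarity a within-phase `similarity_by_phase`.
#' @param phase_a,phase_b phases to contrast (direction: `phase_b` lower).
#' @param n_perm permutations for the calibrated test (default 999).
#' @param seed RNG seed for the permutations.
#' @return A `noise_contrast` list: `p_pairwise`, `p_subject`,
#'   `p_permutation`, `summary` tibble; one-row overview via [glance()].
#' @export
noise_contrast <- function(similarity, phase_a = 3, phase_b = 4,
                           n_perm = 999, seed = 1) {
  stopifnot(inherits(similarity, "similarity_by_phase"))
  df <- tibble::as_tibble(similarity)
  ra <- df$correlation[df$phase == phase_a]
  rb <- df$correlation[df$phase == phase_b]
  if (length(ra) < 2 || length(rb) < 2) {
    abort("both phases need at least 2 within-phase pairs.")
  }
  p_pair <- suppressWarnings(
    wilcox.test(rb, ra, alternative = "less")$p.value
  )
  subj_median <- function(p) {
    sub <- df[df$phase == p, ]
    ids <- unique(c(sub$subject_a, sub$subject_b))
    vapply(ids, function(s) {
      median(sub$correlation[sub$subject_a == s | sub$subject_b == s])
    }, numeric(1))
  }
  p_subj <- suppressWarnings(
    wilcox.test(subj_median(phase_b), subj_median(phase_a),
                alternative = "less")$p.value
  )
  p_perm <- NA_real_
  cm <- attr(similarity, "cor_matrix")
  phases <- attr(similarity, "phases")
  if (!is.null(cm) && !is.null(phases)) {
    ids <- names(phases)[phases %in% c(phase_a, phase_b)]
    lab <- phases[ids] == phase_b
    mean_diff <- function(is_b) {
      sub <- cm[ids, ids]
      mean(sub[is_b, is_b][upper.tri(sub[is_b, is_b])]) -
        mean(sub[!is_b, !is_b][upper.tri(sub[!is_b, !is_b])])
    }
    obs <- mean_diff(lab)
    null <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) mean_diff(sample(lab)), numeric(1))
    })
    p_perm <- (1 + sum(null <= obs)) / (n_perm + 1)
  }
  structure(
    list(
      phase_a = phase_a, phase_b = phase_b,
      p_pairwise = p_pair, p_subject = p_subj, p_permutation = p_perm,
      summary = tidy(similarity)
    ),
    class = "noise_contrast"
  )
}

#' @export
glance.noise_contrast <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    phase_a = x$phase_a, phase_b = x$phase_b,
    mean_correlation_a = s$mean_correlation[s$phase == x$phase_a],
    mean_correlation_b = s$mean_correlation[s$phase == x$phase_b],
    p_pairwise = x$p_pairwise, p_subject = x$p_subject,
    p_permutation = x$p_permutation
  )
}

#' @export
print.noise_contrast <- function(x, ...) {
  cat(sprintf(
    "<noise_contrast> phase %s -> %s: one-sided p (pair level) = %.3g, p (subject level) = %.3g\n",
    x$phase_a, x$phase_b, x$p_pairwise, x$p_subject
  ))
  invisible(x)
}
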