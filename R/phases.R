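#' Order raw cluster labels into aging phases
#'
#' Relabels clusters so that phase numbers ascend with median chronological
#' age (phase 1 = youngest cluster). Ties on the median are broken by mean
#' age, then by smallest original label.
#'
#' @param labels integer cluster labels named by subject id (e.g. from
#'   [spectral_cluster()]), or a data frame with `subject_id` and `cluster`.
#' @param metadata data frame with `subject_id` and `chron_age` covering all
#'   labeled subjects.
#' @return A `phase_assignment` tibble: `subject_id`, `phase` (1..K),
#'   `chron_age`; per-phase summaries via [tidy()].
#' @export
order_phases <- function(labels, metadata) {
  if (is.data.frame(labels)) {
    labels <- setNames(labels$cluster, labels$subject_id)
  }
  if (is.null(names(labels))) abort("`labels` must be named by subject id.")
  md <- validate_metadata(tibble::as_tibble(metadata))
  age <- setNames(md$chron_age, md$subject_id)
  if (!all(names(labels) %in% names(age))) {
    abort("every labeled subject needs a chronological age in `metadata`.")
  }
  age <- age[names(labels)]
  lev <- sort(unique(labels))
  if (any(table(factor(labels, levels = lev)) == 0)) abort("empty cluster.")
  stats_tbl <- tibble::tibble(
    cluster = lev,
    median_age = vapply(lev, function(l) median(age[labels == l]), numeric(1)),
    mean_age = vapply(lev, function(l) mean(age[labels == l]), numeric(1))
  )
  ord <- order(stats_tbl$median_age, stats_tbl$mean_age, stats_tbl$cluster)
  relabel <- setNames(seq_along(lev), stats_tbl$cluster[ord])
  out <- tibble::tibble(
    subject_id = names(labels),
    phase = as.integer(relabel[as.character(labels)]),
    chron_age = unname(age)
  )
  class(out) <- c("phase_assignment", class(out))
  out
}

#' Coerce to a phase assignment
#'
#' Builds a `phase_assignment` from already-ordered labels (e.g. ground-truth
#' phases), without relabeling.
#'
#' @param phases integer phase labels named by subject, or data frame with
#'   `subject_id` and `phase`.
#' @param metadata data frame with `subject_id` and `chron_age`.
#' @return A `phase_assignment` tibble.
#' @export
as_phase_assignment <- function(phases, metadata) {
  if (is.data.frame(phases)) phases <- setNames(phases$phase, phases$subject_id)
  md <- validate_metadata(tibble::as_tibble(metadata))
  age <- setNames(md$chron_age, md$subject_id)
  out <- tibble::tibble(
    subject_id = names(phases),
    phase = as.integer(phases),
    chron_age = unname(age[names(phases)])
  )
  class(out) <- c("phase_assignment", class(out))
  out
}

phase_vector <- function(assignment) {
  setNames(assignment$phase, assignment$subject_id)
}

#' @export
tidy.phase_assignment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$phase),
    n = dplyr::n(),
    median_age = median(.data$chron_age),
    mean_age = mean(.data$chron_age),
    sd_age = sd(.data$chron_age),
    .groups = "drop"
  )
}

#' @export
autoplot.phase_assignment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$phase), y = .data$chron_age)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "aging phase", y = "chronological age [y]",
                  title = "Chronological age by aging phase")
}

#' Test association between a per-subject variable and a grouping
#'
#' One-way ANOVA F-test (default) or Kruskal-Wallis of `values` across groups.
#' If all values are identical the statistic is 0 and p = 1.
#'
#' @param values numeric vector, one value per subject.
#' @param groups grouping: a `phase_assignment` (matched by subject when
#'   `values` is named) or a vector of group labels aligned with `values`.
#' @param method `"anova"` or `"kruskal"`.
#' @return A one-row tibble: `method`, `statistic`, `p_value`.
#' @export
association_test <- function(values, groups, method = c("anova", "kruskal")) {
  method <- match.arg(method)
  g <- resolve_groups(values, groups)
  values <- g$values
  grp <- factor(g$groups)
  if (nlevels(grp) < 2) abort("need at least two groups.")
  if (sd(values) == 0) {
    return(tibble::tibble(method = method, statistic = 0, p_value = 1))
  }
  if (method == "anova") {
    if (any(table(grp) < 2)) abort("ANOVA requires every group to have >= 2 members.")
    a <- anova(lm(values ~ grp))
    tibble::tibble(method = method, statistic = a$`F value`[1],
                   p_value = a$`Pr(>F)`[1])
  } else {
    k <- kruskal.test(values, grp)
    tibble::tibble(method = method, statistic = unname(k$statistic),
                   p_value = k$p.value)
  }
}

resolve_groups <- function(values, groups) {
  if (inherits(groups, "phase_assignment")) {
    pv <- phase_vector(groups)
    if (!is.null(names(values))) {
      common <- intersect(names(values), names(pv))
      return(list(values = unname(values[common]), groups = unname(pv[common])))
    }
    if (length(values) != length(pv)) {
      abort("`values` must be named by subject or aligned with the assignment.")
    }
    return(list(values = values, groups = unname(pv)))
  }
  stopifnot(length(values) == length(groups))
  list(values = values, groups = groups)
}

#' Predict molecular age with a linear clock
#'
#' Applies `intercept + sum(coefficient * feature value)` per subject. Clock
#' features missing from the matrix are dropped with a warning; if none are
#' present this is an error.
#'
#' @param x an `omics_matrix` whose scale matches `clock$input_scale`.
#' @param clock a [clock_model()].
#' @return A tibble: `subject_id`, `predicted_age`.
#' @export
apply_linear_clock <- function(x, clock) {
  stopifnot(inherits(x, "omics_matrix"), inherits(clock, "clock_model"))
  if (x$scale != clock$input_scale) {
    abort(sprintf("matrix scale '%s' does not match clock input scale '%s'.",
                  x$scale, clock$input_scale))
  }
  present <- intersect(names(clock$coefficients), feature_ids(x))
  n_missing <- length(clock$coefficients) - length(present)
  if (length(present) == 0) abort("none of the clock features are present.")
  if (n_missing > 0) {
    warn(sprintf("%d of %d clock feature(s) missing from the matrix; dropped.",
                 n_missing, length(clock$coefficients)))
  }
  pred <- clock$intercept +
    drop(crossprod(x$values[present, , drop = FALSE], clock$coefficients[present]))
  tibble::tibble(subject_id = subject_ids(x), predicted_age = unname(pred))
}

#' Flag chronological-age outliers within each aging phase
#'
#' Within each phase computes Q1, Q3 and the IQR of chronological age
#' (linear-interpolation, type-7 quantiles). A subject is `young_like` when
#' their age exceeds Q3 by at least one third of the IQR (chronologically old
#' for a phase of younger subjects, hence biologically young), and `old_like`
#' when it falls below Q1 by the same margin. Exceedance is strict, so an IQR
#' of 0 can flag no one.
#'
#' @param assignment a `phase_assignment` (every phase needs >= 4 subjects).
#' @return A tibble: `subject_id`, `phase`, `chron_age`, `status`
#'   (`none`/`young_like`/`old_like`), and the per-phase `q1`, `q3`, `iqr`.
#' @export
classify_age_outliers <- function(assignment) {
  stopifnot(inherits(assignment, "phase_assignment"))
  df <- tibble::as_tibble(assignment)
  sizes <- table(df$phase)
  if (any(sizes < 4)) {
    abort(sprintf("phase %s has fewer than 4 subjects; quartiles unreliable.",
                  names(sizes)[sizes < 4][1]))
  }
  out <- dplyr::mutate(
    dplyr::group_by(df, .data$phase),
    q1 = unname(quantile(.data$chron_age, 0.25, type = 7)),
    q3 = unname(quantile(.data$chron_age, 0.75, type = 7)),
    iqr = .data$q3 - .data$q1,
    status = dplyr::case_when(
      .data$chron_age > .data$q3 & (.data$chron_age - .data$q3) >= .data$iqr / 3 ~ "young_like",
      .data$chron_age < .data$q1 & (.data$q1 - .data$chron_age) >= .data$iqr / 3 ~ "old_like",
      TRUE ~ "none"
    )
  )
  out <- dplyr::ungroup(out)
  out$status <- factor(out$status, levels = c("none", "young_like", "old_like"))
  out
}

#' Pairwise group-difference tests
#'
#' All pairwise comparisons of `values` between groups with Welch t-tests or
#' Wilcoxon rank-sum tests (one- or two-sided), with optional
#' Benjamini-Hochberg adjustment across the pairs. For one-sided tests the
#' alternative is that the first group of the pair (lower label in sort order)
#' is shifted downward relative to the second.
#'
#' @param values numeric vector.
#' @param groups group labels (or a `phase_assignment`).
#' @param method `"t_pairwise"`, `"wilcoxon_one_sided"`, `"wilcoxon_two_sided"`.
#' @param adjust `"BH"` or `"none"`.
#' @return A tibble: `group_a`, `group_b`, `statistic`, `p_value`,
#'   `p_adjusted`. Pairs with a group of < 2 values are skipped with a warning.
#' @export
group_difference_tests <- function(values, groups,
                                   method = c("t_pairwise", "wilcoxon_one_sided",
                                              "wilcoxon_two_sided"),
                                   adjust = c("BH", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  g <- resolve_groups(values, groups)
  values <- g$values
  grp <- g$groups
  lev <- sort(unique(grp))
  if (length(lev) < 2) abort("need at least two groups.")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    va <- values[grp == pr[1]]
    vb <- values[grp == pr[2]]
    if (length(va) < 2 || length(vb) < 2) {
      warn(sprintf("skipping pair %s vs %s: a group has < 2 values.", pr[1], pr[2]))
      return(NULL)
    }
    if (method == "t_pairwise" && sd(va) == 0 && sd(vb) == 0) {
      # degenerate case: identical constants give t = 0, p = 1
      stat <- if (mean(va) == mean(vb)) 0 else Inf * sign(mean(va) - mean(vb))
      pval <- if (mean(va) == mean(vb)) 1 else 0
      return(tibble::tibble(group_a = as.character(pr[1]),
                            group_b = as.character(pr[2]),
                            statistic = stat, p_value = pval))
    }
    res <- suppressWarnings(switch(
      method,
      t_pairwise = t.test(va, vb, var.equal = FALSE),
      wilcoxon_one_sided = wilcox.test(va, vb, alternative = "less"),
      wilcoxon_two_sided = wilcox.test(va, vb, alternative = "two.sided")
    ))
    tibble::tibble(group_a = as.character(pr[1]), group_b = as.character(pr[2]),
                   statistic = unname(res$statistic), p_value = res$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out
}

#' Age-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on an exposure,
#' optionally adjusting for chronological age, with the Wald p-value for the
#' exposure term. Complete or quasi-complete separation is flagged by setting
#' `reliable = FALSE`.
#'
#' @param data data frame holding the variables.
#' @param outcome name of the binary (0/1) outcome column.
#' @param exposure name of the exposure column.
#' @param age name of the age column used for adjustment.
#' @param adjust_for_age include age as a covariate (default `TRUE`).
#' @return A one-row tibble: `estimate`, `odds_ratio`, `std_error`, `p_value`,
#'   `reliable`.
#' @export
logistic_association <- function(data, outcome, exposure, age = "chron_age",
                                 adjust_for_age = TRUE) {
  df <- as.data.frame(data)
  y <- df[[outcome]]
  if (is.null(y)) abort(sprintf("column '%s' not found.", outcome))
  if (length(unique(y)) < 2) abort("outcome is constant; nothing to model.")
  if (nrow(df) < 10) abort("need at least 10 observations.")
  rhs <- if (adjust_for_age) paste(exposure, "+", age) else exposure
  fit <- suppressWarnings(
    glm(stats::reformulate(rhs, response = outcome), data = df, family = binomial())
  )
  cf <- summary(fit)$coefficients
  est <- cf[exposure, "Estimate"]
  se <- cf[exposure, "Std. Error"]
  fitted_p <- fitted(fit)
  separated <- !fit$converged || any(fitted_p > 1 - 1e-8) || any(fitted_p < 1e-8) ||
    se > 50
  if (separated) warn("possible separation: the p-value is unreliable.")
  tibble::tibble(
    estimate = est, odds_ratio = exp(est), std_error = se,
    p_value = cf[exposure, "Pr(>|z|)"], reliable = !separated
  )
}

#' Near-equal-size chronological age groups
#'
#' Cuts chronological age into `n_groups` quantile bins (type-7), the
#' comparison grouping used when contrasting aging phases with a naive
#' chronological stratification.
#'
#' @param ages numeric ages.
#' @param n_groups number of bins.
#' @return Integer group labels 1..n_groups.
#' @export
chronological_age_groups <- function(ages, n_groups = 4) {
  br <- quantile(ages, probs = seq(0, 1, length.out = n_groups + 1), type = 7)
  br[1] <- -Inf
  br[length(br)] <- Inf
  as.integer(cut(ages, breaks = unique(br), labels = FALSE))
}
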