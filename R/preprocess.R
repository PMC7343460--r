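#' Convert omics values between scales
#'
#' Supported conversions: raw TPM to log2-TPM (`log2(tpm + pseudocount)`),
#' methylation beta to M-value (`log2(beta / (1 - beta))`, with beta clipped
#' into `[eps, 1 - eps]`) and back.
#'
#' @param x an `omics_matrix`.
#' @param target_scale one of `"log2_tpm"`, `"m_value"`, `"beta"`.
#' @param pseudocount added to TPM before log2 (default 1).
#' @param eps clipping bound for beta values (default 1e-6).
#' @return An `omics_matrix` on the target scale.
#' @export
transform_values <- function(x, target_scale, pseudocount = 1, eps = 1e-6) {
  stopifnot(inherits(x, "omics_matrix"))
  pair <- paste(x$scale, target_scale, sep = "->")
  v <- x$values
  out <- switch(
    pair,
    "raw_tpm->log2_tpm" = log2(v + pseudocount),
    "beta->m_value" = {
      b <- pmin(pmax(v, eps), 1 - eps)
      log2(b / (1 - b))
    },
    "m_value->beta" = 2^v / (1 + 2^v),
    abort(sprintf("unsupported scale conversion: %s", pair))
  )
  retag_scale(x, out, target_scale)
}

# Raw median absolute deviation (no consistency constant): the ranking used
# for feature selection is invariant to any positive scaling.
row_mad <- function(m) {
  apply(m, 1, function(v) median(abs(v - median(v))))
}

#' Variance-based feature selection by median absolute deviation
#'
#' Keeps the `ceiling(fraction * n_features)` features with largest MAD across
#' subjects. Ties are broken by feature id (lexicographic); the output keeps
#' the input feature order.
#'
#' @param x an `omics_matrix`.
#' @param fraction fraction of features to retain, in (0, 1\].
#' @return An `omics_matrix` restricted to the selected features.
#' @export
mad_feature_select <- function(x, fraction = 0.10) {
  stopifnot(inherits(x, "omics_matrix"))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  n <- nrow(x$values)
  keep_n <- ceiling(fraction * n)
  mads <- row_mad(x$values)
  ord <- order(-mads, feature_ids(x))
  keep <- sort(ord[seq_len(keep_n)])
  replace_values(x, x$values[keep, , drop = FALSE])
}

#' Empirical-Bayes batch correction (ComBat)
#'
#' Removes additive/multiplicative batch effects with the parametric
#' empirical-Bayes location/scale model of Johnson et al., as implemented in
#' the sva package, with no covariate design. A single-batch input is returned
#' unchanged; a batch with fewer than two subjects is an error (its scale is
#' undefined).
#'
#' @param x an `omics_matrix` with batch labels (or `batch` supplied here).
#' @param batch optional batch labels overriding `x$batch`.
#' @param parametric use parametric empirical-Bayes priors (default `TRUE`).
#' @return A batch-corrected `omics_matrix`.
#' @export
combat_correct <- function(x, batch = NULL, parametric = TRUE) {
  stopifnot(inherits(x, "omics_matrix"))
  batch <- batch %||% x$batch
  if (is.null(batch)) abort("no batch labels available.")
  batch <- as.character(batch)
  if (length(batch) != ncol(x$values)) abort("`batch` must have one label per subject.")
  sizes <- table(batch)
  if (length(sizes) == 1) return(x)
  if (any(sizes < 2)) {
    abort(sprintf("batch '%s' has fewer than 2 subjects; scale is undefined.",
                  names(sizes)[sizes < 2][1]))
  }
  corrected <- suppressMessages(
    sva::ComBat(dat = x$values, batch = batch, mod = NULL,
                par.prior = parametric, prior.plots = FALSE)
  )
  dimnames(corrected) <- dimnames(x$values)
  replace_values(x, corrected)
}

#' One-call preprocessing: transform, MAD-select, batch-correct
#'
#' Applies the standard preparation preceding network fusion: optional scale
#' transform, MAD feature selection (default: retain the top 10%), then ComBat
#' batch correction. `order = "correct_first"` swaps the last two steps.
#'
#' @param x an `omics_matrix`.
#' @param target_scale optional scale to transform to first (`NULL` = keep).
#' @param mad_fraction fraction of features to retain (`1` disables selection).
#' @param combat apply batch correction (skipped when no batch labels).
#' @param order `"select_first"` (default) or `"correct_first"`.
#' @return A preprocessed `omics_matrix`.
#' @export
preprocess_omics <- function(x, target_scale = NULL, mad_fraction = 0.10,
                             combat = TRUE,
                             order = c("select_first", "correct_first")) {
  order <- match.arg(order)
  if (!is.null(target_scale) && !identical(target_scale, x$scale)) {
    x <- transform_values(x, target_scale)
  }
  do_combat <- combat && !is.null(x$batch) && length(unique(x$batch)) > 1
  if (order == "select_first") {
    x <- mad_feature_select(x, mad_fraction)
    if (do_combat) x <- combat_correct(x)
  } else {
    if (do_combat) x <- combat_correct(x)
    x <- mad_feature_select(x, mad_fraction)
  }
  x
}
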