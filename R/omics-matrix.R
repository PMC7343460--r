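#' Construct an omics matrix
#'
#' A light container for a features x subjects numeric matrix with an omics
#' kind ("expression" or "methylation"), a value scale, and optional per-subject
#' batch labels. Feature ids are the rownames, subject ids the colnames; both
#' must be unique and the matrix must be complete (no missing values).
#'
#' @param values numeric matrix, features in rows, subjects in columns, with
#'   unique non-empty dimnames.
#' @param kind `"expression"` or `"methylation"`.
#' @param scale value scale: `"raw_tpm"`, `"log2_tpm"`, `"beta"`, `"m_value"`.
#'   Beta values must lie in \[0, 1\].
#' @param batch optional character vector of batch labels, either named by
#'   subject id or in column order.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values,
                         kind = c("expression", "methylation"),
                         scale = c("raw_tpm", "log2_tpm", "beta", "m_value"),
                         batch = NULL) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x subjects).")
  }
  if (nrow(values) == 0 || ncol(values) == 0) {
    abort("`values` must have at least one feature and one subject.")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("`values` must carry feature ids as rownames and subject ids as colnames.")
  }
  if (anyDuplicated(fid)) abort("duplicate feature ids are not allowed.")
  if (anyDuplicated(sid)) abort("duplicate subject ids are not allowed.")
  if (anyNA(values)) abort("missing values are not allowed in an omics matrix.")
  if (scale == "beta" && (min(values) < 0 || max(values) > 1)) {
    abort("beta-scale values must lie in [0, 1].")
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (!is.null(names(batch))) {
      if (!setequal(names(batch), sid)) {
        abort("names of `batch` must match the subject ids.")
      }
      batch <- batch[sid]
    } else if (length(batch) != ncol(values)) {
      abort("`batch` must have one label per subject.")
    } else {
      names(batch) <- sid
    }
  }
  structure(
    list(values = values, kind = kind, scale = scale, batch = batch),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %s [%s]: %d features x %d subjects%s\n",
    x$kind, x$scale, nrow(x$values), ncol(x$values),
    if (is.null(x$batch)) "" else sprintf(", %d batches", length(unique(x$batch)))
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and subject ids of an omics matrix
#' @param x an `omics_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
subject_ids <- function(x) colnames(x$values)

# Replace values keeping metadata; batch subset follows the columns.
replace_values <- function(x, values) {
  omics_matrix(values, kind = x$kind, scale = x$scale,
               batch = if (is.null(x$batch)) NULL else x$batch[colnames(values)])
}

# internal: allow constructing with a different scale tag
retag_scale <- function(x, values, scale) {
  omics_matrix(values, kind = x$kind, scale = scale,
               batch = if (is.null(x$batch)) NULL else x$batch[colnames(values)])
}

#' @export
tidy.omics_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    stats::setNames(c("feature_id", "subject_id", "value")) |>
    tibble::as_tibble()
}

#' Restrict two omics matrices to their common features
#'
#' Cross-platform comparability step: both matrices are reduced to the sorted
#' set of shared feature ids (exact string match); subject columns are left
#' untouched. Mirrors the reduction of a larger methylation array to the probes
#' of a smaller one.
#'
#' @param a,b `omics_matrix` objects of the same kind and scale.
#' @return A list with elements `a` and `b`, both restricted to common features.
#' @export
intersect_features <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (a$kind != b$kind || a$scale != b$scale) {
    abort("`a` and `b` must share omics kind and scale.")
  }
  common <- sort(intersect(feature_ids(a), feature_ids(b)))
  if (length(common) == 0) abort("the feature sets have an empty intersection.")
  list(
    a = replace_values(a, a$values[common, , drop = FALSE]),
    b = replace_values(b, b$values[common, , drop = FALSE])
  )
}
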