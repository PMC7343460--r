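#' PLAGE single-sample gene-set activity scores
#'
#' Pathway-level analysis of gene expression: genes are z-scored across
#' subjects (population SD), and each set's activity profile is the first
#' right singular vector of its z-scored gene x subject submatrix — one score
#' per subject, unit norm. Because the SVD sign is arbitrary, each score
#' vector is oriented to correlate non-negatively with the set's mean
#' z-scored expression, which makes scores reproducible across platforms.
#'
#' @param expr an `omics_matrix` (expression) with >= 2 subjects.
#' @param sets a `gene_sets` collection (or named list of gene vectors).
#' @return An `enrichment_scores` matrix (sets x subjects). Sets with no
#'   matched genes are dropped with a warning; single-gene sets are allowed
#'   and flagged in the `"singleton"` attribute. Long format via [tidy()].
#' @export
plage_scores <- function(expr, sets) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (ncol(expr$values) < 2) abort("PLAGE needs at least 2 subjects.")
  sets <- as_gene_list(sets)
  v <- expr$values
  sds <- sqrt(rowMeans((v - rowMeans(v))^2))  # population SD
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s) from z-scoring.", sum(sds == 0)))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (v - rowMeans(v)) / sds
  scores <- matrix(NA_real_, length(sets), ncol(z),
                   dimnames = list(names(sets), colnames(z)))
  singleton <- logical(length(sets))
  keep <- logical(length(sets))
  for (i in seq_along(sets)) {
    genes <- intersect(sets[[i]], rownames(z))
    if (length(genes) == 0) next
    keep[i] <- TRUE
    singleton[i] <- length(genes) == 1
    zs <- z[genes, , drop = FALSE]
    sv <- svd(zs, nu = 0, nv = 1)
    act <- sv$v[, 1]
    ref <- colMeans(zs)
    s <- sum(act * ref)
    if (s < 0) act <- -act
    scores[i, ] <- act
  }
  if (!all(keep)) {
    warn(sprintf("dropping %d set(s) with no genes in the matrix: %s",
                 sum(!keep), paste(names(sets)[!keep], collapse = ", ")))
  }
  out <- scores[keep, , drop = FALSE]
  structure(out, class = c("enrichment_scores", class(out)),
            singleton = setNames(singleton[keep], rownames(out)),
            kind = expr$kind)
}

#' @export
`[.enrichment_scores` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, class = c("enrichment_scores", class(out)),
              singleton = attr(x, "singleton")[rownames(out)],
              kind = attr(x, "kind"))
  } else {
    out
  }
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf("<enrichment_scores> %d sets x %d subjects\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
tidy.enrichment_scores <- function(x, ...) {
  m <- unclass(x)
  attr(m, "singleton") <- NULL
  attr(m, "kind") <- NULL
  df <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(df) <- c("set", "subject_id", "score")
  tibble::as_tibble(df)
}

#' Compare how strongly alternative groupings segregate enrichment scores
#'
#' For each gene set and each grouping, a one-way ANOVA of the PLAGE scores
#' across the grouping's classes, with Benjamini-Hochberg adjustment across
#' sets within each grouping. Comparing the adjusted p-values between, say,
#' latent aging phases and chronological age bins shows which grouping
#' captures the pathway signal better (smaller adjusted p).
#'
#' @param scores an `enrichment_scores` matrix.
#' @param groupings named list of groupings; each is a vector of labels named
#'   by subject id (or aligned with the score columns), or a
#'   `phase_assignment`.
#' @param adjust `"BH"` or `"none"`.
#' @return A tibble: `set`, `grouping`, `statistic`, `p_value`, `p_adjusted`.
#'   Groupings containing a singleton class are skipped with a warning.
#' @export
grouping_signal_anova <- function(scores, groupings, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(scores, "enrichment_scores"))
  if (is.null(names(groupings))) abort("`groupings` must be a named list.")
  subjects <- colnames(scores)
  rows <- purrr::imap(groupings, function(g, gname) {
    if (inherits(g, "phase_assignment")) g <- phase_vector(g)
    if (!is.null(names(g))) {
      if (!all(subjects %in% names(g))) {
        abort(sprintf("grouping '%s' does not cover all scored subjects.", gname))
      }
      g <- g[subjects]
    } else if (length(g) != length(subjects)) {
      abort(sprintf("grouping '%s' must cover all scored subjects.", gname))
    }
    g <- factor(g)
    if (any(table(g) < 2)) {
      warn(sprintf("grouping '%s' has a singleton class; skipped.", gname))
      return(NULL)
    }
    res <- purrr::map(rownames(scores), function(s) {
      association_test(scores[s, ], g, method = "anova")
    })
    out <- dplyr::bind_rows(res)
    out$set <- rownames(scores)
    out$grouping <- gname
    out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
    out[, c("set", "grouping", "statistic", "p_value", "p_adjusted")]
  })
  dplyr::bind_rows(rows)
}
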