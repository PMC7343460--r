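#' Create a gene-set collection
#'
#' A gene-set collection is a tibble with one row per set: `set` (unique name),
#' `description`, and `genes` (list-column of character vectors, duplicates
#' collapsed). Row order is the collection order.
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector, recycled to length of `sets`.
#' @return A `gene_sets` tibble.
#' @export
gene_sets <- function(sets, descriptions = "") {
  if (length(sets) == 0) {
    out <- tibble::tibble(set = character(), description = character(),
                          genes = list())
    class(out) <- c("gene_sets", class(out))
    return(out)
  }
  nm <- names(sets)
  if (is.null(nm) || any(nm == "")) abort("every gene set must be named.")
  if (anyDuplicated(nm)) abort("duplicate gene set names are not allowed.")
  genes <- lapply(sets, function(g) {
    g <- as.character(g)
    if (length(g) == 0) abort("gene lists must be non-empty.")
    unique(g)
  })
  if (any(lengths(genes) < lengths(sets))) {
    warn("duplicate genes within a set were collapsed.")
  }
  out <- tibble::tibble(
    set = nm,
    description = rep_len(as.character(descriptions), length(sets)),
    genes = unname(genes)
  )
  class(out) <- c("gene_sets", class(out))
  out
}

as_gene_list <- function(x) {
  if (inherits(x, "gene_sets")) return(setNames(x$genes, x$set))
  if (is.list(x)) return(x)
  abort("expected a `gene_sets` collection or a named list of gene vectors.")
}

#' Read and write gene sets in GMT format
#'
#' GMT is the Broad tab-separated format: one set per line with fields
#' name, description, then one or more gene ids. Duplicate genes within a line
#' are collapsed with a warning; duplicate set names or lines with fewer than
#' three fields are errors.
#'
#' @param path file path.
#' @return `read_gene_sets()` returns a `gene_sets` tibble preserving file
#'   order; `write_gene_sets()` returns `path` invisibly.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields.", bad[1]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene set name: %s", nm[duplicated(nm)][1]))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_sets(sets, desc)
}

#' @rdname read_gene_sets
#' @param x a `gene_sets` collection.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$set[i], x$description[i], x$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write omics matrices as TSV
#'
#' Expects a header row of subject ids and a first column of feature ids,
#' tab-separated, numeric body, no quoting. Missing values are rejected by
#' default or imputed with the per-feature median when `impute = TRUE`.
#'
#' @param path file path.
#' @param kind,scale passed to [omics_matrix()].
#' @param batch optional batch labels, see [omics_matrix()].
#' @param impute impute missing cells with the per-feature median instead of
#'   failing.
#' @return An `omics_matrix`.
#' @export
read_omics_matrix <- function(path, kind, scale, batch = NULL, impute = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort("matrix file has an empty body or no subject columns.")
  }
  fid <- as.character(df[[1]])
  if (anyDuplicated(fid)) abort("duplicate feature ids in matrix file.")
  body <- df[-1]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v)) {
        i <- which(is.na(num))[1]
        abort(sprintf("non-numeric cell at feature '%s', subject '%s'.",
                      fid[i], names(body)[j]))
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- fid
  if (anyNA(m)) {
    if (!impute) {
      abort("matrix contains missing values; set `impute = TRUE` to use per-feature medians.")
    }
    for (i in which(rowSums(is.na(m)) > 0)) {
      v <- m[i, ]
      v[is.na(v)] <- median(v, na.rm = TRUE)
      m[i, ] <- v
    }
  }
  omics_matrix(m, kind = kind, scale = scale, batch = batch)
}

#' @rdname read_omics_matrix
#' @param x an `omics_matrix`.
#' @export
write_omics_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = feature_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' TSV with at least `subject_id` and `chron_age` columns; `batch` and
#' `timepoint` are used when present (timepoint defaults to 1). Ages must be
#' positive and subject ids unique within each timepoint.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_subject_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(tibble::as_tibble(df))
}

validate_metadata <- function(df) {
  need <- setdiff(c("subject_id", "chron_age"), names(df))
  if (length(need) > 0) {
    abort(sprintf("metadata is missing column(s): %s", paste(need, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  if (!is.numeric(df$chron_age) || any(df$chron_age <= 0)) {
    abort("`chron_age` must be positive and numeric.")
  }
  tp <- if ("timepoint" %in% names(df)) df$timepoint else 1L
  if (anyDuplicated(paste(df$subject_id, tp))) {
    abort("subject ids must be unique within a timepoint.")
  }
  df
}

#' Linear molecular-age clock models
#'
#' A clock is an intercept plus a sparse linear combination of features
#' (methylation M-values or log2-TPM expression). The TSV interchange format
#' has columns `feature_id` and `coefficient`, with the intercept stored under
#' the feature id `(Intercept)`.
#'
#' @param coefficients named numeric vector of feature weights (at least one
#'   nonzero).
#' @param intercept numeric intercept in years.
#' @param input_scale `"m_value"` or `"log2_tpm"`: the scale the clock expects.
#' @return A `clock_model` object.
#' @export
clock_model <- function(coefficients, intercept = 0,
                        input_scale = c("m_value", "log2_tpm")) {
  input_scale <- match.arg(input_scale)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    abort("clock coefficients must have unique feature names.")
  }
  if (all(coefficients == 0)) abort("a clock needs at least one nonzero coefficient.")
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 input_scale = input_scale),
            class = "clock_model")
}

#' @rdname clock_model
#' @param path file path.
#' @export
read_clock_model <- function(path, input_scale = c("m_value", "log2_tpm")) {
  input_scale <- match.arg(input_scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("feature_id", "coefficient") %in% names(df))) {
    abort("clock file needs columns `feature_id` and `coefficient`.")
  }
  ic <- df$feature_id == "(Intercept)"
  clock_model(setNames(df$coefficient[!ic], df$feature_id[!ic]),
              intercept = if (any(ic)) df$coefficient[ic][1] else 0,
              input_scale = input_scale)
}

#' @rdname clock_model
#' @param x a `clock_model`.
#' @export
write_clock_model <- function(x, path) {
  stopifnot(inherits(x, "clock_model"))
  df <- data.frame(
    feature_id = c("(Intercept)", names(x$coefficients)),
    coefficient = c(x$intercept, unname(x$coefficients))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d features on %s, intercept %.2f\n",
              length(x$coefficients), x$input_scale, x$intercept))
  invisible(x)
}
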