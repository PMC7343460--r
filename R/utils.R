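#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median quantile rnorm runif sd cor dist p.adjust
#' @importFrom stats wilcox.test t.test kruskal.test lm anova glm binomial
#' @importFrom stats kmeans hclust cutree setNames predict plogis qlogis pnorm
#' @importFrom utils head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user-level streams.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one integer seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' throughout to score recovery of ground-truth phases. Delegates to
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length (any type coercible to factor).
#' @return A single number, 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
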