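#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n row_number across all_of desc
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median quantile rnorm runif rexp rnbinom cor pt pchisq
#'   phyper sd var hclust cutree dist kmeans setNames
#' @importFrom utils head tail
NULL

# Interval convention: 0-based half-open [start, end). This predicate is the
# single source of truth for overlap tests throughout the package.

#' Do two half-open intervals overlap?
#'
#' Intervals are 0-based half-open `[start, end)`. Vectorised over both pairs.
#'
#' @param start1,end1,start2,end2 Integer coordinate vectors.
#' @return Logical vector: `TRUE` where the intervals share at least 1 bp.
#' @export
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 < end2 & start2 < end1
}

#' Midpoint of a half-open interval
#'
#' @param start,end Integer coordinate vectors.
#' @return Integer midpoint, `floor((start + end) / 2)`.
#' @export
interval_midpoint <- function(start, end) {
  as.integer(floor((start + end) / 2))
}

#' Derive a stage-specific RNG seed from a base seed
#'
#' One global seed fans out to per-stage seeds (hashed by stage name) so that
#' pipeline stages can be rerun independently yet deterministically. The
#' derived seed stays within 32-bit range so `set.seed()` accepts it on every
#' platform.
#'
#' @param seed Integer base seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) * 48271 + h * 69621) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}
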