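# Ordinal difficulty scoring and D1-D4 classification.
#
# The total score is the sum of the four feature scores (range 4-14). Class
# ranges: D1 4-6 (easy), D2 7-8 (slightly difficult), D3 9-10 (moderately
# difficult), D4 from 11 up (very difficult). The published upper bound of
# the D4 range is 13, yet the feature maxima sum to 4+3+3+4 = 14; D4 here
# covers 11-14 so that every reachable total classifies, and the published
# bound is kept as metadata (`printed_hi`).

#' The four difficulty classes and their score ranges
#'
#' @return A tibble with columns `label` (D1..D4), `name`, `lo`, `hi`
#'   (inclusive bounds actually used; they partition 4..14) and `printed_hi`
#'   (the published upper bound, 13 for D4).
#' @export
difficulty_classes <- function() {
  tibble::tibble(
    label = c("D1", "D2", "D3", "D4"),
    name = c("Easy", "Slightly difficult", "Moderately difficult",
             "Very difficult"),
    lo = c(4L, 7L, 9L, 11L),
    hi = c(6L, 8L, 10L, 14L),
    printed_hi = c(6L, 8L, 10L, 13L)
  )
}

DIFFICULTY_LABELS <- c("D1", "D2", "D3", "D4")

.validate_feature_scores <- function(fv) {
  if (is.data.frame(fv)) fv <- unlist(fv[1, unname(FEATURE_COLS)])
  if (is.null(names(fv)) && length(fv) == 4L) names(fv) <- unname(FEATURE_COLS)
  fv <- fv[unname(FEATURE_COLS)]
  for (col in unname(FEATURE_COLS)) {
    v <- fv[[col]]
    if (is.na(v) || v < 1L || v > FEATURE_MAX[[col]] || v != as.integer(v)) {
      stop("feature '", col, "' score ", v, " outside its scale 1..",
           FEATURE_MAX[[col]], call. = FALSE)
    }
  }
  stats::setNames(as.integer(fv), names(fv))
}

#' Total difficulty score of a feature vector
#'
#' @param fv Feature scores: a named numeric vector (names `angulation`,
#'   `root_count`, `root_curvature`, `canal`), an unnamed length-4 vector in
#'   that order, or a one-row data frame with those columns.
#' @return Integer total in 4..14.
#' @examples
#' total_score(c(1, 1, 1, 1))
#' total_score(c(angulation = 4, root_count = 3, root_curvature = 3, canal = 4))
#' @export
total_score <- function(fv) {
  sum(.validate_feature_scores(fv))
}

#' Classify a total score into a difficulty class
#'
#' @param total Integer vector of total scores, each in 4..14.
#' @return A tibble with one row per input: `total`, `label`, `name`, `lo`,
#'   `hi`.
#' @examples
#' classify_score(7)$label   # "D2"
#' classify_score(10)$label  # "D3"
#' @export
classify_score <- function(total) {
  total <- as.numeric(total)
  if (any(is.na(total)) || any(total != floor(total)) ||
      any(total < 4) || any(total > 14)) {
    stop("total score must be an integer in 4..14", call. = FALSE)
  }
  cls <- difficulty_classes()
  idx <- vapply(
    as.integer(total),
    function(t) which(t >= cls$lo & t <= cls$hi),
    integer(1)
  )
  out <- cls[idx, c("label", "name", "lo", "hi")]
  out <- tibble::as_tibble(out)
  out$total <- as.integer(total)
  out[, c("total", "label", "name", "lo", "hi")]
}

#' Enumerate all feature-score combinations
#'
#' Brute-force oracle: all 4 x 3 x 3 x 4 = 144 feature vectors with their
#' totals and classes. Used for exhaustive tests and stratified sampling.
#'
#' @return A tibble with the four score columns, `total` and `class`.
#' @export
enumerate_combinations <- function() {
  grid <- expand.grid(
    angulation = 1:4, root_count = 1:3, root_curvature = 1:3, canal = 1:4,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- tibble::as_tibble(grid)
  grid$total <- as.integer(rowSums(grid))
  grid$class <- classify_score(grid$total)$label
  grid
}
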