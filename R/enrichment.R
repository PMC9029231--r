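# Core over-representation statistics: the OR ratio, the Additional Sites
# score, exact one-sided binomial significance, and the exhaustive
# ("flexible") threshold scan with the control-set site-frequency
# constraint.
#
# Notation: A sites in the test promoters (total length lenA bp), B sites in
# the control promoters (total length lenB bp), at a given score threshold.
# A candidate threshold is admissible only if the control-set site frequency
# 1000*B/lenB lies in [0.01, 0.2] sites/kb, keeping the binomial rate model
# in a regime where neither arm is saturated nor empty.

#' Over-representation ratio
#'
#' `(A/lenA) / (B/lenB)`: the per-length site frequency in the test set
#' relative to the control set. `B = 0` yields `Inf` as a flag; such points
#' are never admissible (frequency below 0.01/kb) and the flag is never
#' compared numerically.
#'
#' @param A,B Site counts in test and control sets.
#' @param lenA,lenB Total promoter lengths (bp), both positive.
#' @return The ratio (possibly `Inf`).
#' @export
or_ratio <- function(A, lenA, B, lenB) {
  if (any(lenA <= 0) || any(lenB <= 0)) abort("lenA and lenB must be > 0")
  ifelse(B == 0, Inf, (A / lenA) / (B / lenB))
}

#' Additional Sites score
#'
#' `A - B * lenA / lenB`: the excess of test-set sites over the number
#' expected at the control-set site frequency. May be negative.
#'
#' @inheritParams or_ratio
#' @return The AS score.
#' @export
additional_sites <- function(A, lenA, B, lenB) {
  if (any(lenB <= 0)) abort("lenB must be > 0")
  A - B * lenA / lenB
}

#' One-sided exact binomial significance of over-/under-representation
#'
#' Two exact parameterizations built from the same four numbers are
#' offered. `"conditional"` conditions on the total site count: sites fall
#' into the test arm with probability `lenA / (lenA + lenB)` under the null
#' of equal per-length frequency, `X ~ Binomial(A + B, lenA/(lenA + lenB))`,
#' over-representation p-value `P(X >= A)`. `"rate"` treats the control-set
#' site frequency as the reference rate and asks how surprising the test
#' count is at that rate: `X ~ Binomial(lenA, B/lenB)` over the `lenA`
#' scanned positions, p-value `P(X >= A)`. The rate model is the
#' construction used by threshold-optimizing site-frequency methods and is
#' what the enrichment pipeline reports; the conditional model is the
#' classical exact two-sample comparison. Under-representation p-values are
#' `P(X <= A)`; all tails are exact sums.
#'
#' @inheritParams or_ratio
#' @param sidedness `"over"` or `"under"`.
#' @param model `"conditional"` (default) or `"rate"`, as above.
#' @return p-value in `[0, 1]`.
#' @export
binomial_p <- function(A, B, lenA, lenB, sidedness = c("over", "under"),
                       model = c("conditional", "rate")) {
  sidedness <- match.arg(sidedness)
  model <- match.arg(model)
  if (any(A < 0) || any(B < 0)) abort("counts must be non-negative")
  if (any(lenA <= 0) || any(lenB <= 0)) abort("lenA and lenB must be > 0")
  if (model == "conditional") {
    n <- A + B
    p <- lenA / (lenA + lenB)
  } else {
    n <- round(lenA)
    p <- pmin(B / lenB, 1)
  }
  if (sidedness == "over") {
    pbinom(A - 1, n, p, lower.tail = FALSE)
  } else {
    pbinom(A, n, p)
  }
}

#' All candidate thresholds for one PWM
#'
#' The flexible-threshold procedure tests every threshold that can change
#' the counts: the sorted unique (conserved) scores observed in the test and
#' control hit lists combined.
#'
#' @param test_scores,control_scores Numeric score vectors (the
#'   `conserved_score` columns of the two hit tables).
#' @return Ascending unique scores; empty input gives an empty vector.
#' @export
candidate_thresholds <- function(test_scores, control_scores) {
  sort(unique(c(test_scores, control_scores)))
}

#' Exhaustive threshold scan
#'
#' Evaluates every candidate threshold `t` (inclusive: a site counts when
#' its score is `>= t`), filling in counts, OR ratio, Additional Sites,
#' the one-sided binomial p-value and the control-frequency admissibility
#' flag.
#'
#' @param test_scores,control_scores Score vectors for one PWM under one
#'   window/conservation setting.
#' @param lenA,lenB Total lengths (bp) of the test and control sets.
#' @param control_freq_bounds Admissible control-site frequency band in
#'   sites/kb, default `c(0.01, 0.2)`.
#' @param sidedness Direction of the binomial test, default `"over"`.
#' @param model Binomial parameterization (see [binomial_p()]); the
#'   pipeline default is the control-rate reference model.
#' @return A tibble with one row per candidate threshold: `threshold`, `A`,
#'   `B`, `len_test`, `len_control`, `or_ratio`, `additional_sites`,
#'   `p_value`, `admissible`.
#' @export
scan_thresholds <- function(test_scores, control_scores, lenA, lenB,
                            control_freq_bounds = c(0.01, 0.2),
                            sidedness = "over", model = "rate") {
  thr <- candidate_thresholds(test_scores, control_scores)
  if (length(thr) == 0) {
    return(tibble(threshold = numeric(), A = integer(), B = integer(),
                  len_test = numeric(), len_control = numeric(),
                  or_ratio = numeric(), additional_sites = numeric(),
                  p_value = numeric(), admissible = logical()))
  }
  # every observed score equals some candidate threshold, so counts >= t
  # follow from a reverse cumulative tally over threshold indices
  count_ge <- function(scores) {
    if (length(scores) == 0) return(integer(length(thr)))
    idx <- findInterval(scores, thr)
    rev(cumsum(rev(tabulate(idx, nbins = length(thr)))))
  }
  A <- count_ge(test_scores)
  B <- count_ge(control_scores)
  freq_b <- 1000 * B / lenB
  tibble(
    threshold = thr,
    A = A,
    B = B,
    len_test = lenA,
    len_control = lenB,
    or_ratio = or_ratio(A, lenA, B, lenB),
    additional_sites = additional_sites(A, lenA, B, lenB),
    p_value = binomial_p(A, B, lenA, lenB, sidedness, model),
    admissible = freq_b >= control_freq_bounds[1] &
      freq_b <= control_freq_bounds[2]
  )
}

#' Pick the optimal threshold
#'
#' Among admissible scan points, returns the maximizer of the configured
#' objective. Under the `"as"` objective a minimum OR ratio (default 2.5) is
#' additionally required. Ties are broken by smaller p-value, then larger
#' threshold.
#'
#' @param points A [scan_thresholds()] tibble.
#' @param objective `"or"` (maximize the OR ratio) or `"as"` (maximize
#'   Additional Sites).
#' @param min_or Minimum OR ratio imposed under the `"as"` objective.
#' @return A one-row tibble (the winning point), or a zero-row tibble when
#'   no point is admissible.
#' @export
optimize_threshold <- function(points, objective = c("as", "or"),
                               min_or = 2.5) {
  objective <- match.arg(objective)
  ok <- points$admissible
  if (objective == "as") ok <- ok & points$or_ratio >= min_or
  cand <- points[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(points[0, , drop = FALSE])
  obj <- if (objective == "or") cand$or_ratio else cand$additional_sites
  best <- order(-obj, cand$p_value, -cand$threshold)[1]
  cand[best, , drop = FALSE]
}
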