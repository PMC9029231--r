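# Information-content-weighted position weight models and window scoring.
#
# Scoring convention (matrix-similarity style): with column-stochastic
# frequencies f(b,i) and per-position information weight
#   ci[i] = sum_b f(b,i) * ln(4 f(b,i)),
# a window s gets raw score sum_i ci[i] * f(s_i, i), min/max-normalized over
# the attainable range so that scores live in [0, 1] (reported as percent in
# figures). ci[i] is zero exactly for a uniform column, so uninformative
# positions do not contribute.

#' Build an information-weighted position weight model from a PFM
#'
#' @param x A [pfm()] object.
#' @param pseudocount Count added to every cell before column normalization
#'   (default 0.01); avoids `ln 0` while perturbing dominant columns
#'   negligibly.
#' @return An object of class `flex_pwm` with fields `f` (4 x L
#'   column-stochastic frequencies), `ci` (per-position information weight,
#'   nats), `raw_min`/`raw_max` (attainable raw-score bounds) and the 4 x L
#'   weight matrix used for scoring.
#' @export
build_pwm <- function(x, pseudocount = 0.01) {
  if (!inherits(x, "flex_pfm")) abort("`x` must be a flex_pfm")
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    abort("`pseudocount` must be >= 0")
  }
  counts <- x$counts + pseudocount
  f <- sweep(counts, 2, colSums(counts), "/")
  # 0 * log(0) := 0 (only reachable with pseudocount = 0)
  fl <- f * log(4 * f)
  fl[f == 0] <- 0
  ci <- colSums(fl)
  ci[ci < 0] <- 0   # guard tiny negative round-off on near-uniform columns
  v <- sweep(f, 2, ci, "*")          # per-base, per-position contribution
  raw_min <- sum(apply(v, 2, min))
  raw_max <- sum(apply(v, 2, max))
  if (!(raw_max > raw_min + 1e-12)) {
    abort(sprintf("matrix '%s' rejected: uninformative (raw score range empty)",
                  x$motif_id))
  }
  m <- ncol(f)
  # weight matrices indexed [position, base-code]; minus strand scores the
  # reverse complement without touching the sequence
  w_plus <- t(v)
  w_minus <- w_plus[m:1, 4:1, drop = FALSE]
  dimnames(w_plus) <- dimnames(w_minus) <- NULL
  structure(
    list(motif_id = x$motif_id, tf_name = x$tf_name, source = x$source,
         f = f, ci = ci, raw_min = raw_min, raw_max = raw_max,
         length = m, w_plus = w_plus, w_minus = w_minus),
    class = "flex_pwm"
  )
}

#' @export
print.flex_pwm <- function(x, ...) {
  cat(sprintf("<flex_pwm> %s (%s), length %d, info %.2f nats\n",
              x$motif_id, x$tf_name, x$length, sum(x$ci)))
  invisible(x)
}

# Normalized scores for every window of `codes` (integer-encoded sequence)
# on one strand. Returns numeric vector of length L - m + 1 with NA where
# the window contains a non-ACGT base.
window_scores_codes <- function(pwm, codes, strand = "+") {
  m <- pwm$length
  L <- length(codes)
  n_off <- L - m + 1L
  if (n_off < 1L) return(numeric(0))
  w <- if (strand == "+") pwm$w_plus else pwm$w_minus
  s <- numeric(n_off)
  bad <- logical(n_off)
  for (j in seq_len(m)) {
    cj <- codes[j:(j + n_off - 1L)]
    na_j <- is.na(cj)
    if (any(na_j)) {
      bad <- bad | na_j
      cj[na_j] <- 1L
    }
    s <- s + w[j, cj]
  }
  s <- (s - pwm$raw_min) / (pwm$raw_max - pwm$raw_min)
  s <- pmin(pmax(s, 0), 1)   # clamp float round-off; scores live in [0, 1]
  s[bad] <- NA_real_
  s
}

#' Score one sequence window against a PWM
#'
#' @param pwm A [build_pwm()] model.
#' @param sequence Promoter sequence (string over A,C,G,T,N).
#' @param offset 0-based start of the window within `sequence`.
#' @param strand `"+"` scores the window as written; `"-"` scores its
#'   reverse complement.
#' @return Normalized score in `[0, 1]`, or `NA` if the window contains `N`
#'   (such windows can never be hits).
#' @export
score_window <- function(pwm, sequence, offset, strand = "+") {
  if (!inherits(pwm, "flex_pwm")) abort("`pwm` must be a flex_pwm")
  strand <- match.arg(strand, c("+", "-"))
  codes <- encode_dna(sequence)
  m <- pwm$length
  if (offset < 0 || offset + m > length(codes)) {
    abort(sprintf("offset %d out of range for a %d bp window in a %d bp sequence",
                  offset, m, length(codes)))
  }
  win <- codes[(offset + 1L):(offset + m)]
  if (anyNA(win)) return(NA_real_)
  w <- if (strand == "+") pwm$w_plus else pwm$w_minus
  raw <- sum(w[cbind(seq_len(m), win)])
  min(max((raw - pwm$raw_min) / (pwm$raw_max - pwm$raw_min), 0), 1)
}
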