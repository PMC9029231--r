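# Shared fixture and independent oracle implementations. Oracles are kept
# deliberately naive (double loops, explicit sums) so they are independent
# of the vectorized implementation paths they check.

fx <- worked_fixture()
fx_pool <- dplyr::bind_rows(fx$test, fx$control)

# naive O(L * m) scan oracle: every offset, both strands, via score_window
oracle_scan <- function(pwm, promoters, low_threshold) {
  rows <- list()
  for (k in seq_len(nrow(promoters))) {
    seq <- promoters$sequence[k]
    L <- nchar(seq)
    m <- pwm$length
    for (off in 0:(L - m)) {
      sp <- score_window(pwm, seq, off, "+")
      sm <- score_window(pwm, seq, off, "-")
      if (is.na(sp) && is.na(sm)) next
      sc <- max(sp, sm, na.rm = TRUE)
      strand <- if (!is.na(sm) && (is.na(sp) || sm > sp)) "-" else "+"
      if (sc >= low_threshold) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          promoter_id = promoters$gene_id[k],
          offset = off + promoters$offset0[k],
          strand = strand, score = sc,
          center = off + promoters$offset0[k] + m %/% 2L
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# exact one-sided binomial tail by explicit log-space term summation
oracle_binomial_p <- function(A, B, lenA, lenB, sidedness = "over") {
  n <- A + B
  p <- lenA / (lenA + lenB)
  ks <- if (sidedness == "over") A:n else 0:A
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# exact rate-model upper tail P(X >= A), X ~ Bin(lenA, B/lenB), by explicit
# term summation; far tail summed directly to avoid cancellation
oracle_rate_binomial_p <- function(A, B, lenA, lenB) {
  n <- round(lenA)
  p0 <- B / lenB
  if (A == 0) return(1)
  if (p0 == 0) return(0)
  lterm <- function(k) lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)
  z <- (A - n * p0) / sqrt(n * p0 * (1 - p0))
  if (z > 3) {
    acc <- 0
    for (k in A:min(n, A + 50000L)) {
      tm <- exp(lterm(k))
      acc <- acc + tm
      if (tm < acc * 1e-17) break
    }
    acc
  } else {
    1 - sum(exp(lterm(0:(A - 1))))
  }
}

# brute-force optimizer: filter-and-compare loop over all points
oracle_optimize <- function(points, objective, min_or = 2.5) {
  best <- NULL
  for (i in seq_len(nrow(points))) {
    r <- points[i, ]
    if (!r$admissible) next
    if (objective == "as" && r$or_ratio < min_or) next
    val <- if (objective == "or") r$or_ratio else r$additional_sites
    if (is.null(best)) { best <- r; best_val <- val; next }
    if (val > best_val ||
        (val == best_val && r$p_value < best$p_value) ||
        (val == best_val && r$p_value == best$p_value &&
         r$threshold > best$threshold)) {
      best <- r
      best_val <- val
    }
  }
  best
}

# per-threshold recount oracle for scan_thresholds
oracle_counts <- function(scores, t) sum(scores >= t)

# conservation predicate oracle: "mouse >= t and >= n species windows >= t"
oracle_conservation_pass <- function(mouse, species_scores, n_required, t) {
  if (n_required == 0) return(mouse >= t)
  mouse >= t & sum(species_scores >= t, na.rm = TRUE) >= n_required
}

scan_fragments_for_test <- function(pwm, fragments, low_threshold) {
  flexsite:::scan_fragments(pwm, fragments, low_threshold)
}

random_pfm <- function(m = 6, seed = NULL) {
  gen <- function() {
    counts <- matrix(stats::runif(4 * m, 0.2, 10), nrow = 4)
    pfm(counts, paste0("rnd_", paste(sample(letters, 5), collapse = "")))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
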