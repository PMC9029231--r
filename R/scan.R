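# Promoter scanning: emit candidate sites above a permissive low threshold.
# Both strands are scored at every offset; where both pass, only the higher
# scoring strand is kept (one hit per position), preventing double counting
# of palindromic sites. Offsets are 0-based, in full-promoter coordinates.

#' Scan a promoter set for candidate PWM matches
#'
#' @param pwm A [build_pwm()] model.
#' @param promoters A promoter-set tibble.
#' @param low_threshold Permissive normalized-score threshold in `[0, 1)`;
#'   candidate sites scoring at least this are emitted. Calibrate with
#'   [calibrate_low_threshold()] so matches are frequent (>= ~1 site/kb).
#' @return A tibble of hits: `promoter_id`, `offset` (0-based window start),
#'   `strand`, `score`, `center` (offset + floor(motif_length/2), the
#'   position used for cross-species mapping and for grouping).
#' @export
scan_promoters <- function(pwm, promoters, low_threshold) {
  if (!inherits(pwm, "flex_pwm")) abort("`pwm` must be a flex_pwm")
  if (low_threshold < 0 || low_threshold >= 1) {
    abort("`low_threshold` must be in [0, 1)")
  }
  m <- pwm$length
  half <- m %/% 2L
  res <- purrr::pmap(
    list(promoters$gene_id, promoters$sequence, promoters$offset0),
    function(id, seq, off0) {
      codes <- encode_dna(seq)
      sp <- window_scores_codes(pwm, codes, "+")
      if (length(sp) == 0) return(NULL)
      sm <- window_scores_codes(pwm, codes, "-")
      # best strand per offset; NA (N in window) drops the offset
      use_minus <- !is.na(sm) & (is.na(sp) | sm > sp)
      sc <- ifelse(use_minus, sm, sp)
      keep <- which(!is.na(sc) & sc >= low_threshold)
      if (length(keep) == 0) return(NULL)
      tibble(
        promoter_id = id,
        offset = keep - 1L + off0,
        strand = ifelse(use_minus[keep], "-", "+"),
        score = sc[keep]
      )
    }
  )
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(promoter_id = character(), offset = integer(),
                  strand = character(), score = numeric())
  }
  dplyr::mutate(out, center = .data$offset + half)
}

#' Calibrate the permissive scanning threshold
#'
#' Chooses a low threshold yielding at least `per_kb` candidate matches per
#' kilobase on the given (control) promoter set: the threshold is the score
#' of the `ceiling(per_kb * total_kb)`-th best window.
#'
#' @param pwm A [build_pwm()] model.
#' @param promoters Promoter-set tibble to calibrate on.
#' @param per_kb Target candidate frequency, default 2 sites/kb.
#' @return A threshold in `[0, 1)`.
#' @export
calibrate_low_threshold <- function(pwm, promoters, per_kb = 2) {
  # score-only fast path: no hit tibbles, just the best-strand score vector
  scores <- unlist(lapply(promoters$sequence, function(seq) {
    codes <- encode_dna(seq)
    sp <- window_scores_codes(pwm, codes, "+")
    if (length(sp) == 0) return(numeric(0))
    sm <- window_scores_codes(pwm, codes, "-")
    sc <- pmax(sp, sm, na.rm = TRUE)
    sc[!is.na(sc)]
  }), use.names = FALSE)
  if (length(scores) == 0) return(0)
  k <- max(1L, ceiling(per_kb * total_length(promoters) / 1000))
  k <- min(k, length(scores))
  thr <- sort(scores, decreasing = TRUE)[k]
  min(max(0, thr), 1 - 1e-9)
}

#' Export hits as BED6
#'
#' chrom = promoter_id, 0-based half-open interval of the match window,
#' score = `round(1000 * normalized score)`.
#'
#' @param hits A hit tibble from [scan_promoters()].
#' @param pwm The model that produced the hits (for the window length and
#'   the BED name field).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, pwm, path) {
  bed <- tibble(
    chrom = hits$promoter_id,
    start = hits$offset,
    end = hits$offset + pwm$length,
    name = pwm$motif_id,
    score = round(1000 * hits$score),
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
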