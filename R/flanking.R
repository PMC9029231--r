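# Flanking-region analysis: composite-element detection by testing motif
# over-representation in the sequence immediately flanking previously
# identified anchor sites (e.g. CRE sites next to AP1 anchors), against
# random fixed-length fragments of the control promoter set.

#' Extract flanking fragments around anchor sites
#'
#' Takes `flank_bp` on either side of every anchor hit, clips to promoter
#' bounds, merges overlapping flank intervals, and masks out every anchor
#' match window (for that PWM) so no anchor sequence leaks into the
#' fragments. Fragments carry original promoter coordinates.
#'
#' @param anchor_hits Hit tibble (from one PWM's optimized result), offsets
#'   in full-promoter coordinates.
#' @param promoters The promoter set the hits were found in.
#' @param motif_length Anchor motif length in bp (or a `flex_pwm`).
#' @param flank_bp Flank width on each side, default 100.
#' @return A fragment tibble: `gene_id` (unique fragment id), `source_id`
#'   (originating promoter), `sequence`, `length`, `offset0` (0-based
#'   original coordinate of the fragment start).
#' @export
flanking_regions <- function(anchor_hits, promoters, motif_length,
                             flank_bp = 100) {
  if (inherits(motif_length, "flex_pwm")) motif_length <- motif_length$length
  m <- as.integer(motif_length)
  frs <- purrr::map(split(anchor_hits, anchor_hits$promoter_id),
    function(h) {
      id <- h$promoter_id[1]
      pr <- promoters[promoters$gene_id == id, ]
      if (nrow(pr) == 0) return(NULL)
      lo <- pr$offset0                      # first stored original coord
      hi <- pr$offset0 + pr$length          # one past last
      anchors <- IRanges::IRanges(start = h$offset + 1L, width = m)
      flanks <- c(
        IRanges::IRanges(start = h$offset - flank_bp + 1L, width = flank_bp),
        IRanges::IRanges(start = h$offset + m + 1L, width = flank_bp)
      )
      flanks <- IRanges::restrict(IRanges::reduce(flanks),
                                  start = lo + 1L, end = hi)
      frags <- IRanges::setdiff(flanks, anchors)
      if (length(frags) == 0) return(NULL)
      tibble(
        source_id = id,
        start = IRanges::start(frags) - 1L,   # back to 0-based
        end = IRanges::end(frags),
        sequence = substr(rep(pr$sequence, length(frags)),
                          IRanges::start(frags) - lo,
                          IRanges::end(frags) - lo)
      )
    })
  out <- dplyr::bind_rows(frs)
  if (nrow(out) == 0) {
    return(tibble(gene_id = character(), source_id = character(),
                  sequence = character(), length = integer(),
                  offset0 = integer()))
  }
  tibble(
    gene_id = sprintf("%s:%d-%d", out$source_id, out$start, out$end),
    source_id = out$source_id,
    sequence = out$sequence,
    length = nchar(out$sequence),
    offset0 = as.integer(out$start)
  )
}

#' Sample fixed-length control fragments
#'
#' Draws `n` fragments of `fragment_length` bp from the control promoters,
#' choosing each promoter with probability proportional to its number of
#' eligible start positions and the start uniformly.
#'
#' @param control_promoters Promoter-set tibble.
#' @param n Number of fragments.
#' @param fragment_length Fragment length (bp), default 200.
#' @return A fragment tibble (same shape as [flanking_regions()]).
#' @export
sample_control_fragments <- function(control_promoters, n,
                                     fragment_length = 200) {
  elig <- control_promoters$length - fragment_length + 1L
  ok <- which(elig >= 1L)
  if (length(ok) == 0) {
    abort(sprintf("no control promoter is at least %d bp", fragment_length))
  }
  pick <- ok[sample.int(length(ok), n, replace = TRUE, prob = elig[ok])]
  start_rel <- floor(runif(n) * elig[pick])      # 0-based within stored seq
  src <- control_promoters[pick, ]
  start0 <- as.integer(src$offset0 + start_rel)
  tibble(
    gene_id = sprintf("%s:%d-%d#%d", src$gene_id, start0,
                      start0 + fragment_length, seq_len(n)),
    source_id = src$gene_id,
    sequence = substr(src$sequence, start_rel + 1L,
                      start_rel + fragment_length),
    length = fragment_length,
    offset0 = start0
  )
}

# scan a fragment set and re-key hits to their source promoters so that
# conservation lookup and grouping see original coordinates
scan_fragments <- function(pwm, fragments, low_threshold) {
  fs <- fragments
  names(fs)[names(fs) == "gene_id"] <- ".frag_id"
  h <- scan_promoters(
    pwm,
    tibble(gene_id = fs$.frag_id, sequence = fs$sequence,
           length = fs$length, offset0 = fs$offset0),
    low_threshold
  )
  h$promoter_id <- fs$source_id[match(h$promoter_id, fs$.frag_id)]
  h
}

#' Over-representation analysis of flanking regions
#'
#' Applies the same scan/threshold-optimization machinery with anchor
#' flanking fragments as the test set and randomly sampled fixed-length
#' control fragments as the control set. Seed-reproducible.
#'
#' @param fragments Fragment tibble from [flanking_regions()].
#' @param control_promoters Control promoter set to sample fragments from.
#' @param pwms List of [pfm()]/[build_pwm()] objects to test.
#' @param bundles,n_required Conservation configuration (fragment hits are
#'   mapped back to original promoter coordinates, so ortholog bundles for
#'   the source promoters apply directly).
#' @param n_fragments Number of control fragments; default
#'   `max(1000, 5 * nrow(fragments))`.
#' @param fragment_length Control fragment length (bp), default 200.
#' @param seed RNG seed for the control-fragment draw.
#' @param objective,min_or,low_threshold,per_kb,control_freq_bounds,sidedness
#'   As in [run_enrichment()].
#' @param keep_hits Keep hit lists at the optimum.
#' @return A `flex_enrichment` tibble (window column reports the fragment
#'   configuration as `NA`).
#' @export
flanking_enrichment <- function(fragments, control_promoters, pwms,
                                bundles = list(), n_required = 0,
                                n_fragments = NULL, fragment_length = 200,
                                seed = 1L, objective = c("as", "or"),
                                min_or = 2.5, low_threshold = NULL,
                                per_kb = 2,
                                control_freq_bounds = c(0.01, 0.2),
                                sidedness = "over", keep_hits = TRUE) {
  objective <- match.arg(objective)
  if (nrow(fragments) == 0) abort("no flanking fragments to analyze")
  n_fragments <- n_fragments %||% max(1000L, 5L * nrow(fragments))
  if (n_fragments < 1) abort("`n_fragments` must be >= 1")
  ctrl_frags <- withr::with_seed(seed,
    sample_control_fragments(control_promoters, n_fragments, fragment_length))
  pwms <- as_pwm_list(pwms)
  lenA <- sum(fragments$length)
  lenB <- sum(ctrl_frags$length)
  rows <- list()
  for (pwm in pwms) {
    lt <- low_threshold %||% {
      cf <- tibble(gene_id = ctrl_frags$gene_id,
                   sequence = ctrl_frags$sequence,
                   length = ctrl_frags$length, offset0 = 0L)
      calibrate_low_threshold(pwm, cf, per_kb)
    }
    h_test <- scan_fragments(pwm, fragments, lt)
    h_ctrl <- scan_fragments(pwm, ctrl_frags, lt)
    cs_test <- conserved_from_matrix(
      h_test$score, species_score_matrix(h_test, pwm, bundles), n_required)
    cs_ctrl <- conserved_from_matrix(
      h_ctrl$score, species_score_matrix(h_ctrl, pwm, bundles), n_required)
    pts <- scan_thresholds(cs_test, cs_ctrl, lenA, lenB,
                           control_freq_bounds, sidedness)
    best <- optimize_threshold(pts, objective, min_or)
    if (nrow(best) == 0) next
    row <- tibble(motif_id = pwm$motif_id, tf_name = pwm$tf_name,
                  window = NA_integer_, n_required = n_required,
                  objective = objective, low_threshold = lt)
    row <- dplyr::bind_cols(row, best)
    if (keep_hits) {
      keep <- which(cs_test >= best$threshold)
      hh <- h_test[keep, , drop = FALSE]
      hh$conserved_score <- cs_test[keep]
      row$hits <- list(hh)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    obj_col <- if (objective == "or") out$or_ratio else out$additional_sites
    out <- out[order(-obj_col, out$motif_id), , drop = FALSE]
  }
  structure(out, class = c("flex_enrichment", class(out)),
            objective = objective, min_or = min_or)
}
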