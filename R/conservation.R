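# Cross-species conservation: ortholog bundles (per-species ortholog
# sequence + a mouse->ortholog position map), window rescoring at mapped
# positions, and the rank-based conserved score.
#
# The conserved score reduces the mouse score plus up-to-five ortholog
# window scores to a single number with the defining property that
# thresholding it at t is exactly the predicate "mouse score >= t AND the
# site's window scores >= t in at least n other species".

#' Construct an ortholog bundle
#'
#' @param species Species name.
#' @param sequences Named character vector of ortholog sequences
#'   (names = promoter_id). Promoters absent here are unaligned.
#' @param position_map Tibble with columns `promoter_id`, `mouse_pos`,
#'   `ortholog_pos` (both 0-based); pairs must be strictly increasing in
#'   both coordinates within a promoter. Positions absent from the map are
#'   unaligned (no interpolation is ever applied).
#' @return An object of class `flex_bundle`.
#' @export
ortholog_bundle <- function(species, sequences, position_map) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  need <- c("promoter_id", "mouse_pos", "ortholog_pos")
  if (!all(need %in% names(position_map))) {
    abort("position_map needs columns promoter_id, mouse_pos, ortholog_pos")
  }
  sequences <- toupper(sequences)
  maps <- split(position_map[c("mouse_pos", "ortholog_pos")],
                position_map$promoter_id)
  maps <- lapply(maps, function(df) {
    df <- df[order(df$mouse_pos), , drop = FALSE]
    if (is.unsorted(df$ortholog_pos, strictly = TRUE) ||
        anyDuplicated(df$mouse_pos)) {
      abort("position map must be strictly increasing in both coordinates")
    }
    stats::setNames(as.integer(df$ortholog_pos), df$mouse_pos)
  })
  unknown <- setdiff(names(maps), names(sequences))
  if (length(unknown)) {
    abort(sprintf("position map references promoters without ortholog sequence: %s",
                  paste(unknown, collapse = ", ")))
  }
  codes <- lapply(sequences, encode_dna)
  structure(list(species = species, sequences = sequences, codes = codes,
                 maps = maps),
            class = "flex_bundle")
}

# fast-path constructor used internally (maps already named int vectors)
new_flex_bundle <- function(species, sequences, maps) {
  structure(list(species = species, sequences = sequences,
                 codes = lapply(sequences, encode_dna), maps = maps),
            class = "flex_bundle")
}

#' @export
print.flex_bundle <- function(x, ...) {
  cat(sprintf("<flex_bundle> %s: %d aligned promoters\n",
              x$species, length(x$maps)))
  invisible(x)
}

#' Read an ortholog bundle from FASTA + TSV
#'
#' @param species Species name.
#' @param fasta_path FASTA of ortholog sequences (headers = promoter_id).
#' @param map_path 3-column TSV `promoter_id, mouse_pos, ortholog_pos`
#'   (0-based).
#' @return A `flex_bundle`.
#' @export
read_ortholog_bundle <- function(species, fasta_path, map_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  pm <- readr::read_tsv(map_path, col_types = "cii", comment = "#")
  ortholog_bundle(species, seqs, pm)
}

#' Write an ortholog bundle to FASTA + TSV
#' @param bundle A `flex_bundle`.
#' @param fasta_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ortholog_bundle <- function(bundle, fasta_path, map_path) {
  ss <- Biostrings::DNAStringSet(bundle$sequences)
  names(ss) <- names(bundle$sequences)
  Biostrings::writeXStringSet(ss, fasta_path, width = 80)
  pm <- purrr::imap(bundle$maps, function(mp, id) {
    tibble(promoter_id = id,
           mouse_pos = as.integer(names(mp)),
           ortholog_pos = unname(mp))
  })
  readr::write_tsv(dplyr::bind_rows(pm), map_path)
  invisible(c(fasta_path, map_path))
}

#' Map a mouse promoter position into an ortholog
#'
#' Exact lookup in the bundle's position map; returns `NA` when the promoter
#' or the position is unaligned.
#'
#' @param bundle A `flex_bundle`.
#' @param promoter_id Promoter identifier.
#' @param mouse_pos 0-based mouse position.
#' @return 0-based ortholog position, or `NA`.
#' @export
map_position <- function(bundle, promoter_id, mouse_pos) {
  mp <- bundle$maps[[promoter_id]]
  if (is.null(mp)) return(NA_integer_)
  out <- unname(mp[as.character(mouse_pos)])
  if (length(out) == 0) NA_integer_ else out
}

# vectorised ortholog window score for hits on one promoter
ortholog_scores_one <- function(pwm, bundle, promoter_id, offsets) {
  m <- pwm$length
  half <- m %/% 2L
  mp <- bundle$maps[[promoter_id]]
  out <- rep(NA_real_, length(offsets))
  if (is.null(mp)) return(out)
  codes <- bundle$codes[[promoter_id]]
  L <- length(codes)
  centers <- offsets + half
  mapped <- unname(mp[as.character(centers)])
  for (i in seq_along(offsets)) {
    mc <- mapped[i]
    if (is.na(mc)) next
    start <- mc - half                       # 0-based window start
    if (start < 0 || start + m > L) next
    win <- codes[(start + 1L):(start + m)]
    if (anyNA(win)) next
    raw_p <- sum(pwm$w_plus[cbind(seq_len(m), win)])
    raw_m <- sum(pwm$w_minus[cbind(seq_len(m), win)])
    out[i] <- (max(raw_p, raw_m) - pwm$raw_min) / (pwm$raw_max - pwm$raw_min)
  }
  out
}

#' Score the ortholog window aligned to a mouse hit
#'
#' Maps the central position of the mouse match (offset +
#' floor(motif_length/2)) through the bundle's position map, extracts the
#' motif-length ungapped ortholog window centred there, and returns the
#' best-of-both-strands normalized score. `NA` when the position is
#' unaligned, the window runs out of bounds, or it contains `N`.
#'
#' @param pwm A [build_pwm()] model.
#' @param bundle A `flex_bundle`.
#' @param promoter_id Promoter identifier.
#' @param offset 0-based start of the mouse match window.
#' @return Normalized score in `[0, 1]`, or `NA`.
#' @export
score_ortholog_window <- function(pwm, bundle, promoter_id, offset) {
  ortholog_scores_one(pwm, bundle, promoter_id, offset)[1]
}

#' Rank-based conserved score
#'
#' With `n_required = 0` the mouse score is returned unchanged. With
#' `n_required >= 1` the score is `min(mouse_score, n-th highest available
#' species score)`, and 0 when fewer than `n_required` species have a score:
#' thresholding the result at `t` is then exactly "mouse >= t and at least
#' n species windows >= t".
#'
#' @param mouse_score Normalized mouse score.
#' @param species_scores Numeric vector of ortholog window scores; `NA`
#'   entries (unaligned species) are dropped.
#' @param n_required Number of non-mouse species required to be conserved
#'   (0-5).
#' @return Conserved score in `[0, 1]`.
#' @export
conserved_score <- function(mouse_score, species_scores, n_required) {
  if (n_required < 0) abort("`n_required` must be >= 0")
  if (n_required == 0) return(mouse_score)
  ss <- sort(species_scores[!is.na(species_scores)], decreasing = TRUE)
  if (length(ss) < n_required) return(0)
  min(mouse_score, ss[n_required])
}

#' Attach per-species and conserved scores to a hit table
#'
#' @param hits Hit tibble from [scan_promoters()] (offsets in full-promoter
#'   coordinates).
#' @param pwm The model that produced the hits.
#' @param bundles List of `flex_bundle` objects (one per species).
#' @param n_required Conservation requirement `n` (0 .. length(bundles)).
#' @return `hits` with one score column per species and a `conserved_score`
#'   column for the configured `n`.
#' @export
add_conserved_scores <- function(hits, pwm, bundles, n_required) {
  if (n_required > length(bundles)) {
    abort("`n_required` exceeds the number of species bundles")
  }
  if (nrow(hits) == 0) {
    hits$conserved_score <- numeric(0)
    return(hits)
  }
  if (n_required == 0 && length(bundles) == 0) {
    hits$conserved_score <- hits$score
    return(hits)
  }
  sp_mat <- matrix(NA_real_, nrow = nrow(hits), ncol = length(bundles))
  idx <- split(seq_len(nrow(hits)), hits$promoter_id)
  for (b in seq_along(bundles)) {
    for (ii in idx) {
      sp_mat[ii, b] <- ortholog_scores_one(
        pwm, bundles[[b]], hits$promoter_id[ii[1]], hits$offset[ii])
    }
  }
  colnames(sp_mat) <- purrr::map_chr(bundles, "species")
  for (nm in colnames(sp_mat)) hits[[paste0("score_", nm)]] <- sp_mat[, nm]
  if (n_required == 0) {
    hits$conserved_score <- hits$score
  } else {
    nth <- apply(sp_mat, 1, function(v) {
      v <- sort(v[!is.na(v)], decreasing = TRUE)
      if (length(v) < n_required) -Inf else v[n_required]
    })
    hits$conserved_score <- pmax(0, pmin(hits$score, nth))
  }
  hits
}
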