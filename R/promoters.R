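# Promoter sets as tibbles. A promoter sequence is written 5'->3' on the
# gene's sense strand with the TSS at the 3' end, i.e. the last base is the
# TSS-adjacent one; truncating to a window keeps the TSS-proximal (3') bp.
# `offset0` records the original coordinate of the first stored base so hit
# offsets can always be reported in full-promoter coordinates.

#' Construct a promoter set
#'
#' @param gene_id Character vector of unique promoter/gene identifiers.
#' @param sequence Character vector of upstream sequences over `A,C,G,T,N`,
#'   each at most 5000 bp, TSS at the 3' end.
#' @param label Optional set label (`"test"` or `"control"`).
#' @return A tibble with columns `gene_id`, `sequence`, `length`, `offset0`.
#' @export
promoter_set <- function(gene_id, sequence, label = NULL) {
  if (anyDuplicated(gene_id)) abort("gene_ids must be unique")
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGTN]", sequence))) {
    abort("sequences may only contain A, C, G, T, N")
  }
  out <- tibble(
    gene_id = unname(as.character(gene_id)),
    sequence = unname(sequence),
    length = nchar(sequence),
    offset0 = 0L
  )
  if (any(out$length > 5000)) abort("promoter sequences are capped at 5 kb")
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Total promoter set length in bp
#' @param promoters A promoter-set tibble.
#' @return Integer total bp (the `lenA`/`lenB` of the enrichment statistics).
#' @export
total_length <- function(promoters) sum(promoters$length)

#' Read promoters from FASTA
#'
#' Headers become `gene_id`; an optional `win=<bp>` token in the header
#' truncates that entry to its TSS-proximal `<bp>` bases on load.
#'
#' @param path FASTA file path.
#' @param label Optional set label.
#' @return A promoter-set tibble.
#' @export
read_promoters <- function(path, label = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  out <- promoter_set(ids, as.character(ss), label = label)
  win <- stringr::str_match(headers, "\\bwin=(\\d+)\\b")[, 2]
  win <- suppressWarnings(as.integer(win))
  if (any(!is.na(win))) {
    keep <- pmin(out$length, ifelse(is.na(win), out$length, win))
    out <- truncate_promoters(out, keep, per_entry = TRUE)
  }
  out
}

#' Write a promoter set to FASTA
#' @param promoters A promoter-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- promoters$gene_id
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}

#' Truncate promoters to an analysis window
#'
#' Keeps the TSS-proximal `window` bp of each promoter (the 3' end of the
#' stored sequence). `offset0` is advanced so downstream hit offsets remain
#' in original full-promoter coordinates.
#'
#' @param promoters A promoter-set tibble.
#' @param window Window length in bp (scalar, or per-entry when
#'   `per_entry = TRUE`).
#' @param per_entry Recycle `window` per entry instead of applying one
#'   scalar window.
#' @return A promoter-set tibble.
#' @export
truncate_promoters <- function(promoters, window, per_entry = FALSE) {
  if (!per_entry && length(window) != 1) abort("`window` must be a scalar")
  keep <- pmin(promoters$length, as.integer(window))
  trim <- promoters$length - keep
  dplyr::mutate(
    promoters,
    sequence = substr(.data$sequence, trim + 1L, .data$length),
    offset0 = .data$offset0 + trim,
    length = keep
  )
}
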