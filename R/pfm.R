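# Position frequency matrices: construction and parsers for the two standard
# plain-text interchange formats (JASPAR and TRANSFAC).

#' Create a position frequency matrix
#'
#' A PFM stores raw base counts (or frequencies) per motif position. Columns
#' are positions, rows are the bases A, C, G, T.
#'
#' @param counts A 4 x L numeric matrix (rows A,C,G,T) or an L x 4 matrix,
#'   which is transposed. All entries must be non-negative and every position
#'   must have a positive column total.
#' @param motif_id Identifier, e.g. `"MA0099.3"` or `"V$AP1_C"`.
#' @param tf_name Transcription factor name (defaults to `motif_id`).
#' @param source One of `"JASPAR_CORE"`, `"JASPAR_PBM"`, `"TRANSFAC"`,
#'   `"CUSTOM"`.
#' @return An object of class `flex_pfm`.
#' @export
pfm <- function(counts, motif_id, tf_name = motif_id, source = "CUSTOM") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix")
  }
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) abort("`counts` must have 4 base rows (A,C,G,T)")
  if (ncol(counts) < 2) abort("motif length must be at least 2")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("`counts` must be finite and non-negative")
  }
  if (any(colSums(counts) <= 0)) abort("every position needs a positive total")
  source <- match.arg(source, c("JASPAR_CORE", "JASPAR_PBM", "TRANSFAC", "CUSTOM"))
  rownames(counts) <- DNA_BASES
  structure(
    list(motif_id = motif_id, tf_name = tf_name, source = source,
         counts = counts),
    class = "flex_pfm"
  )
}

#' @export
print.flex_pfm <- function(x, ...) {
  cat(sprintf("<flex_pfm> %s (%s, %s), length %d\n",
              x$motif_id, x$tf_name, x$source, ncol(x$counts)))
  print(round(x$counts, 3))
  invisible(x)
}

#' Motif length of a PFM or PWM
#' @param x A `flex_pfm` or `flex_pwm`.
#' @return Integer motif length in bp.
#' @export
motif_length <- function(x) {
  if (inherits(x, "flex_pfm")) return(ncol(x$counts))
  if (inherits(x, "flex_pwm")) return(x$length)
  abort("not a flex_pfm / flex_pwm")
}

#' Build a PFM from a consensus string
#'
#' Convenience constructor used by the synthetic-data generators and in
#' examples: at each position the consensus base receives weight `dominance`
#' and the other three split the remainder equally. IUPAC two-fold codes
#' (R,Y,S,W,K,M) split `dominance` over their two bases; `N` is uniform.
#'
#' @param consensus Consensus string, e.g. `"TGACTCA"` for an AP1-like site.
#' @param motif_id,tf_name,source Passed to [pfm()].
#' @param dominance Probability mass on the consensus base(s), default 0.85.
#' @param scale Pseudo-count total per column (counts = frequencies * scale).
#' @return A `flex_pfm`.
#' @export
pfm_from_consensus <- function(consensus, motif_id = consensus,
                               tf_name = motif_id, source = "CUSTOM",
                               dominance = 0.85, scale = 100) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                N = DNA_BASES)
  letters_ <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  cols <- lapply(letters_, function(ch) {
    on <- iupac[[ch]]
    if (is.null(on)) abort(sprintf("unsupported consensus letter '%s'", ch))
    p <- rep((1 - dominance) / (4 - length(on)), 4)
    if (length(on) == 4) p <- rep(0.25, 4)
    names(p) <- DNA_BASES
    if (length(on) < 4) p[on] <- dominance / length(on)
    p
  })
  pfm(matrix(unlist(cols), nrow = 4) * scale, motif_id, tf_name, source)
}

#' Read motif matrices in JASPAR text format
#'
#' Parses multi-record JASPAR `.jaspar`/`.pfm` text: each record is a header
#' line `>ID name` followed by four base rows, either bracketed
#' (`A [ 0 4 ... ]`) or bare numbers. Rows are mapped to A,C,G,T in file
#' order, as the format prescribes.
#'
#' @param path Path to the file, or a character vector of lines.
#' @param source Collection tag stored on each matrix.
#' @return A list of [pfm()] objects.
#' @export
read_jaspar <- function(path, source = "JASPAR_CORE") {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("no JASPAR records ('>' headers) found")
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[seq(s + 1L, length.out = e - s)]
    if (length(body) != 4) {
      abort(sprintf("record '%s': expected 4 base rows, found %d",
                    motif_id, length(body)))
    }
    rows <- lapply(seq_along(body), function(i) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(body[i]))
      ln <- gsub("\\[|\\]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(vals) == 0 || anyNA(vals)) {
        abort(sprintf("record '%s', row %d: non-numeric cell", motif_id, i))
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("record '%s': rows of unequal length", motif_id))
    }
    pfm(do.call(rbind, rows), motif_id, tf_name, source)
  })
}

#' Read motif matrices in TRANSFAC format
#'
#' Parses TRANSFAC `.dat` matrix records: `AC`/`ID` lines, a `P0` column
#' header, numbered position lines carrying four counts plus a consensus
#' letter, terminated by `//`. The TRANSFAC identifier (e.g. `V$AP1_C`) is
#' retained as `motif_id`.
#'
#' @param path Path to the file, or a character vector of lines.
#' @return A list of [pfm()] objects with `source = "TRANSFAC"`.
#' @export
read_transfac <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list())
  recs <- list()
  cur <- NULL
  terminated <- TRUE
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    rest <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "AC" || (is.null(cur) && tag == "ID")) {
      if (!is.null(cur) && !terminated) abort("missing '//' terminator")
      cur <- list(ac = rest, id = rest, rows = list(), nums = integer())
      terminated <- FALSE
      if (tag == "ID") cur$id <- rest
      next
    }
    if (is.null(cur)) next
    if (tag == "ID") { cur$id <- rest; next }
    if (tag == "//") {
      if (!identical(cur$nums, seq_along(cur$nums))) {
        abort(sprintf("record '%s': position lines out of order", cur$id))
      }
      counts <- do.call(rbind, cur$rows)
      recs[[length(recs) + 1L]] <- pfm(counts, cur$id, cur$id, "TRANSFAC")
      cur <- NULL
      terminated <- TRUE
      next
    }
    if (grepl("^\\d+$", tag) || grepl("^\\d", tag)) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      num <- suppressWarnings(as.integer(toks[1]))
      if (is.na(num)) next
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (length(toks) < 5 || anyNA(vals)) {
        abort(sprintf("record '%s': malformed position line '%s'", cur$id, ln))
      }
      cur$rows[[length(cur$rows) + 1L]] <- vals
      cur$nums <- c(cur$nums, num)
    }
    # P0 / XX / other annotation lines are skipped
  }
  if (!is.null(cur) && !terminated) abort("missing '//' terminator")
  recs
}

#' Idealized example motifs
#'
#' Synthetic consensus-derived matrices used in examples, tests and the
#' simulators: an AP1-like TPA-response element `TGACTCA`, the CRE-like
#' `TGACGTCA` (AP1 with one extra central base), an SRF-like CArG box and a
#' GC-box decoy. These are constructed in code from their consensus with a
#' per-position dominance of 0.95 (comparable to the near-deterministic core
#' positions of curated AP1/CREB matrices), not taken from any motif
#' database.
#'
#' @return A `flex_pfm`.
#' @export
motif_ap1 <- function() pfm_from_consensus("TGACTCA", "AP1_syn", "AP1", dominance = 0.95)

#' @rdname motif_ap1
#' @export
motif_cre <- function() pfm_from_consensus("TGACGTCA", "CRE_syn", "CREB1", dominance = 0.95)

#' @rdname motif_ap1
#' @export
motif_srf <- function() pfm_from_consensus("CCWWAWWWGG", "SRF_syn", "SRF", dominance = 0.95)

#' @rdname motif_ap1
#' @export
motif_gcbox <- function() pfm_from_consensus("GGGGCGGGG", "GC_syn", "SP1", dominance = 0.95)
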