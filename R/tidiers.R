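# broom-style tidiers for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment result
#'
#' Returns the per-setting result table as a plain tibble, dropping the
#' hit-list column.
#'
#' @param x A `flex_enrichment` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.flex_enrichment <- function(x, ...) {
  out <- as_tibble(x[setdiff(names(x), "hits")])
  class(out) <- setdiff(class(out), "flex_enrichment")
  out
}

#' Summarise an enrichment result in one row
#'
#' @param x A `flex_enrichment` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of settings and motifs reported, the
#'   objective, the best motif and its objective value and p-value.
#' @exportS3Method generics::glance
glance.flex_enrichment <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(n_results = 0L, n_motifs = 0L,
                  objective = attr(x, "objective") %||% NA_character_,
                  best_motif = NA_character_, best_value = NA_real_,
                  best_p = NA_real_))
  }
  obj <- objective_value(x)
  i <- which.max(obj)
  tibble(
    n_results = nrow(x),
    n_motifs = dplyr::n_distinct(x$motif_id),
    objective = attr(x, "objective"),
    best_motif = x$motif_id[i],
    best_value = obj[i],
    best_p = x$p_value[i]
  )
}
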