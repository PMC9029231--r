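# Regulatory-class gene classification for a two-genotype (WT / knockout)
# injury time course. Genes are classified per timepoint from two contrasts:
# WT injured vs WT uninjured (axotomy regulation) and KO vs WT at the same
# timepoint (the knockout effect), then combined:
#
#   WT regulation   KO relative to WT   class
#   up              lower               JunUP    (Jun-upregulated)
#   down            higher              JunDOWN  (Jun-downregulated)
#   up or none      higher              AltUP    (alternative upregulated)
#   down or none    lower               AltDOWN  (alternative repressed)
#   anything else                       none
#
# JunUP genes are further split into completely Jun-dependent (no residual
# axotomy upregulation in the KO) and partially dependent (still upregulated
# in the KO, but significantly less than in WT).

#' Call the regulation direction of one contrast
#'
#' `"up"` when `log2FC >= log2(fc_cut)` and `fdr < fdr_cut`; `"down"` when
#' `log2FC <= -log2(fc_cut)` and `fdr < fdr_cut`; otherwise `"none"`. The
#' fold-change boundary is inclusive on the log2 scale; missing values give
#' `"none"`.
#'
#' @param log2fc Log2 fold changes.
#' @param fdr Adjusted p-values.
#' @param fc_cut Fold-change cutoff (> 1), default 1.5.
#' @param fdr_cut FDR cutoff (strict `<`), default 0.01.
#' @return Character vector over `{"up", "down", "none"}`.
#' @export
call_regulation <- function(log2fc, fdr, fc_cut = 1.5, fdr_cut = 0.01) {
  if (fc_cut <= 1) abort("`fc_cut` must be > 1")
  lfc <- log2(fc_cut)
  sig <- !is.na(fdr) & !is.na(log2fc) & fdr < fdr_cut
  dplyr::case_when(
    sig & log2fc >= lfc ~ "up",
    sig & log2fc <= -lfc ~ "down",
    TRUE ~ "none"
  )
}

# Table-driven class map: (wt_direction, ko_relative) -> class
.class_map <- function(wt_dir, ko_rel) {
  dplyr::case_when(
    wt_dir == "up" & ko_rel == "lower" ~ "JunUP",
    wt_dir == "down" & ko_rel == "higher" ~ "JunDOWN",
    wt_dir %in% c("up", "none") & ko_rel == "higher" ~ "AltUP",
    wt_dir %in% c("down", "none") & ko_rel == "lower" ~ "AltDOWN",
    TRUE ~ "none"
  )
}

#' Classify genes into regulatory classes per timepoint
#'
#' Expects a tidy contrast table with one row per gene x timepoint and
#' columns `gene`, `timepoint`, `wt_log2fc`, `wt_fdr` (WT injured vs WT
#' uninjured), `ko_vs_wt_log2fc`, `ko_vs_wt_fdr` (KO vs WT at the same
#' timepoint), and optionally `ko_log2fc`, `ko_fdr` (KO injured vs KO
#' uninjured) for the dependence call.
#'
#' @param contrasts The contrast tibble.
#' @param fc_cut,fdr_cut Cutoffs applied to every contrast (one global
#'   pair).
#' @return The input with `wt_direction`, `ko_relative`, `class`,
#'   `dependence` (`"complete"`/`"partial"` for JunUP rows, `NA`
#'   otherwise), `timecourse_complete` (per gene: JunUP at some timepoint
#'   and never axotomy-upregulated in the KO at any timepoint), and
#'   `missing_data` flag columns.
#' @export
classify_genes <- function(contrasts, fc_cut = 1.5, fdr_cut = 0.01) {
  need <- c("gene", "timepoint", "wt_log2fc", "wt_fdr",
            "ko_vs_wt_log2fc", "ko_vs_wt_fdr")
  miss <- setdiff(need, names(contrasts))
  if (length(miss)) {
    abort(paste("contrast table lacks columns:", paste(miss, collapse = ", ")))
  }
  out <- dplyr::mutate(
    contrasts,
    missing_data = is.na(.data$wt_log2fc) | is.na(.data$wt_fdr) |
      is.na(.data$ko_vs_wt_log2fc) | is.na(.data$ko_vs_wt_fdr),
    wt_direction = call_regulation(.data$wt_log2fc, .data$wt_fdr,
                                   fc_cut, fdr_cut),
    ko_regulation = call_regulation(.data$ko_vs_wt_log2fc, .data$ko_vs_wt_fdr,
                                    fc_cut, fdr_cut),
    ko_relative = dplyr::case_when(
      .data$ko_regulation == "up" ~ "higher",
      .data$ko_regulation == "down" ~ "lower",
      TRUE ~ "none"
    ),
    class = ifelse(.data$missing_data, "none",
                   .class_map(.data$wt_direction, .data$ko_relative))
  )
  out$ko_regulation <- NULL
  if (all(c("ko_log2fc", "ko_fdr") %in% names(out))) {
    out$.ko_up <- call_regulation(out$ko_log2fc, out$ko_fdr,
                                  fc_cut, fdr_cut) == "up"
    out$dependence <- ifelse(out$class == "JunUP",
                             ifelse(out$.ko_up, "partial", "complete"),
                             NA_character_)
    per_gene <- out |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        timecourse_complete = any(.data$class == "JunUP") & !any(.data$.ko_up),
        .groups = "drop"
      )
    out$.ko_up <- NULL
    out <- dplyr::left_join(out, per_gene, by = "gene")
  }
  out
}

#' Jun-dependence of a JunUP gene at one timepoint
#'
#' `"complete"` when the KO shows no axotomy upregulation at this timepoint
#' under the same cuts; `"partial"` otherwise. With `across_ko_up` (the
#' gene's KO-upregulation calls at all timepoints) the time-course flag is
#' also returned: complete over the whole course iff the KO is never
#' upregulated at any timepoint.
#'
#' @param class The gene's class at this timepoint (must be `"JunUP"`).
#' @param ko_log2fc,ko_fdr KO injured vs KO uninjured contrast.
#' @param fc_cut,fdr_cut Cutoffs.
#' @param across_ko_up Optional logical vector of KO-upregulation calls
#'   across all timepoints.
#' @return A list with `dependence` and (when `across_ko_up` given)
#'   `timecourse_complete`.
#' @export
call_dependence <- function(class, ko_log2fc, ko_fdr, fc_cut = 1.5,
                            fdr_cut = 0.01, across_ko_up = NULL) {
  if (!identical(class, "JunUP")) {
    abort("dependence is defined only for JunUP genes")
  }
  ko_up <- call_regulation(ko_log2fc, ko_fdr, fc_cut, fdr_cut) == "up"
  out <- list(dependence = if (ko_up) "partial" else "complete")
  if (!is.null(across_ko_up)) {
    out$timecourse_complete <- !any(across_ko_up)
  }
  out
}

#' Select unregulated control genes
#'
#' Control promoters come from genes with no evidence of a genotype effect:
#' no significant KO-vs-WT contrast at any timepoint, absolute genotype
#' fold change below `fc_genotype_max` at every timepoint, and a maximum
#' expression level above `min_expr` (log2 array-intensity scale; excludes
#' silent, possibly heterochromatic promoters).
#'
#' @param contrasts Tidy contrast tibble (as in [classify_genes()]) with a
#'   `max_expression` column.
#' @param fc_genotype_max Genotype fold-change bound, default 1.3.
#' @param min_expr Minimum of the gene's maximum expression, default 7.
#' @param fc_cut,fdr_cut Significance cuts for "no significant KO effect".
#' @return Character vector of control gene ids.
#' @export
select_control_genes <- function(contrasts, fc_genotype_max = 1.3,
                                 min_expr = 7, fc_cut = 1.5, fdr_cut = 0.01) {
  if (!"max_expression" %in% names(contrasts)) {
    abort("contrast table lacks a `max_expression` column")
  }
  tab <- dplyr::mutate(
    contrasts,
    geno_sig = call_regulation(.data$ko_vs_wt_log2fc, .data$ko_vs_wt_fdr,
                               fc_cut, fdr_cut) != "none",
    geno_small = abs(.data$ko_vs_wt_log2fc) < log2(fc_genotype_max)
  )
  ok <- tab |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      keep = !any(.data$geno_sig) & all(.data$geno_small) &
        max(.data$max_expression) > min_expr,
      .groups = "drop"
    )
  ok$gene[ok$keep]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (wraps `stats::p.adjust`).
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted values.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
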