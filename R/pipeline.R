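# Grid enrichment runner: window lengths x conservation requirements per
# PWM, each setting optimized with the flexible-threshold machinery.

# species score matrix for a hit table (rows = hits, cols = species)
species_score_matrix <- function(hits, pwm, bundles) {
  sp <- matrix(NA_real_, nrow = nrow(hits), ncol = length(bundles))
  if (nrow(hits) == 0 || length(bundles) == 0) return(sp)
  idx <- split(seq_len(nrow(hits)), hits$promoter_id)
  for (b in seq_along(bundles)) {
    for (ii in idx) {
      sp[ii, b] <- ortholog_scores_one(
        pwm, bundles[[b]], hits$promoter_id[ii[1]], hits$offset[ii])
    }
  }
  sp
}

# conserved scores from a mouse-score vector and species matrix
conserved_from_matrix <- function(mouse, sp_mat, n_required) {
  if (n_required == 0 || nrow(sp_mat) == 0) return(mouse)
  nth <- apply(sp_mat, 1, function(v) {
    v <- sort(v[!is.na(v)], decreasing = TRUE)
    if (length(v) < n_required) -Inf else v[n_required]
  })
  pmax(0, pmin(mouse, nth))
}

as_pwm_list <- function(pwms) {
  if (inherits(pwms, "flex_pfm") || inherits(pwms, "flex_pwm")) {
    pwms <- list(pwms)
  }
  out <- list()
  for (p in pwms) {
    if (inherits(p, "flex_pfm")) {
      p <- tryCatch(build_pwm(p), error = function(e) {
        message("skipping matrix: ", conditionMessage(e))
        NULL
      })
    }
    if (!is.null(p)) out[[p$motif_id]] <- p
  }
  out
}

#' Run flexible-threshold over-representation analysis
#'
#' For every PWM and every combination of promoter window length and
#' conservation requirement, scans both promoter sets with a permissive
#' threshold, attaches conserved scores, tests every candidate threshold
#' exhaustively under the control-frequency constraint, and reports the
#' optimal point.
#'
#' @param test,control Promoter-set tibbles ([promoter_set()]).
#' @param pwms List of [pfm()] or [build_pwm()] objects (matrices rejected
#'   as uninformative are skipped with a message).
#' @param bundles List of [ortholog_bundle()] objects, one per species.
#' @param windows Integer vector of promoter window lengths (bp) to test.
#' @param n_required Integer vector of conservation requirements to test
#'   (each between 0 and `length(bundles)`).
#' @param objective `"as"` (Additional Sites, with `min_or` imposed) or
#'   `"or"` (OR ratio).
#' @param min_or Minimum OR ratio required under the `"as"` objective.
#' @param low_threshold Fixed permissive scan threshold; `NULL` (default)
#'   calibrates per PWM on the control set via [calibrate_low_threshold()].
#' @param per_kb Calibration target for the permissive threshold.
#' @param control_freq_bounds Admissible control frequency band (sites/kb).
#' @param sidedness `"over"` or `"under"`.
#' @param keep_hits Keep the test-set hits at the optimum as a list-column
#'   (needed for grouping and flanking analysis).
#' @return A `flex_enrichment` tibble: one row per PWM x window x
#'   `n_required` with an admissible optimum, ordered by motif then
#'   objective value; settings with no admissible threshold are absent.
#' @export
run_enrichment <- function(test, control, pwms, bundles = list(),
                           windows = 1000, n_required = 0,
                           objective = c("as", "or"), min_or = 2.5,
                           low_threshold = NULL, per_kb = 2,
                           control_freq_bounds = c(0.01, 0.2),
                           sidedness = "over", keep_hits = TRUE) {
  objective <- match.arg(objective)
  pwms <- as_pwm_list(pwms)
  rows <- list()
  for (w in windows) {
    tt <- truncate_promoters(test, w)
    tc <- truncate_promoters(control, w)
    lenA <- total_length(tt)
    lenB <- total_length(tc)
    for (pwm in pwms) {
      lt <- low_threshold %||% calibrate_low_threshold(pwm, tc, per_kb)
      h_test <- scan_promoters(pwm, tt, lt)
      h_ctrl <- scan_promoters(pwm, tc, lt)
      sp_test <- species_score_matrix(h_test, pwm, bundles)
      sp_ctrl <- species_score_matrix(h_ctrl, pwm, bundles)
      for (n_req in n_required) {
        if (n_req > length(bundles)) {
          abort("`n_required` exceeds the number of species bundles")
        }
        cs_test <- conserved_from_matrix(h_test$score, sp_test, n_req)
        cs_ctrl <- conserved_from_matrix(h_ctrl$score, sp_ctrl, n_req)
        pts <- scan_thresholds(cs_test, cs_ctrl, lenA, lenB,
                               control_freq_bounds, sidedness)
        best <- optimize_threshold(pts, objective, min_or)
        if (nrow(best) == 0) next
        row <- tibble(
          motif_id = pwm$motif_id, tf_name = pwm$tf_name,
          window = w, n_required = n_req, objective = objective,
          low_threshold = lt
        )
        row <- dplyr::bind_cols(row, best)
        if (keep_hits) {
          keep <- which(cs_test >= best$threshold)
          hh <- h_test[keep, , drop = FALSE]
          hh$conserved_score <- cs_test[keep]
          row$hits <- list(hh)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    obj_col <- if (objective == "or") out$or_ratio else out$additional_sites
    out <- out[order(out$motif_id, -obj_col), , drop = FALSE]
  }
  structure(out, class = c("flex_enrichment", class(out)),
            objective = objective, min_or = min_or)
}

#' Objective value column of an enrichment result
#' @param results A `flex_enrichment` tibble.
#' @return Numeric vector (`or_ratio` or `additional_sites` per the
#'   configured objective).
#' @export
objective_value <- function(results) {
  if (identical(attr(results, "objective"), "or")) {
    results$or_ratio
  } else {
    results$additional_sites
  }
}

#' Write enrichment results as TSV
#'
#' Drops the hit list-column; columns follow the result schema
#' (`motif_id`, `window`, `n_required`, `objective`, `threshold`, `A`, `B`,
#' lengths, statistics, and `group_id`/`fdr` when present).
#'
#' @param results A `flex_enrichment` tibble.
#' @param path Output path.
#' @param comment Optional provenance lines written as leading `#` comments.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, comment = NULL) {
  out <- results[setdiff(names(results), "hits")]
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(as_tibble(out), path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(as_tibble(out), path)
  }
  invisible(path)
}
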