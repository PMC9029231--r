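# Location-based grouping of redundant matrices and the resampling
# group-wise FDR.
#
# Many matrices in a motif collection are near-duplicates and detect sites
# at the same promoter locations. Two PWMs are related when at least `frac`
# (default 50%) of either one's hit centers lie within `window_bp` (default
# 4 bp) of some hit center of the other on the same promoter; groups are the
# connected components of this relation.

# TRUE when >= frac of hx's centers have a close hy center (same promoter)
frac_close <- function(hx, hy, window_bp) {
  if (nrow(hx) == 0) return(FALSE)
  close <- logical(nrow(hx))
  ys <- split(hy$center, hy$promoter_id)
  for (pid in names(ys)) {
    ii <- which(hx$promoter_id == pid)
    if (length(ii) == 0) next
    y <- sort(ys[[pid]])
    # nearest y to each x center via findInterval on the sorted centers
    x <- hx$center[ii]
    lo <- findInterval(x, y)
    d_lo <- ifelse(lo >= 1, x - y[pmax(lo, 1)], Inf)
    d_hi <- ifelse(lo < length(y), y[pmin(lo + 1L, length(y))] - x, Inf)
    close[ii] <- pmin(d_lo, d_hi) <= window_bp
  }
  mean(close)
}

#' Group PWMs that detect sites at the same locations
#'
#' @param results A `flex_enrichment` tibble with a `hits` list-column
#'   (each hit table carrying `promoter_id` and `center`). When the same
#'   motif appears in several rows (window/conservation grid), supply one
#'   setting at a time.
#' @param window_bp Centers within this many bp count as the same location
#'   (default 4).
#' @param frac Fraction of one PWM's hits that must co-locate with the
#'   other's (default 0.5). The relation holds if either direction reaches
#'   `frac`; groups are connected components of the relation.
#' @return `results` with a `group_id` column (integer; groups numbered by
#'   their best objective value, best first).
#' @export
group_motifs <- function(results, window_bp = 4, frac = 0.5) {
  n <- nrow(results)
  if (n == 0) {
    results$group_id <- integer(0)
    return(results)
  }
  if (is.null(results$hits)) abort("`results` must carry a `hits` list-column")
  hits <- results$hits
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      rel <- frac_close(hits[[i]], hits[[j]], window_bp) >= frac ||
        frac_close(hits[[j]], hits[[i]], window_bp) >= frac
      adj[i, j] <- adj[j, i] <- rel
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by their best objective value (best = group 1)
  obj <- objective_value(results)
  best_by_comp <- tapply(obj, comp, max)
  ord <- rank(-best_by_comp, ties.method = "first")
  results$group_id <- as.integer(ord[as.character(comp)])
  results
}

#' Summarise location groups
#'
#' @param results A grouped `flex_enrichment` tibble (see [group_motifs()]).
#' @param expression Optional tibble `tf_name`, `expression` used to
#'   annotate each group with the highest-expressed member TF whose
#'   objective value is within 75% of the group's top score.
#' @return One row per group: `group_id`, `members`, `representative`
#'   (member with the highest objective value), `optimum`, `n_members`, and
#'   `annotated_tf` when `expression` is given.
#' @export
summarise_groups <- function(results, expression = NULL) {
  if (nrow(results) == 0) {
    out <- tibble(group_id = integer(), members = character(),
                  representative = character(), optimum = numeric(),
                  n_members = integer())
    if (!is.null(expression)) out$annotated_tf <- character()
    return(out)
  }
  obj <- objective_value(results)
  res <- dplyr::mutate(as_tibble(results), .obj = obj)
  out <- res |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      members = paste(.data$motif_id, collapse = ","),
      representative = .data$motif_id[which.max(.data$.obj)],
      optimum = max(.data$.obj),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group_id)
  if (!is.null(expression)) {
    ann <- res |>
      dplyr::left_join(expression, by = "tf_name") |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(annotated_tf = {
        top <- max(.data$.obj)
        cand <- which(.data$.obj >= 0.75 * top & !is.na(.data$expression))
        if (length(cand) == 0) NA_character_
        else .data$tf_name[cand[which.max(.data$expression[cand])]]
      }, .groups = "drop")
    out <- dplyr::left_join(out, ann, by = "group_id")
  }
  out
}

# --- resampling FDR ---------------------------------------------------------

# one optimization pass over cached per-PWM pooled hits for a given test-arm
# membership; returns per-PWM best rows with hits at the optimum
optimize_arms <- function(cache, test_ids, len_by_prom, objective, min_or,
                          control_freq_bounds, sidedness, keep_hits = TRUE) {
  lenA <- sum(len_by_prom[test_ids])
  lenB <- sum(len_by_prom) - lenA
  rows <- list()
  for (mid in names(cache)) {
    h <- cache[[mid]]
    in_test <- h$promoter_id %in% test_ids
    pts <- scan_thresholds(h$conserved_score[in_test],
                           h$conserved_score[!in_test],
                           lenA, lenB, control_freq_bounds, sidedness)
    best <- optimize_threshold(pts, objective, min_or)
    if (nrow(best) == 0) next
    row <- dplyr::bind_cols(tibble(motif_id = mid), best)
    if (keep_hits) {
      keep <- in_test & h$conserved_score >= best$threshold
      row$hits <- list(h[keep, , drop = FALSE])
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(motif_id = character(), threshold = numeric(),
                  A = integer(), B = integer(), len_test = numeric(),
                  len_control = numeric(), or_ratio = numeric(),
                  additional_sites = numeric(), p_value = numeric(),
                  admissible = logical())
    if (keep_hits) out$hits <- list()
  }
  structure(out, class = c("flex_enrichment", class(out)),
            objective = objective, min_or = min_or)
}

# build the pooled per-PWM hit cache at one window/conservation setting
build_hit_cache <- function(test, control, pwms, bundles, window, n_required,
                            low_threshold, per_kb) {
  pool <- dplyr::bind_rows(truncate_promoters(test, window),
                           truncate_promoters(control, window))
  if (anyDuplicated(pool$gene_id)) {
    abort("test and control promoter ids must not overlap")
  }
  ctrl_trunc <- truncate_promoters(control, window)
  cache <- list()
  for (pwm in pwms) {
    lt <- low_threshold %||% calibrate_low_threshold(pwm, ctrl_trunc, per_kb)
    h <- scan_promoters(pwm, pool, lt)
    h$conserved_score <- conserved_from_matrix(
      h$score, species_score_matrix(h, pwm, bundles), n_required)
    cache[[pwm$motif_id]] <- h
  }
  list(cache = cache,
       len_by_prom = stats::setNames(pool$length, pool$gene_id))
}

#' Resampling group-wise FDR
#'
#' Estimates, for each observed location group, the expected number of null
#' groups with an equal or better optimum of the same objective. Each null
#' run draws `a = nrow(test)` promoters without replacement from the pooled
#' test + control promoters as a pseudo-test set, re-executes the full
#' flexible-threshold optimization and grouping on that split, and counts
#' null groups whose optimum is `>=` the observed group's optimum. The FDR
#' estimate is the arithmetic mean of those counts over `n_runs`.
#'
#' @param test,control Promoter-set tibbles (ids must be disjoint).
#' @param pwms List of [pfm()]/[build_pwm()] objects.
#' @param bundles Ortholog bundles for the conservation requirement.
#' @param window Promoter window length (bp) for this analysis.
#' @param n_required Conservation requirement.
#' @param objective,min_or,control_freq_bounds,sidedness,low_threshold,per_kb
#'   As in [run_enrichment()]. The permissive threshold is calibrated once
#'   on the observed control arm and reused across runs so that every run
#'   optimizes over the same candidate sites.
#' @param n_runs Number of resampling runs (default 100).
#' @param seed RNG seed for the resampling draws.
#' @param window_bp,frac Grouping parameters (see [group_motifs()]).
#' @return A list with `results` (the observed `flex_enrichment` rows with
#'   `group_id` and `fdr` columns), `groups` (per-group tibble with
#'   `optimum`, `fdr`, `n_runs`), and `null_counts` (runs x groups matrix of
#'   equal-or-better null-group counts).
#' @export
resample_fdr <- function(test, control, pwms, bundles = list(), window = 1000,
                         n_required = 0, objective = c("as", "or"),
                         min_or = 2.5, n_runs = 100, seed = 1L,
                         low_threshold = NULL, per_kb = 2,
                         control_freq_bounds = c(0.01, 0.2),
                         sidedness = "over", window_bp = 4, frac = 0.5) {
  objective <- match.arg(objective)
  if (nrow(test) + nrow(control) < 2) abort("need at least 2 promoters")
  pwms <- as_pwm_list(pwms)
  built <- build_hit_cache(test, control, pwms, bundles, window, n_required,
                           low_threshold, per_kb)
  cache <- built$cache
  len_by_prom <- built$len_by_prom
  pool_ids <- names(len_by_prom)
  a <- nrow(test)

  observed <- optimize_arms(cache, test$gene_id, len_by_prom, objective,
                            min_or, control_freq_bounds, sidedness)
  observed <- group_motifs(observed, window_bp, frac)
  grp <- summarise_groups(observed)
  if (nrow(grp) == 0) {
    return(list(results = observed, groups = grp,
                null_counts = matrix(numeric(0), nrow = n_runs, ncol = 0)))
  }

  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_runs), function(r) {
      pseudo <- sample(pool_ids, a)
      nullres <- optimize_arms(cache, pseudo, len_by_prom, objective, min_or,
                               control_freq_bounds, sidedness)
      if (nrow(nullres) == 0) return(numeric(nrow(grp)))
      nullres <- group_motifs(nullres, window_bp, frac)
      null_opt <- summarise_groups(nullres)$optimum
      vapply(grp$optimum, function(o) sum(null_opt >= o), numeric(1))
    }, numeric(nrow(grp)))
  })
  counts <- matrix(counts, nrow = nrow(grp))   # groups x runs
  grp$fdr <- rowMeans(counts)
  grp$n_runs <- n_runs
  observed$fdr <- grp$fdr[match(observed$group_id, grp$group_id)]
  list(results = observed, groups = grp, null_counts = t(counts))
}

#' Filter results by group-wise FDR
#'
#' Keeps rows whose group FDR is strictly below `fdr_cut` (default 0.05);
#' order among survivors is preserved.
#'
#' @param results A tibble with an `fdr` column.
#' @param fdr_cut FDR cutoff (strict `<`).
#' @return The filtered tibble.
#' @export
report_filter <- function(results, fdr_cut = 0.05) {
  results[!is.na(results$fdr) & results$fdr < fdr_cut, , drop = FALSE]
}
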