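# Location-based grouping of matrices and the resampling group-wise FDR.

mk_result <- function(motifs, hit_sets, obj_vals, objective = "as") {
  out <- tibble::tibble(
    motif_id = motifs,
    or_ratio = obj_vals, additional_sites = obj_vals,
    p_value = 0.01, threshold = 0.9,
    hits = hit_sets
  )
  structure(out, class = c("flex_enrichment", class(out)),
            objective = objective, min_or = 2.5)
}

hits_at <- function(promoters, centers) {
  tibble::tibble(promoter_id = promoters, center = as.integer(centers))
}

test_that("grouping follows the shared-location rule with transitive closure", {
  shared <- hits_at(c("p1", "p2"), c(100, 250))
  res <- mk_result(c("m1", "m2"), list(shared, shared), c(5, 4))
  g <- group_motifs(res)
  expect_equal(g$group_id, c(1L, 1L))
  # disjoint promoters: two groups
  res2 <- mk_result(c("m1", "m2"),
                    list(hits_at("p1", 100), hits_at("p9", 100)), c(5, 4))
  expect_equal(sort(unique(group_motifs(res2)$group_id)), c(1L, 2L))
  # chain: A~B (within 4 bp), B~C, but A and C far apart -> one group
  res3 <- mk_result(c("A", "B", "C"),
                    list(hits_at("p1", 100), hits_at("p1", 104),
                         hits_at("p1", 108)), c(3, 2, 1))
  expect_equal(group_motifs(res3)$group_id, c(1L, 1L, 1L))
  # 5 bp apart is beyond the window: separate groups
  res4 <- mk_result(c("A", "B"),
                    list(hits_at("p1", 100), hits_at("p1", 105)), c(3, 2))
  expect_equal(sort(group_motifs(res4)$group_id), c(1L, 2L))
})

test_that("the 50% co-location fraction applies to either member", {
  # m2 has 4 hits, only 1 near m1's single hit (25% of m2) but 100% of m1
  res <- mk_result(c("m1", "m2"),
                   list(hits_at("p1", 100),
                        hits_at(rep("p1", 4), c(100, 300, 500, 700))),
                   c(5, 4))
  expect_equal(group_motifs(res)$group_id, c(1L, 1L))
  # 1 of 3 near (33%) in one direction and 1 of 3 in the other: no group
  res2 <- mk_result(c("m1", "m2"),
                    list(hits_at(rep("p1", 3), c(100, 400, 800)),
                         hits_at(rep("p1", 3), c(102, 600, 900))),
                    c(5, 4))
  expect_equal(sort(group_motifs(res2)$group_id), c(1L, 2L))
})

test_that("grouping is invariant to the order of the results", {
  res <- mk_result(c("A", "B", "C", "D"),
                   list(hits_at("p1", 100), hits_at("p1", 103),
                        hits_at("p2", 50), hits_at("p2", 51)),
                   c(4, 3, 2, 1))
  part1 <- split(res$motif_id, group_motifs(res)$group_id)
  perm <- res[c(3, 1, 4, 2), ]
  part2 <- split(perm$motif_id, group_motifs(perm)$group_id)
  norm <- function(p) unname(lapply(p, sort))[order(vapply(p, min, ""))]
  expect_equal(norm(part1), norm(part2))
})

test_that("group summaries pick the representative and annotate by expression", {
  res <- mk_result(c("m1", "m2", "m3"),
                   list(hits_at("p1", 100), hits_at("p1", 101),
                        hits_at("p3", 10)), c(10, 9, 3))
  res$tf_name <- c("TFa", "TFb", "TFc")
  g <- group_motifs(res)
  s <- summarise_groups(g, expression = tibble::tibble(
    tf_name = c("TFa", "TFb", "TFc"), expression = c(5, 8, 2)))
  expect_equal(s$representative[s$group_id == 1], "m1")
  expect_equal(s$optimum[s$group_id == 1], 10)
  # TFb is within 75% of the top score (9 >= 7.5) and higher expressed
  expect_equal(s$annotated_tf[s$group_id == 1], "TFb")
  expect_equal(s$members[s$group_id == 1], "m1,m2")
})

test_that("the resampling FDR matches an explicit re-implementation", {
  sim <- worked_fixture()
  got <- resample_fdr(sim$test, sim$control, sim$pfms, window = 500,
                      n_required = 0, objective = "or", n_runs = 20,
                      seed = 71, low_threshold = 0.75)
  # independent loop: same cached-scan construction, explicit runs
  pwms <- lapply(sim$pfms, build_pwm)
  pool <- dplyr::bind_rows(truncate_promoters(sim$test, 500),
                           truncate_promoters(sim$control, 500))
  hits <- lapply(pwms, function(p) {
    h <- scan_promoters(p, pool, 0.75)
    h$conserved_score <- h$score
    h
  })
  names(hits) <- vapply(pwms, function(p) p$motif_id, "")
  len_by <- stats::setNames(pool$length, pool$gene_id)
  one_pass <- function(test_ids) {
    rows <- list()
    lenA <- sum(len_by[test_ids])
    lenB <- sum(len_by) - lenA
    for (mid in names(hits)) {
      h <- hits[[mid]]
      tin <- h$promoter_id %in% test_ids
      pts <- scan_thresholds(h$conserved_score[tin], h$conserved_score[!tin],
                             lenA, lenB)
      best <- optimize_threshold(pts, "or")
      if (nrow(best) == 0) next
      best$motif_id <- mid
      best$hits <- list(h[tin & h$conserved_score >= best$threshold, ])
      rows[[length(rows) + 1L]] <- best
    }
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("flex_enrichment", class(out)),
              objective = "or", min_or = 2.5)
  }
  obs <- one_pass(sim$test$gene_id)
  obs_groups <- summarise_groups(group_motifs(obs))
  expect_equal(obs_groups$optimum, got$groups$optimum)
  counts <- withr::with_seed(71, {
    vapply(1:20, function(r) {
      pseudo <- sample(pool$gene_id, nrow(sim$test))
      nr <- one_pass(pseudo)
      if (nrow(nr) == 0) return(numeric(nrow(obs_groups)))
      nopt <- summarise_groups(group_motifs(nr))$optimum
      vapply(obs_groups$optimum, function(o) sum(nopt >= o), numeric(1))
    }, numeric(nrow(obs_groups)))
  })
  expect_equal(got$groups$fdr,
               rowMeans(matrix(counts, nrow = nrow(obs_groups))))
})

test_that("dominant observed optima give FDR 0 and the filter is strict", {
  # planted signal so strong no null split can match it
  spec <- sim_spec(seed = 13, n_test = 20, n_control = 20,
                   promoter_length = 500,
                   plant = list(list(pfm = motif_ap1(), rate_test = 2,
                                     rate_control = 0.1)))
  sim <- gen_promoters(spec)
  fit <- resample_fdr(sim$test, sim$control, list(motif_ap1()),
                      window = 500, objective = "or", n_runs = 15, seed = 5)
  expect_equal(nrow(fit$groups), 1)
  expect_true(fit$groups$fdr < 0.5)
  # report_filter: strict inequality at the cut, order preserved
  df <- tibble::tibble(motif_id = c("a", "b", "c"),
                       fdr = c(0.04, 0.05, 0.001))
  kept <- report_filter(df)
  expect_equal(kept$motif_id, c("a", "c"))
  expect_equal(nrow(report_filter(df[0, ])), 0)
})
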