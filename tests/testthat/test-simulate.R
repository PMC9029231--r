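# Synthetic-data generators: determinism, planting statistics,
# conservation structure, and the shared worked fixture.

test_that("generators are pure functions of the seed", {
  spec <- sim_spec(seed = 8, n_test = 5, n_control = 5, promoter_length = 400,
                   plant = list(list(pfm = motif_ap1(), rate_test = 0.5,
                                     rate_control = 0.2)),
                   species = c("s1", "s2"))
  a <- gen_promoters(spec)
  b <- gen_promoters(spec)
  expect_identical(a$test$sequence, b$test$sequence)
  expect_identical(a$truth, b$truth)
  ba <- gen_ortholog_bundles(dplyr::bind_rows(a$test, a$control), a$truth, spec)
  bb <- gen_ortholog_bundles(dplyr::bind_rows(b$test, b$control), b$truth, spec)
  expect_identical(ba$s1$sequences, bb$s1$sequences)
  # worked fixture is version-stable across calls
  expect_identical(fx$test$sequence, worked_fixture()$test$sequence)
  expect_equal(nrow(fx$test) + nrow(fx$control), 40)
})

test_that("planted-site truth matches the emitted sequences and rates", {
  spec0 <- sim_spec(seed = 2, n_test = 3, n_control = 3,
                    promoter_length = 300, plant = list())
  sim0 <- gen_promoters(spec0)
  expect_equal(nrow(sim0$truth), 0)
  # planted windows rescored at their truth coordinates score high
  for (r in withr::with_seed(1, sample(seq_len(nrow(fx$truth)), 10))) {
    tr <- fx$truth[r, ]
    pool <- fx_pool
    seq <- pool$sequence[pool$gene_id == tr$promoter_id]
    pwm <- build_pwm(Filter(function(p) p$motif_id == tr$motif_id,
                            fx$pfms)[[1]], 0.01)
    win <- substr(seq, tr$start + 1, tr$end)
    sc <- max(score_window(pwm, win, 0, "+"), score_window(pwm, win, 0, "-"))
    expect_true(sc > 0.45)   # sites are PFM draws, so a few mismatches occur
  }
  # AP1 is planted at a higher rate in the fixture's test arm
  ap1_arm <- fx$truth$arm[fx$truth$motif_id == "AP1_syn"]
  expect_true(sum(ap1_arm == "test") > sum(ap1_arm == "control"))
  # Poisson planting: total count within 3 sd of rate * length
  spec <- sim_spec(seed = 4, n_test = 250, n_control = 250,
                   promoter_length = 1000,
                   plant = list(list(pfm = motif_ap1(), rate_test = 0.2,
                                     rate_control = 0.2)))
  sim <- gen_promoters(spec)
  expect_true(abs(nrow(sim$truth) - 100) <= 3 * sqrt(100))
  # non-overlap of planted windows within each promoter
  by_prom <- split(sim$truth, sim$truth$promoter_id)
  overlaps <- vapply(by_prom, function(d) {
    d <- d[order(d$start), ]
    any(d$start[-1] < d$end[-nrow(d)])
  }, logical(1))
  expect_false(any(overlaps))
  expect_error(
    gen_promoters(sim_spec(seed = 1, n_test = 1, n_control = 1,
                           promoter_length = 100,
                           plant = list(list(pfm = motif_ap1(),
                                             rate_test = 200,
                                             rate_control = 0)))),
    "lower the rate")
})

test_that("orthologs reflect the retention and divergence parameters", {
  spec <- sim_spec(seed = 6, n_test = 10, n_control = 2,
                   promoter_length = 500,
                   plant = list(list(pfm = motif_ap1(), rate_test = 1,
                                     rate_control = 0.2)),
                   species = c("s1", "s2"), retention = 1, divergence = 0)
  sim <- gen_promoters(spec)
  pool <- dplyr::bind_rows(sim$test, sim$control)
  bundles <- gen_ortholog_bundles(pool, sim$truth, spec)
  expect_identical(unname(bundles$s1$sequences), pool$sequence)
  # retention 0: planted windows diverge like background
  spec0 <- sim_spec(seed = 6, n_test = 10, n_control = 2,
                    promoter_length = 500,
                    plant = list(list(pfm = motif_ap1(), rate_test = 1,
                                      rate_control = 0.2)),
                    species = "s1", retention = 0, divergence = 0.5)
  b0 <- gen_ortholog_bundles(pool, sim$truth, spec0)
  tr <- sim$truth[sim$truth$arm == "test", ]
  mism <- purrr::map2_dbl(tr$promoter_id, tr$start, function(id, st) {
    a <- substr(pool$sequence[pool$gene_id == id], st + 1, st + 7)
    b <- substr(b0$s1$sequences[[id]], st + 1, st + 7)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  })
  expect_true(mean(mism) > 1.5)   # ~3.5 expected at divergence 0.5
  # deletions shift the map but keep it strictly monotone and consistent
  specd <- sim_spec(seed = 9, n_test = 2, n_control = 2,
                    promoter_length = 300, species = "s1",
                    divergence = 0, deletion_rate = 0.05)
  simd <- gen_promoters(specd)
  poold <- dplyr::bind_rows(simd$test, simd$control)
  bd <- gen_ortholog_bundles(poold, simd$truth, specd)
  mp <- bd$s1$maps[[1]]
  expect_true(all(diff(unname(mp)) > 0))
  # mapped positions agree base-by-base (no substitutions here)
  id <- names(bd$s1$maps)[1]
  mouse <- strsplit(poold$sequence[poold$gene_id == id], "")[[1]]
  orth <- strsplit(bd$s1$sequences[[id]], "")[[1]]
  expect_equal(mouse[as.integer(names(mp)) + 1], orth[unname(mp) + 1])
})

test_that("site conservation frequency matches a direct per-site simulation", {
  spec <- sim_spec(seed = 12, n_test = 60, n_control = 2,
                   promoter_length = 800,
                   plant = list(list(pfm = motif_ap1(), rate_test = 1,
                                     rate_control = 0)),
                   retention = 0.9, divergence = 0.25)
  sim <- gen_promoters(spec)
  pool <- dplyr::bind_rows(sim$test, sim$control)
  bundles <- gen_ortholog_bundles(pool, sim$truth, spec)
  pwm <- build_pwm(motif_ap1())
  tr <- sim$truth
  t_cut <- 0.85
  # fraction of planted sites with >= 3 species scoring >= t at the site
  n_ge3 <- vapply(seq_len(nrow(tr)), function(r) {
    sc <- vapply(bundles, function(b) {
      s <- score_ortholog_window(pwm, b, tr$promoter_id[r], tr$start[r])
      if (is.na(s)) -1 else s
    }, numeric(1))
    sum(sc >= t_cut) >= 3
  }, logical(1))
  got <- mean(n_ge3)
  # oracle: simulate retention/divergence on each planted window directly
  oracle <- withr::with_seed(123, {
    mean(vapply(seq_len(nrow(tr)), function(r) {
      pool_seq <- pool$sequence[pool$gene_id == tr$promoter_id[r]]
      win <- substr(pool_seq, tr$start[r] + 1, tr$end[r])
      codes <- flexsite:::encode_dna(win)
      per_species <- vapply(1:5, function(s) {
        if (runif(1) < 0.9) {
          w <- codes
        } else {
          w <- codes
          sub <- runif(length(w)) < 0.25
          w[sub] <- ((w[sub] - 1L + sample.int(3L, sum(sub),
                                               replace = TRUE)) %% 4L) + 1L
        }
        ws <- flexsite:::decode_dna(w)
        max(score_window(pwm, ws, 0, "+"), score_window(pwm, ws, 0, "-")) >=
          t_cut
      }, logical(1))
      sum(per_species) >= 3
    }, logical(1)))
  })
  n <- nrow(tr)
  tol <- 3 * sqrt(0.25 / n) * 2   # binomial tolerance on both estimates
  expect_lt(abs(got - oracle), tol + 0.05)
})
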