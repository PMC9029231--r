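# OR ratio, Additional Sites, exact binomial p-values, and the flexible
# threshold scan/optimization.

test_that("OR ratio and Additional Sites follow their closed forms", {
  expect_equal(or_ratio(10, 100000, 20, 400000), 2.0)
  expect_equal(or_ratio(7, 5000, 14, 10000), 1.0)
  expect_identical(or_ratio(5, 10000, 0, 10000), Inf)
  expect_error(or_ratio(1, 0, 1, 10), "> 0")
  expect_equal(additional_sites(10, 100000, 20, 400000), 5.0)
  expect_equal(additional_sites(4, 1000, 8, 2000), 0.0)
  expect_equal(additional_sites(30, 50000, 100, 500000), 20.0)
  expect_true(additional_sites(1, 1000, 50, 1000) < 0)
})

test_that("binomial significance is the exact conditional tail", {
  expect_equal(binomial_p(0, 5, 100, 100, "over"), 1.0)
  expect_equal(binomial_p(1, 1, 100, 100, "over"), 0.75)
  expect_equal(binomial_p(20, 5, 1000, 1000, "over"),
               oracle_binomial_p(20, 5, 1000, 1000, "over"),
               tolerance = 1e-12)
  # control-rate reference model: test count against Bin(lenA, B/lenB)
  expect_equal(binomial_p(20, 5, 1000, 2000, model = "rate"),
               pbinom(19, 1000, 5 / 2000, lower.tail = FALSE))
  expect_equal(binomial_p(0, 5, 100, 100, "over", model = "rate"), 1.0)
  # over-side p is non-increasing in A at fixed B and lengths
  ps <- vapply(0:30, function(a) binomial_p(a, 10, 1e5, 1e5), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(binomial_p(-1, 2, 10, 10), "non-negative")
})

test_that("candidate thresholds are the sorted unique scores of both sets", {
  expect_equal(candidate_thresholds(c(0.8, 0.9), c(0.9, 0.95)),
               c(0.8, 0.9, 0.95))
  expect_equal(candidate_thresholds(numeric(), numeric()), numeric())
  withr::with_seed(9, {
    a <- sample(round(runif(40), 2), 30, replace = TRUE)
    b <- sample(round(runif(40), 2), 25, replace = TRUE)
    expect_equal(candidate_thresholds(a, b), sort(unique(c(a, b))))
  })
})

test_that("the threshold scan reproduces a naive filter-and-count oracle", {
  withr::with_seed(31, {
    test_s <- round(runif(30, 0.5, 1), 3)
    ctrl_s <- round(runif(40, 0.5, 1), 3)
  })
  lenA <- 60000
  lenB <- 200000
  pts <- scan_thresholds(test_s, ctrl_s, lenA, lenB)
  expect_equal(nrow(pts), length(unique(c(test_s, ctrl_s))))
  for (i in seq_len(nrow(pts))) {
    t <- pts$threshold[i]
    A <- oracle_counts(test_s, t)
    B <- oracle_counts(ctrl_s, t)
    expect_equal(pts$A[i], A)
    expect_equal(pts$B[i], B)
    expect_equal(pts$or_ratio[i], or_ratio(A, lenA, B, lenB))
    expect_equal(pts$additional_sites[i], additional_sites(A, lenA, B, lenB))
    expect_equal(pts$p_value[i],
                 binomial_p(A, B, lenA, lenB, model = "rate"))
    expect_equal(pts$admissible[i],
                 1000 * B / lenB >= 0.01 && 1000 * B / lenB <= 0.2)
  }
  # counts are non-increasing step functions of the threshold
  expect_true(all(diff(pts$A) <= 0))
  expect_true(all(diff(pts$B) <= 0))
})

test_that("admissibility tracks the control-frequency band", {
  # B/lenB = 0.005 sites/kb: below the band
  pts <- scan_thresholds(0.9, rep(0.9, 1), 1000, 200000)
  expect_false(pts$admissible)
  # all-identical scores collapse to a single point with total counts
  pts2 <- scan_thresholds(rep(0.8, 5), rep(0.8, 3), 10000, 100000)
  expect_equal(nrow(pts2), 1)
  expect_equal(pts2$A, 5L)
  expect_equal(pts2$B, 3L)
  expect_true(pts2$admissible)
})

test_that("threshold optimization equals the brute-force enumeration oracle", {
  expect_equal(nrow(optimize_threshold(
    scan_thresholds(0.9, rep(0.9, 1), 1000, 200000), "or")), 0)
  one <- scan_thresholds(rep(0.8, 5), rep(0.8, 3), 10000, 100000)
  expect_equal(optimize_threshold(one, "or"), one)
  withr::with_seed(17, {
    for (rep in 1:30) {
      nT <- sample(5:60, 1)
      nC <- sample(5:80, 1)
      test_s <- sample(round(runif(25, 0.5, 1), 2), nT, replace = TRUE)
      ctrl_s <- sample(round(runif(25, 0.5, 1), 2), nC, replace = TRUE)
      lenA <- sample(2:50, 1) * 1000
      lenB <- sample(50:400, 1) * 1000
      pts <- scan_thresholds(test_s, ctrl_s, lenA, lenB)
      for (obj in c("or", "as")) {
        got <- optimize_threshold(pts, obj)
        want <- oracle_optimize(pts, obj)
        if (is.null(want)) {
          expect_equal(nrow(got), 0)
        } else {
          expect_equal(as.data.frame(got), as.data.frame(want))
        }
      }
    }
  })
})

test_that("identical test and control sets give OR 1 and AS 0 everywhere", {
  spec <- sim_spec(seed = 77, n_test = 60, n_control = 1,
                   promoter_length = 1000,
                   plant = list(list(pfm = motif_ap1(), rate_test = 0.15,
                                     rate_control = 0)))
  sim <- gen_promoters(spec)
  pwm <- build_pwm(motif_ap1())
  s <- scan_promoters(pwm, sim$test, 0.7)$score
  L <- total_length(sim$test)
  pts <- scan_thresholds(s, s, L, L)
  expect_true(all(abs(pts$or_ratio - 1) < 1e-12))
  expect_true(all(abs(pts$additional_sites) < 1e-9))
  expect_equal(pts$A, pts$B)
  # and the optimized pipeline on the identical sets reports OR exactly 1
  res <- run_enrichment(sim$test, sim$test, list(motif_ap1()),
                        windows = 1000, objective = "or",
                        low_threshold = 0.7)
  expect_equal(nrow(res), 1)
  expect_equal(res$or_ratio, 1)
  expect_equal(res$additional_sites, 0)
})

test_that("a planted rate difference is detected with OR > 1 and small p", {
  spec <- sim_spec(seed = 101, n_test = 60, n_control = 60,
                   promoter_length = 1000,
                   plant = list(list(pfm = motif_ap1(), rate_test = 0.15,
                                     rate_control = 0.05)),
                   species = character(0))
  sim <- gen_promoters(spec)
  res <- run_enrichment(sim$test, sim$control, list(motif_ap1()),
                        windows = 1000, objective = "or")
  expect_equal(nrow(res), 1)
  expect_true(res$or_ratio > 1)
  expect_true(res$p_value < 0.05)
  # hits at the optimum are test-arm hits above the winning threshold
  h <- res$hits[[1]]
  expect_true(all(h$conserved_score >= res$threshold))
  expect_true(all(grepl("^test_", h$promoter_id)))
})

test_that("requiring conservation improves the OR ratio when planted sites are retained", {
  spec <- sim_spec(seed = 202, n_test = 80, n_control = 80,
                   promoter_length = 1000,
                   plant = list(list(pfm = motif_ap1(), rate_test = 0.15,
                                     rate_control = 0.05)),
                   retention = 0.9, divergence = 0.25)
  sim <- gen_promoters(spec)
  pool <- dplyr::bind_rows(sim$test, sim$control)
  bundles <- gen_ortholog_bundles(pool, sim$truth, spec)
  res <- run_enrichment(sim$test, sim$control, list(motif_ap1()), bundles,
                        windows = 1000, n_required = c(0, 3),
                        objective = "or")
  or0 <- res$or_ratio[res$n_required == 0]
  or3 <- res$or_ratio[res$n_required == 3]
  expect_length(or0, 1)
  expect_length(or3, 1)
  expect_true(or3 > or0)
})
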