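test_that("binomial_tail matches its closed-form anchor values", {
  expect_identical(binomial_tail(0, 1, 5e-5), 1)
  expect_equal(binomial_tail(1, 1, 5e-5), 5e-5)
  expect_equal(binomial_tail(1, 2, 5e-5), 9.99975e-5, tolerance = 1e-12)
  expect_equal(binomial_tail(2, 2, 5e-5), 2.5e-9, tolerance = 1e-12)
  expect_error(binomial_tail(3, 2, 0.1), "exceed")
  expect_error(binomial_tail(1, 2, 0), "\\(0, 1\\)")
  expect_error(binomial_tail(1, 2, 1), "\\(0, 1\\)")
})

test_that("binomial_tail agrees with the direct-summation oracle for r <= 30", {
  for (p in c(0.5, 0.07, 5e-5, 1e-7)) {
    for (r in c(1:10, 20, 30)) {
      ks <- 0:r
      got <- binomial_tail(ks, r, p)
      want <- vapply(ks, oracle_binom_tail, 0, r = r, p = p)
      expect_rel_equal(got, want, rel = 1e-10)
    }
  }
})

test_that("cprun_at reproduces the worked threshold values", {
  p1 <- significance_params(p_adj = 5e-5)
  expect_identical(cprun_at(1, p1), 1L)
  expect_identical(cprun_at(2, p1), 2L)
  p2 <- significance_params(p_adj = 1e-7)
  expect_identical(cprun_at(4473, p2), 2L)
  expect_identical(cprun_at(4474, p2), 3L)
  expect_identical(cprun_at(10000, p1), 6L)
  # degenerate parameters where no count can trigger pruning
  p3 <- significance_params(p_raw = 1, p_adj = 0.9, p_prun = 1e-9)
  expect_identical(cprun_at(1, p3), 2L)
  expect_identical(cprun_at(3, p3), 4L)
})

test_that("build_schedule matches cprun_at, is monotone, minimal and bounded", {
  for (p_adj in c(5e-5, 1e-7)) {
    params <- significance_params(p_adj = p_adj)
    sch <- build_schedule(params, 10000)
    thr <- sch$thresholds
    expect_true(all(diff(thr) >= 0))
    expect_true(all(thr >= 1 & thr <= seq_len(10000) + 1))
    # spot-check the incremental build against independent per-round scans
    spots <- c(1:5, 50, 4473, 4474, 9999, 10000)
    expect_identical(thr[spots], vapply(spots, cprun_at, 1L, params = params))
    # minimality: attained level <= p_prun, one less fails (tolerance-aware)
    r <- seq_len(10000)
    real <- thr <= r
    expect_true(all(binomial_tail(thr[real], r[real], p_adj) <=
                      params$p_prun * (1 + 1e-9)))
    gt1 <- real & thr > 1
    expect_true(all(binomial_tail(thr[gt1] - 1, r[gt1], p_adj) > params$p_prun))
  }
  sch10 <- build_schedule(significance_params(p_adj = 1e-7), 10)
  expect_identical(sch10$thresholds, c(1L, rep(2L, 9)))
  expect_identical(build_schedule(significance_params(p_raw = 0.5, p_adj = 0.5), 1)$thresholds, 1L)
})

test_that("smaller p_adj gives pointwise smaller-or-equal thresholds", {
  a <- build_schedule(significance_params(p_adj = 5e-5), 10000)$thresholds
  b <- build_schedule(significance_params(p_adj = 1e-7), 10000)$thresholds
  expect_true(all(b <= a))
})

test_that("false_prune_risk equals the brute-force tail sum", {
  sch <- build_schedule(significance_params(p_raw = 0.05, p_adj = 0.01), 20)
  brute <- sum(vapply(1:20, function(r) {
    th <- sch$thresholds[r]
    if (th > r) 0 else oracle_binom_tail(th, r, 0.01)
  }, 0))
  expect_equal(false_prune_risk(sch), brute, tolerance = 1e-12)
  # single round at p_prun = p_adj: C = 1, risk = p_adj
  sch1 <- build_schedule(significance_params(p_adj = 0.01), 1)
  expect_equal(false_prune_risk(sch1), 0.01)
})

test_that("exact hitting probability is bounded by the union-bound risk", {
  for (p_adj in c(0.01, 5e-5)) {
    sch <- build_schedule(significance_params(p_adj = p_adj), 10000)
    hit <- prune_hit_probability(sch)
    expect_gt(hit, 0)
    expect_lte(hit, false_prune_risk(sch))
  }
  # and against a Monte-Carlo check of the hitting probability itself
  sch <- build_schedule(significance_params(p_raw = 0.3, p_adj = 0.3), 40)
  set.seed(11)
  n <- 20000
  sim <- simulate_null_features(n, sch, method = "per_round",
                                latent_p = rep(0.3, n))
  mc <- 1 - sim$remaining[40] / n
  hit <- prune_hit_probability(sch, p = 0.3)
  expect_lt(abs(mc - hit), 3 * sqrt(hit * (1 - hit) / n))
})

test_that("admissible_true_signals floors the risk ratio", {
  sch <- build_schedule(significance_params(p_adj = 0.01), 1)  # risk = 0.01
  expect_identical(admissible_true_signals(sch, 0.05), 5L)
  fake <- sch; fake$thresholds <- 2L  # unattainable threshold: zero risk
  expect_error(admissible_true_signals(fake, 0.05), "zero")
})

test_that("schedule export/import round-trips losslessly", {
  sch <- build_schedule(significance_params(p_raw = 0.05, J = 327872L), 500)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(sch, f)
  back <- read_schedule(f)
  expect_identical(back$thresholds, sch$thresholds)
  expect_identical(back$R, sch$R)
  expect_equal(back$params$p_adj, sch$params$p_adj, tolerance = 0)
  expect_equal(back$params$p_prun, sch$params$p_prun, tolerance = 0)
  expect_identical(back$params$J, sch$params$J)
})

test_that("significance_params enforces its invariants", {
  expect_error(significance_params(p_raw = 0), "p_raw")
  expect_error(significance_params(p_raw = 0.05, p_adj = 0.1), "p_adj")
  expect_error(significance_params(p_raw = 0.05), "either")
  p <- significance_params(p_raw = 0.05, J = 1000L)
  expect_identical(p$p_adj, 5e-5)
  expect_identical(p$p_prun, 5e-5)
})
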