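test_that("dataset_bundle validates alignment and syncs the missing mask", {
  G <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3)
  expect_error(dataset_bundle(G, c(1, 2)), "one value per sample")
  expect_error(dataset_bundle(G, c(1, 2, 3), feature_ids = c("a", "a")), "unique")
  d <- dataset_bundle(G, c(1, 2, 3), missing_mask = matrix(c(TRUE, rep(FALSE, 5)), 3))
  expect_true(is.na(d$features[1, 1]))
})

test_that("pruning disabled reproduces the plain permutation test", {
  d <- null_dataset(N = 80, J = 40, seed = 3)
  plain <- run_enpp(d, schedule = NULL, R = 60, seed = 11)
  sch <- build_schedule(significance_params(p_raw = 0.9, p_adj = 0.9), 60)
  fake <- sch
  fake$thresholds <- rep(1000L, 60)  # unreachable thresholds
  withprune <- run_enpp(d, fake, seed = 11)
  expect_identical(plain$exceed_count, withprune$exceed_count)
  expect_identical(plain$p_value, withprune$p_value)
})

test_that("pruning never changes a survivor's p-value", {
  d <- null_dataset(N = 100, J = 120, seed = 4)
  sch <- build_schedule(significance_params(p_adj = 0.02), 80)
  pruned <- run_enpp(d, sch, seed = 21)
  plain <- run_enpp(d, schedule = NULL, R = 80, seed = 21)
  surv <- pruned$feature_id[pruned$status == "completed"]
  expect_gt(length(surv), 0)
  i <- match(surv, plain$feature_id)
  expect_identical(pruned$exceed_count[match(surv, pruned$feature_id)],
                   plain$exceed_count[i])
  expect_identical(pruned$p_value[match(surv, pruned$feature_id)],
                   plain$p_value[i])
})

test_that("about half of null features are pruned at the first round", {
  d <- null_dataset(N = 60, J = 1000, seed = 5, missing_rate = 0)
  sch <- build_schedule(significance_params(p_adj = 5e-5), 1)
  res <- run_enpp(d, sch, seed = 31)
  frac <- mean(res$status == "pruned")
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("run_enpp bookkeeping: statuses, counts, accounting, determinism", {
  d <- null_dataset(N = 90, J = 80, seed = 6)
  sch <- build_schedule(significance_params(p_adj = 0.05), 50)
  res <- run_enpp(d, sch, seed = 41)
  md <- attr(res, "metadata")
  expect_identical(md$total_tests_performed, sum(res$rounds_tested))
  expect_true(all(res$exceed_count <= res$rounds_tested))
  comp <- res$status == "completed"
  expect_true(all(res$rounds_tested[comp] == 50))
  pr <- res$status == "pruned"
  expect_true(all(res$rounds_tested[pr] == res$pruned_round[pr]))
  expect_true(all(res$exceed_count[pr] >= sch$thresholds[res$pruned_round[pr]]))
  expect_equal(res$p_value[comp], (1 + res$exceed_count[comp]) / 51)
  expect_equal(res$p_lower_bound[pr], res$exceed_count[pr] / res$rounds_tested[pr])
  # determinism: bit-identical rerun
  res2 <- run_enpp(d, sch, seed = 41)
  expect_identical(res, res2)
})

test_that("monomorphic features are flagged, not silently dropped", {
  d0 <- null_dataset(N = 50, J = 10, seed = 7, missing_rate = 0)
  G <- d0$features
  G[, 3] <- 1  # constant dosage
  d <- dataset_bundle(G, d0$phenotype, covariates = d0$covariates,
                      feature_ids = d0$feature_ids)
  sch <- build_schedule(significance_params(p_adj = 0.05), 10)
  res <- run_enpp(d, sch, seed = 3)
  expect_identical(res$status[3], "failed")
  expect_identical(res$rounds_tested[3], 0L)
  expect_identical(nrow(res), 10L)
})

test_that("a dominant feature completes with the minimum p-value", {
  set.seed(12)
  N <- 120
  g <- rbinom(N, 2, 0.4)
  y <- 5 * g + rnorm(N)  # overwhelming effect
  G <- cbind(hit = g, matrix(rbinom(N * 10, 2, 0.3), N,
                             dimnames = list(NULL, paste0("null", 1:10))))
  d <- dataset_bundle(G, y)
  sch <- build_schedule(significance_params(p_adj = 0.01), 99)
  res <- run_enpp(d, sch, seed = 9)
  expect_identical(res$status[1], "completed")
  expect_identical(res$exceed_count[1], 0L)
  expect_equal(res$p_value[1], 1 / 100)
})

test_that("full_permutation matches run_enpp survivors under a shared seed", {
  d <- null_dataset(N = 70, J = 50, seed = 8)
  sch <- build_schedule(significance_params(p_adj = 0.02), 40)
  res <- run_enpp(d, sch, seed = 17)
  surv <- res$feature_id[res$status == "completed"]
  fp <- full_permutation(d, surv, R_full = 40, seed = 17)
  expect_identical(fp$exceed_count,
                   res$exceed_count[match(surv, res$feature_id)])
  expect_identical(fp$p_value, res$p_value[match(surv, res$feature_id)])
  # empty survivor set: clean empty table
  e <- full_permutation(d, character(0), R_full = 10, seed = 1)
  expect_identical(nrow(e), 0L)
  expect_identical(attr(e, "metadata")$total_tests_performed, 0L)
  expect_error(full_permutation(d, "not_a_feature", R_full = 5, seed = 1), "subset")
})

test_that("a strongly associated feature survives pruning across seeds", {
  reps <- 20
  survived <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(1000 + i)
    N <- 150
    g <- rbinom(N, 2, 0.3)
    y <- 1.5 * g + rnorm(N)  # parametric p far below p_adj
    G <- cbind(hit = g, matrix(rbinom(N * 30, 2, 0.3), N,
                               dimnames = list(NULL, paste0("null", 1:30))))
    d <- dataset_bundle(G, y)
    sch <- build_schedule(significance_params(p_adj = 0.005), 100)
    res <- run_enpp(d, sch, seed = i)
    survived[i] <- res$status[1] == "completed"
  }
  expect_true(all(survived))
})

test_that("compare_with_parametric applies the exact binomial test per feature", {
  d <- null_dataset(N = 60, J = 20, seed = 9)
  sch <- build_schedule(significance_params(p_adj = 0.02), 30)
  res <- run_enpp(d, sch, seed = 13)
  p0 <- setNames(rep(0.5, 20), res$feature_id)
  cmp <- compare_with_parametric(res, p0)
  expect_identical(cmp$comparable, res$status == "completed")
  expect_true(all(is.na(cmp$comparison_p[!cmp$comparable])))
  i <- which(cmp$comparable)[1]
  expect_equal(cmp$comparison_p[i],
               exact_binom_compare(res$exceed_count[i], res$rounds_tested[i], 0.5))
  # permutation counts exactly at the null expectation compare near 1
  fake <- res[res$status == "completed", , drop = FALSE]
  attr(fake, "metadata") <- attr(res, "metadata")
  class(fake) <- class(res)
  k <- fake$exceed_count[1]
  p_match <- (k + 0.5) / 30
  cmp2 <- compare_with_parametric(fake, setNames(rep(p_match, nrow(fake)),
                                                 fake$feature_id))
  expect_gt(cmp2$comparison_p[1], 0.5)
  expect_error(compare_with_parametric(res, setNames(0.5, "missing_id")), "missing")
})

test_that("result tables round-trip through the tab-separated format", {
  d <- null_dataset(N = 50, J = 15, seed = 10)
  sch <- build_schedule(significance_params(p_adj = 0.05), 25)
  res <- run_enpp(d, sch, seed = 19)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(res, f)
  back <- read_result_table(f)
  expect_identical(back$feature_id, res$feature_id)
  expect_identical(back$exceed_count, res$exceed_count)
  expect_identical(back$status, res$status)
  expect_equal(back$s_obs, res$s_obs, tolerance = 0)
  expect_equal(back$p_value, res$p_value, tolerance = 0)
  expect_identical(attr(back, "metadata")$R, 25)
  # idempotent rewrite: identical bytes
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(res, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("end-to-end family-wise error on null data stays near nominal", {
  # scaled-down analogue of the full experiment: 400 null features per
  # replicate, 100 Bonferroni families (p_adj = 0.0125 = 0.05 / 4 features
  # per family... i.e. J/family = p_raw / p_adj = 4), pruning for 150
  # rounds then an unpruned follow-up of 799 rounds on survivors
  reps <- 12
  fams <- 400 * 0.0125 / 0.05
  fp <- numeric(reps)
  sch <- build_schedule(significance_params(p_raw = 0.05, p_adj = 0.0125), 150)
  for (i in seq_len(reps)) {
    d <- null_dataset(N = 60, J = 400, seed = 500 + i, missing_rate = 0)
    res <- run_enpp(d, sch, seed = 600 + i)
    surv <- res$feature_id[res$status == "completed"]
    fres <- full_permutation(d, surv, R_full = 799, seed = 700 + i)
    fp[i] <- sum(fres$p_value <= 0.0125)
  }
  rates <- fp / fams
  est <- mean(rates)
  se <- sd(rates) / sqrt(reps)
  expect_lt(est, 0.05 + 3 * max(se, 0.01))
  expect_gt(est, 0.05 - 3 * max(se, 0.01))
})
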