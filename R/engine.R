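#' Aligned feature/phenotype/covariate bundle
#'
#' The container consumed by [run_enpp()]: an N x J feature matrix (genotype
#' dosages 0/1/2 or any numeric features), a length-N phenotype, an optional
#' N x q covariate matrix, a missing-data mask, and unique feature and sample
#' identifiers. `NA` entries in `features` and `missing_mask` are kept in
#' sync.
#'
#' @param features numeric matrix, N samples x J features.
#' @param phenotype numeric vector, length N.
#' @param covariates numeric matrix N x q or `NULL`.
#' @param missing_mask logical N x J matrix; defaults to `is.na(features)`.
#' @param feature_ids character vector of J unique identifiers; defaults to
#'   column names or `f1..fJ`.
#' @param sample_ids character vector of N unique identifiers; defaults to
#'   row names or `s1..sN`.
#' @return An object of class `enpp_dataset`.
#' @export
dataset_bundle <- function(features, phenotype, covariates = NULL,
                           missing_mask = NULL, feature_ids = NULL,
                           sample_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  N <- nrow(features); J <- ncol(features)
  .assert(J >= 1, "dataset must contain at least one feature")
  .assert(is.numeric(phenotype) && length(phenotype) == N,
          "phenotype must be numeric with one value per sample")
  .assert(!anyNA(phenotype), "phenotype must not contain missing values")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    .assert(nrow(covariates) == N, "covariates must have one row per sample")
    .assert(!anyNA(covariates), "covariates must not contain missing values")
  }
  if (is.null(missing_mask)) missing_mask <- is.na(features)
  missing_mask <- as.matrix(missing_mask)
  .assert(identical(dim(missing_mask), dim(features)) && is.logical(missing_mask),
          "missing_mask must be a logical matrix matching features")
  features[missing_mask] <- NA
  feature_ids <- feature_ids %||% colnames(features) %||% paste0("f", seq_len(J))
  sample_ids <- sample_ids %||% rownames(features) %||% paste0("s", seq_len(N))
  .assert(length(feature_ids) == J && !anyDuplicated(feature_ids),
          "feature_ids must be unique, one per feature")
  .assert(length(sample_ids) == N && !anyDuplicated(sample_ids),
          "sample_ids must be unique, one per sample")
  colnames(features) <- feature_ids
  dimnames(missing_mask) <- dimnames(features)
  structure(list(features = features, phenotype = phenotype,
                 covariates = covariates, missing_mask = missing_mask,
                 feature_ids = as.character(feature_ids),
                 sample_ids = as.character(sample_ids)),
            class = "enpp_dataset")
}

#' @export
print.enpp_dataset <- function(x, ...) {
  cat(sprintf("enpp dataset: %d samples x %d features, %d covariate(s), %.2f%% missing\n",
              length(x$phenotype), length(x$feature_ids),
              if (is.null(x$covariates)) 0L else ncol(x$covariates),
              100 * mean(x$missing_mask)))
  invisible(x)
}

# shared permutation runner; thresholds may contain Inf (pruning disabled).
# Each round's permutation depends only on (seed, round index), never on the
# pruning history, so pruning cannot change a survivor's exceedance count.
.permute_engine <- function(data, thresholds, R, stat, seed,
                            include_observed = TRUE, verbose = FALSE,
                            permute_residuals = FALSE) {
  N <- length(data$phenotype)
  J <- length(data$feature_ids)
  ctx <- stat$prepare(data$features, data$phenotype, data$covariates,
                      data$missing_mask)
  ok <- ctx$ok
  y <- data$phenotype
  s_obs <- rep(NA_real_, J)
  s_obs[ok] <- stat$evaluate(ctx, y, cols = which(ok))

  if (permute_residuals) {
    X <- cbind(rep(1, N), data$covariates)
    fit <- qr(X)
    y_res <- qr.resid(fit, y)
    y_hat <- y - y_res
  }

  round_seeds <- .derive_seeds(seed, R)
  counts <- integer(J)
  rounds_tested <- integer(J)
  pruned_round <- rep(NA_integer_, J)
  active <- which(ok)
  checkpoints <- if (verbose) .log_rounds(R) else integer()
  total_tests <- 0
  for (r in seq_len(R)) {
    if (!length(active)) break
    set.seed(round_seeds[r])
    perm <- sample.int(N)
    yp <- if (permute_residuals) y_hat + y_res[perm] else y[perm]
    s_perm <- stat$evaluate(ctx, yp, cols = active)
    counts[active] <- counts[active] + exceeds(s_obs[active], s_perm, stat$alternative)
    rounds_tested[active] <- r
    total_tests <- total_tests + length(active)
    if (is.finite(thresholds[r])) {
      hit <- counts[active] >= thresholds[r]
      if (any(hit)) {
        pruned_round[active[hit]] <- r
        active <- active[!hit]
      }
    }
    if (r %in% checkpoints) {
      message(sprintf("round %d: %d active, %d cumulative tests, running ICE %.4g",
                      r, length(active), total_tests, total_tests / (J * r)))
    }
  }

  status <- ifelse(!ok, "failed",
                   ifelse(!is.na(pruned_round), "pruned", "completed"))
  completed <- status == "completed"
  pruned <- status == "pruned"
  p_value <- rep(NA_real_, J)
  p_value[completed] <- permutation_pvalue(counts[completed], R, include_observed)
  p_lower <- rep(NA_real_, J)
  p_lower[pruned] <- counts[pruned] / rounds_tested[pruned]

  res <- data.frame(feature_id = data$feature_ids, s_obs = s_obs,
                    exceed_count = counts, rounds_tested = rounds_tested,
                    status = status, pruned_round = pruned_round,
                    p_value = p_value, p_lower_bound = p_lower,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "metadata") <- list(
    seed = seed, R = R, statistic = stat$name, alternative = stat$alternative,
    include_observed = include_observed,
    total_tests_performed = sum(rounds_tested),
    n_failed = sum(!ok))
  class(res) <- c("enpp_result", "data.frame")
  res
}

#' Run the pruned permutation test
#'
#' Runs the full pruning procedure on a dataset: the observed statistic is
#' computed once per feature, then for each round `r = 1..R` one shared
#' random permutation of the phenotype is drawn, the statistic is recomputed
#' for every still-active feature, exceedance counts are accumulated, and
#' every active feature whose count has reached `C_prun(r)` is pruned from
#' all later rounds. Survivors receive the permutation p-value
#' `(1 + count) / (R + 1)`; pruned features only a running lower bound
#' `count / rounds_tested` (their counts form a stopped sequence, not a
#' valid p-value estimate). Features on which the statistic is undefined
#' (e.g. monomorphic genotypes) are flagged `"failed"` and excluded before
#' round 1, never silently dropped.
#'
#' Permutations are seeded per round from the master seed, independently of
#' the pruning history, so identical seeds give bit-identical results and
#' pruning never changes a survivor's p-value.
#'
#' @param data an [dataset_bundle()].
#' @param schedule an `enpp_schedule` from [build_schedule()], or `NULL` to
#'   disable pruning (plain permutation test over `R` rounds).
#' @param stat an [stat_spec()]; default the additive-genotype t-statistic,
#'   two-sided.
#' @param seed integer master seed.
#' @param R number of rounds when `schedule` is `NULL`; otherwise taken from
#'   the schedule.
#' @param include_observed use the `+1` p-value convention (default `TRUE`).
#' @param verbose log per-round active counts and running inverse
#'   computational efficiency.
#' @param permute_residuals permute residuals of the phenotype on the
#'   covariates instead of the raw phenotype (Freedman-Lane style). Off by
#'   default: the plain procedure shuffles the raw phenotype.
#' @return An `enpp_result` data frame with columns `feature_id`, `s_obs`,
#'   `exceed_count`, `rounds_tested`, `status`, `pruned_round`, `p_value`,
#'   `p_lower_bound`, and run metadata in `attr(, "metadata")`.
#' @examples
#' cfg <- synth_config(N = 60, J = 20, seed = 2)
#' d <- generate_dataset(cfg)
#' sch <- build_schedule(significance_params(p_adj = 0.0025), R = 50)
#' res <- run_enpp(d, sch, seed = 7)
#' table(res$status)
#' @export
run_enpp <- function(data, schedule, stat = stat_spec(), seed = 1L, R = NULL,
                     include_observed = TRUE, verbose = FALSE,
                     permute_residuals = FALSE) {
  .assert(inherits(data, "enpp_dataset"), "data must be a dataset_bundle()")
  .assert(inherits(stat, "enpp_stat_spec"), "stat must be a stat_spec()")
  if (is.null(schedule)) {
    .assert(.is_count(R), "R must be given when schedule is NULL")
    thresholds <- rep(Inf, R)
  } else {
    .assert(inherits(schedule, "enpp_schedule"), "schedule must be an enpp_schedule")
    thresholds <- schedule$thresholds
    R <- schedule$R
  }
  res <- .permute_engine(data, thresholds, R, stat, seed,
                         include_observed = include_observed, verbose = verbose,
                         permute_residuals = permute_residuals)
  md <- attr(res, "metadata")
  md$p_adj <- if (is.null(schedule)) NA_real_ else schedule$params$p_adj
  md$p_prun <- if (is.null(schedule)) NA_real_ else schedule$params$p_prun
  attr(res, "metadata") <- md
  res
}

#' Unpruned follow-up permutation test on selected features
#'
#' A plain permutation test (no pruning) over `R_full` rounds restricted to
#' the given features, typically the survivors of [run_enpp()]. Uses its own
#' seed: the pruning stage and the follow-up are independent permutation
#' streams.
#'
#' @param data an [dataset_bundle()].
#' @param feature_ids features to test; `NULL` means all.
#' @param R_full number of permutation rounds.
#' @inheritParams run_enpp
#' @return An `enpp_result` for the selected features.
#' @export
full_permutation <- function(data, feature_ids = NULL, R_full, stat = stat_spec(),
                             seed = 1L, include_observed = TRUE, verbose = FALSE,
                             permute_residuals = FALSE) {
  .assert(inherits(data, "enpp_dataset"), "data must be a dataset_bundle()")
  .assert(.is_count(R_full), "R_full must be a positive integer")
  if (is.null(feature_ids)) feature_ids <- data$feature_ids
  if (!length(feature_ids)) {
    res <- data.frame(feature_id = character(), s_obs = numeric(),
                      exceed_count = integer(), rounds_tested = integer(),
                      status = character(), pruned_round = integer(),
                      p_value = numeric(), p_lower_bound = numeric(),
                      stringsAsFactors = FALSE)
    attr(res, "metadata") <- list(seed = seed, R = R_full, statistic = stat$name,
                                  alternative = stat$alternative,
                                  include_observed = include_observed,
                                  total_tests_performed = 0L, n_failed = 0L)
    class(res) <- c("enpp_result", "data.frame")
    return(res)
  }
  .assert(all(feature_ids %in% data$feature_ids),
          "feature_ids must be a subset of the dataset's features")
  idx <- match(feature_ids, data$feature_ids)
  sub <- dataset_bundle(data$features[, idx, drop = FALSE], data$phenotype,
                        covariates = data$covariates,
                        missing_mask = data$missing_mask[, idx, drop = FALSE],
                        feature_ids = data$feature_ids[idx],
                        sample_ids = data$sample_ids)
  .permute_engine(sub, rep(Inf, R_full), R_full, stat, seed,
                  include_observed = include_observed, verbose = verbose,
                  permute_residuals = permute_residuals)
}

#' Compare permutation results with parametric p-values
#'
#' For every completed feature, applies [exact_binom_compare()] with the
#' feature's parametric p-value as the null exceedance probability. Pruned
#' and failed features are marked not comparable.
#'
#' @param result an `enpp_result`.
#' @param parametric named numeric vector of parametric p-values, or a data
#'   frame with columns `feature_id` and `p_parametric`.
#' @return Data frame with columns `feature_id`, `exceed_count`,
#'   `rounds_tested`, `p_parametric`, `comparison_p`, `comparable`.
#' @export
compare_with_parametric <- function(result, parametric) {
  .assert(inherits(result, "enpp_result"), "result must be an enpp_result")
  if (is.data.frame(parametric)) {
    .assert(all(c("feature_id", "p_parametric") %in% names(parametric)),
            "parametric data frame needs feature_id and p_parametric columns")
    p0 <- setNames(parametric$p_parametric, parametric$feature_id)
  } else {
    .assert(!is.null(names(parametric)), "parametric vector must be named by feature")
    p0 <- parametric
  }
  .assert(all(result$feature_id %in% names(p0)),
          "parametric p-values missing for some features")
  p0 <- p0[result$feature_id]
  comparable <- result$status == "completed"
  comparison <- rep(NA_real_, nrow(result))
  for (i in which(comparable)) {
    comparison[i] <- exact_binom_compare(result$exceed_count[i],
                                         result$rounds_tested[i], p0[[i]])
  }
  data.frame(feature_id = result$feature_id,
             exceed_count = result$exceed_count,
             rounds_tested = result$rounds_tested,
             p_parametric = unname(p0),
             comparison_p = comparison,
             comparable = comparable,
             stringsAsFactors = FALSE)
}

#' @export
print.enpp_result <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("enpp result: %d features over %d rounds (%s, %s)\n",
              nrow(x), md$R, md$statistic, md$alternative))
  cat(sprintf("  completed %d | pruned %d | failed %d | total tests %d\n",
              sum(x$status == "completed"), sum(x$status == "pruned"),
              sum(x$status == "failed"), md$total_tests_performed))
  NextMethod()
}

#' Write / read a result table
#'
#' Tab-separated text with the run metadata in commented header lines and
#' the columns `feature_id`, `s_obs`, `exceed_count`, `rounds_tested`,
#' `status`, `pruned_round`, `p_value`, `p_lower_bound`. Numeric columns are
#' written at full precision so the round trip is lossless.
#'
#' @param result an `enpp_result`.
#' @param path file path.
#' @return `write_result_table` returns `path` invisibly; `read_result_table`
#'   the reconstructed `enpp_result`.
#' @export
write_result_table <- function(result, path) {
  .assert(inherits(result, "enpp_result"), "result must be an enpp_result")
  md <- attr(result, "metadata")
  hdr <- c(.provenance_header(seed = md$seed, config = md),
           sprintf("# %s=%s", names(md), vapply(md, function(v)
             if (is.numeric(v)) .fmt_num(v) else as.character(v), "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- result
  for (cn in c("s_obs", "p_value", "p_lower_bound")) out[[cn]] <- .fmt_num(out[[cn]])
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# [A-Za-z_]+=", lines, value = TRUE)
  kv <- sub("^# ", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  md <- as.list(setNames(vals, keys))
  for (k in c("seed", "R", "total_tests_performed", "n_failed"))
    if (!is.null(md[[k]])) md[[k]] <- as.numeric(md[[k]])
  for (k in c("p_adj", "p_prun")) if (!is.null(md[[k]])) md[[k]] <- as.numeric(md[[k]])
  if (!is.null(md$include_observed)) md$include_observed <- as.logical(md$include_observed)
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t", colClasses = c(feature_id = "character"),
                    stringsAsFactors = FALSE)
  attr(tab, "metadata") <- md
  class(tab) <- c("enpp_result", "data.frame")
  tab
}
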