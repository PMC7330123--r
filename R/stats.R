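#' Covariate-adjusted additive-genotype t-statistic
#'
#' The t-statistic for the genotype coefficient in the least-squares fit of
#' `y` on `[intercept, covariates, g]`, with the genotype coded as a minor
#' allele dosage 0/1/2 (any numeric coding works; the model is linear in
#' `g`). Internally the residualization shortcut is used: `y` and `g` are
#' both residualized on `[intercept, covariates]` and a simple regression of
#' the residuals with `N - q - 2` degrees of freedom gives a t identical to
#' the full-design fit.
#'
#' @param y numeric phenotype vector, length N.
#' @param g numeric genotype vector, length N. `NA`s are mean-imputed
#'   (`na_action = "impute"`, the default) or dropped together with the
#'   matching rows of `y` and covariates (`na_action = "omit"`).
#' @param covariates numeric matrix N x q, or `NULL`. An intercept is always
#'   added; do not include one.
#' @param na_action `"impute"` or `"omit"` for missing genotypes.
#' @return The t-statistic (signed). A perfect linear fit (zero residual
#'   variance) returns `Inf` with the sign of the genotype coefficient.
#' @examples
#' set.seed(1)
#' g <- rbinom(50, 2, 0.3)
#' y <- 0.5 * g + rnorm(50)
#' lm_additive_t(y, g)
#' @export
lm_additive_t <- function(y, g, covariates = NULL, na_action = c("impute", "omit")) {
  na_action <- match.arg(na_action)
  .assert(is.numeric(y) && is.numeric(g) && length(y) == length(g),
          "y and g must be numeric vectors of equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    .assert(nrow(covariates) == length(y), "covariates must have one row per sample")
  }
  if (anyNA(g)) {
    if (na_action == "impute") {
      g[is.na(g)] <- mean(g, na.rm = TRUE)
    } else {
      keep <- !is.na(g)
      y <- y[keep]; g <- g[keep]
      if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
    }
  }
  .assert(!anyNA(y), "phenotype contains missing values")
  ctx <- .prepare_lm_additive_t(matrix(g, ncol = 1), covariates, length(y))
  .assert(ctx$ok[1], "genotype is constant after missing-data handling; t undefined")
  .evaluate_lm_additive_t(ctx, y)[1]
}

# shared preparation: residualize all feature columns on [intercept, covariates]
.prepare_lm_additive_t <- function(G, covariates, N) {
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  .assert(N > q + 2, "need N > q + 2 samples for the genotype t-statistic")
  X <- cbind(rep(1, N), covariates)
  qrX <- qr(X)
  .assert(qrX$rank == ncol(X),
          "covariate design is rank deficient (collinear columns)")
  Gr <- qr.resid(qrX, G)
  gss <- colSums(Gr^2)
  scale <- colSums(G^2) + 1
  ok <- gss > 1e-12 * scale
  list(qrX = qrX, Gr = Gr, gss = gss, ok = ok, df = N - q - 2L, N = N)
}

# t statistics for all (or a subset of) prepared features against one y
.evaluate_lm_additive_t <- function(ctx, y, cols = NULL) {
  yr <- qr.resid(ctx$qrX, y)
  yss <- sum(yr^2)
  Gr <- if (is.null(cols)) ctx$Gr else ctx$Gr[, cols, drop = FALSE]
  gss <- if (is.null(cols)) ctx$gss else ctx$gss[cols]
  num <- as.vector(crossprod(Gr, yr))
  rss <- yss - num^2 / gss
  s2 <- rss / ctx$df
  t <- num / sqrt(gss * s2)
  perfect <- s2 <= 1e-14 * (yss / ctx$df + 1e-300)
  if (any(perfect)) t[perfect] <- sign(num[perfect]) * Inf
  t
}

# ---- statistic registry ----------------------------------------------------

.stat_registry <- new.env(parent = emptyenv())

#' Register a permutation test statistic
#'
#' Adds a named statistic to the registry used by [run_enpp()]. A statistic
#' is a `prepare(features, phenotype, covariates, missing_mask)` function
#' returning a context list with at least fields `ok` (logical, per feature:
#' statistic well defined) and `evaluate(ctx, y, cols)` computing the
#' statistic of every (or the selected) prepared feature against a phenotype
#' vector.
#'
#' @param name statistic identifier.
#' @param prepare preparation function (see Details).
#' @param evaluate evaluation function `(ctx, y, cols = NULL)`.
#' @param handles_covariates logical flag.
#' @return `name`, invisibly.
#' @export
register_statistic <- function(name, prepare, evaluate, handles_covariates = TRUE) {
  .assert(is.character(name) && length(name) == 1L, "name must be a string")
  .assert(is.function(prepare) && is.function(evaluate),
          "prepare and evaluate must be functions")
  assign(name, list(prepare = prepare, evaluate = evaluate,
                    handles_covariates = handles_covariates),
         envir = .stat_registry)
  invisible(name)
}

#' @rdname register_statistic
#' @export
list_statistics <- function() sort(ls(.stat_registry))

#' Statistic specification
#'
#' Selects a registered statistic by name together with the sidedness of the
#' exceedance rule. The default is the covariate-adjusted additive-genotype
#' t-statistic under a two-sided alternative (both tails of the t matter in
#' a GWAS scan).
#'
#' @param name registered statistic name; see [list_statistics()].
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return An object of class `enpp_stat_spec`.
#' @export
stat_spec <- function(name = "lm_additive_t",
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .assert(exists(name, envir = .stat_registry),
          "unknown statistic '", name, "'; see list_statistics()")
  impl <- get(name, envir = .stat_registry)
  structure(list(name = name, alternative = alternative,
                 handles_covariates = impl$handles_covariates,
                 prepare = impl$prepare, evaluate = impl$evaluate),
            class = "enpp_stat_spec")
}

register_statistic(
  "lm_additive_t",
  prepare = function(features, phenotype, covariates, missing_mask) {
    G <- features
    if (!is.null(missing_mask) && any(missing_mask)) G[missing_mask] <- NA
    if (anyNA(G)) {
      mu <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G))
      G[idx] <- mu[(idx - 1L) %/% nrow(G) + 1L]
    }
    .prepare_lm_additive_t(G, covariates, nrow(G))
  },
  evaluate = .evaluate_lm_additive_t)

# ---- exceedance and p-values ----------------------------------------------

#' Exceedance indicator
#'
#' Whether a permuted statistic is at least as extreme as the observed one.
#' Ties count as exceedances (the comparison is non-strict). Two-sided
#' compares absolute values.
#'
#' @param s_obs observed statistic (scalar or vector).
#' @param s_perm permuted statistic(s).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return Integer 0/1 vector.
#' @examples
#' exceeds(2.0, 2.0)          # 1: ties are exceedances
#' exceeds(2.0, -2.5)         # 1: two-sided uses |s|
#' exceeds(2.0, 1.9, "greater")  # 0
#' @export
exceeds <- function(s_obs, s_perm, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .assert(!anyNA(s_obs) && !anyNA(s_perm), "statistics must not be NA")
  out <- switch(alternative,
                two.sided = abs(s_perm) >= abs(s_obs),
                greater   = s_perm >= s_obs,
                less      = s_perm <= s_obs)
  as.integer(out)
}

#' Permutation p-value from an exceedance count
#'
#' With `include_observed = TRUE` (default) the estimator is
#' `(1 + count) / (rounds + 1)`, which counts the observed arrangement as
#' one permutation and is never zero; without it, `count / rounds`.
#'
#' @param exceed_count number of exceedances, `0 <= count <= rounds`.
#' @param rounds number of permutation rounds, `>= 1`.
#' @param include_observed apply the +1 correction (default `TRUE`).
#' @return p-value(s).
#' @examples
#' permutation_pvalue(0, 999)  # 0.001
#' permutation_pvalue(4, 9)    # 0.5
#' @export
permutation_pvalue <- function(exceed_count, rounds, include_observed = TRUE) {
  .assert(all(rounds >= 1) && all(exceed_count >= 0),
          "need rounds >= 1 and exceed_count >= 0")
  .assert(all(exceed_count <= rounds), "exceed_count cannot exceed rounds")
  if (include_observed) (1 + exceed_count) / (rounds + 1) else exceed_count / rounds
}

#' Exact binomial comparison of permutation and parametric p-values
#'
#' Two-sided exact binomial test of H0: exceedance probability = `p0`, given
#' `exceed_count` exceedances in `rounds` permutation rounds, where `p0` is
#' the parametric p-value for the same feature. Uses the minimum-likelihood
#' two-sided convention of [stats::binom.test()]: all outcomes whose
#' probability under H0 is no larger than that of the observed count
#' contribute.
#'
#' @param exceed_count observed exceedances.
#' @param rounds permutation rounds.
#' @param p0 null exceedance probability (the parametric p-value), in (0, 1).
#' @return Comparison p-value.
#' @export
exact_binom_compare <- function(exceed_count, rounds, p0) {
  .assert(.is_count(rounds) || rounds == 0, "rounds must be a positive integer")
  .assert(rounds >= 1, "rounds must be >= 1")
  .assert(exceed_count >= 0 && exceed_count <= rounds && exceed_count == floor(exceed_count),
          "exceed_count must be an integer in 0..rounds")
  .assert(.is_prob(p0) && p0 > 0 && p0 < 1, "p0 must lie strictly in (0, 1)")
  stats::binom.test(exceed_count, rounds, p = p0)$p.value
}
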