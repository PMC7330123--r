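# ---- skewed phenotype families ---------------------------------------------
# All families are generated on a fasting-plasma-glucose-like scale
# (mg/dL-flavoured: bulk near 95, sd near 19) so covariate and allele effect
# sizes have interpretable units.

# lognormal: skewness s solves (w + 2) sqrt(w - 1) = s with w = exp(sigma^2)
.lognormal_sigma <- function(target) {
  .assert(target > 0, "lognormal family needs positive target skewness")
  f <- function(s) { w <- exp(s^2); (w + 2) * sqrt(w - 1) - target }
  uniroot(f, c(1e-6, 5), tol = 1e-12)$root
}

# two-component mixture: Normal(92, 9) normoglycemic bulk plus, with mixing
# fraction q, a shifted-Gamma hyperglycemic tail 120 + Gamma(1.6, scale 38).
# q is solved from the analytic mixture moments so the population skewness
# hits the target; the upper root is used (the higher, more stable
# prevalence). Raw skewness targets up to ~6 are feasible.
.MIX <- list(m1 = 92, s1 = 9, delta = 120, shape = 1.6, scale = 38)

.mixture_skew <- function(q, mx = .MIX) {
  rm_norm <- c(mx$m1, mx$m1^2 + mx$s1^2, mx$m1^3 + 3 * mx$m1 * mx$s1^2)
  gm <- mx$shape * mx$scale
  gv <- mx$shape * mx$scale^2
  gm3c <- 2 * mx$shape * mx$scale^3
  g1 <- mx$delta + gm
  rmg <- c(g1, gv + g1^2, gm3c + 3 * g1 * gv + g1^3)
  rm <- (1 - q) * rm_norm + q * rmg
  mu <- rm[1]; v <- rm[2] - mu^2
  (rm[3] - 3 * mu * v - mu^3) / v^1.5
}

.mixture_solve_q <- function(target) {
  opt <- optimize(.mixture_skew, c(1e-5, 0.5), maximum = TRUE)
  .assert(target <= opt$objective,
          sprintf("target skewness %.3g infeasible for the mixture family (max %.3g)",
                  target, opt$objective))
  .assert(target > .mixture_skew(0.5),
          "target skewness too small for the mixture family; use gaussian")
  uniroot(function(q) .mixture_skew(q) - target,
          c(opt$maximum, 0.5), tol = 1e-12)$root
}

.draw_phenotype_noise <- function(N, family, target_skewness) {
  switch(family,
    gaussian = rnorm(N, 95, 19),
    skewed_lognormal = {
      sigma <- .lognormal_sigma(target_skewness)
      z <- exp(sigma * rnorm(N))
      w <- exp(sigma^2)
      mu <- exp(sigma^2 / 2); sd0 <- sqrt((w - 1) * w)
      95 + 19 * (z - mu) / sd0
    },
    skewed_chisq = {
      df <- 8 / target_skewness^2
      95 + 19 * (rchisq(N, df) - df) / sqrt(2 * df)
    },
    skewed_mixture = {
      q <- .mixture_solve_q(target_skewness)
      tail_draw <- runif(N) < q
      n_tail <- sum(tail_draw)
      y <- rnorm(N, .MIX$m1, .MIX$s1)
      y[tail_draw] <- .MIX$delta + rgamma(n_tail, .MIX$shape, scale = .MIX$scale)
      y
    },
    stop("unknown phenotype family: ", family, call. = FALSE))
}

#' Configuration of the synthetic GWAS-like generator
#'
#' Describes a dataset with the statistical structure of a quantitative-trait
#' GWAS: per-feature SNP dosages drawn Binomial(2, MAF) with MAF uniform on
#' `maf_range`, a strongly right-skewed quantitative phenotype (the
#' fasting-plasma-glucose-like default `"skewed_mixture"` is a normoglycemic
#' Normal bulk plus a ~4% hyperglycemic Gamma tail calibrated to the target
#' skewness), age/sex/region covariates with additive effects, optional
#' causal SNPs with additive per-allele slopes, and missing genotypes masked
#' completely at random.
#'
#' @param N samples.
#' @param J features (SNPs).
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param n_causal number of causal SNPs (`<= J`).
#' @param effect_sizes per-causal additive slope (phenotype units per minor
#'   allele); recycled to `n_causal`. Default 2.
#' @param phenotype_family `"skewed_mixture"` (default), `"skewed_lognormal"`,
#'   `"skewed_chisq"` or `"gaussian"`.
#' @param target_skewness target skewness of the phenotype noise (default
#'   5.32, a heavily skewed fasting-glucose-like trait).
#' @param covariate_effects named slopes for the `age` (per year, centred at
#'   55), `sex` (0/1) and `region` (0/1, two recruitment cohorts) covariates.
#' @param missing_rate per-entry genotype missingness probability in [0, 1).
#' @param seed integer seed; the generator is fully reproducible.
#' @return An object of class `enpp_synth_config`.
#' @export
synth_config <- function(N = 8842L, J = 1000L, maf_range = c(0.05, 0.5),
                         n_causal = 0L, effect_sizes = 2,
                         phenotype_family = c("skewed_mixture", "skewed_lognormal",
                                              "skewed_chisq", "gaussian"),
                         target_skewness = 5.32,
                         covariate_effects = c(age = 0.15, sex = 1.5, region = 1.0),
                         missing_rate = 0.01, seed = 1L) {
  phenotype_family <- match.arg(phenotype_family)
  .assert(.is_count(N) && .is_count(J), "N and J must be positive integers")
  .assert(is.numeric(maf_range) && length(maf_range) == 2 &&
            maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
          "maf_range must be an interval within (0, 0.5]")
  .assert(n_causal >= 0 && n_causal <= J && n_causal == floor(n_causal),
          "n_causal must be an integer in 0..J")
  .assert(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  .assert(all(c("age", "sex", "region") %in% names(covariate_effects)),
          "covariate_effects must name age, sex and region")
  if (n_causal > 0) {
    effect_sizes <- rep_len(effect_sizes, n_causal)
  } else {
    effect_sizes <- numeric(0)
  }
  # fail early on an infeasible skewness target
  if (phenotype_family == "skewed_mixture") .mixture_solve_q(target_skewness)
  if (phenotype_family == "skewed_lognormal") .lognormal_sigma(target_skewness)
  if (phenotype_family == "skewed_chisq")
    .assert(target_skewness > 0, "chisq family needs positive skewness")
  structure(list(N = as.integer(N), J = as.integer(J), maf_range = maf_range,
                 n_causal = as.integer(n_causal), effect_sizes = effect_sizes,
                 phenotype_family = phenotype_family,
                 target_skewness = target_skewness,
                 covariate_effects = covariate_effects,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "enpp_synth_config")
}

#' Generate a synthetic GWAS-like dataset
#'
#' Draws the dataset described by a [synth_config()]: genotypes
#' Binomial(2, MAF) per feature, covariates (age uniform on 40-70, binary
#' sex, binary recruitment region), phenotype = covariate effects + additive
#' causal effects + skewed noise, and a completely-at-random missing-genotype
#' mask. Identical configurations produce byte-identical datasets.
#'
#' @param config an `enpp_synth_config`.
#' @return An [dataset_bundle()] whose `attr(, "metadata")` records the
#'   config, the causal feature ids and the drawn MAFs.
#' @examples
#' d <- generate_dataset(synth_config(N = 100, J = 50, n_causal = 2, seed = 3))
#' attr(d, "metadata")$causal_ids
#' @export
generate_dataset <- function(config) {
  .assert(inherits(config, "enpp_synth_config"), "config must be a synth_config()")
  set.seed(config$seed)
  N <- config$N; J <- config$J
  maf <- runif(J, config$maf_range[1], config$maf_range[2])
  G <- matrix(rbinom(N * J, 2L, rep(maf, each = N)), nrow = N, ncol = J)
  age <- runif(N, 40, 70)
  sex <- rbinom(N, 1L, 0.5)
  region <- rbinom(N, 1L, 0.5)
  covariates <- cbind(age = age, sex = sex, region = region)
  ce <- config$covariate_effects
  lin <- ce[["age"]] * (age - 55) + ce[["sex"]] * sex + ce[["region"]] * region
  causal_idx <- if (config$n_causal > 0) sort(sample.int(J, config$n_causal)) else integer(0)
  if (length(causal_idx)) {
    lin <- lin + as.vector(G[, causal_idx, drop = FALSE] %*% config$effect_sizes)
  }
  noise <- .draw_phenotype_noise(N, config$phenotype_family, config$target_skewness)
  phenotype <- lin + noise
  mask <- if (config$missing_rate > 0) {
    matrix(runif(N * J) < config$missing_rate, N, J)
  } else {
    matrix(FALSE, N, J)
  }
  feature_ids <- sprintf("snp%0*d", nchar(J), seq_len(J))
  sample_ids <- sprintf("id%0*d", nchar(N), seq_len(N))
  Gm <- G
  Gm[mask] <- NA
  d <- dataset_bundle(Gm, phenotype, covariates = covariates,
                      missing_mask = mask, feature_ids = feature_ids,
                      sample_ids = sample_ids)
  attr(d, "metadata") <- list(config = unclass(config),
                              causal_ids = feature_ids[causal_idx],
                              maf = maf)
  d
}

#' Sample skewness
#'
#' The standard third-standardized-moment estimator
#' `m3 / m2^(3/2)` with central moments `mk = mean((x - mean(x))^k)`. Set
#' `log = TRUE` to measure the skewness after log-transformation (values
#' must be positive), the usual check of whether a transformation restores
#' symmetry.
#'
#' @param values numeric vector, length at least 3, non-constant.
#' @param log compute the skewness of `log(values)`.
#' @return Sample skewness.
#' @examples
#' sample_skewness(rexp(1e4))        # ~2
#' @export
sample_skewness <- function(values, log = FALSE) {
  .assert(is.numeric(values) && length(values) >= 3, "need at least 3 values")
  .assert(!anyNA(values), "values must not contain NA")
  if (log) {
    .assert(all(values > 0), "log skewness needs strictly positive values")
    values <- base::log(values)
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  .assert(m2 > 0, "skewness undefined for constant input")
  mean((values - m)^3) / m2^1.5
}
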