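---
title: "Pruned permutation testing: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pruned permutation testing: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enpp)
```

## The problem

For `N` samples with phenotype `Y` and `J` features `X_1, ..., X_J`, a
permutation test locates the observed statistic `s_obs` of each feature in
an empirical null distribution built from `R` random shufflings of the
phenotype:

$$P_{perm} = \frac{1 + \sum_{r=1}^{R} I(|s_{obs}| \le |s_r|)}{R + 1},$$

where the `+1` terms count the observed arrangement as one permutation (a
flag lets you drop them). Each indicator event — a permuted statistic at
least as extreme as the observed one — is called an *exceedance*; ties count
as exceedances.

After Bonferroni correction at family-wise level `p_raw`, every feature must
resolve `p_adj = p_raw / J`, which requires more than `1 / p_adj` rounds.
For genome-scale `J` the total `J x R` statistic evaluations are
impractical. But almost all features are null, and a null feature betrays
itself fast: its exceedances arrive at the rate of its true permutation
p-value, which is typically orders of magnitude above `p_adj`.

## The pruning schedule

For a feature whose true permutation p-value is exactly `p_adj`, the
exceedance count after `r` rounds is `Binomial(r, p_adj)`. Pruning decides,
each round, the one-sided test

$$H_0: p = p_{adj} \quad \text{vs} \quad H_1: p > p_{adj}$$

at level `p_prun`, via the binomial tail
`p_{k|r} = P(Binomial(r, p_adj) >= k)`. The per-round integer threshold is

$$C_{prun}(r) = \min\{k \ge 1 : p_{k|r} \le p_{prun}\},$$

and a feature whose cumulative count reaches `C_prun(r)` at round `r` is
removed from all later rounds. With `p_prun = p_adj` (the default; both are
user-settable, and `p_adj` defaults to Bonferroni `p_raw / J`):

* round 1: `p_{1|1} = p_adj <= p_prun`, so `C_prun(1) = 1`;
* round 2: `p_{1|2} ≈ 2 p_adj > p_prun` but `p_{2|2} = p_adj^2 <= p_prun`,
  so `C_prun(2) = 2`;
* thresholds grow extremely slowly afterwards: for `p_adj = 5e-5` the
  maximum over 10,000 rounds is 6, and for `p_adj = 1e-7` the schedule is
  1, then 2 up to round 4,473, then 3.

`cprun_at()` returns the sentinel `r + 1` ("cannot prune at this round")
when no count `k <= r` satisfies the bound, which can only happen for
degenerate choices with `p_prun < p_adj`; this keeps the engine's
`count >= threshold` rule well defined with no special cases.
`build_schedule()` exploits that `r -> C_prun(r)` is non-decreasing (the
tail at fixed `k` grows with `r`), so the scan resumes at the previous
threshold and the whole schedule costs `O(R + max C)` tail evaluations.

### False-pruning risk

A truly significant feature could in principle be pruned by bad luck.
`false_prune_risk()` reports the union bound
$\sum_r p_{C_{prun}(r)|r}$ — the summed attained significance of the
per-round tests for a borderline feature with `p = p_adj`. For the
genome-scale default (`p_adj = p_prun = 1.52e-7`, 100,000 rounds) this sum
is ≈ 2.66e-3 (recomputed by both the test suite and the acceptance script),
so `admissible_true_signals()` = `floor(0.05 / risk)` = 18 truly significant
features can be carried while the family-wise probability of falsely
pruning any of them stays below 0.05. The union bound ignores that one
pruning event precludes later ones; `prune_hit_probability()` computes the
exact hitting probability of the count process by dynamic programming over
count states and is always smaller. The summed-significance form is the
quantity we report as *the* risk (it is the standard, conservative budget);
the exact DP is exposed as a diagnostic.

## Test statistic and permutation scheme

The default statistic is the t-statistic of the genotype coefficient in the
least-squares fit of the phenotype on an intercept, the covariates and the
additive minor-allele dosage (0/1/2). It is computed by residualization:
`y` and every genotype column are residualized on `[1, covariates]` once,
then the per-feature t is a simple-regression t of the residuals with
`N - q - 2` degrees of freedom — algebraically identical to the full-design
fit (the Frisch–Waugh–Lovell identity), and it turns a round's work for all
active features into one matrix–vector product. Missing genotypes are
mean-imputed per feature by default (complete-case analysis is available
for the scalar function), which keeps a single shared permutation of the
phenotype valid for every feature in a round. Monomorphic features are
flagged `failed` before round 1 and reported, never silently dropped.

Design choices worth stating:

* **Shared permutation.** One random permutation of the phenotype per round
  is shared by all active features. Each feature's exceedance sequence is
  still an exchangeable Bernoulli stream of the right rate; sharing makes a
  round `J`-fold cheaper. (Features' indicators are weakly dependent within
  a round, which affects no per-feature inference.)
* **Raw-phenotype permutation.** The phenotype vector itself is shuffled,
  covariates stay attached to the samples. Under the global null for a
  feature (genotype independent of phenotype and covariates) this is exact.
  A Freedman–Lane-style residual permutation (`permute_residuals = TRUE`)
  is available for users worried about covariate-induced dependence.
* **Two-sided default.** The exceedance rule compares `|s_perm| >= |s_obs|`
  by default; both tails of a t matter in a scan. One-sided alternatives
  are available.
* **Round-indexed seeding.** Round `r`'s permutation is derived from
  `(seed, r)` only, never from pruning history. Hence identical seeds give
  bit-identical results, pruning cannot change a survivor's exceedance
  count (a literally testable invariant), and the rounds could be
  parallelized without changing output.
* **Pruned features get a lower bound, not a p-value.** A pruned feature's
  count is a stopped sequence; `exceed_count / rounds_tested` is reported
  as `p_lower_bound` to make clear it is not an unbiased p-value estimate.

The follow-up `full_permutation()` on survivors is an independent stage
with its own seed: the pruning rounds and the precision rounds do not reuse
permutations.

## Evaluating the method: remaining and ICE curves

For a *null* feature, the true permutation p-value is uniform on (0, 1),
and its pruning fate depends only on the schedule, not the data. The
evaluation suite therefore simulates at the exceedance level: draw a latent
`p ~ U(0, 1)` per feature and Bernoulli(`p`) exceedances per round
(`method = "per_round"`), or — distributionally identically — only the
geometric waiting times between exceedances (`method = "geometric"`), which
needs `O(max C)` draws per feature regardless of `R` and makes
100,000-round experiments desk-scale. Closed forms anchor the curves: with
`C_prun(1) = 1` the expected pruned fraction at round 1 is
$\int_0^1 p\,dp = 1/2$; no pruning can happen at round 2 (survivors have
count 0, the threshold is 2); round 3 prunes another
$\int_0^1 (1-p)p^2\,dp = 1/12$.

`expected_remaining()` computes the deterministic expectation of the whole
curve by integrating the count process's survival probability over `p`
(dynamic programming over count states on a quadrature grid, see Numerics).

**Inverse computational efficiency (ICE)** is cumulative feature-tests
under pruning divided by the `n x r` tests of the unpruned test. Two
accounting conventions exist and *both appear in the method's literature,
inconsistently with each other*:

* `"entering"`: a feature pruned at round `r` pays for round `r` — its
  count was updated there, and it is removed from the *next* round. This is
  the actual work performed by the engine; the expected curve starts
  `1, 3/4, 2/3, 29/48` (efficiencies `1, 4/3, 3/2, 48/29`).
* `"surviving"`: the cumulative sum of the post-pruning remaining curve, as
  obtained when an efficiency figure is derived directly from a
  remaining-proportion figure. It treats the final, pruning-triggering
  round as saved and is smaller by exactly `(1 - remaining(r)/n)/r`;
  headline values such as "7.4% of the computation at round 100" are of
  this kind.

The package defaults to `"entering"` (it is the true cost) and exposes
`"surviving"` because reported curve values follow that construction; at
round 100 the two are ~8.4% and ~7.4%. By round 10,000 they agree to two
decimal places in percent.

### Type-I control

`type1_experiment()` runs the end-to-end procedure on null features at the
exceedance level: prune for `R` rounds, then give survivors an independent
`follow_up_R`-round follow-up (`Binomial(follow_up_R, p)` exceedances), and
declare significance at `P_perm <= p_adj`. With latent uniform `p`,
$\int_0^1 P(\text{Binomial}(R_f, p) \le c)\,dp = (c+1)/(R_f+1)$, so the
per-feature false-positive rate is exactly `p_adj` whenever
`p_adj (R_f + 1)` is an integer — choose `follow_up_R` accordingly (e.g.
1,999 for `p_adj = 5e-3`). False positives per replicate divided by the
number of Bonferroni families `n p_adj / p_raw` estimates the family-wise
rate; 1e6 features at `p_adj = 5e-5` expect 50 false positives over 1,000
families. Pruning removes a tiny fraction of would-be false positives
(bounded by the false-pruning risk), a deflation far inside Monte-Carlo
error at these scales. Confidence intervals use the replicate-level normal
approximation by default; an exact Clopper–Pearson interval on the pooled
count is available.

## Synthetic data

`generate_dataset()` emulates a quantitative-trait GWAS:

* **Genotypes**: per feature, MAF ~ Uniform(`maf_range`) and dosages
  `Binomial(2, MAF)` — Hardy–Weinberg equilibrium, no linkage
  disequilibrium between features (deliberately: correlated hit clusters
  are out of scope, and independent features are what the operating
  characteristics assume).
* **Covariates**: age ~ U(40, 70) years, binary sex, binary recruitment
  region (two cohorts), with additive effects (defaults 0.15 per year,
  1.5, 1.0 in phenotype units).
* **Phenotype**: covariate effects + additive causal-SNP effects + skewed
  noise.

The default noise family (`"skewed_mixture"`) models a fasting-glucose-like
trait: a normoglycemic Normal(92, 9) bulk plus, with mixing fraction `q`, a
hyperglycemic tail `120 + Gamma(shape 1.6, scale 38)` (mg/dL-flavoured
units; the units are arbitrary, the shape is the point). `q` is solved
analytically from the mixture moments so the *population* skewness equals
`target_skewness` (default 5.32, a heavily skewed glucose-like trait whose
skewness stays near 2.9 even after log-transformation). A mixture was
chosen over a single heavy-tailed family deliberately: a lognormal tuned to
skewness 5.3 has such heavy tails that the standard sample-skewness
estimator at N ≈ 9,000 is badly biased and wildly variable (observed spread
±1.6 across seeds), and its log is exactly normal, losing the
"still skewed after log" property that motivates permutation testing in the
first place. The mixture hits the raw-skewness target stably (±0.27 across
seeds at N = 8,842) and keeps the log-scale skew. `"skewed_lognormal"`
(σ solved from the skewness equation), `"skewed_chisq"` (df = 8/skew²) and
`"gaussian"` remain available.

What a green test on synthetic data does *not* establish: behaviour under
linkage disequilibrium, population stratification, genotype-calling
artefacts, or informative missingness — the generator's missingness is
completely at random and its features independent.

## Numerics

* **Binomial tails** use the regularized-incomplete-beta survival route of
  `pbinom(..., lower.tail = FALSE)`, never term summation: `p_adj` down to
  1.5e-7 with `r` up to 1e5 underflows naive term-by-term accumulation.
  Tests check agreement with an independent direct summation to relative
  1e-10 for `r <= 30`.
* **Threshold comparisons** `p_{k|r} <= p_prun` carry a 1e-9 *relative*
  slack: at `r = 1` the computed tail equals `p_adj` up to one ulp and a
  strict comparison would flip the first threshold. The schedule changes
  only where the tail crosses `p_prun` by orders of magnitude, so the slack
  cannot move a genuine threshold. The same reasoning gives
  `admissible_true_signals()` a 1e-9 slack inside its `floor()`.
* **Quadrature** in `expected_remaining()` is a composite midpoint rule:
  uniform cells over the bulk of (0, 1) plus log-spaced refinement of the
  first cell down to 1e-12. Midpoint exactness for linear integrands keeps
  the round-1 value at 1/2 to ~1e-12; the refinement matters because
  long-horizon survivors concentrate at latent `p` of order
  `threshold / R`, far below a uniform grid's resolution. Nodes whose
  surviving mass falls below 1e-18 are dropped, so cost grows only
  logarithmically with `R`. Default `grid_size = 4096` reproduces the
  closed forms to well under 1e-6; discretization error at extreme horizons
  (1e4+ rounds) is a few percent of the (tiny) remaining fraction.
* **Determinism**: all engines derive per-round / per-replicate seeds from
  the master seed (kept below 2^31), so identical inputs give identical
  outputs; file writers emit full-precision (`%.17g`) numbers and no
  timestamps, making every output byte-reproducible and idempotent.

## Known limitations

* Pruned features receive only a lower bound; if you need a p-value
  distribution over *all* features (for FDR or gene-set combination), run
  some unpruned rounds first and prune afterwards — the engine supports
  this by passing a schedule whose early thresholds are unattainable.
* Single-threaded by design here; the round-indexed seeding was chosen so
  that a parallel implementation would reproduce identical results.
* The exact binomial comparison against parametric p-values treats the
  parametric value as fixed, ignoring its own sampling error.
* `binom.test`-based comparison at 1e7+ rounds allocates the full pmf; it
  is fine at the scales used here but not free.
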