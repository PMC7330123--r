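#' Significance parameters for the pruning schedule
#'
#' Bundles the significance levels that drive pruning: the family-wise
#' unadjusted threshold `p_raw`, the per-feature adjusted threshold `p_adj`
#' (Bonferroni `p_raw / J` when `J` is supplied and `p_adj` is not), and the
#' level `p_prun` of the per-round binomial pruning test of
#' H0: p = p_adj versus H1: p > p_adj. By default `p_prun = p_adj`.
#'
#' @param p_raw unadjusted family-wise significance level, in (0, 1].
#' @param J number of features; used to derive `p_adj = p_raw / J` when
#'   `p_adj` is not given. Optional.
#' @param p_adj per-feature adjusted significance threshold. Defaults to
#'   `p_raw / J` (Bonferroni); must satisfy `0 < p_adj <= p_raw`.
#' @param p_prun significance level of the pruning test. Defaults to `p_adj`.
#' @return An object of class `enpp_sig_params`.
#' @examples
#' significance_params(p_raw = 0.05, J = 1000)      # p_adj = 5e-5
#' significance_params(p_adj = 1.52e-7)             # explicit threshold
#' @export
significance_params <- function(p_raw = 0.05, J = NULL, p_adj = NULL,
                                p_prun = NULL) {
  .assert(.is_prob(p_raw) && p_raw > 0 && p_raw <= 1,
          "p_raw must be a probability in (0, 1]")
  if (is.null(p_adj)) {
    .assert(!is.null(J), "either p_adj or J must be supplied")
    .assert(.is_count(J), "J must be a positive integer")
    p_adj <- p_raw / J
  } else if (!is.null(J)) {
    .assert(.is_count(J), "J must be a positive integer")
  }
  if (is.null(p_prun)) p_prun <- p_adj
  .assert(.is_prob(p_adj) && p_adj > 0 && p_adj <= p_raw,
          "p_adj must satisfy 0 < p_adj <= p_raw")
  .assert(.is_prob(p_prun) && p_prun > 0 && p_prun <= 1,
          "p_prun must be a probability in (0, 1]")
  structure(list(p_raw = p_raw, J = J, p_adj = p_adj, p_prun = p_prun),
            class = "enpp_sig_params")
}

#' @export
print.enpp_sig_params <- function(x, ...) {
  cat("significance parameters:\n")
  cat(sprintf("  p_raw  = %g%s\n", x$p_raw,
              if (!is.null(x$J)) sprintf("  (J = %d)", x$J) else ""))
  cat(sprintf("  p_adj  = %g\n", x$p_adj))
  cat(sprintf("  p_prun = %g\n", x$p_prun))
  invisible(x)
}

#' Upper binomial tail probability of the exceedance count
#'
#' `binomial_tail(k, r, p)` is P(X >= k) for X ~ Binomial(r, p): the
#' probability that a feature whose true permutation p-value equals `p`
#' shows at least `k` exceedances in `r` permutation rounds. Computed via
#' the regularized-incomplete-beta survival routine underlying [pbinom()],
#' never by naive summation of tiny terms (p as small as 1.5e-7 with r up
#' to 1e5 underflows term-by-term accumulation).
#'
#' @param k number of exceedances, `0 <= k <= r`. Vectorized.
#' @param r number of permutation rounds. Vectorized.
#' @param p per-round exceedance probability, in (0, 1).
#' @return P(X >= k), in `[0, 1]`.
#' @examples
#' binomial_tail(0, 1, 5e-5)  # 1
#' binomial_tail(1, 1, 5e-5)  # 5e-5
#' binomial_tail(1, 2, 5e-5)  # ~1e-4
#' @export
binomial_tail <- function(k, r, p) {
  .assert(is.numeric(k) && is.numeric(r) && all(is.finite(k)) && all(is.finite(r)),
          "k and r must be finite numerics")
  .assert(all(k == floor(k)) && all(r == floor(r)) && all(r >= 1) && all(k >= 0),
          "k must be a non-negative integer and r a positive integer")
  .assert(all(k <= r), "k must not exceed r")
  .assert(is.numeric(p) && all(p > 0) && all(p < 1), "p must lie strictly in (0, 1)")
  pbinom(k - 1, r, p, lower.tail = FALSE)
}

# relative slack absorbing floating-point rounding in tail-vs-level
# comparisons; the schedule changes only where the tail crosses p_prun by
# orders of magnitude, so this cannot move a genuine threshold
.CPRUN_REL_TOL <- 1e-9

.cprun_scan <- function(r, p_adj, p_prun, k_start = 1L) {
  lim <- p_prun * (1 + .CPRUN_REL_TOL)
  k <- as.integer(k_start)
  while (k <= r && pbinom(k - 1L, r, p_adj, lower.tail = FALSE) > lim) k <- k + 1L
  if (k <= r) k else as.integer(r + 1L)
}

#' Pruning threshold for a single round
#'
#' Returns the smallest integer `k >= 1` with
#' `binomial_tail(k, r, p_adj) <= p_prun`: the minimal exceedance count that
#' the pruning test rejects at level `p_prun` in round `r`. When no `k <= r`
#' satisfies the bound, `r + 1` is returned, meaning "cannot prune at this
#' round" (unattainable by any count).
#'
#' @param r round index, `r >= 1`.
#' @param params an [significance_params()] object.
#' @return Integer threshold in `1..(r + 1)`.
#' @examples
#' p <- significance_params(p_adj = 5e-5)
#' cprun_at(1, p)   # 1
#' cprun_at(2, p)   # 2
#' @export
cprun_at <- function(r, params) {
  .assert(inherits(params, "enpp_sig_params"), "params must be significance_params()")
  .assert(.is_count(r), "r must be a positive integer")
  .cprun_scan(r, params$p_adj, params$p_prun)
}

#' Build the full pruning threshold schedule
#'
#' Computes `C_prun(r)` for `r = 1..R`. The thresholds are non-decreasing in
#' `r` (for fixed `k` the binomial tail grows with the number of rounds), so
#' the scan resumes from the previous round's threshold and the total cost is
#' O(R + max threshold) tail evaluations.
#'
#' @param params an [significance_params()] object.
#' @param R total number of permutation rounds, `R >= 1`.
#' @return An object of class `enpp_schedule` with fields `params`, `R` and
#'   the integer vector `thresholds`.
#' @examples
#' sch <- build_schedule(significance_params(p_adj = 1e-7), R = 10)
#' sch$thresholds  # 1 2 2 2 2 2 2 2 2 2
#' @export
build_schedule <- function(params, R) {
  .assert(inherits(params, "enpp_sig_params"), "params must be significance_params()")
  .assert(.is_count(R), "R must be a positive integer")
  R <- as.integer(R)
  thr <- integer(R)
  k <- 1L
  for (r in seq_len(R)) {
    k <- .cprun_scan(r, params$p_adj, params$p_prun, k_start = k)
    thr[r] <- k
  }
  structure(list(params = params, R = R, thresholds = thr),
            class = "enpp_schedule")
}

#' @export
print.enpp_schedule <- function(x, ...) {
  cat(sprintf("pruning schedule: R = %d rounds, p_adj = %g, p_prun = %g\n",
              x$R, x$params$p_adj, x$params$p_prun))
  rl <- rle(x$thresholds)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (i in seq_along(rl$values)) {
    cat(sprintf("  C_prun = %d for rounds [%d, %d]\n",
                rl$values[i], starts[i], ends[i]))
  }
  invisible(x)
}

#' Cumulative false-pruning risk of a schedule
#'
#' Sum over rounds of the attained pruning-test significance
#' `binomial_tail(C_prun(r), r, p_adj)`: a union upper bound on the
#' probability that a feature whose true exceedance probability is exactly
#' `p_adj` is ever pruned under the schedule. The exact hitting probability
#' of the count process is available as [prune_hit_probability()] and is
#' always smaller.
#'
#' @param schedule an `enpp_schedule`.
#' @return The summed per-round significance, a probability-scale value.
#' @examples
#' sch <- build_schedule(significance_params(p_adj = 0.01), R = 20)
#' false_prune_risk(sch)
#' @export
false_prune_risk <- function(schedule) {
  .assert(inherits(schedule, "enpp_schedule"), "schedule must be an enpp_schedule")
  r <- seq_len(schedule$R)
  # sentinel rounds (threshold r + 1) contribute exactly zero
  sum(pbinom(schedule$thresholds - 1, r, schedule$params$p_adj,
             lower.tail = FALSE) * (schedule$thresholds <= r))
}

#' Exact probability that a borderline feature is ever pruned
#'
#' Dynamic program over exceedance-count states for a feature with per-round
#' exceedance probability `p` (default `p_adj`): the probability that its
#' cumulative count ever reaches the schedule's threshold within `R` rounds.
#' This is the sharp version of the union bound reported by
#' [false_prune_risk()].
#'
#' @param schedule an `enpp_schedule`.
#' @param p per-round exceedance probability; defaults to the schedule's
#'   `p_adj`.
#' @return Hitting probability in `[0, 1]`.
#' @export
prune_hit_probability <- function(schedule, p = schedule$params$p_adj) {
  .assert(inherits(schedule, "enpp_schedule"), "schedule must be an enpp_schedule")
  .assert(.is_prob(p) && p > 0 && p < 1, "p must lie in (0, 1)")
  thr <- schedule$thresholds
  maxC <- max(thr[thr <= seq_along(thr)], 1L)
  q <- numeric(maxC)          # q[c] = P(count = c - 1, not yet pruned)
  q[1] <- 1
  for (r in seq_len(schedule$R)) {
    th <- thr[r]
    qn <- q * (1 - p)
    if (maxC >= 2) qn[2:maxC] <- qn[2:maxC] + q[1:(maxC - 1)] * p
    # counts >= th are pruned; overflow past state maxC - 1 is implicitly lost
    if (th <= maxC) qn[seq.int(th + 1L, length.out = maxC - th)] <- 0
    q <- qn
  }
  1 - sum(q)
}

#' Number of true signals the schedule can protect
#'
#' `floor(p_raw / false_prune_risk(schedule))`: the largest number of truly
#' significant features for which the family-wise probability of falsely
#' pruning any of them stays below `p_raw`, by the union bound.
#'
#' @param schedule an `enpp_schedule`.
#' @param p_raw family-wise level to protect, default 0.05.
#' @return Integer count.
#' @export
admissible_true_signals <- function(schedule, p_raw = 0.05) {
  .assert(.is_prob(p_raw) && p_raw > 0 && p_raw <= 1, "p_raw must be in (0, 1]")
  risk <- false_prune_risk(schedule)
  .assert(risk > 0, "schedule has zero false-pruning risk; ratio undefined")
  # tiny relative slack so exact ratios (e.g. 0.05 / 0.01) survive floating
  # point; a genuine fraction is never within 1e-9 of an integer here
  as.integer(floor(p_raw / risk + 1e-9))
}

#' Write / read a pruning schedule as a delimited table
#'
#' Two tab-separated columns (`round`, `threshold`) preceded by comment lines
#' recording `p_raw`, `p_adj`, `p_prun`, `J` and `R` at full precision, so
#' that `read_schedule(write_schedule(...))` is lossless.
#'
#' @param schedule an `enpp_schedule`.
#' @param path file path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` returns
#'   the reconstructed `enpp_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  .assert(inherits(schedule, "enpp_schedule"), "schedule must be an enpp_schedule")
  p <- schedule$params
  hdr <- c(.provenance_header(config = list(p, schedule$R)),
           sprintf("# p_raw=%s", .fmt_num(p$p_raw)),
           sprintf("# p_adj=%s", .fmt_num(p$p_adj)),
           sprintf("# p_prun=%s", .fmt_num(p$p_prun)),
           sprintf("# J=%s", if (is.null(p$J)) "NA" else format(p$J)),
           sprintf("# R=%d", schedule$R),
           "round\tthreshold")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%d\t%d", seq_len(schedule$R), schedule$thresholds), con)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  meta <- lines[is_comment]
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    .assert(length(hit) == 1L, "schedule file is missing metadata field ", key)
    sub(sprintf("^# %s=", key), "", hit)
  }
  J <- get_meta("J")
  params <- significance_params(
    p_raw = as.numeric(get_meta("p_raw")),
    J = if (J == "NA") NULL else as.integer(J),
    p_adj = as.numeric(get_meta("p_adj")),
    p_prun = as.numeric(get_meta("p_prun")))
  tab <- read.table(text = lines[!is_comment], header = TRUE, sep = "\t")
  .assert(identical(tab$round, seq_len(nrow(tab))), "schedule rounds must be 1..R")
  R <- as.integer(get_meta("R"))
  .assert(R == nrow(tab), "schedule R does not match table length")
  structure(list(params = params, R = R, thresholds = as.integer(tab$threshold)),
            class = "enpp_schedule")
}
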