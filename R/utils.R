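`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# non-cryptographic FNV-1a-style hash of a configuration, kept in double
# arithmetic below 2^31 so it is stable across platforms
.config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = " ")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- (h %% 65536) * 403 + (h %/% 65536) * 179 + b  # mixed congruential step
    h <- h %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.provenance_header <- function(seed = NULL, config = NULL, extra = character()) {
  c(sprintf("# enpp %s", as.character(utils::packageVersion("enpp"))),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)),
    if (!is.null(config)) sprintf("# config_hash=%s", .config_hash(config)),
    extra)
}

# derive independent sub-seeds from one master seed, all below 2^31
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

# logging cadence: every round when R is small, geometric checkpoints otherwise
.log_rounds <- function(R) {
  if (R <= 1000) return(seq_len(R))
  unique(c(1L, as.integer(round(10^seq(0, log10(R), length.out = 60L))), R))
}

# full-precision, unpadded numeric formatting (lossless double round trip)
.fmt_num <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  out[is.na(x)] <- "NA"
  out
}
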