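# Internal helpers shared across modules.

.sexhetLog <- function(...) {
  if (isTRUE(getOption("sexhet.verbose", TRUE))) message("[sexhet] ", ...)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive `n` independent per-stream seeds (< 2^31) from a master seed.
.deriveSeeds <- function(master, n) {
  .withSeed(master, sample.int(.Machine$integer.max - 1L, n))
}

# chi-square(1) quantile from an upper-tail p-value; log.p allows p-values
# stored in log space to survive below the double underflow threshold.
.chisqFromP <- function(p, log.p = FALSE) {
  qchisq(p, df = 1, lower.tail = FALSE, log.p = log.p)
}

.pFromChisq <- function(q) pchisq(q, df = 1, lower.tail = FALSE)

.pTwoSidedZ <- function(z) 2 * pnorm(abs(z), lower.tail = FALSE)

# Median of the chi-square distribution with 1 df, the null reference for
# the genomic inflation factor.
.CHISQ1_MEDIAN <- qchisq(0.5, df = 1)

# sample() semantics safe for length-1 numeric x
.resample <- function(x, ...) x[sample.int(length(x), ...)]

.isAmbiguousPair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.stopifnotCols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}
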