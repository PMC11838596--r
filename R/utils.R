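# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats runif rnorm rpois rbinom rgamma var sd cor
#' @importFrom utils head tail read.delim write.table
NULL

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

## Deterministic per-stage substream seed: all randomness flows from one
## config seed; stage names hash to distinct offsets. Kept below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stage)
  off <- sum(chars * seq_along(chars)) %% 104729L
  as.integer(((abs(seed) %% 44488L) * 48271 + off) %% 2147483647)
}

## Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## One draw per row from the categorical distribution given by a
## row-stochastic probability matrix; `rows` selects the row per draw.
sample_categorical <- function(prob, rows, u = runif(length(rows))) {
  k <- ncol(prob)
  cum <- prob %*% upper.tri(diag(k), diag = TRUE)
  cp <- cum[rows, , drop = FALSE]
  as.integer(rowSums(u > cp) + 1L)
}

rdirichlet_one <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

## Vectorised Pearson correlation of paired rows of two matrices, exact for
## small-integer entries (single-pass sums stay inside double precision).
row_pearson <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  n <- ncol(a)
  sa <- rowSums(a); sb <- rowSums(b)
  da <- n * rowSums(a * a) - sa^2
  db <- n * rowSums(b * b) - sb^2
  num <- n * rowSums(a * b) - sa * sb
  r <- num / sqrt(da * db)
  r[da <= 1e-9 | db <= 1e-9] <- NA_real_
  pmin(pmax(r, -1), 1)
}

chrom_order <- function(chrom) {
  u <- unique(chrom)
  factor(chrom, levels = u)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, ...)
}
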