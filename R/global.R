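#' Global ancestry proportions from local calls
#'
#' Both channels reduce to an individual-by-ancestry proportion matrix
#' whose rows sum to 1. For the interval channel the proportion of
#' ancestry k is the length-weighted count sum divided by twice the total
#' interval length: `sum_i len_i * count_ik / (2 * sum_i len_i)`. For the
#' SNP channel every SNP gets equal weight: half the mean diploid count.
#'
#' @param calls an [interval_calls()] or [snp_calls()] object.
#' @return A `global_ancestry` object: list with `proportions`
#'   (individual x ancestry matrix) and `source_label`.
#' @export
global_from_intervals <- function(calls) {
  stopifnot(inherits(calls, "interval_calls"))
  if (n_loci(calls) == 0L) abort_config("empty interval call set")
  len <- calls$intervals$end - calls$intervals$start + 1
  tot <- sum(len)
  if (tot <= 0) abort_config("zero total interval length")
  k <- length(calls$ancestry_labels)
  pp <- vapply(seq_len(k),
               function(j) colSums(slice_counts(calls, j) * len) / (2 * tot),
               numeric(length(calls$sample_ids)))
  pp <- matrix(pp, ncol = k,
               dimnames = list(calls$sample_ids, calls$ancestry_labels))
  global_ancestry(pp, "interval-channel")
}

#' @rdname global_from_intervals
#' @export
global_from_snps <- function(calls) {
  stopifnot(inherits(calls, "snp_calls"))
  if (n_loci(calls) == 0L) abort_config("empty SNP call set")
  k <- length(calls$ancestry_labels)
  pp <- vapply(seq_len(k),
               function(j) colMeans(slice_counts(calls, j)) / 2,
               numeric(length(calls$sample_ids)))
  pp <- matrix(pp, ncol = k,
               dimnames = list(calls$sample_ids, calls$ancestry_labels))
  global_ancestry(pp, "snp-channel")
}

#' @rdname global_from_intervals
#' @param proportions individual x ancestry matrix with unit row sums.
#' @param source_label provenance tag (`interval-channel`, `snp-channel`,
#'   `external`, ...).
#' @export
global_ancestry <- function(proportions, source_label = "external") {
  stopifnot(is.matrix(proportions))
  if (any(proportions < -1e-9 | proportions > 1 + 1e-9))
    stop("proportions must lie in [0, 1]")
  if (any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("proportion rows must sum to 1")
  structure(list(proportions = proportions, source_label = source_label),
            class = "global_ancestry")
}

#' @export
print.global_ancestry <- function(x, ...) {
  cat(sprintf("<global_ancestry> %d individuals x %d ancestries [%s]\n",
              nrow(x$proportions), ncol(x$proportions), x$source_label))
  print(round(utils::head(x$proportions, 3), 3))
  invisible(x)
}

#' Agreement between two global ancestry tables
#'
#' Computes, per shared ancestry, the Pearson correlation of proportions
#' across individuals, plus the mean signed difference (`b - a`) that
#' exposes systematic shifts (e.g. one method assigning uniformly lower
#' European proportions). Extra ancestries present in only one table can
#' be renamed onto the other's labels with `label_map`, or are otherwise
#' ignored; collapsing a 7-ancestry table to 3 majors + other is done
#' upstream with [collapse_ancestries()].
#'
#' @param a,b `global_ancestry` objects over the same individuals.
#' @param label_map optional named character vector renaming `b`'s
#'   ancestry labels onto `a`'s (`c(oldname = "newname")`).
#' @return A list: `correlations` (named vector; `NA` when either vector
#'   has zero variance), `mean_difference`, and `scatter` (long data.frame
#'   of paired proportions for plotting).
#' @export
compare_global <- function(a, b, label_map = NULL) {
  stopifnot(inherits(a, "global_ancestry"), inherits(b, "global_ancestry"))
  pb <- b$proportions
  if (!is.null(label_map)) {
    idx <- match(colnames(pb), names(label_map))
    colnames(pb)[!is.na(idx)] <- label_map[idx[!is.na(idx)]]
  }
  if (!identical(rownames(a$proportions), rownames(pb)))
    stop("tables must cover the same individuals in the same order")
  shared <- intersect(colnames(a$proportions), colnames(pb))
  if (length(shared) == 0L) stop("no shared ancestry labels")
  cors <- vapply(shared, function(k) {
    x <- a$proportions[, k]; y <- pb[, k]
    if (sd(x) < 1e-12 || sd(y) < 1e-12) NA_real_ else cor(x, y)
  }, 0)
  md <- vapply(shared, function(k) mean(pb[, k] - a$proportions[, k]), 0)
  ids <- rownames(pb) %||% as.character(seq_len(nrow(pb)))
  scatter <- do.call(rbind, lapply(shared, function(k)
    data.frame(sample_id = ids, ancestry = k,
               a = a$proportions[, k], b = pb[, k], row.names = NULL)))
  list(correlations = cors, mean_difference = md, scatter = scatter)
}
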