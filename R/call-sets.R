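#' Local ancestry call containers
#'
#' Two containers hold diploid local ancestry counts, one per inference
#' channel. `interval_calls()` stores counts over genomic intervals
#' (RFMix-style); `snp_calls()` stores counts at single positions
#' (FLARE-style) together with per-variant minor allele frequency and
#' imputation quality. Counts are integer arrays indexed
#' `[locus, individual, ancestry]` and must sum to 2 over ancestries at
#' every (locus, individual) cell: each of the two chromosome copies
#' carries exactly one ancestry.
#'
#' Coordinates are 1-based and closed throughout the package; the BED
#' annotation boundary converts to/from 0-based half-open on disk.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (1-based, closed). Intervals within a chromosome must be
#'   non-overlapping; rows are sorted on construction.
#' @param positions data.frame with columns `chrom`, `pos`, `id`.
#' @param counts integer array `[locus x individual x ancestry]`.
#' @param maf numeric vector of per-variant minor allele frequencies.
#' @param r2 numeric vector of imputation quality scores; `NA` marks a
#'   directly genotyped variant (exempt from the R2 QC filter).
#' @param sample_ids character vector of individual identifiers.
#' @param ancestry_labels character vector naming the ancestries.
#' @return An object of class `interval_calls` or `snp_calls`.
#' @name call-sets
NULL

#' @rdname call-sets
#' @export
interval_calls <- function(intervals, counts, sample_ids, ancestry_labels) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals$chrom <- as.character(intervals$chrom)
  ord <- order(chrom_order(intervals$chrom), intervals$start)
  intervals <- intervals[ord, c("chrom", "start", "end"), drop = FALSE]
  rownames(intervals) <- NULL
  counts <- check_counts(counts[ord, , , drop = FALSE],
                         nrow(intervals), sample_ids, ancestry_labels)
  check_disjoint(intervals)
  structure(list(intervals = intervals, counts = counts,
                 sample_ids = sample_ids,
                 ancestry_labels = ancestry_labels),
            class = "interval_calls")
}

#' @rdname call-sets
#' @export
snp_calls <- function(positions, counts, maf, r2, sample_ids,
                      ancestry_labels) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  positions$chrom <- as.character(positions$chrom)
  if (is.null(positions$id))
    positions$id <- sprintf("%s:%d", positions$chrom, positions$pos)
  ord <- order(chrom_order(positions$chrom), positions$pos)
  positions <- positions[ord, c("chrom", "pos", "id"), drop = FALSE]
  rownames(positions) <- NULL
  counts <- check_counts(counts[ord, , , drop = FALSE],
                         nrow(positions), sample_ids, ancestry_labels)
  maf <- maf[ord]; r2 <- r2[ord]
  stopifnot(length(maf) == nrow(positions), length(r2) == nrow(positions))
  structure(list(positions = positions, counts = counts,
                 maf = as.numeric(maf), r2 = as.numeric(r2),
                 sample_ids = sample_ids,
                 ancestry_labels = ancestry_labels),
            class = "snp_calls")
}

check_counts <- function(counts, n_loci, sample_ids, ancestry_labels) {
  if (length(dim(counts)) != 3L)
    stop("counts must be a 3-d array [locus x individual x ancestry]")
  if (dim(counts)[1] != n_loci) stop("counts rows do not match loci")
  if (dim(counts)[2] != length(sample_ids))
    stop("counts columns do not match sample_ids")
  if (dim(counts)[3] != length(ancestry_labels))
    stop("counts slices do not match ancestry_labels")
  storage.mode(counts) <- "integer"
  if (n_loci > 0L && length(sample_ids) > 0L) {
    if (any(counts < 0L | counts > 2L, na.rm = TRUE))
      stop("ancestry counts must lie in {0, 1, 2}")
    tot <- rowSums(counts, dims = 2L)
    bad <- which(tot != 2L, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf(
        "ancestry counts do not sum to 2 at locus %d, individual %d",
        bad[1, 1], bad[1, 2]))
  }
  dimnames(counts) <- list(NULL, sample_ids, ancestry_labels)
  counts
}

check_disjoint <- function(intervals) {
  for (ch in unique(intervals$chrom)) {
    d <- intervals[intervals$chrom == ch, ]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop(sprintf("overlapping intervals on %s", ch))
  }
  invisible(TRUE)
}

n_loci <- function(x) UseMethod("n_loci")
#' @export
n_loci.interval_calls <- function(x) nrow(x$intervals)
#' @export
n_loci.snp_calls <- function(x) nrow(x$positions)

## GRanges views used by interval arithmetic.
loci_ranges <- function(x) UseMethod("loci_ranges")
#' @export
loci_ranges.interval_calls <- function(x) {
  GenomicRanges::GRanges(x$intervals$chrom,
                         IRanges::IRanges(x$intervals$start, x$intervals$end))
}
#' @export
loci_ranges.snp_calls <- function(x) {
  GenomicRanges::GRanges(x$positions$chrom,
                         IRanges::IRanges(x$positions$pos, x$positions$pos))
}

## counts for one ancestry as a [locus x individual] matrix, never dropped
slice_counts <- function(x, j) {
  if (is.character(j)) j <- match(j, x$ancestry_labels)
  matrix(x$counts[, , j], nrow = n_loci(x),
         dimnames = list(NULL, x$sample_ids))
}

subset_loci <- function(x, idx) {
  if (inherits(x, "interval_calls")) {
    interval_calls(x$intervals[idx, , drop = FALSE],
                   x$counts[idx, , , drop = FALSE],
                   x$sample_ids, x$ancestry_labels)
  } else {
    snp_calls(x$positions[idx, , drop = FALSE],
              x$counts[idx, , , drop = FALSE],
              x$maf[idx], x$r2[idx], x$sample_ids, x$ancestry_labels)
  }
}

#' @export
print.interval_calls <- function(x, ...) {
  cat(sprintf("<interval_calls> %d intervals x %d individuals x %d ancestries (%s)\n",
              n_loci(x), length(x$sample_ids), length(x$ancestry_labels),
              paste(x$ancestry_labels, collapse = ", ")))
  invisible(x)
}

#' @export
print.snp_calls <- function(x, ...) {
  cat(sprintf("<snp_calls> %d SNPs x %d individuals x %d ancestries (%s)\n",
              n_loci(x), length(x$sample_ids), length(x$ancestry_labels),
              paste(x$ancestry_labels, collapse = ", ")))
  invisible(x)
}

#' Collapse a 7-ancestry call set to the three major ancestries plus "other"
#'
#' African, Amerindian and European counts are kept; the remaining
#' ancestries are summed into a single combined pseudo-ancestry. Diploid
#' totals of 2 are preserved at every locus. Used when a 7-reference-panel
#' call set must be compared or scanned alongside a 3-ancestry one, where
#' the sparse minor ancestries are individually uninformative.
#'
#' @param x an `interval_calls` or `snp_calls` object.
#' @param majors ancestry labels kept as-is (must be present in `x`).
#' @param other_label label for the combined remainder.
#' @return A call set of the same class with `length(majors) + 1` ancestries.
#' @export
collapse_ancestries <- function(x, majors = c("African", "Amerindian", "European"),
                                other_label = "other") {
  stopifnot(inherits(x, c("interval_calls", "snp_calls")))
  labs <- x$ancestry_labels
  if (!all(majors %in% labs))
    abort_config("majors not present in ancestry labels: %s",
                 paste(setdiff(majors, labs), collapse = ", "))
  minors <- setdiff(labs, majors)
  if (length(minors) == 0L)
    abort_config("no ancestries left to collapse")
  cc <- array(0L, dim = c(dim(x$counts)[1:2], length(majors) + 1L))
  for (j in seq_along(majors)) cc[, , j] <- x$counts[, , majors[j]]
  cc[, , length(majors) + 1L] <-
    rowSums(x$counts[, , minors, drop = FALSE], dims = 2L)
  labs2 <- c(majors, other_label)
  if (inherits(x, "interval_calls"))
    interval_calls(x$intervals, cc, x$sample_ids, labs2)
  else
    snp_calls(x$positions, cc, x$maf, x$r2, x$sample_ids, labs2)
}
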