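#' Match SNP-level calls to (lifted) intervals
#'
#' A SNP is matched to an interval when its position is greater than or
#' equal to the interval start and less than or equal to the interval end
#' (closed on both ends). Intervals must already live on the SNP build
#' (see [apply_liftover()]) and be non-overlapping; if two intervals abut
#' so that a SNP equals one interval's end and the next one's start, the
#' earlier interval wins.
#'
#' @param snps a [snp_calls()] object.
#' @param intervals an [interval_calls()] object on the same build.
#' @return A list: `pairs` (data.frame `snp_index`, `interval_index`,
#'   `chrom`, `pos`), `match_rate` (matched / total SNPs), `n_snps`,
#'   `n_matched`.
#' @export
match_snps_to_intervals <- function(snps, intervals) {
  stopifnot(inherits(snps, "snp_calls"), inherits(intervals, "interval_calls"))
  check_disjoint(intervals$intervals)
  hit <- GenomicRanges::findOverlaps(loci_ranges(snps),
                                     loci_ranges(intervals),
                                     select = "first")
  matched <- which(!is.na(hit))
  pairs <- data.frame(snp_index = matched,
                      interval_index = hit[matched],
                      chrom = snps$positions$chrom[matched],
                      pos = snps$positions$pos[matched])
  list(pairs = pairs,
       match_rate = length(matched) / max(1L, n_loci(snps)),
       n_snps = n_loci(snps), n_matched = length(matched))
}

#' Per-pair Pearson correlation of local ancestry counts
#'
#' For each matched (SNP, interval) pair and each ancestry, computes the
#' Pearson correlation of the diploid counts across individuals. A
#' correlation is undefined (`NA`) when either count vector is constant;
#' such pairs are recorded and excluded from downstream means.
#'
#' @param match result of [match_snps_to_intervals()], or its `pairs`
#'   data.frame.
#' @param snps,intervals the call sets the pairs index into; sample
#'   orderings must be identical.
#' @param ancestries ancestry labels to correlate (default: labels shared
#'   by the two call sets).
#' @return A long data.frame of class `pair_correlations`: one row per
#'   (pair, ancestry) with `snp_index`, `interval_index`, `chrom`, `pos`,
#'   `interval_start`, `interval_end`, `ancestry`, `r`.
#' @export
pair_correlations <- function(match, snps, intervals, ancestries = NULL) {
  pairs <- if (is.data.frame(match)) match else match$pairs
  if (!identical(snps$sample_ids, intervals$sample_ids))
    stop("snp and interval call sets cover different individuals")
  if (is.null(ancestries))
    ancestries <- intersect(snps$ancestry_labels, intervals$ancestry_labels)
  stopifnot(length(ancestries) > 0)
  out <- lapply(ancestries, function(k) {
    a <- slice_counts(snps, k)[pairs$snp_index, , drop = FALSE]
    b <- slice_counts(intervals, k)[pairs$interval_index, , drop = FALSE]
    data.frame(pairs,
               interval_start = intervals$intervals$start[pairs$interval_index],
               interval_end = intervals$intervals$end[pairs$interval_index],
               ancestry = k, r = row_pearson(a, b), row.names = NULL)
  })
  res <- do.call(rbind, out)
  class(res) <- c("pair_correlations", "data.frame")
  res
}

#' Genome-wide summary of pair correlations
#'
#' Unweighted mean and standard deviation of the per-pair correlations for
#' each ancestry (undefined correlations excluded and counted), plus a
#' long per-chromosome table for plotting correlation profiles.
#'
#' @param correlations a [pair_correlations()] data.frame.
#' @return A list with `overall` (ancestry, mean_r, sd_r, n_pairs,
#'   n_undefined) and `by_chrom` (chromosome-resolved means).
#' @export
genome_summary <- function(correlations) {
  spl <- split(correlations$r, correlations$ancestry)
  overall <- do.call(rbind, lapply(names(spl), function(k) {
    r <- spl[[k]]
    data.frame(ancestry = k, mean_r = mean(r, na.rm = TRUE),
               sd_r = sd(r, na.rm = TRUE),
               n_pairs = sum(!is.na(r)), n_undefined = sum(is.na(r)))
  }))
  key <- interaction(correlations$chrom, correlations$ancestry, drop = TRUE)
  by_chrom <- do.call(rbind, lapply(split(correlations, key), function(d)
    data.frame(chrom = d$chrom[1], ancestry = d$ancestry[1],
               mean_r = mean(d$r, na.rm = TRUE),
               n_pairs = sum(!is.na(d$r)))))
  rownames(by_chrom) <- NULL
  list(overall = overall, by_chrom = by_chrom)
}

#' Per-locus ancestry proportion profiles
#'
#' For every locus and ancestry: the mean ancestry proportion across
#' individuals (mean diploid count / 2) and the sample variance of the
#' counts. Used to localize systematic shifts between channels along the
#' genome.
#'
#' @param calls an [interval_calls()] or [snp_calls()] object.
#' @return A long data.frame: locus coordinates, `ancestry`,
#'   `mean_proportion`, `count_variance`, `n`.
#' @export
position_profiles <- function(calls) {
  n <- length(calls$sample_ids)
  locus <- if (inherits(calls, "snp_calls"))
    calls$positions[c("chrom", "pos")]
  else calls$intervals
  out <- lapply(calls$ancestry_labels, function(k) {
    cc <- slice_counts(calls, k)
    m <- rowMeans(cc)
    v <- if (n > 1) (rowSums(cc * cc) - n * m^2) / (n - 1) else rep(NA_real_, nrow(cc))
    data.frame(locus, ancestry = k, mean_proportion = m / 2,
               count_variance = pmax(v, 0), n = n, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Flag low-correlation pairs and merge them into regions
#'
#' A (SNP, interval) pair is flagged when its correlation falls below
#' `low_threshold` in any considered ancestry (undefined correlations do
#' not flag). `merge_regions()` unions the interval spans of flagged
#' pairs per chromosome, merging overlapping and adjacent spans into
#' sorted disjoint regions.
#'
#' @param correlations a [pair_correlations()] data.frame.
#' @param low_threshold flag threshold (paper default 0.9).
#' @param ancestries restrict the any-ancestry rule to these labels
#'   (default: all present).
#' @return `flag_low_pairs()`: data.frame of flagged pairs with `min_r`
#'   and a `flagged_fraction` attribute (flagged / total pairs).
#'   `merge_regions()`: data.frame `chrom`, `start`, `end`.
#' @export
flag_low_pairs <- function(correlations, low_threshold = 0.9,
                           ancestries = NULL) {
  stopifnot(low_threshold > 0, low_threshold < 1)
  d <- correlations
  if (!is.null(ancestries)) d <- d[d$ancestry %in% ancestries, , drop = FALSE]
  ru <- rollup_pairs(d)
  low <- rowSums(!is.na(ru$rmat) & ru$rmat < low_threshold) > 0
  base <- ru$base
  base$min_r <- ru$min_r
  flagged <- base[low, , drop = FALSE]
  rownames(flagged) <- NULL
  attr(flagged, "n_pairs") <- nrow(base)
  attr(flagged, "flagged_fraction") <- nrow(flagged) / max(1L, nrow(base))
  flagged
}

## One row per (snp, interval) pair with the per-ancestry correlations as
## matrix columns. pair_correlations() emits every ancestry with the pairs
## in a common order (the balanced case, handled without grouping); ragged
## inputs fall back to key-wise grouping.
rollup_pairs <- function(d) {
  idx <- split(seq_len(nrow(d)), d$ancestry)
  first <- idx[[1]]
  balanced <- all(vapply(idx, function(i)
    length(i) == length(first) &&
      identical(d$snp_index[i], d$snp_index[first]) &&
      identical(d$interval_index[i], d$interval_index[first]), TRUE))
  cols <- intersect(c("snp_index", "interval_index", "chrom", "pos",
                      "interval_start", "interval_end"), names(d))
  if (balanced) {
    rmat <- vapply(idx, function(i) d$r[i], numeric(length(first)))
    rmat <- matrix(rmat, ncol = length(idx))
    base <- d[first, cols, drop = FALSE]
  } else {
    key <- paste(d$snp_index, d$interval_index)
    ukey <- !duplicated(key)
    base <- d[ukey, cols, drop = FALSE]
    kf <- factor(key, levels = key[ukey])
    anc <- factor(d$ancestry)
    rmat <- matrix(NA_real_, nrow(base), nlevels(anc))
    rmat[cbind(as.integer(kf), as.integer(anc))] <- d$r
  }
  min_r <- suppressWarnings(do.call(pmin, c(
    lapply(seq_len(ncol(rmat)), function(j) rmat[, j]), na.rm = TRUE)))
  min_r[is.infinite(min_r)] <- NA_real_
  rownames(base) <- NULL
  list(base = base, rmat = rmat, min_r = min_r)
}

#' @rdname flag_low_pairs
#' @param flagged a data.frame carrying `chrom` and either
#'   `interval_start`/`interval_end` or `start`/`end` columns.
#' @export
merge_regions <- function(flagged) {
  if (nrow(flagged) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  st <- flagged$interval_start %||% flagged$start
  en <- flagged$interval_end %||% flagged$end
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(flagged$chrom, IRanges::IRanges(st, en)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr))
}
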