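#' Assign pairs or regions to annotation classes by proximity
#'
#' Because local ancestry carries very long-range LD, a discordant locus
#' is credited to an annotation class (ENCODE-blacklist-style or gene
#' cluster) when it lies within `proximity_bp` of any annotation interval
#' of that class on the same chromosome. Distance is the edge-to-edge gap
#' in coordinates (overlap counts as distance 0; different chromosomes are
#' infinitely far). A query exactly `proximity_bp` away is assigned
#' ("up to 0.5 Mb"); one base farther is not. A query may carry several
#' classes.
#'
#' @param x data.frame of queries with `chrom` and either `pos` (SNP
#'   point) or `start`/`end` (region span); flagged-pair tables from
#'   [flag_low_pairs()] are used as SNP points.
#' @param track annotation `GRanges` (see [annotation_track()]).
#' @param proximity_bp assignment radius in bp (default 0.5 Mb).
#' @return The input data.frame with one logical column per annotation
#'   class, a `<class>_nearest` column identifying the closest annotation
#'   interval of that class, and a `mapped` column (any class assigned).
#' @export
map_pairs_to_annotations <- function(x, track, proximity_bp = 500000) {
  if (proximity_bp < 0) abort_config("proximity_bp must be non-negative")
  x <- as.data.frame(x)
  if (!is.null(x$pos)) {
    q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  } else {
    q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  }
  classes <- sort(unique(track$name))
  out <- x
  for (cl in classes) {
    sub <- track[track$name == cl]
    hit <- GenomicRanges::distanceToNearest(q, sub)
    assigned <- rep(FALSE, length(q))
    nearest <- rep(NA_character_, length(q))
    qi <- S4Vectors::queryHits(hit)
    # GRanges gap distance g means g bases strictly between the ranges, so
    # a coordinate offset of proximity_bp corresponds to g = proximity_bp - 1
    ok <- S4Vectors::mcols(hit)$distance < proximity_bp |
      S4Vectors::mcols(hit)$distance == 0L
    assigned[qi[ok]] <- TRUE
    sj <- S4Vectors::subjectHits(hit)[ok]
    nearest[qi[ok]] <- sprintf("%s:%d-%d",
                               as.character(GenomicRanges::seqnames(sub))[sj],
                               GenomicRanges::start(sub)[sj],
                               GenomicRanges::end(sub)[sj])
    out[[cl]] <- assigned
    out[[paste0(cl, "_nearest")]] <- nearest
  }
  out$mapped <- Reduce(`|`, lapply(classes, function(cl) out[[cl]]),
                       rep(FALSE, nrow(out)))
  attr(out, "classes") <- classes
  out
}

#' Sample matched high-correlation control pairs
#'
#' Selects, uniformly at random and without replacement, `n` pairs whose
#' correlation exceeds `high_threshold` in every considered ancestry, to
#' serve as a background against which annotation enrichment of the
#' low-correlation group is judged.
#'
#' @param correlations a [pair_correlations()] data.frame.
#' @param n number of control pairs (normally the flagged-pair count).
#' @param high_threshold eligibility threshold (paper default 0.97,
#'   strict `>`).
#' @param ancestries restrict eligibility to these labels.
#' @param seed optional integer making the draw reproducible without
#'   touching the caller's RNG stream.
#' @return A data.frame of control pairs in the layout of
#'   [flag_low_pairs()] output.
#' @export
sample_matched_high_pairs <- function(correlations, n, high_threshold = 0.97,
                                      ancestries = NULL, seed = NULL) {
  stopifnot(high_threshold > 0, high_threshold < 1)
  d <- correlations
  if (!is.null(ancestries)) d <- d[d$ancestry %in% ancestries, , drop = FALSE]
  ru <- rollup_pairs(d)
  high <- rowSums(!is.na(ru$rmat) & ru$rmat > high_threshold) == ncol(ru$rmat)
  eligible <- ru$base[high, , drop = FALSE]
  if (n > nrow(eligible))
    stop(sprintf("requested %d control pairs but only %d exceed r > %.2f",
                 n, nrow(eligible), high_threshold))
  idx <- if (is.null(seed)) sample.int(nrow(eligible), n)
         else with_seed(seed, sample.int(nrow(eligible), n))
  out <- eligible[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment bookkeeping for low- versus control-correlation pairs
#'
#' Tallies, for the low-correlation group and the matched high-correlation
#' control group, how many pairs were assigned to each annotation class.
#' The overall mapped percentage uses the group size as denominator; the
#' per-class percentages use the group's mapped count as denominator (so
#' classes may jointly exceed 100% when they overlap). Optionally adds a
#' 2x2 Fisher exact test of mapped status between the groups.
#'
#' @param low_assignments,control_assignments outputs of
#'   [map_pairs_to_annotations()] for the two groups.
#' @param fisher add `fisher_p` from a mapped-vs-unmapped by group 2x2
#'   table.
#' @return An `enrichment_report`: per group, `n_pairs`, `n_mapped`,
#'   `pct_mapped`, per-class counts and percentages of mapped, and the
#'   unique annotated regions hit (nearest-region identifiers).
#' @export
enrichment_summary <- function(low_assignments, control_assignments,
                               fisher = FALSE) {
  classes <- attr(low_assignments, "classes") %||%
    attr(control_assignments, "classes")
  tally <- function(a) {
    n <- nrow(a)
    n_mapped <- sum(a$mapped)
    per_class <- lapply(classes, function(cl) {
      cnt <- sum(a[[cl]])
      list(n = cnt,
           pct_of_mapped = if (n_mapped > 0) 100 * cnt / n_mapped else 0)
    })
    names(per_class) <- classes
    regions <- unique(unlist(lapply(classes, function(cl)
      a[[paste0(cl, "_nearest")]][a[[cl]]])))
    list(n_pairs = n, n_mapped = n_mapped,
         pct_mapped = if (n > 0) 100 * n_mapped / n else 0,
         classes = per_class,
         unique_regions_hit = length(regions))
  }
  rep <- list(low = tally(low_assignments),
              control = tally(control_assignments),
              class_labels = classes)
  if (fisher) {
    tab <- matrix(c(rep$low$n_mapped, rep$low$n_pairs - rep$low$n_mapped,
                    rep$control$n_mapped,
                    rep$control$n_pairs - rep$control$n_mapped), 2)
    rep$fisher_p <- stats::fisher.test(tab)$p.value
  }
  structure(rep, class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  fmt <- function(g, label) {
    cat(sprintf("%s: %d pairs, %d mapped (%.2f%%)\n", label, g$n_pairs,
                g$n_mapped, g$pct_mapped))
    for (cl in names(g$classes))
      cat(sprintf("  %-14s %6d pairs (%.2f%% of mapped)\n", cl,
                  g$classes[[cl]]$n, g$classes[[cl]]$pct_of_mapped))
    cat(sprintf("  unique annotated regions hit: %d\n", g$unique_regions_hit))
  }
  fmt(x$low, "low-correlation")
  fmt(x$control, "matched control")
  if (!is.null(x$fisher_p))
    cat(sprintf("Fisher mapped-vs-group p = %.3g\n", x$fisher_p))
  invisible(x)
}
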