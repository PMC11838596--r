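#' Read and write interval-channel local ancestry calls
#'
#' The interchange format is a TSV with columns `chrom`, `start`, `end`
#' (1-based, closed) followed by one column per (individual, ancestry)
#' combination named `sample|ancestry`, holding diploid counts in
#' \{0, 1, 2\}. Reading validates that counts sum to 2 over ancestries at
#' every row and individual; the error names the offending row.
#'
#' @param x an [interval_calls()] object.
#' @param path file path.
#' @return `read_interval_calls()` returns an [interval_calls()] object;
#'   an empty file yields an empty set. `write_interval_calls()` returns
#'   `path` invisibly.
#' @export
write_interval_calls <- function(x, path) {
  stopifnot(inherits(x, "interval_calls"))
  m <- n_loci(x)
  flat <- matrix(as.integer(x$counts), m)
  colnames(flat) <- as.vector(outer(x$sample_ids, x$ancestry_labels,
                                    function(s, a) paste(s, a, sep = "|")))
  # column-major over (sample, ancestry): regroup sample-major for readability
  ord <- order(rep(seq_along(x$sample_ids), times = length(x$ancestry_labels)))
  write_tsv(cbind(x$intervals, as.data.frame(flat[, ord, drop = FALSE],
                                             check.names = FALSE)), path)
}

#' @rdname write_interval_calls
#' @export
read_interval_calls <- function(path) {
  if (file.size(path) == 0)
    return(interval_calls(data.frame(chrom = character(), start = integer(),
                                     end = integer()),
                          array(integer(), c(0, 0, 0)),
                          character(), character()))
  df <- read_tsv(path)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cn <- setdiff(names(df), c("chrom", "start", "end"))
  parts <- strsplit(cn, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("count columns must be named sample|ancestry")
  samples <- unique(vapply(parts, `[`, "", 1L))
  ancestries <- unique(vapply(parts, `[`, "", 2L))
  cc <- array(NA_integer_, c(nrow(df), length(samples), length(ancestries)))
  for (j in seq_along(cn)) {
    v <- df[[cn[j]]]
    if (any(!v %in% 0:2))
      stop(sprintf("counts outside {0,1,2} in column %s (first bad row %d)",
                   cn[j], which(!v %in% 0:2)[1]))
    cc[, match(parts[[j]][1], samples), match(parts[[j]][2], ancestries)] <- v
  }
  tot <- rowSums(cc, dims = 2L)
  bad <- which(rowSums(tot != 2L) > 0)
  if (length(bad) > 0L)
    stop(sprintf("ancestry counts do not sum to 2 at row %d", bad[1]))
  interval_calls(df[c("chrom", "start", "end")], cc, samples, ancestries)
}

#' Read and write SNP-channel local ancestry calls
#'
#' Two dialects are supported. `"tsv"` mirrors the interval format with
#' columns `chrom`, `pos`, `id`, `maf`, `r2` (empty = directly genotyped)
#' and `sample|ancestry` count columns. `"vcf"` mirrors FLARE output: one
#' record per variant with INFO fields `MAF` and `R2` (absent for
#' genotyped variants) and per-sample FORMAT fields `AN1`/`AN2` holding
#' the 0-based ancestry index of each haplotype; the ancestry labels are
#' carried in a `##ANCESTRY=` header line. Haplotype codes referencing an
#' ancestry index at or beyond K raise an error naming the variant.
#'
#' @param x a [snp_calls()] object.
#' @param path file path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param ancestry_labels required when reading a VCF without an
#'   `##ANCESTRY` header line.
#' @return `read_snp_calls()` returns a [snp_calls()] object.
#' @export
write_snp_calls <- function(x, path, dialect = c("tsv", "vcf")) {
  stopifnot(inherits(x, "snp_calls"))
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    m <- n_loci(x)
    flat <- matrix(as.integer(x$counts), m)
    colnames(flat) <- as.vector(outer(x$sample_ids, x$ancestry_labels,
                                      function(s, a) paste(s, a, sep = "|")))
    ord <- order(rep(seq_along(x$sample_ids),
                     times = length(x$ancestry_labels)))
    df <- cbind(x$positions, maf = x$maf, r2 = x$r2,
                as.data.frame(flat[, ord, drop = FALSE], check.names = FALSE))
    return(write_tsv(df, path))
  }
  m <- n_loci(x); n <- length(x$sample_ids); k <- length(x$ancestry_labels)
  cm <- matrix(as.integer(x$counts), m * n, k)
  a1 <- max.col(cm > 0L, ties.method = "first")
  cm[cbind(seq_len(m * n), a1)] <- cm[cbind(seq_len(m * n), a1)] - 1L
  a2 <- max.col(cm > 0L, ties.method = "first")
  gt <- matrix(paste0(a1 - 1L, ":", a2 - 1L), m, n)
  info <- ifelse(is.na(x$r2),
                 sprintf("MAF=%.6g", x$maf),
                 sprintf("MAF=%.6g;R2=%.6g", x$maf, x$r2))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=laconcord",
    sprintf("##ANCESTRY=%s", paste(x$ancestry_labels, collapse = ",")),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality (absent when directly genotyped)\">",
    "##FORMAT=<ID=AN1,Number=1,Type=Integer,Description=\"Ancestry index of haplotype 1 (0-based)\">",
    "##FORMAT=<ID=AN2,Number=1,Type=Integer,Description=\"Ancestry index of haplotype 2 (0-based)\">",
    sprintf("##contig=<ID=%s>", unique(x$positions$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t"))
  body <- paste(x$positions$chrom, x$positions$pos, x$positions$id,
                "A", ".", ".", "PASS", info, "AN1:AN2",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_snp_calls
#' @export
read_snp_calls <- function(path, dialect = c("tsv", "vcf"),
                           ancestry_labels = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read_tsv(path)
    cn <- setdiff(names(df), c("chrom", "pos", "id", "maf", "r2"))
    parts <- strsplit(cn, "|", fixed = TRUE)
    samples <- unique(vapply(parts, `[`, "", 1L))
    ancestries <- unique(vapply(parts, `[`, "", 2L))
    cc <- array(NA_integer_, c(nrow(df), length(samples), length(ancestries)))
    for (j in seq_along(cn))
      cc[, match(parts[[j]][1], samples), match(parts[[j]][2], ancestries)] <-
        df[[cn[j]]]
    return(snp_calls(df[c("chrom", "pos", "id")], cc, df$maf, df$r2,
                     samples, ancestries))
  }
  hdr <- readLines(path, n = 500L)
  anc_line <- grep("^##ANCESTRY=", hdr, value = TRUE)
  if (length(anc_line) == 1L)
    ancestry_labels <- strsplit(sub("^##ANCESTRY=", "", anc_line), ",")[[1]]
  if (is.null(ancestry_labels))
    stop("VCF lacks an ##ANCESTRY header line; supply ancestry_labels")
  k <- length(ancestry_labels)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  an1 <- VariantAnnotation::geno(vcf)$AN1
  an2 <- VariantAnnotation::geno(vcf)$AN2
  storage.mode(an1) <- "integer"; storage.mode(an2) <- "integer"
  bad <- which(an1 >= k | an2 >= k | an1 < 0L | an2 < 0L, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("haplotype ancestry index out of range at variant %s",
                 rownames(an1)[bad[1, 1]]))
  m <- nrow(an1); n <- ncol(an1)
  cc <- array(0L, c(m, n, k))
  for (j in seq_len(k)) cc[, , j] <- (an1 == j - 1L) + (an2 == j - 1L)
  info <- VariantAnnotation::info(vcf)
  r2 <- if ("R2" %in% names(info)) as.numeric(info$R2) else rep(NA_real_, m)
  maf <- if ("MAF" %in% names(info)) as.numeric(info$MAF) else rep(NA_real_, m)
  snp_calls(data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                       pos = GenomicRanges::start(rr), id = names(rr)),
            cc, maf, r2, colnames(an1), ancestry_labels)
}

#' Annotation tracks (BED)
#'
#' Annotations are held as a `GRanges` whose `name` metadata column is the
#' class label (`blacklist`, `gene_cluster`, ...). On disk the track is a
#' 4-column BED (0-based half-open); coordinate conversion is handled by
#' rtracklayer at this boundary only.
#'
#' @param chrom,start,end 1-based closed spans.
#' @param class_label class per span.
#' @param track a `GRanges` as returned by `annotation_track()`.
#' @param path file path.
#' @return A `GRanges` with a `name` column.
#' @export
annotation_track <- function(chrom, start, end, class_label) {
  stopifnot(all(start <= end))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               name = as.character(class_label))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' @rdname annotation_track
#' @export
write_annotations <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}

#' @rdname annotation_track
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Monotone block liftover maps
#'
#' A liftover map is an ordered table of source-to-target coordinate
#' blocks standing in for an assembly chain file: columns `src_chrom`,
#' `src_start`, `src_end`, `dst_chrom`, `dst_start`, `dst_end` (1-based,
#' closed). Within a source chromosome blocks must not overlap, and every
#' block's source and target spans must have equal length.
#'
#' @param blocks data.frame of blocks.
#' @param map a `liftover_map`.
#' @param path file path.
#' @return A `liftover_map` object.
#' @export
liftover_map <- function(blocks) {
  blocks <- as.data.frame(blocks)
  need <- c("src_chrom", "src_start", "src_end", "dst_chrom", "dst_start",
            "dst_end")
  stopifnot(all(need %in% names(blocks)))
  blocks <- blocks[order(chrom_order(blocks$src_chrom), blocks$src_start),
                   need]
  rownames(blocks) <- NULL
  if (any((blocks$src_end - blocks$src_start) !=
          (blocks$dst_end - blocks$dst_start)))
    stop("liftover blocks must preserve span length")
  for (ch in unique(blocks$src_chrom)) {
    d <- blocks[blocks$src_chrom == ch, ]
    if (nrow(d) > 1L && any(d$src_start[-1] <= d$src_end[-nrow(d)]))
      stop(sprintf("overlapping liftover blocks on %s", ch))
  }
  structure(list(blocks = blocks), class = "liftover_map")
}

#' @rdname liftover_map
#' @export
write_liftover_map <- function(map, path) {
  write_tsv(map$blocks, path)
}

#' @rdname liftover_map
#' @export
read_liftover_map <- function(path) {
  liftover_map(read_tsv(path))
}

#' Lift interval calls onto the target build
#'
#' Each interval wholly contained in a single liftover block is shifted by
#' that block's offset. Intervals spanning more than one block (mapped
#' into more than one region), intervals whose block maps to a different
#' chromosome, and intervals covered by no block are discarded and
#' reported, not converted. Converted intervals keep their length.
#'
#' @param calls an [interval_calls()] object in source coordinates.
#' @param map a [liftover_map()].
#' @return A list with `calls` (converted [interval_calls()]) and `report`
#'   (class `liftover_report`): input/converted counts, the conversion
#'   percentage, and a data.frame of discarded intervals with their
#'   original coordinates and discard reason (`multi_region`,
#'   `different_chromosome`, `unmapped`).
#' @export
apply_liftover <- function(calls, map) {
  stopifnot(inherits(calls, "interval_calls"), inherits(map, "liftover_map"))
  b <- map$blocks
  bgr <- GenomicRanges::GRanges(b$src_chrom,
                                IRanges::IRanges(b$src_start, b$src_end))
  q <- loci_ranges(calls)
  within_hit <- GenomicRanges::findOverlaps(q, bgr, type = "within",
                                            select = "first")
  n_any <- GenomicRanges::countOverlaps(q, bgr)
  reason <- rep(NA_character_, length(q))
  reason[is.na(within_hit) & n_any > 0L] <- "multi_region"
  reason[n_any == 0L] <- "unmapped"
  ok <- !is.na(within_hit)
  diff_chrom <- ok & b$dst_chrom[within_hit] != b$src_chrom[within_hit]
  reason[diff_chrom] <- "different_chromosome"
  keep <- ok & !diff_chrom
  off <- b$dst_start[within_hit[keep]] - b$src_start[within_hit[keep]]
  new_int <- data.frame(chrom = calls$intervals$chrom[keep],
                        start = calls$intervals$start[keep] + off,
                        end = calls$intervals$end[keep] + off)
  converted <- interval_calls(new_int,
                              calls$counts[keep, , , drop = FALSE],
                              calls$sample_ids, calls$ancestry_labels)
  report <- structure(list(
    n_input = length(q), n_converted = sum(keep),
    n_discarded = sum(!keep),
    conversion_pct = 100 * sum(keep) / length(q),
    discarded = cbind(calls$intervals[!keep, , drop = FALSE],
                      reason = reason[!keep])),
    class = "liftover_report")
  list(calls = converted, report = report)
}

#' @export
print.liftover_report <- function(x, ...) {
  cat(sprintf("<liftover_report> %d/%d intervals converted (%.2f%%); %d discarded\n",
              x$n_converted, x$n_input, x$conversion_pct, x$n_discarded))
  if (x$n_discarded > 0)
    print(table(x$discarded$reason))
  invisible(x)
}

#' QC-filter SNP-channel variants
#'
#' Keeps variants with minor allele frequency at least `maf_min` and,
#' for imputed variants only, imputation quality at least `r2_min`;
#' variants with missing R2 are treated as directly genotyped and exempt
#' from the quality filter. Defaults are MAF >= 0.005 and R2 >= 0.8; a
#' stricter re-run uses `r2_min = 0.95`.
#'
#' @param calls a [snp_calls()] object.
#' @param maf_min,r2_min thresholds in `[0, 1]`.
#' @return The filtered [snp_calls()], with a `qc_report` attribute
#'   (retrievable via [qc_report()]) recording counts and kept fraction.
#' @export
filter_snps <- function(calls, maf_min = 0.005, r2_min = 0.8) {
  stopifnot(inherits(calls, "snp_calls"),
            maf_min >= 0, maf_min <= 1, r2_min >= 0, r2_min <= 1)
  keep <- calls$maf >= maf_min & (is.na(calls$r2) | calls$r2 >= r2_min)
  out <- subset_loci(calls, which(keep))
  attr(out, "qc_report") <- list(n_input = n_loci(calls),
                                 n_kept = sum(keep),
                                 kept_fraction = sum(keep) / n_loci(calls),
                                 maf_min = maf_min, r2_min = r2_min)
  out
}

#' @rdname filter_snps
#' @param x a filtered [snp_calls()] object.
#' @export
qc_report <- function(x) attr(x, "qc_report")
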