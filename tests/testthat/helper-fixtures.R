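# Fixture builders shared across the test files. Everything is generated
# in code; no binary fixtures.

## A hand-built ancestry panel: full control over tracts for exact checks.
manual_panel <- function(tracts, config, proportions = NULL) {
  n <- max(tracts$ind)
  k <- config$n_ancestries
  if (is.null(proportions))
    proportions <- matrix(1 / k, n, k)
  ids <- sprintf("ind%04d", seq_len(n))
  rownames(proportions) <- ids
  colnames(proportions) <- config$ancestry_labels
  structure(list(tracts = tracts, proportions = proportions,
                 groups = rep("Mainland", n), sample_ids = ids,
                 config = config),
            class = "ancestry_panel")
}

## Tracts covering each chromosome with a single ancestry per haplotype.
uniform_tracts <- function(config, ancestry = 1L) {
  n <- config$n_individuals
  do.call(rbind, lapply(seq_along(config$chrom_lengths_bp), function(ci) {
    data.frame(ind = rep(seq_len(n), each = 2), hap = rep(1:2, n),
               chrom = names(config$chrom_lengths_bp)[ci], start = 1L,
               end = as.integer(config$chrom_lengths_bp[[ci]]),
               ancestry = ancestry)
  }))
}

## SNP call set with independent loci: per locus and haplotype the
## ancestry is drawn from each individual's proportion vector.
independent_snp_set <- function(n_ind, m, pmat = NULL,
                                labels = c("African", "Amerindian", "European"),
                                chrom = "chr1", spacing = 1000L) {
  k <- length(labels)
  if (is.null(pmat)) {
    a <- c(4, 6, 10)[seq_len(k)]
    pmat <- laconcord:::rdirichlet_one(n_ind, a)
  }
  ids <- sprintf("s%04d", seq_len(n_ind))
  cum <- pmat %*% upper.tri(diag(k), diag = TRUE)
  draw_hap <- function(i) rowSums(outer(runif(m), cum[i, ], `>`)) + 1L
  h1 <- matrix(0L, m, n_ind); h2 <- matrix(0L, m, n_ind)
  for (i in seq_len(n_ind)) {
    h1[, i] <- draw_hap(i)
    h2[, i] <- draw_hap(i)
  }
  cc <- array(0L, c(m, n_ind, k))
  for (j in seq_len(k)) cc[, , j] <- (h1 == j) + (h2 == j)
  snp_calls(data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                       id = sprintf("rs%06d", seq_len(m))),
            cc, maf = runif(m, 0.05, 0.5), r2 = runif(m, 0.9, 1),
            sample_ids = ids, ancestry_labels = labels)
}

## Small interval set from explicit per-ancestry count matrices.
toy_interval_set <- function(intervals, count_list, ids = NULL) {
  k <- length(count_list)
  m <- nrow(intervals)
  n <- ncol(count_list[[1]])
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  cc <- array(0L, c(m, n, k))
  for (j in seq_len(k)) cc[, , j] <- count_list[[j]]
  interval_calls(intervals, cc, ids, names(count_list))
}

toy_snp_set <- function(positions, count_list, ids = NULL,
                        maf = NULL, r2 = NULL) {
  k <- length(count_list)
  m <- nrow(positions)
  n <- ncol(count_list[[1]])
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  cc <- array(0L, c(m, n, k))
  for (j in seq_len(k)) cc[, , j] <- count_list[[j]]
  snp_calls(positions, cc, maf %||% rep(0.2, m), r2 %||% rep(0.95, m),
            ids, names(count_list))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Phenotype table on top of a minimal SNP set, for mixed-model tests
## that do not need the tract machinery.
quick_phenotype <- function(n, variances, seed,
                            household_size = 4L, gamma = 0) {
  cfg <- simulation_config(
    n_individuals = n, seed = seed,
    chrom_lengths_bp = c(chr1 = 1e6), snp_spacing_bp = 5e5,
    interval_width_bp = 5e5,
    phenotype_spec = list(
      gamma = gamma, variances = variances,
      household_size_probs = stats::setNames(1, household_size)))
  snp <- toy_snp_set(data.frame(chrom = "chr1", pos = 1L, id = "rs1"),
                     list(African = matrix(1L, 1, n),
                          Amerindian = matrix(1L, 1, n),
                          European = matrix(0L, 1, n)),
                     ids = sprintf("ind%04d", seq_len(n)))
  simulate_phenotype(NULL, snp, cfg)
}
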