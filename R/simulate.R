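#' Configure a synthetic admixed cohort
#'
#' Builds the configuration object consumed by [simulate_tracts()],
#' [observe_intervals()], [observe_snps()] and [simulate_phenotype()]. The
#' generator emulates the statistical structure of a Hispanic/Latino-style
#' admixed cohort: per-individual global ancestry proportions drawn from
#' group-specific Dirichlet priors, ancestry tracts from a Poisson switch
#' process along the genetic map (rate `generations_g` per Morgan, each
#' switch redrawing ancestry from the individual's proportion vector), and
#' two noisy observation channels living on two coordinate systems offset
#' by `build_shift_bp`.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_ancestries number of ancestral populations K (3 or 7 have
#'   ready-made labels; any K >= 2 is accepted).
#' @param ancestry_labels optional character vector of length K.
#' @param group_dirichlet_alphas named list of length-K positive vectors,
#'   one per genetic analysis group; global proportions for an individual
#'   are drawn once from the group's Dirichlet.
#' @param group_weights sampling weights over groups (default uniform).
#' @param generations_g generations since admixture; ancestry switch rate
#'   per Morgan, so tract lengths are Exponential(`generations_g`) in
#'   genetic distance.
#' @param chrom_lengths_bp named or unnamed vector of chromosome lengths.
#' @param cm_per_mb genetic map rate (centimorgan per megabase).
#' @param snp_spacing_bp spacing of the SNP channel grid (target build).
#' @param interval_width_bp width of the interval channel grid (source
#'   build); must be at least `snp_spacing_bp`.
#' @param base_miscall_rate length-2 named vector `c(interval=, snp=)` of
#'   per-haplotype miscall probabilities outside problem regions.
#' @param leak_matrix K x K row-stochastic ancestry relabeling matrix
#'   applied to the SNP channel before the miscall step (identity by
#'   default); models systematic confusions such as European calls leaking
#'   into Middle Eastern when extra reference panels are added.
#' @param problem_regions data.frame with columns `chrom`, `start`, `end`,
#'   `rate` and optionally `class` (annotation label, default alternates
#'   `blacklist`/`gene_cluster`); within these spans both channels miscall
#'   at `rate` instead of the base rate.
#' @param build_shift_bp signed offset between the source (interval) and
#'   target (SNP) coordinate systems.
#' @param genotyped_frac fraction of SNP-channel variants emitted without
#'   an imputation R2 (directly genotyped).
#' @param r2_low_frac fraction of imputed variants whose R2 is drawn below
#'   0.8, so the QC filter has work to do.
#' @param phenotype_spec list controlling [simulate_phenotype()]; see that
#'   function. Entries override defaults.
#' @param seed integer master seed; every stage derives its own substream
#'   deterministically from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 200L,
                              n_ancestries = 3L,
                              ancestry_labels = NULL,
                              group_dirichlet_alphas = NULL,
                              group_weights = NULL,
                              generations_g = 10,
                              chrom_lengths_bp = c(chr1 = 60e6, chr2 = 50e6),
                              cm_per_mb = 1,
                              snp_spacing_bp = 20000L,
                              interval_width_bp = 200000L,
                              base_miscall_rate = c(interval = 0.01, snp = 0.01),
                              leak_matrix = NULL,
                              problem_regions = NULL,
                              build_shift_bp = 1000L,
                              genotyped_frac = 0.05,
                              r2_low_frac = 0.15,
                              phenotype_spec = list(),
                              seed = 1L) {
  k <- as.integer(n_ancestries)
  if (k < 2L) abort_config("n_ancestries must be at least 2")
  if (is.null(ancestry_labels)) {
    base7 <- c("African", "Amerindian", "European", "CSAsian", "EastAsian",
               "Oceanian", "MiddleEastern")
    ancestry_labels <- if (k <= 7L) base7[seq_len(k)]
                       else c(base7, paste0("anc", 8:k))
  }
  stopifnot(length(ancestry_labels) == k)
  if (is.null(group_dirichlet_alphas)) {
    base3 <- list(Mainland  = c(2, 18, 20),
                  Caribbean = c(10, 4, 26),
                  Cuban     = c(5, 2, 33))
    extra <- c(0.3, 0.4, 0.05, 1.0)  # sparse minor ancestries
    group_dirichlet_alphas <- lapply(base3, function(a)
      if (k <= 3L) a[seq_len(k)] else c(a, extra, rep(0.1, max(0, k - 7L)))[seq_len(k)])
  }
  for (a in group_dirichlet_alphas) {
    if (length(a) != k || any(a <= 0))
      abort_config("each Dirichlet alpha vector must have K positive entries")
  }
  if (is.null(group_weights))
    group_weights <- rep(1, length(group_dirichlet_alphas))
  if (is.null(leak_matrix)) leak_matrix <- diag(k)
  leak_matrix <- as.matrix(leak_matrix)
  if (!all(dim(leak_matrix) == c(k, k)) ||
      any(abs(rowSums(leak_matrix) - 1) > 1e-9) || any(leak_matrix < 0))
    abort_config("leak_matrix must be K x K row-stochastic")
  if (generations_g <= 0) abort_config("generations_g must be positive")
  if (length(chrom_lengths_bp) == 0L || any(chrom_lengths_bp <= 0))
    abort_config("chrom_lengths_bp must be a non-empty vector of positive lengths")
  if (is.null(names(chrom_lengths_bp)))
    names(chrom_lengths_bp) <- paste0("chr", seq_along(chrom_lengths_bp))
  if (interval_width_bp < snp_spacing_bp)
    abort_config("interval_width_bp must be >= snp_spacing_bp")
  if (any(base_miscall_rate < 0) || any(base_miscall_rate >= 1))
    abort_config("base_miscall_rate entries must lie in [0, 1)")
  if (is.null(names(base_miscall_rate)))
    names(base_miscall_rate) <- c("interval", "snp")
  if (is.null(problem_regions))
    problem_regions <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), rate = numeric(),
                                  class = character())
  problem_regions <- as.data.frame(problem_regions)
  if (nrow(problem_regions) > 0L) {
    if (is.null(problem_regions$class))
      problem_regions$class <- rep_len(c("blacklist", "gene_cluster"),
                                       nrow(problem_regions))
    bad <- !(problem_regions$chrom %in% names(chrom_lengths_bp)) |
      problem_regions$start < 1 |
      problem_regions$end > chrom_lengths_bp[problem_regions$chrom]
    if (any(bad))
      abort_config("problem_regions must lie within chrom_lengths_bp")
  }
  spec <- utils::modifyList(default_phenotype_spec(), phenotype_spec)
  structure(list(
    n_individuals = as.integer(n_individuals), n_ancestries = k,
    ancestry_labels = ancestry_labels,
    group_dirichlet_alphas = group_dirichlet_alphas,
    group_weights = group_weights,
    generations_g = generations_g,
    chrom_lengths_bp = chrom_lengths_bp, cm_per_mb = cm_per_mb,
    snp_spacing_bp = as.integer(snp_spacing_bp),
    interval_width_bp = as.integer(interval_width_bp),
    base_miscall_rate = base_miscall_rate, leak_matrix = leak_matrix,
    problem_regions = problem_regions,
    build_shift_bp = as.integer(build_shift_bp),
    genotyped_frac = genotyped_frac, r2_low_frac = r2_low_frac,
    phenotype_spec = spec, seed = as.integer(seed)),
    class = "simulation_config")
}

default_phenotype_spec <- function() {
  list(causal_chrom = NULL, causal_pos = NULL,   # default: middle of chrom 1
       causal_ancestry = "African",
       gamma = 0.5,
       variances = c(household = 0.1, block = 0.05, kinship = 0.1,
                     residual = 1),
       household_size_probs = c(`1` = 0.3, `2` = 0.35, `3` = 0.2, `4` = 0.15),
       households_per_block = 10L,
       sibpair_fraction = 0.3,
       beta = NULL)
}

morgans <- function(bp, config) bp / 1e6 * config$cm_per_mb / 100

#' Simulate diploid ancestry tracts
#'
#' Draws per-individual global ancestry proportions from the configured
#' group Dirichlet priors, then lays down ancestry tracts along each
#' haplotype as a Markov jump process in genetic distance: switch points
#' arrive as a Poisson process with rate `generations_g` per Morgan, and at
#' each switch the ancestry is redrawn from the individual's proportion
#' vector (self-transitions allowed). Stationary per-site ancestry
#' fractions therefore equal the drawn proportions in expectation, and
#' uncensored tract lengths are Exponential(`generations_g`) in Morgans.
#'
#' @param config a [simulation_config()].
#' @return An object of class `ancestry_panel`: a list with `tracts`
#'   (data.frame `ind`, `hap`, `chrom`, `start`, `end`, `ancestry`),
#'   `proportions` (individual x ancestry matrix), `groups`, `sample_ids`
#'   and the config. Tract coordinates are 1-based closed in the source
#'   build and tile each chromosome exactly; adjacent tracts may share an
#'   ancestry (switches with self-transition are retained so that
#'   inter-switch distances keep the exponential law).
#' @export
simulate_tracts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_individuals
  k <- config$n_ancestries
  with_seed(stage_seed(config$seed, "tracts"), {
    groups <- sample(names(config$group_dirichlet_alphas), n, replace = TRUE,
                     prob = config$group_weights)
    pmat <- matrix(NA_real_, n, k)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      pmat[idx, ] <- rdirichlet_one(length(idx),
                                    config$group_dirichlet_alphas[[g]])
    }
    n_hap <- 2L * n
    out <- vector("list", length(config$chrom_lengths_bp))
    for (ci in seq_along(config$chrom_lengths_bp)) {
      ch <- names(config$chrom_lengths_bp)[ci]
      len <- config$chrom_lengths_bp[[ci]]
      lam <- config$generations_g * morgans(len, config)
      nsw <- rpois(n_hap, lam)
      tot <- sum(nsw)
      hid <- rep.int(seq_len(n_hap), nsw)
      pos <- as.integer(floor(runif(tot) * (len - 1))) + 1L
      o <- order(hid, pos)
      hid <- hid[o]; pos <- pos[o]
      if (tot > 1L) {
        dup <- c(FALSE, diff(pos) == 0L & diff(hid) == 0L)
        hid <- hid[!dup]; pos <- pos[!dup]
      }
      nsw <- tabulate(hid, n_hap)
      nseg <- nsw + 1L
      seg_hid <- rep.int(seq_len(n_hap), nseg)
      seg_rank <- sequence(nseg)
      is_first <- seg_rank == 1L
      is_last <- seg_rank == nseg[seg_hid]
      starts <- integer(length(seg_hid)); ends <- integer(length(seg_hid))
      starts[is_first] <- 1L
      starts[!is_first] <- pos + 1L
      ends[!is_last] <- pos
      ends[is_last] <- as.integer(len)
      ind <- (seg_hid + 1L) %/% 2L
      anc <- sample_categorical(pmat, ind)
      out[[ci]] <- data.frame(ind = ind, hap = seg_hid - 2L * (ind - 1L),
                              chrom = ch, start = starts, end = ends,
                              ancestry = anc)
    }
    sample_ids <- sprintf("ind%04d", seq_len(n))
    rownames(pmat) <- sample_ids
    colnames(pmat) <- config$ancestry_labels
    structure(list(tracts = do.call(rbind, out), proportions = pmat,
                   groups = groups, sample_ids = sample_ids,
                   config = config),
              class = "ancestry_panel")
  })
}

#' @export
print.ancestry_panel <- function(x, ...) {
  cat(sprintf("<ancestry_panel> %d individuals, %d ancestries, %d tracts over %d chromosome(s)\n",
              length(x$sample_ids), x$config$n_ancestries, nrow(x$tracts),
              length(x$config$chrom_lengths_bp)))
  invisible(x)
}

#' Uncensored tract lengths in Morgans
#'
#' Returns inter-switch tract lengths, dropping the segment that runs into
#' each chromosome end (its length is censored by the chromosome boundary,
#' not by a recombination switch).
#'
#' Even uncensored segments carry a slight window bias: a long segment is
#' more likely to collide with the chromosome end and be excluded, so the
#' retained lengths run short by roughly one part in `g * L_Morgans`. For
#' distribution checks set `first_n` to keep only the first few segments
#' of each haplotype — when their expected total is well below the
#' chromosome length the selection effect is negligible and the retained
#' lengths are exponential to Monte-Carlo accuracy.
#'
#' @param panel an `ancestry_panel`.
#' @param keep_censored also return chromosome-end segments.
#' @param first_n keep at most this many segments per haplotype per
#'   chromosome (default all).
#' @return Numeric vector of lengths in Morgans.
#' @export
tract_lengths <- function(panel, keep_censored = FALSE, first_n = Inf) {
  tr <- panel$tracts
  if (!keep_censored) {
    lens <- panel$config$chrom_lengths_bp[tr$chrom]
    tr <- tr[tr$end < lens, , drop = FALSE]
  }
  if (is.finite(first_n)) {
    key <- paste(tr$ind, tr$hap, tr$chrom)
    keep <- unlist(lapply(split(seq_len(nrow(tr)), key), function(i)
      i[seq_len(min(first_n, length(i)))]), use.names = FALSE)
    tr <- tr[sort(keep), , drop = FALSE]
  }
  morgans(tr$end - tr$start + 1, panel$config)
}

## Haplotype ancestry at given source-build positions on one chromosome:
## matrix [position x haplotype], haplotypes ordered (ind1 hap1, ind1 hap2, ...).
hap_ancestry_at <- function(panel, chrom, pos) {
  tr <- panel$tracts[panel$tracts$chrom == chrom, , drop = FALSE]
  n_hap <- 2L * length(panel$sample_ids)
  hid <- (tr$ind - 1L) * 2L + tr$hap
  o <- order(hid, tr$start)
  tr <- tr[o, , drop = FALSE]; hid <- hid[o]
  st <- split(tr$start, hid); an <- split(tr$ancestry, hid)
  out <- matrix(NA_integer_, length(pos), n_hap)
  for (h in seq_len(n_hap)) {
    key <- as.character(h)
    idx <- findInterval(pos, st[[key]])
    out[, h] <- an[[key]][idx]
  }
  out
}

#' True diploid ancestry counts at a position
#'
#' @param panel an `ancestry_panel`.
#' @param chrom,pos source-build locus.
#' @param ancestry label of the ancestry counted.
#' @return Integer vector (one diploid count in 0..2 per individual).
#' @export
true_counts_at <- function(panel, chrom, pos, ancestry) {
  ai <- match(ancestry, panel$config$ancestry_labels)
  if (is.na(ai)) abort_config("unknown ancestry label '%s'", ancestry)
  h <- hap_ancestry_at(panel, chrom, pos)
  m <- h == ai
  as.integer(m[, seq(1, ncol(h), 2)] + m[, seq(2, ncol(h), 2)])
}

## Per-haplotype miscall: with probability `rate` (per locus) replace the
## ancestry by a uniform draw over the other K-1 ancestries.
apply_miscall <- function(anc, rate, k) {
  flip <- runif(length(anc)) < rate
  nf <- sum(flip)
  if (nf > 0L) {
    ri <- as.integer(floor(runif(nf) * (k - 1))) + 1L
    anc[flip] <- ri + (ri >= anc[flip])
  }
  anc
}

locus_rates <- function(chrom, start, end, base, regions) {
  rate <- rep(base, length(start))
  if (nrow(regions) > 0L) {
    for (j in seq_len(nrow(regions))) {
      hit <- chrom == regions$chrom[j] &
        start <= regions$end[j] & end >= regions$start[j]
      rate[hit] <- pmax(rate[hit], regions$rate[j])
    }
  }
  rate
}

#' Observe the interval (RFMix-style) channel
#'
#' Tiles each chromosome with intervals of `interval_width_bp` in the
#' source build and, per haplotype and interval, records the
#' majority-by-length ancestry (ties broken by lowest ancestry index).
#' The per-haplotype call is then passed through the miscall model, with
#' the inflated rate inside declared problem regions, and haplotypes are
#' summed to diploid counts.
#'
#' @param panel an `ancestry_panel`.
#' @param config the same [simulation_config()] used to build the panel.
#' @return An [interval_calls()] object in source-build coordinates.
#' @export
observe_intervals <- function(panel, config = panel$config) {
  k <- config$n_ancestries
  w <- config$interval_width_bp
  n_hap <- 2L * length(panel$sample_ids)
  with_seed(stage_seed(config$seed, "intervals"), {
    per_chrom <- lapply(seq_along(config$chrom_lengths_bp), function(ci) {
      ch <- names(config$chrom_lengths_bp)[ci]
      len <- config$chrom_lengths_bp[[ci]]
      st <- seq(1L, as.integer(len), by = w)
      en <- pmin(st + w - 1L, as.integer(len))
      n_int <- length(st)
      tr <- panel$tracts[panel$tracts$chrom == ch, , drop = FALSE]
      hid <- (tr$ind - 1L) * 2L + tr$hap
      o <- order(hid, tr$start)
      tr <- tr[o, , drop = FALSE]; hid <- hid[o]
      ts <- split(tr$start, hid); te <- split(tr$end, hid)
      ta <- split(tr$ancestry, hid)
      maj <- matrix(0L, n_int, n_hap)
      for (h in seq_len(n_hap)) {
        key <- as.character(h)
        s <- ts[[key]]; e <- te[[key]]; a <- ta[[key]]
        lm <- matrix(0, n_int, k)
        i1 <- (s - 1L) %/% w + 1L
        i2 <- (e - 1L) %/% w + 1L
        for (t in seq_along(s)) {
          if (i1[t] == i2[t]) {
            lm[i1[t], a[t]] <- lm[i1[t], a[t]] + (e[t] - s[t] + 1)
          } else {
            lm[i1[t], a[t]] <- lm[i1[t], a[t]] + (i1[t] * w - s[t] + 1)
            lm[i2[t], a[t]] <- lm[i2[t], a[t]] + (e[t] - (i2[t] - 1L) * w)
            if (i2[t] > i1[t] + 1L) {
              mid <- (i1[t] + 1L):(i2[t] - 1L)
              lm[mid, a[t]] <- lm[mid, a[t]] + w
            }
          }
        }
        maj[, h] <- max.col(lm, ties.method = "first")
      }
      rate <- locus_rates(rep(ch, n_int), st, en,
                          config$base_miscall_rate[["interval"]],
                          config$problem_regions)
      maj <- matrix(apply_miscall(as.vector(maj), rep(rate, n_hap), k),
                    n_int, n_hap)
      list(intervals = data.frame(chrom = ch, start = st, end = en),
           maj = maj)
    })
    intervals <- do.call(rbind, lapply(per_chrom, `[[`, "intervals"))
    maj <- do.call(rbind, lapply(per_chrom, `[[`, "maj"))
    interval_calls(intervals, hap_to_counts(maj, k),
                   panel$sample_ids, config$ancestry_labels)
  })
}

hap_to_counts <- function(hapmat, k) {
  a1 <- hapmat[, seq(1, ncol(hapmat), 2), drop = FALSE]
  a2 <- hapmat[, seq(2, ncol(hapmat), 2), drop = FALSE]
  cc <- array(0L, dim = c(nrow(hapmat), ncol(a1), k))
  for (j in seq_len(k)) cc[, , j] <- (a1 == j) + (a2 == j)
  cc
}

#' Observe the SNP (FLARE-style) channel
#'
#' Places SNPs every `snp_spacing_bp` along the source build, shifts their
#' positions into the target build (`+ build_shift_bp`), and per haplotype
#' passes the true ancestry through the relabeling `leak_matrix` and then
#' the miscall model (inflated inside problem regions). Each variant also
#' carries a simulated minor allele frequency (uniform on (0, 0.5)) and an
#' imputation quality R2 drawn from a mixture with mass below 0.8 plus a
#' directly-genotyped fraction with missing R2, so QC filtering is
#' exercised.
#'
#' @inheritParams observe_intervals
#' @return A [snp_calls()] object in target-build coordinates. SNPs whose
#'   shifted position would fall below 1 are dropped with a warning.
#' @export
observe_snps <- function(panel, config = panel$config) {
  k <- config$n_ancestries
  with_seed(stage_seed(config$seed, "snps"), {
    per_chrom <- lapply(seq_along(config$chrom_lengths_bp), function(ci) {
      ch <- names(config$chrom_lengths_bp)[ci]
      len <- config$chrom_lengths_bp[[ci]]
      src <- seq(1L, as.integer(len), by = config$snp_spacing_bp)
      hapanc <- hap_ancestry_at(panel, ch, src)
      if (!identical(config$leak_matrix, diag(k))) {
        hapanc <- matrix(sample_categorical(config$leak_matrix,
                                            as.vector(hapanc)),
                         nrow(hapanc), ncol(hapanc))
      }
      rate <- locus_rates(rep(ch, length(src)), src, src,
                          config$base_miscall_rate[["snp"]],
                          config$problem_regions)
      hapanc <- matrix(apply_miscall(as.vector(hapanc),
                                     rep(rate, ncol(hapanc)), k),
                       nrow(hapanc), ncol(hapanc))
      list(chrom = ch, src = src, hapanc = hapanc)
    })
    src_all <- unlist(lapply(per_chrom, `[[`, "src"))
    chrom_all <- rep(vapply(per_chrom, `[[`, "", "chrom"),
                     vapply(per_chrom, function(x) length(x$src), 0L))
    hapanc <- do.call(rbind, lapply(per_chrom, `[[`, "hapanc"))
    pos <- src_all + config$build_shift_bp
    keep <- pos >= 1L
    if (any(!keep))
      warning(sprintf("%d SNP(s) dropped: build shift places them below position 1",
                      sum(!keep)))
    m <- sum(keep)
    maf <- runif(m, 0, 0.5)
    genotyped <- runif(m) < config$genotyped_frac
    low <- runif(m) < config$r2_low_frac
    r2 <- ifelse(low, runif(m, 0.5, 0.8), runif(m, 0.8, 1))
    r2[genotyped] <- NA_real_
    snp_calls(data.frame(chrom = chrom_all[keep], pos = pos[keep],
                         id = sprintf("rs%07d", which(keep))),
              hap_to_counts(hapanc[keep, , drop = FALSE], k),
              maf, r2, panel$sample_ids, config$ancestry_labels)
  })
}

#' Simulate a phenotype with design random effects
#'
#' Generates a quantitative trait on top of the synthetic cohort:
#' `y = X beta + gamma * g_true + u_household + u_block + a_kinship + e`,
#' where `g_true` is the true diploid count of the causal ancestry at the
#' causal locus, the covariates mimic a population-cohort design (age,
#' sex, recruitment center, genetic analysis group, eGFR, five genetic
#' PCs), households and census blocks are nested grouping factors, and the
#' kinship effect uses a block-diagonal sib-pair kinship matrix (kinship
#' 0.25 within pairs). All variances come from
#' `config$phenotype_spec$variances`.
#'
#' @param panel the `ancestry_panel` carrying the true tracts; may be
#'   `NULL` when `gamma = 0` (no genetic effect is added).
#' @param snps the SNP channel, used to check the causal locus exists.
#' @param config a [simulation_config()].
#' @return A list of class `phenotype_table`: `data` (one row per
#'   individual: `y`, covariates, `household`, `block`), `kinship`
#'   (kinship coefficient matrix, diagonal 0.5), `covariates` (names used
#'   as fixed effects), and `spec` (the effects actually used, including
#'   `beta_used` and the true causal counts, for oracle checks).
#' @export
simulate_phenotype <- function(panel, snps, config = panel$config) {
  spec <- config$phenotype_spec
  n <- if (!is.null(panel)) length(panel$sample_ids)
       else length(snps$sample_ids)
  sample_ids <- if (!is.null(panel)) panel$sample_ids else snps$sample_ids
  causal_chrom <- spec$causal_chrom %||% names(config$chrom_lengths_bp)[1]
  causal_pos <- spec$causal_pos
  if (is.null(causal_pos)) {
    len <- config$chrom_lengths_bp[[causal_chrom]]
    grid <- seq(1L, as.integer(len), by = config$snp_spacing_bp)
    causal_pos <- grid[ceiling(length(grid) / 2)] + config$build_shift_bp
  }
  hit <- snps$positions$chrom == causal_chrom & snps$positions$pos == causal_pos
  if (spec$gamma != 0 && !any(hit))
    abort_config("causal locus %s:%d not present in the SNP channel",
                 causal_chrom, causal_pos)
  with_seed(stage_seed(config$seed, "phenotype"), {
    sizes_pool <- as.integer(names(spec$household_size_probs))
    hh <- integer(0); hid <- 0L
    while (length(hh) < n) {
      hid <- hid + 1L
      sz <- sizes_pool[sample.int(length(sizes_pool), 1L,
                                  prob = spec$household_size_probs)]
      hh <- c(hh, rep(hid, sz))
    }
    household <- sprintf("H%04d", hh[seq_len(n)])
    block <- sprintf("B%03d", (hh[seq_len(n)] - 1L) %/%
                       spec$households_per_block + 1L)
    n_pairs <- floor(n * spec$sibpair_fraction / 2)
    kin <- diag(0.5, n)
    if (n_pairs > 0L) {
      pick <- sample.int(n, 2L * n_pairs)
      p1 <- pick[seq_len(n_pairs)]; p2 <- pick[n_pairs + seq_len(n_pairs)]
      kin[cbind(p1, p2)] <- 0.25
      kin[cbind(p2, p1)] <- 0.25
    }
    dimnames(kin) <- list(sample_ids, sample_ids)
    grp <- if (!is.null(panel)) panel$groups
           else sample(c("Mainland", "Caribbean", "Cuban"), n, replace = TRUE)
    df <- data.frame(
      sample_id = sample_ids,
      age = rnorm(n, 47, 13.5),
      sex = factor(sample(c("Female", "Male"), n, TRUE, prob = c(0.59, 0.41))),
      center = factor(sample(c("Bronx", "Chicago", "Miami", "SanDiego"),
                             n, TRUE)),
      group = factor(grp),
      egfr = rnorm(n, 108, 26.6),
      stringsAsFactors = FALSE)
    for (j in 1:5) df[[paste0("PC", j)]] <- rnorm(n)
    covars <- c("age", "sex", "center", "group", "egfr", paste0("PC", 1:5))
    xm <- stats::model.matrix(stats::reformulate(covars), df)
    beta <- rep(0, ncol(xm)); names(beta) <- colnames(xm)
    defaults <- c(`(Intercept)` = 0, age = 0.01, sexMale = 0.2,
                  egfr = -0.005)
    defaults[grep("^center", colnames(xm), value = TRUE)] <-
      seq(-0.1, 0.1, length.out = length(grep("^center", colnames(xm))))
    defaults[grep("^group", colnames(xm), value = TRUE)] <-
      seq(0.05, 0.2, length.out = length(grep("^group", colnames(xm))))
    defaults[grep("^PC", colnames(xm), value = TRUE)] <- 0.1
    beta[names(defaults)] <- defaults
    if (!is.null(spec$beta)) beta[names(spec$beta)] <- spec$beta
    g_true <- rep(0L, n)
    if (spec$gamma != 0) {
      src_pos <- causal_pos - config$build_shift_bp
      g_true <- true_counts_at(panel, causal_chrom, src_pos,
                               spec$causal_ancestry)
    }
    v <- spec$variances
    u_h <- rnorm(length(unique(household)), 0, sqrt(v[["household"]]))
    names(u_h) <- unique(household)
    u_b <- rnorm(length(unique(block)), 0, sqrt(v[["block"]]))
    names(u_b) <- unique(block)
    a <- rnorm(n, 0, sqrt(v[["kinship"]]))
    if (n_pairs > 0L && v[["kinship"]] > 0) {
      # joint draw with relationship 2*kinship = 0.5 within sib pairs
      z2 <- rnorm(n_pairs)
      a[p2] <- sqrt(v[["kinship"]]) *
        (0.5 * a[p1] / sqrt(v[["kinship"]]) + sqrt(1 - 0.25) * z2)
    }
    y <- drop(xm %*% beta) + spec$gamma * g_true +
      u_h[household] + u_b[block] + a +
      rnorm(n, 0, sqrt(v[["residual"]]))
    df$y <- as.numeric(y)
    df$household <- factor(household)
    df$block <- factor(block)
    spec_out <- utils::modifyList(spec, list(
      beta_used = beta, g_true = g_true, causal_chrom = causal_chrom,
      causal_pos = causal_pos))
    structure(list(data = df, kinship = kin, covariates = covars,
                   spec = spec_out),
              class = "phenotype_table")
  })
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d individuals, %d households, %d blocks\n",
              nrow(x$data), nlevels(x$data$household), nlevels(x$data$block)))
  invisible(x)
}

#' Build a block liftover map between the two synthetic builds
#'
#' Stands in for an assembly chain file: each chromosome is split into
#' `n_blocks` contiguous blocks, every block mapping to the target build
#' by `build_shift_bp`. Block boundaries are placed off the interval grid
#' so that some intervals straddle two blocks and exercise the
#' multi-region discard rule; optionally the last block is redirected to a
#' different chromosome to exercise the cross-chromosome discard rule.
#'
#' @param config a [simulation_config()].
#' @param n_blocks blocks per chromosome.
#' @param cross_chrom_block if `TRUE`, the final block of the last
#'   chromosome maps to the first chromosome.
#' @return A `liftover_map` (see [liftover_map()]).
#' @export
make_liftover_map <- function(config, n_blocks = 4L, cross_chrom_block = FALSE) {
  rows <- list()
  chroms <- names(config$chrom_lengths_bp)
  half_w <- config$interval_width_bp %/% 2L
  for (ci in seq_along(chroms)) {
    len <- as.integer(config$chrom_lengths_bp[[ci]])
    cuts <- unique(pmin(len - 1L,
      as.integer(round(len * seq_len(n_blocks - 1L) / n_blocks)) + half_w))
    st <- c(1L, cuts + 1L)
    en <- c(cuts, len)
    dst_chrom <- rep(chroms[ci], length(st))
    if (cross_chrom_block && ci == length(chroms))
      dst_chrom[length(dst_chrom)] <- chroms[1]
    rows[[ci]] <- data.frame(src_chrom = chroms[ci], src_start = st,
                             src_end = en, dst_chrom = dst_chrom,
                             dst_start = st + config$build_shift_bp,
                             dst_end = en + config$build_shift_bp)
  }
  liftover_map(do.call(rbind, rows))
}

#' Annotation track implied by the configured problem regions
#'
#' @param config a [simulation_config()].
#' @return An annotation `GRanges` (see [annotation_track()]) labeling
#'   each problem region with its class.
#' @export
annotations_from_config <- function(config) {
  pr <- config$problem_regions
  annotation_track(pr$chrom, pr$start, pr$end, pr$class)
}

#' Serialize a full synthetic fixture set
#'
#' Writes the interval channel, SNP channel (VCF dialect), annotations
#' (BED), liftover map, phenotype table, kinship matrix and the
#' configuration into `dir`, and returns a manifest listing every file
#' with its row count and MD5 checksum. Re-running with the same config
#' (hence seed) reproduces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param intervals,snps,phenotype,map,annotations the objects to write;
#'   any may be `NULL` to skip.
#' @param config the [simulation_config()] used.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
write_fixture_set <- function(dir, intervals = NULL, snps = NULL,
                              phenotype = NULL, map = NULL,
                              annotations = NULL, config = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", dir))
  }
  files <- list()
  put <- function(name, rows) files[[name]] <<- rows
  if (!is.null(intervals)) {
    write_interval_calls(intervals, file.path(dir, "interval_calls.tsv"))
    put("interval_calls.tsv", n_loci(intervals))
  }
  if (!is.null(snps)) {
    write_snp_calls(snps, file.path(dir, "snp_calls.vcf"), dialect = "vcf")
    put("snp_calls.vcf", n_loci(snps))
  }
  if (!is.null(phenotype)) {
    write_tsv(phenotype$data, file.path(dir, "phenotype.tsv"))
    put("phenotype.tsv", nrow(phenotype$data))
    kin <- data.frame(sample_id = rownames(phenotype$kinship),
                      phenotype$kinship, check.names = FALSE)
    write_tsv(kin, file.path(dir, "kinship.tsv"))
    put("kinship.tsv", nrow(kin))
  }
  if (!is.null(map)) {
    write_liftover_map(map, file.path(dir, "liftover_map.tsv"))
    put("liftover_map.tsv", nrow(map$blocks))
  }
  if (!is.null(annotations)) {
    write_annotations(annotations, file.path(dir, "annotations.bed"))
    put("annotations.bed", length(annotations))
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put("config.json", 1L)
  }
  fnames <- names(files)
  manifest <- list(
    seed = if (!is.null(config)) config$seed else NA_integer_,
    files = data.frame(
      file = fnames,
      rows = unname(unlist(files)),
      md5 = unname(tools::md5sum(file.path(dir, fnames)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
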