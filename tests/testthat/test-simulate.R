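test_that("degenerate proportions yield a single ancestry everywhere", {
  cfg <- simulation_config(
    n_individuals = 10, seed = 11, chrom_lengths_bp = c(chr1 = 5e6),
    group_dirichlet_alphas = list(only = c(1e8, 1e-8, 1e-8)))
  panel <- simulate_tracts(cfg)
  expect_true(all(panel$tracts$ancestry == 1L))
  expect_equal(unname(panel$proportions[, 1]), rep(1, 10))
})

test_that("tracts tile chromosomes contiguously and switch counts are Poisson", {
  cfg <- simulation_config(n_individuals = 1000, seed = 5,
                           chrom_lengths_bp = c(chr1 = 10e6),
                           generations_g = 10)
  panel <- simulate_tracts(cfg)
  tr <- panel$tracts
  # tiling: per haplotype, starts follow previous ends, endpoints exact
  key <- paste(tr$ind, tr$hap)
  spl <- split(tr, key)
  one <- spl[[1]]
  expect_equal(one$start[1], 1L)
  expect_equal(one$end[nrow(one)], 10e6)
  if (nrow(one) > 1)
    expect_equal(one$start[-1], one$end[-nrow(one)] + 1L)
  # switch count per haplotype ~ Poisson(g * L_morgans), mean within 3 SE
  lambda <- 10 * (10e6 / 1e6 / 100)  # = 1
  counts <- vapply(spl, nrow, 0L) - 1L
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("stationary ancestry fractions match the drawn proportions", {
  pi0 <- c(0.3, 0.45, 0.25)
  cfg <- simulation_config(
    n_individuals = 500, seed = 9, chrom_lengths_bp = c(chr1 = 50e6),
    generations_g = 10,
    group_dirichlet_alphas = list(fixed = pi0 * 1e8))
  panel <- simulate_tracts(cfg)
  tr <- panel$tracts
  len <- tr$end - tr$start + 1
  for (k in 1:3) {
    by_ind <- tapply(len * (tr$ancestry == k), tr$ind, sum) /
      tapply(len, tr$ind, sum)
    se <- sd(by_ind) / sqrt(length(by_ind))
    expect_lt(abs(mean(by_ind) - pi0[k]), 3 * se)
  }
})

test_that("noise-free interval channel reports the spanning tract", {
  cfg <- simulation_config(n_individuals = 3, seed = 1,
                           chrom_lengths_bp = c(chr1 = 1e6),
                           interval_width_bp = 5e5, snp_spacing_bp = 1e5,
                           base_miscall_rate = c(interval = 0, snp = 0))
  panel <- manual_panel(uniform_tracts(cfg, ancestry = 2L), cfg)
  iv <- observe_intervals(panel, cfg)
  expect_equal(n_loci(iv), 2L)
  expect_true(all(iv$counts[, , 2] == 2L))
  expect_true(all(iv$counts[, , c(1, 3)] == 0L))
})

test_that("interval majority is by length with low-index tie-break", {
  cfg <- simulation_config(n_individuals = 1, seed = 1,
                           chrom_lengths_bp = c(chr1 = 100L),
                           interval_width_bp = 100L, snp_spacing_bp = 50L,
                           base_miscall_rate = c(interval = 0, snp = 0))
  # hap 1: ancestry 3 covers 60 bp, ancestry 1 covers 40 -> majority 3
  # hap 2: ancestry 2 and 1 cover 50/50 -> tie broken to ancestry 1
  tr <- data.frame(ind = 1L, hap = c(1L, 1L, 2L, 2L),
                   chrom = "chr1", start = c(1L, 61L, 1L, 51L),
                   end = c(60L, 100L, 50L, 100L),
                   ancestry = c(3L, 1L, 2L, 1L))
  iv <- observe_intervals(manual_panel(tr, cfg), cfg)
  expect_equal(as.integer(iv$counts[1, 1, ]), c(1L, 0L, 1L))
})

test_that("miscall at rate 2/3 over K=3 equalizes mean counts", {
  cfg <- simulation_config(n_individuals = 300, seed = 3,
                           chrom_lengths_bp = c(chr1 = 10e6),
                           interval_width_bp = 1e5, snp_spacing_bp = 1e5,
                           base_miscall_rate = c(interval = 2 / 3, snp = 0))
  panel <- manual_panel(uniform_tracts(cfg, ancestry = 1L), cfg)
  iv <- observe_intervals(panel, cfg)
  means <- apply(iv$counts, 3, mean)
  # keep prob 1/3 for truth, miscall splits 2/3 over the other two
  expect_true(all(abs(means - 2 / 3) < 0.02))
  expect_true(all(rowSums(iv$counts, dims = 2) == 2L))
})

test_that("problem regions inflate interval-channel discordance", {
  region <- data.frame(chrom = "chr1", start = 10e6, end = 20e6, rate = 0.3)
  base_cfg <- function(pr) simulation_config(
    n_individuals = 200, seed = 21, chrom_lengths_bp = c(chr1 = 40e6),
    interval_width_bp = 2e5, snp_spacing_bp = 1e5,
    base_miscall_rate = c(interval = 0, snp = 0), problem_regions = pr)
  cfg <- base_cfg(region)
  cfg0 <- base_cfg(NULL)
  panel <- simulate_tracts(cfg)
  noisy <- observe_intervals(panel, cfg)
  clean <- observe_intervals(panel, cfg0)
  mism <- rowMeans(apply(noisy$counts != clean$counts, 1:2, any))
  inside <- noisy$intervals$start <= 20e6 & noisy$intervals$end >= 10e6
  expect_gt(mean(mism[inside]), mean(mism[!inside]) + 0.1)
  expect_lt(mean(mism[!inside]), 1e-9)
})

test_that("noise-free SNP channel equals the truth at every position", {
  cfg <- simulation_config(n_individuals = 50, seed = 13,
                           chrom_lengths_bp = c(chr1 = 5e6),
                           snp_spacing_bp = 1e5, interval_width_bp = 1e5,
                           base_miscall_rate = c(interval = 0, snp = 0),
                           build_shift_bp = 0L)
  panel <- simulate_tracts(cfg)
  sn <- observe_snps(panel, cfg)
  for (j in seq_len(n_loci(sn))) {
    tc <- true_counts_at(panel, "chr1", sn$positions$pos[j], "African")
    expect_equal(as.integer(sn$counts[j, , 1]), tc)
  }
})

test_that("ancestry leakage attenuates the source ancestry as expected", {
  k <- 7
  leak <- diag(k)
  leak[3, 3] <- 0.9; leak[3, 7] <- 0.1   # European -> MiddleEastern
  cfg <- simulation_config(
    n_individuals = 500, n_ancestries = 7, seed = 17,
    chrom_lengths_bp = c(chr1 = 20e6), snp_spacing_bp = 2e5,
    interval_width_bp = 2e5,
    base_miscall_rate = c(interval = 0, snp = 0), leak_matrix = leak)
  panel <- simulate_tracts(cfg)
  sn <- observe_snps(panel, cfg)
  cfg0 <- cfg; cfg0$leak_matrix <- diag(k)
  sn0 <- observe_snps(panel, cfg0)
  ratio <- mean(sn$counts[, , 3]) / mean(sn0$counts[, , 3])
  expect_lt(abs(ratio - 0.9), 0.02)
})

test_that("QC is a no-op when every imputed variant clears the threshold", {
  cfg <- simulation_config(n_individuals = 20, seed = 2,
                           chrom_lengths_bp = c(chr1 = 2e6),
                           snp_spacing_bp = 1e5, interval_width_bp = 1e5,
                           r2_low_frac = 0, genotyped_frac = 0)
  sn <- observe_snps(simulate_tracts(cfg), cfg)
  kept <- filter_snps(sn, maf_min = 0, r2_min = 0.8)
  expect_equal(n_loci(kept), n_loci(sn))
  expect_equal(qc_report(kept)$kept_fraction, 1)
})

test_that("phenotype fixed effects are recoverable by OLS when pure noise", {
  ph <- quick_phenotype(800, c(household = 0, block = 0, kinship = 0,
                               residual = 1), seed = 31)
  xm <- model.matrix(reformulate(ph$covariates), ph$data)
  fit <- lm.fit(xm, ph$data$y)
  se <- sqrt(diag(chol2inv(fit$qr$qr[1:ncol(xm), 1:ncol(xm)])) *
               sum(fit$residuals^2) / fit$df.residual)
  beta_true <- ph$spec$beta_used[colnames(xm)]
  expect_true(all(abs(fit$coefficients - beta_true) < 3.5 * se))
})

test_that("deterministic limit: phenotype equals fixed part plus gamma*count", {
  cfg <- simulation_config(
    n_individuals = 60, seed = 41, chrom_lengths_bp = c(chr1 = 5e6),
    snp_spacing_bp = 1e5, interval_width_bp = 1e5,
    base_miscall_rate = c(interval = 0, snp = 0),
    phenotype_spec = list(gamma = 1, variances = c(
      household = 0, block = 0, kinship = 0, residual = 0)))
  panel <- simulate_tracts(cfg)
  sn <- observe_snps(panel, cfg)
  ph <- simulate_phenotype(panel, sn, cfg)
  xm <- model.matrix(reformulate(ph$covariates), ph$data)
  resid <- unname(ph$data$y - drop(xm %*% ph$spec$beta_used[colnames(xm)]))
  expect_equal(resid, as.numeric(ph$spec$g_true), tolerance = 1e-12)
  # individuals with counts 2 vs 0 differ by exactly 2 after adjustment
  i2 <- which(ph$spec$g_true == 2)[1]; i0 <- which(ph$spec$g_true == 0)[1]
  expect_equal(resid[i2] - resid[i0], 2, tolerance = 1e-12)
})

test_that("household variance drives the configured intraclass correlation", {
  ph <- quick_phenotype(2000, c(household = 4, block = 0, kinship = 0,
                                residual = 1), seed = 51,
                        household_size = 2L)
  xm <- model.matrix(reformulate(ph$covariates), ph$data)
  r <- ph$data$y - drop(xm %*% ph$spec$beta_used[colnames(xm)])
  pairs <- split(r, ph$data$household)
  pairs <- do.call(rbind, pairs[lengths(pairs) == 2])
  icc <- cor(pairs[, 1], pairs[, 2])
  expect_lt(abs(icc - 0.8), 0.05)
})

test_that("fixture sets are byte-identical under a seed and differ across seeds", {
  make <- function(seed, dir) {
    cfg <- simulation_config(n_individuals = 8, seed = seed,
                             chrom_lengths_bp = c(chr1 = 2e6),
                             snp_spacing_bp = 2e5, interval_width_bp = 4e5,
                             problem_regions = data.frame(
                               chrom = "chr1", start = 1e5, end = 3e5,
                               rate = 0.3))
    panel <- simulate_tracts(cfg)
    write_fixture_set(dir,
                      intervals = observe_intervals(panel, cfg),
                      snps = observe_snps(panel, cfg),
                      phenotype = simulate_phenotype(panel,
                                                     observe_snps(panel, cfg),
                                                     cfg),
                      map = make_liftover_map(cfg),
                      annotations = annotations_from_config(cfg),
                      config = cfg)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  m1 <- make(99, d1); m2 <- make(99, d2); m3 <- make(100, d3)
  expect_equal(m1$files$md5, m2$files$md5)
  expect_false(all(m1$files$md5 == m3$files$md5))
  # manifest row counts match the files on disk
  iv <- read_interval_calls(file.path(d1, "interval_calls.tsv"))
  expect_equal(n_loci(iv), m1$files$rows[m1$files$file == "interval_calls.tsv"])
})

test_that("configuration errors are caught", {
  expect_error(simulation_config(generations_g = 0), "generations_g")
  expect_error(simulation_config(chrom_lengths_bp = numeric(0)), "non-empty")
  expect_error(simulation_config(snp_spacing_bp = 1e5,
                                 interval_width_bp = 1e4), "interval_width")
  expect_error(simulation_config(
    problem_regions = data.frame(chrom = "chr9", start = 1, end = 10,
                                 rate = 0.1)), "within")
  expect_error(simulation_config(leak_matrix = matrix(1, 3, 3)),
               "row-stochastic")
})
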