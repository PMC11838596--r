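test_that("REML collapses to OLS when the data carry no random effects", {
  ph <- quick_phenotype(500, c(household = 0, block = 0, kinship = 0,
                               residual = 1), seed = 61)
  fit <- fit_null_model(ph)
  nonres <- fit$varcomp[setdiff(names(fit$varcomp), "residual")]
  expect_true(all(nonres < 0.05 * fit$varcomp[["residual"]]))
  xm <- model.matrix(reformulate(ph$covariates), ph$data)
  ols <- qr.coef(qr(xm), ph$data$y)
  # the GLS estimate converges to OLS as the spurious components vanish;
  # with the components at O(1/n) the coefficients agree to ~1%
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 0.05)
  fit0 <- fit_null_model(ph, random = character(0), kinship = NULL)
  expect_equal(fit0$coefficients$estimate, unname(ols), tolerance = 1e-10)
})

test_that("REML recovers household and residual variances (Monte-Carlo)", {
  ests <- t(vapply(1:10, function(rep) {
    ph <- quick_phenotype(800, c(household = 2, block = 0, kinship = 0,
                                 residual = 1), seed = 700 + rep)
    fit <- fit_null_model(ph, random = "household", kinship = NULL,
                          projection = FALSE)
    fit$varcomp[c("household", "residual")]
  }, numeric(2)))
  expect_lt(abs(mean(ests[, 1]) - 2), 0.2)
  expect_lt(abs(mean(ests[, 2]) - 1), 0.1)
})

test_that("the factor-path REML agrees with an independent mixed-model fit", {
  set.seed(301)
  n <- 400; hh <- factor(rep(1:100, each = 4))
  x1 <- rnorm(n)
  y <- 1 + 0.5 * x1 + rep(rnorm(100, 0, sqrt(1.5)), each = 4) + rnorm(n)
  df <- data.frame(y = y, x1 = x1, household = hh)
  fit <- fit_null_model(df, covariates = "x1", random = "household",
                        kinship = NULL, projection = FALSE,
                        control = list(drop_tol = 1e-5, factr = 100))
  lm4 <- lme4::lmer(y ~ x1 + (1 | household), df, REML = TRUE)
  expect_equal(fit$varcomp[["household"]],
               unname(lme4::VarCorr(lm4)$household[1]), tolerance = 1e-4)
  expect_equal(fit$varcomp[["residual"]], sigma(lm4)^2, tolerance = 1e-4)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(lm4)),
               tolerance = 1e-5)
})

test_that("refitting on identical input reproduces the components", {
  ph <- quick_phenotype(300, c(household = 1, block = 0.5, kinship = 0,
                               residual = 1), seed = 71)
  f1 <- fit_null_model(ph, projection = FALSE)
  f2 <- fit_null_model(ph, projection = FALSE)
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-8)
  expect_true(all(f1$varcomp >= 0))
  expect_gt(f1$varcomp[["residual"]], 0)
})

test_that("rank deficiency and bad kinship are reported by name", {
  ph <- quick_phenotype(100, c(household = 0, block = 0, kinship = 0,
                               residual = 1), seed = 81)
  ph$data$age_copy <- ph$data$age
  expect_error(fit_null_model(ph, covariates = c("age", "age_copy")),
               "age_copy")
  bad <- diag(0.5, 100); bad[1, 2] <- bad[2, 1] <- 5
  expect_error(fit_null_model(ph, kinship = bad), "positive semi-definite")
})

test_that("score test equals the OLS score oracle without variance components", {
  for (rep in 1:10) {
    set.seed(900 + rep)
    n <- 80
    df <- data.frame(y = rnorm(n), c1 = rnorm(n), c2 = runif(n))
    df$y <- df$y + 0.4 * df$c1
    fit <- fit_null_model(df, covariates = c("c1", "c2"),
                          random = character(0), kinship = NULL)
    g <- rbinom(n, 2, 0.35)
    st <- score_test(fit, g)
    x <- cbind(1, df$c1, df$c2)
    e <- df$y - x %*% qr.coef(qr(x), df$y)
    s2 <- sum(e^2) / (n - 3)
    mg <- g - x %*% qr.coef(qr(x), g)
    oracle <- sum(g * e)^2 / (s2 * sum(g * mg))
    expect_equal(st$stat, oracle, tolerance = 1e-8)
  }
})

test_that("counts in the covariate span are flagged untestable", {
  ph <- quick_phenotype(150, c(household = 0.5, block = 0, kinship = 0,
                               residual = 1), seed = 91)
  fit <- fit_null_model(ph)
  expect_true(score_test(fit, rep(2, 150))$untestable)
  expect_true(score_test(fit, ph$data$age)$untestable)
  expect_false(score_test(fit, rbinom(150, 2, 0.5))$untestable)
  expect_error(score_test(fit_null_model(ph, projection = FALSE),
                          rbinom(150, 2, 0.5)), "projection")
})

test_that("scan results are deterministic and affine-equivariant", {
  set.seed(101)
  n <- 120
  sn <- independent_snp_set(n, 30)
  ph <- quick_phenotype(n, c(household = 0.5, block = 0, kinship = 0,
                             residual = 1), seed = 102)
  ph$data$sample_id <- sn$sample_ids
  ctl <- list(drop_tol = 1e-5, factr = 100)  # resolve the optimum finely
  fit <- fit_null_model(ph, control = ctl)
  fit$sample_ids <- sn$sample_ids
  sc1 <- scan_ancestry(fit, sn)
  sc2 <- scan_ancestry(fit, sn)
  expect_equal(sc1, sc2)
  # location-scale change of y with refit leaves the statistics unchanged
  ph2 <- ph
  ph2$data$y <- 3 + 2.5 * ph$data$y
  fit2 <- fit_null_model(ph2, control = ctl)
  fit2$sample_ids <- sn$sample_ids
  sc3 <- scan_ancestry(fit2, sn)
  expect_equal(sc3$stat, sc1$stat, tolerance = 1e-6)
  # scans agree with locus-by-locus score tests
  g <- laconcord:::slice_counts(sn, "African")[4, ]
  expect_equal(sc1$stat[sc1$pos == sn$positions$pos[4] &
                          sc1$ancestry == "African"],
               score_test(fit, g)$stat, tolerance = 1e-10)
})

test_that("ancestry collapse follows the 7-to-4 rule and preserves totals", {
  labs7 <- c("African", "Amerindian", "European", "CSAsian", "EastAsian",
             "Oceanian", "MiddleEastern")
  cc <- array(0L, c(1, 1, 7))
  cc[1, 1, ] <- c(0L, 0L, 1L, 1L, 0L, 0L, 0L)
  sn <- snp_calls(data.frame(chrom = "chr1", pos = 1L), cc, 0.2, 0.9,
                  "s1", labs7)
  col <- collapse_ancestries(sn)
  expect_equal(col$ancestry_labels,
               c("African", "Amerindian", "European", "other"))
  expect_equal(as.integer(col$counts[1, 1, ]), c(0L, 0L, 1L, 1L))
  cc[1, 1, ] <- c(2L, 0L, 0L, 0L, 0L, 0L, 0L)
  sn2 <- snp_calls(data.frame(chrom = "chr1", pos = 1L), cc, 0.2, 0.9,
                   "s1", labs7)
  expect_equal(as.integer(collapse_ancestries(sn2)$counts[1, 1, ]),
               c(2L, 0L, 0L, 0L))
  # conservation on random inputs
  set.seed(7)
  sn7 <- independent_snp_set(20, 50, labels = labs7,
                             pmat = laconcord:::rdirichlet_one(
                               20, c(4, 6, 10, 0.5, 0.5, 0.2, 1)))
  col7 <- collapse_ancestries(sn7)
  expect_true(all(rowSums(col7$counts, dims = 2) == 2L))
})

test_that("collapsing never changes the African/Amerindian scan", {
  set.seed(11)
  labs7 <- c("African", "Amerindian", "European", "CSAsian", "EastAsian",
             "Oceanian", "MiddleEastern")
  n <- 100
  sn7 <- independent_snp_set(n, 25, labels = labs7,
                             pmat = laconcord:::rdirichlet_one(
                               n, c(4, 6, 10, 0.5, 0.5, 0.2, 1)))
  ph <- quick_phenotype(n, c(household = 0.5, block = 0, kinship = 0,
                             residual = 1), seed = 12)
  fit <- fit_null_model(ph)
  fit$sample_ids <- sn7$sample_ids
  s_full <- scan_ancestry(fit, sn7)
  s_col <- scan_ancestry(fit, collapse_ancestries(sn7))
  expect_equal(s_col$stat, s_full$stat)
  expect_equal(s_col$p, s_full$p)
})

test_that("effective-loci Bonferroni approaches alpha/M for independent loci", {
  set.seed(21)
  # common proportions: no global-ancestry correlation between loci, so
  # the loci are truly independent
  sn <- independent_snp_set(400, 150,
                            pmat = matrix(rep(c(0.25, 0.35, 0.4), each = 400),
                                          400))
  thr <- significance_threshold(sn, method = "bonferroni_effective",
                                alpha = 0.05, ancestries = "African")
  expect_lt(thr$threshold, 1.5 * 0.05 / 150)
  expect_gt(thr$threshold, 0.05 / (1.5 * 150))
})

test_that("permutation threshold hits alpha for perfectly duplicated loci", {
  set.seed(22)
  n <- 150
  one <- rbinom(n, 2, 0.4)
  cc <- array(0L, c(20, n, 3))
  for (j in 1:20) {
    cc[j, , 1] <- one
    cc[j, , 2] <- 2L - one
  }
  sn <- snp_calls(data.frame(chrom = "chr1", pos = (1:20) * 1000L),
                  cc, rep(0.2, 20), rep(0.9, 20),
                  sprintf("ind%04d", 1:n),
                  c("African", "Amerindian", "European"))
  ph <- quick_phenotype(n, c(household = 0, block = 0, kinship = 0,
                             residual = 1), seed = 23)
  fit <- fit_null_model(ph)
  fit$sample_ids <- sn$sample_ids
  thr <- significance_threshold(sn, fit, method = "permutation",
                                alpha = 0.05, ancestries = "African",
                                B = 600, seed = 24)
  expect_lt(abs(thr$threshold - 0.05), 0.03)
  expect_error(significance_threshold(sn, fit, method = "permutation",
                                      B = 50), "B >= 100")
})

test_that("analytic and permutation thresholds bracket each other sanely", {
  set.seed(25)
  n <- 200
  sn <- independent_snp_set(n, 60)
  ph <- quick_phenotype(n, c(household = 0, block = 0, kinship = 0,
                             residual = 1), seed = 26)
  fit <- fit_null_model(ph)
  fit$sample_ids <- sn$sample_ids
  t1 <- significance_threshold(sn, method = "bonferroni_effective",
                               alpha = 0.05, ancestries = "African")
  t2 <- significance_threshold(sn, fit, method = "permutation",
                               alpha = 0.05, ancestries = "African",
                               B = 500, seed = 27)
  expect_lt(max(t1$threshold, t2$threshold) /
              min(t1$threshold, t2$threshold), 10)
  for (t in c(t1$threshold, t2$threshold)) {
    expect_gt(t, 0.05 / (10 * 60))
    expect_lt(t, 0.05)
  }
})

test_that("top-hit comparison finds the argmin with positional tie-break", {
  sc <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                   end = c(10L, 20L, 30L, 40L, 50L),
                   id = paste0("v", 1:5), ancestry = "African",
                   stat = c(1, 9, 4, 9, 2),
                   p = c(0.3, 0.001, 0.04, 0.001, 0.2),
                   direction = 1L, untestable = FALSE)
  regions <- data.frame(chrom = "chr1", start = 1L, end = 100L,
                        region_id = "R1")
  top <- compare_top_hits(list(chanA = sc), regions)
  expect_equal(top$id, "v2")     # tie at p = 0.001 broken by position
  expect_equal(top$p, 0.001)
  single <- compare_top_hits(list(chanA = sc),
                             data.frame(chrom = "chr1", start = 25L,
                                        end = 35L))
  expect_equal(single$id, "v3")
  sc$untestable <- TRUE; sc$p <- NA_real_
  none <- compare_top_hits(list(chanA = sc), regions)
  expect_true(none$all_untestable)
  expect_true(is.na(none$id))
})
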