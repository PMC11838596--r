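#' Fit the admixture-mapping null mixed model by REML
#'
#' Fits `y = X beta + u_household + u_block + a_kinship + e` without any
#' local ancestry term: fixed covariate effects plus independent Gaussian
#' random effects for the sampling-design grouping factors and a
#' polygenic term with covariance proportional to twice the kinship
#' matrix. Variance components are estimated by restricted maximum
#' likelihood with non-negativity constraints; components estimated at
#' the zero boundary are dropped and the model refit. The fit exposes the
#' residual projection `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1` reused
#' by every downstream score test.
#'
#' When all random effects are grouping factors the restricted likelihood
#' is evaluated through the low-rank (Woodbury) identity in the factor
#' dimension; a dense kinship matrix switches to Cholesky factorization
#' of the full n x n covariance.
#'
#' @param data a `phenotype_table` from [simulate_phenotype()], or a
#'   data.frame with the outcome, covariates and grouping factors.
#' @param outcome name of the outcome column.
#' @param covariates character vector of fixed-effect columns; defaults
#'   to the phenotype table's covariate set.
#' @param random names of grouping-factor columns receiving independent
#'   random intercepts (default household and census block).
#' @param kinship optional kinship coefficient matrix (diagonal 0.5 for
#'   outbred individuals); the modeled covariance contribution is
#'   `sigma^2_kin * 2 * kinship`. Must be positive semi-definite.
#' @param projection if `FALSE`, skip forming the n x n projection matrix
#'   (variance components and fixed effects only; score tests then
#'   require a refit with `projection = TRUE`).
#' @param control list: `drop_tol` (relative threshold below which a
#'   component counts as zero), `factr` (L-BFGS-B convergence factor).
#' @return An object of class `null_model_fit`: `coefficients` (GLS
#'   estimates with standard errors), `varcomp` (named variance
#'   components including `residual`), `logrestlik`, `converged`,
#'   `dropped` (components removed at the boundary), and the projection
#'   ingredients (`P`, `Py`, marginal residuals) when requested.
#' @export
fit_null_model <- function(data, outcome = "y", covariates = NULL,
                           random = c("household", "block"), kinship = NULL,
                           projection = TRUE,
                           control = list(drop_tol = 1e-5, factr = 1e7)) {
  if (inherits(data, "phenotype_table")) {
    covariates <- covariates %||% data$covariates
    if (missing(kinship)) kinship <- data$kinship
    df <- data$data
  } else df <- as.data.frame(data)
  stopifnot(outcome %in% names(df))
  y <- as.numeric(df[[outcome]])
  n <- length(y)
  covariates <- covariates %||% character(0)
  x <- if (length(covariates) > 0)
    stats::model.matrix(stats::reformulate(covariates), df)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop(sprintf("rank-deficient covariate matrix; collinear column(s): %s",
                 paste(drop_cols, collapse = ", ")))
  }
  random <- intersect(random, names(df))
  zs <- lapply(random, function(f)
    stats::model.matrix(~ 0 + factor(df[[f]])))
  names(zs) <- random
  if (!is.null(kinship)) {
    kinship <- as.matrix(kinship)
    stopifnot(nrow(kinship) == n, ncol(kinship) == n)
    rel <- 2 * kinship
    ev_ok <- tryCatch({ chol(rel + diag(1e-8 * mean(diag(rel)), n)); TRUE },
                      error = function(e) FALSE)
    if (!ev_ok) stop("kinship matrix is not positive semi-definite")
  }
  comp_names <- c(random, if (!is.null(kinship)) "kinship", "residual")
  fit <- reml_fit(y, x, zs, if (is.null(kinship)) NULL else 2 * kinship,
                  control)
  # boundary handling: drop components estimated at (numerical) zero, refit
  vy <- var(y)
  active <- names(fit$theta)[fit$theta > control$drop_tol * vy |
                               names(fit$theta) == "residual"]
  dropped <- setdiff(names(fit$theta), active)
  if (length(dropped) > 0) {
    zs2 <- zs[intersect(random, active)]
    kin2 <- if ("kinship" %in% active && !is.null(kinship)) 2 * kinship
    fit <- reml_fit(y, x, zs2, kin2, control)
    theta <- stats::setNames(numeric(length(comp_names)), comp_names)
    theta[names(fit$theta)] <- fit$theta
  } else theta <- fit$theta
  out <- list(coefficients = fit$coefficients, varcomp = theta,
              logrestlik = fit$logrestlik, converged = fit$converged,
              dropped = dropped, n = n, x = x, y = y,
              sample_ids = df$sample_id)
  if (projection) {
    vinv <- fit$vinv()
    vix <- vinv %*% x
    xtvx_inv <- solve(crossprod(x, vix))
    p <- vinv - vix %*% xtvx_inv %*% t(vix)
    out$P <- p
    out$Py <- drop(p %*% y)
    out$resid_marginal <- y - drop(x %*% fit$coefficients$estimate)
  }
  structure(out, class = "null_model_fit")
}

## REML core. zs: list of factor design matrices; kin: dense relationship
## matrix (already 2*kinship) or NULL. Returns theta, GLS coefficients,
## restricted log-likelihood and a closure producing dense V^-1.
reml_fit <- function(y, x, zs, kin, control) {
  n <- length(y)
  vy <- var(y)
  comp <- c(names(zs), if (!is.null(kin)) "kinship", "residual")
  m <- length(comp) - 1L
  if (is.null(kin) && m > 0L) {
    z <- do.call(cbind, zs)
    qs <- vapply(zs, ncol, 0L)
    col_comp <- rep(seq_len(m), qs)
    ztz <- crossprod(z)
    ztyx <- crossprod(z, cbind(y, x))
    byx <- crossprod(cbind(y, x))
    nll <- function(th) {
      d <- th[col_comp]; se <- th[m + 1L]
      if (se <= 0) return(1e10)
      act <- d > 0
      if (!any(act)) {
        bt <- byx / se
        val <- reml_from_blocks(n * log(se), bt, n, ncol(x))
        return(val)
      }
      ds <- sqrt(d[act])
      wtw <- ds * t(ds * ztz[act, act, drop = FALSE])
      a <- wtw + diag(se, sum(act))
      ra <- tryCatch(chol(a), error = function(e) NULL)
      if (is.null(ra)) return(1e10)
      wb <- ds * ztyx[act, , drop = FALSE]
      q <- backsolve(ra, wb, transpose = TRUE)
      bt <- (byx - crossprod(q)) / se
      logdetv <- (n - sum(act)) * log(se) + 2 * sum(log(diag(ra)))
      reml_from_blocks(logdetv, bt, n, ncol(x))
    }
    make_vinv <- function(th) {
      d <- th[col_comp]; se <- th[m + 1L]
      act <- d > 0
      if (!any(act)) return(diag(1 / se, n))
      w <- z[, act, drop = FALSE] * rep(sqrt(d[act]), each = n)
      a <- crossprod(w) + diag(se, sum(act))
      (diag(n) - w %*% solve(a, t(w))) / se
    }
  } else {
    ks <- c(lapply(zs, tcrossprod), if (!is.null(kin)) list(kin))
    nll <- function(th) {
      se <- th[m + 1L]
      if (se <= 0) return(1e10)
      v <- diag(se, n)
      for (j in seq_len(m)) if (th[j] > 0) v <- v + th[j] * ks[[j]]
      rv <- tryCatch(chol(v), error = function(e) NULL)
      if (is.null(rv)) return(1e10)
      s <- backsolve(rv, backsolve(rv, cbind(y, x), transpose = TRUE))
      bt <- crossprod(cbind(y, x), s)
      reml_from_blocks(2 * sum(log(diag(rv))), bt, n, ncol(x))
    }
    make_vinv <- function(th) {
      se <- th[m + 1L]
      v <- diag(se, n)
      for (j in seq_len(m)) if (th[j] > 0) v <- v + th[j] * ks[[j]]
      chol2inv(chol(v))
    }
  }
  if (m == 0L) {
    # residual-only model: closed form (REML variance = RSS / (n - p))
    b <- qr.coef(qr(x), y)
    r <- y - drop(x %*% b)
    se2 <- sum(r^2) / (n - ncol(x))
    theta <- stats::setNames(se2, "residual")
    vinvf <- function() diag(1 / se2, n)
    xtxi <- chol2inv(qr.R(qr(x)))
    coefs <- data.frame(term = colnames(x), estimate = as.numeric(b),
                        se = sqrt(diag(xtxi) * se2))
    ll <- -nll_closed_ols(y, x, se2)
    return(list(theta = theta, coefficients = coefs, logrestlik = ll,
                converged = TRUE, vinv = vinvf))
  }
  th0 <- c(rep(vy / (2 * m), m), vy / 2)
  opt <- stats::optim(th0, nll, method = "L-BFGS-B",
                      lower = c(rep(0, m), 1e-8 * vy),
                      control = list(maxit = 500,
                                     factr = control$factr %||% 1e7))
  theta <- stats::setNames(opt$par, comp)
  vinv <- make_vinv(opt$par)
  vix <- vinv %*% x
  xtvx <- crossprod(x, vix)
  beta <- solve(xtvx, crossprod(vix, y))
  coefs <- data.frame(term = colnames(x), estimate = as.numeric(beta),
                      se = sqrt(diag(solve(xtvx))))
  list(theta = theta, coefficients = coefs, logrestlik = -opt$value,
       converged = opt$convergence == 0,
       vinv = function() make_vinv(opt$par))
}

## -2 * restricted log-likelihood pieces from the [y X]' V^-1 [y X] block
## matrix; bt[1,1] = y'V^-1 y, bt[1,-1] = y'V^-1 X, bt[-1,-1] = X'V^-1 X.
reml_from_blocks <- function(logdetv, bt, n, p) {
  xtvx <- bt[-1, -1, drop = FALSE]
  rx <- tryCatch(chol(xtvx), error = function(e) NULL)
  if (is.null(rx)) return(1e10)
  xtvy <- bt[-1, 1]
  beta <- backsolve(rx, backsolve(rx, xtvy, transpose = TRUE))
  ypy <- bt[1, 1] - sum(xtvy * beta)
  if (ypy <= 0) return(1e10)
  0.5 * (logdetv + 2 * sum(log(diag(rx))) + ypy)
}

nll_closed_ols <- function(y, x, se2) {
  n <- length(y)
  b <- qr.coef(qr(x), y)
  r <- y - drop(x %*% b)
  0.5 * (n * log(se2) + determinant(crossprod(x) / se2)$modulus[1] +
           sum(r^2) / se2)
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat(sprintf("<null_model_fit> n = %d, REML logLik = %.3f%s\n", x$n,
              x$logrestlik, if (x$converged) "" else " (NOT converged)"))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  if (length(x$dropped) > 0)
    cat("dropped at zero boundary:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Score test of a local ancestry count vector
#'
#' Tests association between the phenotype and a per-individual diploid
#' ancestry count vector under the fitted null model:
#' `U = g' V^-1 (y - X beta)`, `Var(U) = g' P g`, statistic
#' `U^2 / Var(U)` referred to chi-squared with 1 df. Counts lying in the
#' span of the covariates (or constant) are flagged untestable.
#'
#' @param null a [fit_null_model()] result with `projection = TRUE`.
#' @param g numeric vector of ancestry counts aligned with the null
#'   model's sample ordering.
#' @param id optional locus identifier copied to the output.
#' @return One-row data.frame: `id`, `stat`, `p`, `direction`,
#'   `untestable`, `n`.
#' @export
score_test <- function(null, g, id = NA_character_) {
  stopifnot(inherits(null, "null_model_fit"))
  if (is.null(null$P))
    stop("null model was fitted with projection = FALSE; refit to score-test")
  g <- as.numeric(g)
  stopifnot(length(g) == null$n)
  u <- sum(g * null$Py)
  varu <- drop(crossprod(g, null$P %*% g))
  gc <- g - mean(g)
  scale <- sum(gc^2) * max(diag(null$P))
  if (varu <= 1e-10 * max(scale, 1e-300) || scale == 0) {
    return(data.frame(id = id, stat = NA_real_, p = NA_real_,
                      direction = NA_integer_, untestable = TRUE,
                      n = null$n))
  }
  stat <- u^2 / varu
  data.frame(id = id, stat = stat,
             p = stats::pchisq(stat, 1, lower.tail = FALSE),
             direction = as.integer(sign(u)), untestable = FALSE,
             n = null$n)
}

#' Genome scan of local ancestry counts
#'
#' Runs the score test at every locus of a call set for each tested
#' ancestry (African and Amerindian by default, the ancestries whose
#' frequency differentials drive admixture-mapping signals in
#' Hispanic/Latino cohorts). Results are ordered by chromosome, position,
#' then ancestry, and are deterministic.
#'
#' @param null a [fit_null_model()] result with projection.
#' @param calls an [interval_calls()] or [snp_calls()] object whose
#'   sample ordering matches the null model.
#' @param ancestries ancestry labels to test.
#' @return A data.frame of class `ancestry_scan`: `chrom`, `pos` (SNP
#'   position or interval start), `end`, `id`, `ancestry`, `stat`, `p`,
#'   `direction`, `untestable`.
#' @export
scan_ancestry <- function(null, calls,
                          ancestries = c("African", "Amerindian")) {
  stopifnot(inherits(null, "null_model_fit"))
  if (is.null(null$P))
    stop("null model was fitted with projection = FALSE; refit to scan")
  if (!is.null(null$sample_ids) &&
      !identical(as.character(null$sample_ids), calls$sample_ids))
    stop("call set and null model cover different individuals")
  ancestries <- intersect(ancestries, calls$ancestry_labels)
  stopifnot(length(ancestries) > 0)
  if (inherits(calls, "snp_calls")) {
    loc <- data.frame(chrom = calls$positions$chrom,
                      pos = calls$positions$pos,
                      end = calls$positions$pos, id = calls$positions$id)
  } else {
    loc <- data.frame(chrom = calls$intervals$chrom,
                      pos = calls$intervals$start,
                      end = calls$intervals$end,
                      id = sprintf("%s:%d-%d", calls$intervals$chrom,
                                   calls$intervals$start,
                                   calls$intervals$end))
  }
  out <- lapply(ancestries, function(k) {
    g <- t(slice_counts(calls, k))          # n x m
    pg <- null$P %*% g
    u <- drop(crossprod(g, null$Py))
    varu <- colSums(g * pg)
    gc <- sweep(g, 2, colMeans(g))
    scale <- colSums(gc^2) * max(diag(null$P))
    unt <- varu <= 1e-10 * pmax(scale, 1e-300) | scale == 0
    stat <- ifelse(unt, NA_real_, u^2 / varu)
    data.frame(loc, ancestry = k, stat = stat,
               p = ifelse(unt, NA_real_,
                          stats::pchisq(stat, 1, lower.tail = FALSE)),
               direction = ifelse(unt, NA_integer_, as.integer(sign(u))),
               untestable = unt, row.names = NULL)
  })
  res <- do.call(rbind, out)
  res <- res[order(chrom_order(res$chrom), res$pos, res$ancestry), ]
  rownames(res) <- NULL
  class(res) <- c("ancestry_scan", "data.frame")
  res
}

#' Genome-wide significance threshold for an admixture-mapping scan
#'
#' Two simplified substitutes for a full test-statistic-process
#' calibration are provided. `bonferroni_effective` estimates the
#' effective number of independent tests from the decay of inter-locus
#' local-ancestry correlation: walking each chromosome, a locus opens a
#' new independent block when its count correlation with the previous
#' block-opening locus falls below `cor_break`; the threshold is
#' `alpha / M_eff` summed over tested ancestries. `permutation` permutes
#' the null-model marginal residuals `B` times, rescans, and returns the
#' `alpha`-quantile of the per-permutation minimum p-value.
#'
#' @param calls call set supplying the local ancestry counts.
#' @param null a [fit_null_model()] result (required for `permutation`).
#' @param method `"bonferroni_effective"` or `"permutation"`.
#' @param alpha family-wise error rate.
#' @param ancestries ancestries the scan will test.
#' @param cor_break correlation below which loci count as independent.
#' @param B number of permutations (at least 100).
#' @param seed optional seed for the permutation draw.
#' @return A list of class `threshold_estimate`: `method`, `alpha`,
#'   `threshold`, and `m_eff` (per ancestry and total) or `B`.
#' @export
significance_threshold <- function(calls, null = NULL,
                                   method = c("bonferroni_effective",
                                              "permutation"),
                                   alpha = 0.05,
                                   ancestries = c("African", "Amerindian"),
                                   cor_break = 0.1, B = 1000L, seed = NULL) {
  method <- match.arg(method)
  ancestries <- intersect(ancestries, calls$ancestry_labels)
  stopifnot(length(ancestries) > 0)
  chroms <- if (inherits(calls, "snp_calls")) calls$positions$chrom
            else calls$intervals$chrom
  if (method == "bonferroni_effective") {
    m_eff <- vapply(ancestries, function(k) {
      cc <- slice_counts(calls, k)
      tot <- 0L
      for (ch in unique(chroms)) {
        rows <- which(chroms == ch)
        ref <- NULL
        for (i in rows) {
          v <- cc[i, ]
          if (sd(v) < 1e-12) next
          if (is.null(ref)) { ref <- v; tot <- tot + 1L; next }
          r <- suppressWarnings(cor(v, ref))
          if (is.na(r) || abs(r) < cor_break) { ref <- v; tot <- tot + 1L }
        }
      }
      tot
    }, 0L)
    total <- sum(m_eff)
    return(structure(list(method = method, alpha = alpha,
                          m_eff = m_eff, m_eff_total = total,
                          threshold = alpha / max(1L, total)),
                     class = "threshold_estimate"))
  }
  if (B < 100L) abort_config("permutation requires B >= 100")
  if (is.null(null) || is.null(null$P))
    stop("permutation thresholds need a null model fitted with projection")
  e <- null$resid_marginal
  n <- null$n
  run <- function() {
    perm <- replicate(B, sample.int(n))
    minp <- rep(1, B)
    for (k in ancestries) {
      g <- t(slice_counts(calls, k))
      pg <- null$P %*% g
      varu <- colSums(g * pg)
      ok <- varu > 1e-12 * pmax(colSums(g * g), 1e-300)
      if (!any(ok)) next
      tg <- t(pg[, ok, drop = FALSE])        # m x n
      ep <- matrix(e[perm], n, B)
      u <- tg %*% ep                         # m x B
      stat <- sweep(u^2, 1, varu[ok], "/")
      pv <- stats::pchisq(stat, 1, lower.tail = FALSE)
      minp <- pmin(minp, apply(pv, 2, min))
    }
    minp
  }
  minp <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(method = method, alpha = alpha, B = B,
                 threshold = unname(stats::quantile(minp, alpha, type = 1))),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %s: threshold = %.3g (alpha = %.3g%s)\n",
              x$method, x$threshold, x$alpha,
              if (!is.null(x$m_eff_total))
                sprintf(", M_eff = %d", x$m_eff_total)
              else sprintf(", B = %d", x$B)))
  invisible(x)
}

#' Top-hit comparison across channels and batches
#'
#' For each genomic region and each scan (one per inference channel per
#' batch), finds the most significantly associated locus within the
#' region and its p-value — the machine analogue of a
#' discovery/replication comparison table. Ties are broken by position;
#' regions where every locus is untestable yield an `NA` row flagged
#' `all_untestable`.
#'
#' @param scans named list of [scan_ancestry()] results.
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `region_id`.
#' @return A long data.frame: `region_id`, `chrom`, `start`, `end`,
#'   `channel`, `ancestry`, `id`, `pos`, `p`, `n_loci`, `all_untestable`.
#' @export
compare_top_hits <- function(scans, regions) {
  stopifnot(is.list(scans), !is.null(names(scans)))
  regions <- as.data.frame(regions)
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                                 regions$end)
  rows <- list()
  for (ri in seq_len(nrow(regions))) {
    for (nm in names(scans)) {
      sc <- scans[[nm]]
      for (k in unique(sc$ancestry)) {
        d <- sc[sc$ancestry == k & sc$chrom == regions$chrom[ri] &
                  sc$pos >= regions$start[ri] & sc$pos <= regions$end[ri], ,
                drop = FALSE]
        if (nrow(d) == 0L) next
        def <- d[!d$untestable, , drop = FALSE]
        if (nrow(def) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            region_id = regions$region_id[ri], chrom = regions$chrom[ri],
            start = regions$start[ri], end = regions$end[ri], channel = nm,
            ancestry = k, id = NA_character_, pos = NA_integer_,
            p = NA_real_, n_loci = nrow(d), all_untestable = TRUE)
          next
        }
        best <- def[order(def$p, def$pos), ][1, ]
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = regions$region_id[ri], chrom = regions$chrom[ri],
          start = regions$start[ri], end = regions$end[ri], channel = nm,
          ancestry = k, id = best$id, pos = best$pos, p = best$p,
          n_loci = nrow(d), all_untestable = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(region_id = character(), chrom = character(),
               start = integer(), end = integer(), channel = character(),
               ancestry = character(), id = character(), pos = integer(),
               p = numeric(), n_loci = integer(), all_untestable = logical())
  class(out) <- c("comparison_table", "data.frame")
  out
}
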