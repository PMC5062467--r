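#' Count matrix with sample annotations
#'
#' Container for a raw RNA-seq gene x sample count matrix together with the
#' per-sample annotations (tissue of origin, condition such as
#' tumor/normal, cohort) the pipeline stages key on.
#'
#' @param counts non-negative integer matrix, genes in rows (unique
#'   rownames), samples in columns (unique colnames).
#' @param sample_meta data.frame with columns `sample`, `tissue`,
#'   `condition` and optionally `cohort`, one row per column of `counts`.
#' @return object of class `count_matrix` with elements `counts` and
#'   `samples`.
#' @export
count_matrix <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique sample colnames")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  need <- c("sample", "tissue", "condition")
  if (!all(need %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  if (!("cohort" %in% names(sample_meta))) sample_meta$cohort <- "cohort1"
  miss <- setdiff(colnames(counts), sample_meta$sample)
  if (length(miss) > 0L)
    stop("samples without annotation: ", paste(utils::head(miss, 5L), collapse = ", "))
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, samples = sample_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      length(unique(x$samples$tissue)), "tissue(s),",
      length(unique(x$samples$condition)), "condition(s)\n")
  invisible(x)
}

.counts_of <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalization constants: for each sample,
#' the median over genes of the ratio between its count and the gene's
#' geometric mean across samples, restricted to genes whose geometric mean
#' is positive (i.e. genes expressed in every sample).
#'
#' @param counts matrix or [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  y <- .counts_of(counts)
  loggeo <- rowMeans(log(y))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no gene is expressed in all samples; cannot form a median-of-ratios ",
         "reference. Consider filtering samples or a pseudo-reference fallback.")
  sf <- apply(y[ok, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - loggeo[ok]))
  })
  sf
}

## ---- internal NB GLM machinery ------------------------------------------

# Vectorized IRLS for a per-gene NB GLM with log link, design
# ~ 1 + group (group a 0/1 indicator), offsets log size factors.
# y: G x n matrix, x: 0/1 length n, alpha: per-gene dispersion (length G).
# Returns beta0/beta1 (natural-log scale), se1, fitted mu.
nb_irls <- function(y, x, logsf, alpha, maxit = 50L, tol = 1e-10) {
  G <- nrow(y); n <- ncol(y)
  sf <- exp(logsf)
  k <- sweep(y, 2L, sf, "/")
  i1 <- x == 1
  m0 <- rowMeans(k[, !i1, drop = FALSE]); m1 <- rowMeans(k[, i1, drop = FALSE])
  beta0 <- log(pmax(m0, 1e-8))
  beta1 <- log(pmax(m1, 1e-8)) - beta0
  offs <- matrix(logsf, G, n, byrow = TRUE)
  for (it in seq_len(maxit)) {
    eta <- beta0 + outer(beta1, as.numeric(x)) + offs
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + mu * alpha)
    z <- (eta - offs) + (y - mu) / mu
    wz <- w * z
    a <- rowSums(w)
    b <- rowSums(w[, i1, drop = FALSE])
    r1 <- rowSums(wz)
    r2 <- rowSums(wz[, i1, drop = FALSE])
    nb0 <- (r1 - r2) / pmax(a - b, 1e-300)
    nb1 <- r2 / pmax(b, 1e-300) - nb0
    nb0 <- pmin(pmax(nb0, -50), 50)
    nb1 <- pmin(pmax(nb1, -50), 50)
    delta <- max(abs(nb0 - beta0), abs(nb1 - beta1))
    beta0 <- nb0; beta1 <- nb1
    if (delta < tol) break
  }
  eta <- beta0 + outer(beta1, as.numeric(x)) + offs
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w <- mu / (1 + mu * alpha)
  b <- rowSums(w[, i1, drop = FALSE])
  a <- rowSums(w)
  se1 <- sqrt(1 / pmax(b, 1e-300) + 1 / pmax(a - b, 1e-300))
  list(beta0 = beta0, beta1 = beta1, se1 = se1, mu = mu)
}

# Cox-Reid adjusted NB profile log-likelihood in alpha for one gene,
# with the mean held at the current fit (the standard profile approximation).
nb_cr_loglik <- function(alpha, yg, mug, x = NULL) {
  kk <- 1 / alpha
  ll <- sum(lgamma(yg + kk) - lgamma(kk) - lgamma(yg + 1) +
            kk * log(kk / (kk + mug)) + yg * log(mug / (kk + mug) + 1e-300))
  w <- mug / (1 + mug * alpha)
  cr <- if (is.null(x)) {
    -0.5 * log(sum(w))
  } else {
    b <- sum(w[x == 1]); a <- sum(w)
    -0.5 * (log(b) + log(a - b))
  }
  ll + cr
}

# Per-gene ML dispersion (Cox-Reid adjusted), optimized in log space.
estimate_dispersion_genewise <- function(y, mu, x = NULL,
                                         min_disp = 1e-8, max_disp = 30) {
  G <- nrow(y)
  out <- rep(NA_real_, G)
  lo <- log(min_disp); hi <- log(max_disp)
  for (g in seq_len(G)) {
    yg <- y[g, ]; mug <- mu[g, ]
    if (all(yg == 0)) next
    opt <- stats::optimize(function(la) nb_cr_loglik(exp(la), yg, mug, x),
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    out[g] <- exp(opt$maximum)
  }
  out
}

# Parametric dispersion-mean trend alpha(mu) = a0 + a1/mu, fitted by an
# iteratively outlier-trimmed Gamma GLM. Returns c(a0, a1) or NULL when the
# fit is unusable (degenerate data, non-positive asymptotic dispersion).
fit_dispersion_trend <- function(means, disps) {
  keep <- is.finite(means) & is.finite(disps) & means > 0 & disps >= 1e-7
  if (sum(keep) < 10L) return(NULL)
  use <- keep
  coefs <- c(0.1, 1)
  for (it in 1:10) {
    fit <- tryCatch(
      suppressWarnings(stats::glm(disps[use] ~ I(1 / means[use]),
                                  family = stats::Gamma(link = "identity"),
                                  start = coefs)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged && it == 1L) return(NULL)
    if (is.null(fit)) break
    newc <- unname(stats::coef(fit))
    if (any(!is.finite(newc))) return(NULL)
    pred <- newc[1] + newc[2] / means
    ratio <- disps / pmax(pred, 1e-12)
    use <- keep & ratio < 15 & ratio > 1e-4
    done <- all(abs(newc - coefs) < 1e-4 * pmax(abs(coefs), 1e-4))
    coefs <- newc
    if (done) break
  }
  if (coefs[1] <= 0) return(NULL)
  if (coefs[2] < 0) coefs[2] <- 0
  coefs
}

# MAP dispersion: posterior mode under a log-normal prior centred on the
# trend, with outlier genes (far above the trend) kept at their gene-wise
# estimate rather than shrunk.
estimate_dispersion_map <- function(y, mu, x, disp_gw, trend_coefs, base_mean,
                                    n_params = 2L, min_disp = 1e-8,
                                    max_disp = 30) {
  n <- ncol(y)
  log_tr <- log(trend_coefs[1] + trend_coefs[2] / pmax(base_mean, 1e-8))
  slr <- log(disp_gw) - log_tr
  var_log <- (stats::mad(slr, na.rm = TRUE))^2
  prior_var <- max(var_log - trigamma((n - n_params) / 2), 0.25)
  out <- disp_gw
  lo <- log(min_disp); hi <- log(max_disp)
  outlier <- !is.na(slr) & slr > 2 * sqrt(max(var_log, 0.25))
  for (g in seq_len(nrow(y))) {
    if (is.na(disp_gw[g]) || outlier[g]) next
    yg <- y[g, ]; mug <- mu[g, ]; m <- log_tr[g]
    post <- function(la) nb_cr_loglik(exp(la), yg, mug, x) -
      (la - m)^2 / (2 * prior_var)
    opt <- stats::optimize(post, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    out[g] <- exp(opt$maximum)
  }
  attr(out, "prior_var") <- prior_var
  attr(out, "outlier") <- outlier
  out
}

#' Negative-binomial Wald test of differential expression
#'
#' Fits, per gene, a negative-binomial GLM with log link, design
#' `~ 1 + group`, and log size-factor offsets; gene-wise dispersions are
#' estimated by Cox-Reid adjusted maximum likelihood, moderated towards a
#' parametric mean-dispersion trend `alpha(mu) = a0 + a1/mu` via a
#' log-normal prior (posterior mode), and the group coefficient is tested
#' by a Wald z statistic with two-sided normal p-values and BH adjustment.
#'
#' @param counts matrix or [count_matrix()] of raw counts.
#' @param groupA,groupB disjoint character vectors of sample names (or
#'   integer column indices); the reported fold change is B vs A.
#' @param dispersion `"moderated"` (trend-shrunken, the default),
#'   `"gene-wise"` (no shrinkage) or `"fixed"` (use `fixed_alpha`).
#' @param fixed_alpha single dispersion used when `dispersion = "fixed"`.
#' @param sf optional precomputed size factors (named by sample).
#' @return data.frame of class `de_result`: `gene`, `base_mean`,
#'   `log2fc` (B vs A), `lfc_se`, `stat` (Wald z), `pvalue`, `padj`,
#'   `dispersion`. All-zero genes carry `NA` statistics and are excluded
#'   from the BH family. The fitted trend is attached as attribute
#'   `"trend"` (`c(a0, a1)` or `NULL`).
#' @export
nb_wald_test <- function(counts, groupA, groupB,
                         dispersion = c("moderated", "gene-wise", "fixed"),
                         fixed_alpha = NULL, sf = NULL) {
  dispersion <- match.arg(dispersion)
  y_all <- .counts_of(counts)
  if (is.numeric(groupA)) groupA <- colnames(y_all)[groupA]
  if (is.numeric(groupB)) groupB <- colnames(y_all)[groupB]
  if (length(intersect(groupA, groupB)) > 0L) stop("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 samples to estimate dispersion")
  miss <- setdiff(c(groupA, groupB), colnames(y_all))
  if (length(miss) > 0L) stop("unknown samples: ", paste(miss, collapse = ", "))
  y <- y_all[, c(groupA, groupB), drop = FALSE]
  x <- rep(c(0, 1), c(length(groupA), length(groupB)))
  if (is.null(sf)) sf <- size_factors(y) else sf <- sf[colnames(y)]
  logsf <- log(sf)
  nz <- rowSums(y) > 0
  yz <- y[nz, , drop = FALSE]
  base_mean <- rowMeans(sweep(yz, 2L, sf, "/"))

  # moment initialisation of dispersion for the first mean fit
  knorm <- sweep(yz, 2L, sf, "/")
  vhat <- apply(knorm, 1L, stats::var)
  alpha0 <- pmin(pmax((vhat - base_mean) / base_mean^2, 1e-8), 10)

  fit <- nb_irls(yz, x, logsf, alpha0)
  trend <- NULL
  if (dispersion == "fixed") {
    if (is.null(fixed_alpha)) stop("fixed_alpha required for dispersion='fixed'")
    alpha <- rep(fixed_alpha, nrow(yz))
  } else {
    alpha_gw <- estimate_dispersion_genewise(yz, fit$mu, x)
    fit <- nb_irls(yz, x, logsf, alpha_gw)
    alpha_gw <- estimate_dispersion_genewise(yz, fit$mu, x)
    alpha <- alpha_gw
    if (dispersion == "moderated") {
      trend <- fit_dispersion_trend(base_mean, alpha_gw)
      if (is.null(trend)) {
        log_note("parametric dispersion trend fit failed; ",
                 "using a constant prior centred on the median dispersion")
        med <- stats::median(alpha_gw, na.rm = TRUE)
        trend <- c(med, 0)
      }
      alpha <- estimate_dispersion_map(yz, fit$mu, x, alpha_gw, trend, base_mean)
    }
  }
  fit <- nb_irls(yz, x, logsf, alpha)
  stat <- fit$beta1 / fit$se1
  pval <- 2 * stats::pnorm(-abs(stat))

  res <- data.frame(
    gene = rownames(y), base_mean = NA_real_, log2fc = NA_real_,
    lfc_se = NA_real_, stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
    dispersion = NA_real_, stringsAsFactors = FALSE)
  idx <- which(nz)
  res$base_mean[idx] <- base_mean
  res$log2fc[idx] <- fit$beta1 / log(2)
  res$lfc_se[idx] <- fit$se1 / log(2)
  res$stat[idx] <- stat
  res$pvalue[idx] <- pval
  res$dispersion[idx] <- as.numeric(alpha)
  res$padj <- bh_adjust(res$pvalue)
  if (sum(!nz) > 0L) log_note(sum(!nz), " all-zero gene(s) excluded from testing")
  attr(res, "trend") <- trend
  attr(res, "size_factors") <- sf
  class(res) <- c("de_result", "data.frame")
  res
}

#' Normality-checked two-sample t-test pipeline
#'
#' For continuous expression matrices (microarray or already-normalized
#' data): per gene, a Shapiro-Wilk normality p-value is recorded as a QC
#' field on the within-group-centred residuals, followed by a two-sided
#' Welch t-test of group B vs group A, with BH adjustment across testable
#' genes.
#'
#' @param expr numeric matrix genes x samples.
#' @param groupA,groupB sample name vectors (>= 3 samples each).
#' @return data.frame of class `de_result`: `gene`, `effect` (mean B -
#'   mean A; equals a log2 fold change when `expr` is log2 scale), `stat`,
#'   `pvalue`, `padj`, `sw_pvalue`. Genes with zero variance in both
#'   groups get `NA` and are excluded from BH.
#' @export
ttest_pipeline <- function(expr, groupA, groupB) {
  expr <- as.matrix(expr)
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs >= 3 samples")
  if (length(intersect(groupA, groupB)) > 0L) stop("groups must be disjoint")
  xa <- expr[, groupA, drop = FALSE]
  xb <- expr[, groupB, drop = FALSE]
  G <- nrow(expr)
  stat <- pval <- swp <- rep(NA_real_, G)
  eff <- rowMeans(xb) - rowMeans(xa)
  for (g in seq_len(G)) {
    a <- xa[g, ]; b <- xb[g, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) next
    tt <- tryCatch(stats::t.test(b, a, var.equal = FALSE), error = function(e) NULL)
    if (is.null(tt)) next
    stat[g] <- unname(tt$statistic)
    pval[g] <- tt$p.value
    res <- c(a - mean(a), b - mean(b))
    if (length(res) >= 3L && length(res) <= 5000L && stats::var(res) > 0)
      swp[g] <- tryCatch(stats::shapiro.test(res)$p.value,
                         error = function(e) NA_real_)
  }
  out <- data.frame(gene = rownames(expr) %||% as.character(seq_len(G)),
                    effect = eff, stat = stat, pvalue = pval,
                    padj = bh_adjust(pval), sw_pvalue = swp,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}
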