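## Spearman correlation analyses with BH adjustment.

# Spearman rho via average-rank Pearson with the large-sample t
# approximation for the p-value. Constant vectors yield NA.
spearman_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, pvalue = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, pvalue = 0, n = n))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, pvalue = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

#' Spearman correlations with BH adjustment
#'
#' @param pairs list of lists, each with elements `x`, `y` (numeric
#'   vectors of equal length) and `label`.
#' @return data.frame: `label`, `n`, `rho`, `pvalue`, `padj`. Pairs with a
#'   constant vector get `NA` and are excluded from the BH family.
#' @export
spearman_bh <- function(pairs) {
  rows <- lapply(pairs, function(p) {
    sc <- spearman_cor(p$x, p$y)
    data.frame(label = p$label, n = sc$n, rho = sc$rho, pvalue = sc$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Correlate pathway mean expression with a per-sample feature
#'
#' For each pathway, the Spearman correlation between the per-sample mean
#' expression of the pathway's measured genes and a per-sample feature
#' (metabolite abundance, growth rate, ...), BH-adjusted across pathways.
#'
#' @param v numeric matrix genes x samples (VST or any expression scale).
#' @param sig a [metabolic_signature()].
#' @param feature numeric vector named by sample (or aligned with the
#'   columns of `v`).
#' @return data.frame: `pathway`, `n_genes`, `n`, `rho`, `pvalue`, `padj`.
#' @export
pathway_vs_feature <- function(v, sig, feature) {
  v <- as.matrix(v)
  if (!is.null(names(feature))) {
    miss <- setdiff(colnames(v), names(feature))
    if (length(miss) > 0L)
      stop("feature missing for sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
    feature <- feature[colnames(v)]
  }
  pm <- pathway_score_matrix(v, sig)  # samples x pathways
  rows <- lapply(colnames(pm), function(p) {
    sc <- spearman_cor(pm[, p], feature)
    data.frame(pathway = p,
               n_genes = length(intersect(sig$pathways[[p]], rownames(v))),
               n = sc$n, rho = sc$rho, pvalue = sc$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Correlation between OXPHOS and EMT expression in survival groups
#'
#' Per cohort: restrict to the high- and low-survival patients, compute
#' for each patient the median expression of the OXPHOS genes and of the
#' EMT genes, and correlate the two across the cohort's patients
#' (Spearman); BH adjustment across cohorts. The group labels only select
#' patients — the correlation is over unlabelled points, so swapping the
#' labels leaves it unchanged.
#'
#' @param expr_by_cohort named list of expression matrices (genes x
#'   samples), one per cohort.
#' @param oxphos_set,emt_set character vectors of gene identifiers (the
#'   EMT set is typically the hallmark epithelial-mesenchymal-transition
#'   set M5930, supplied via GMT).
#' @param groups_by_cohort named list of `survival_groups` (same cohort
#'   names).
#' @return data.frame: `cohort`, `n_samples`, `rho`, `pvalue`, `padj`.
#' @export
oxphos_vs_emt <- function(expr_by_cohort, oxphos_set, emt_set, groups_by_cohort) {
  if (length(oxphos_set) == 0L || length(emt_set) == 0L)
    stop("both gene sets must be non-empty")
  cohorts <- intersect(names(expr_by_cohort), names(groups_by_cohort))
  if (length(cohorts) == 0L) stop("no cohort shared between expression and groups")
  rows <- lapply(cohorts, function(ch) {
    v <- as.matrix(expr_by_cohort[[ch]])
    gr <- groups_by_cohort[[ch]]
    pts <- intersect(c(gr$high, gr$low), colnames(v))
    ox <- intersect(oxphos_set, rownames(v))
    em <- intersect(emt_set, rownames(v))
    if (length(ox) == 0L || length(em) == 0L)
      stop("cohort ", ch, ": gene set absent from the expression matrix")
    if (length(pts) < 3L) {
      log_note("cohort ", ch, " skipped: fewer than 3 stratified patients")
      return(NULL)
    }
    ox_med <- apply(v[ox, pts, drop = FALSE], 2L, stats::median)
    em_med <- apply(v[em, pts, drop = FALSE], 2L, stats::median)
    sc <- spearman_cor(ox_med, em_med)
    data.frame(cohort = ch, n_samples = length(pts), rho = sc$rho,
               pvalue = sc$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cohort with enough stratified patients")
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}
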