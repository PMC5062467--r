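## Tissue-specific metabolic rewiring: variance-stabilized expression,
## per-tissue gene means, fold change of each tissue against the average
## tissue, pathway-level scores, normal-cancer score correlations,
## cross-tissue diversity, and the rewiring classification.

# Intercept-only NB IRLS (log link, offsets): fits the per-gene mean used
# to profile dispersion for the variance-stabilizing transform.
nb_irls_intercept <- function(y, logsf, alpha, maxit = 25L, tol = 1e-10) {
  G <- nrow(y); n <- ncol(y)
  sf <- exp(logsf)
  beta0 <- log(pmax(rowMeans(sweep(y, 2L, sf, "/")), 1e-8))
  offs <- matrix(logsf, G, n, byrow = TRUE)
  for (it in seq_len(maxit)) {
    mu <- pmin(pmax(exp(beta0 + offs), 1e-10), 1e12)
    w <- mu / (1 + mu * alpha)
    z <- beta0 + (y - mu) / mu
    nb <- rowSums(w * z) / pmax(rowSums(w), 1e-300)
    nb <- pmin(pmax(nb, -50), 50)
    if (max(abs(nb - beta0)) < tol) { beta0 <- nb; break }
    beta0 <- nb
  }
  list(beta0 = beta0, mu = pmin(pmax(exp(beta0 + offs), 1e-10), 1e12))
}

#' Variance-stabilizing transformation of raw counts
#'
#' Size-factor-normalizes the counts, estimates gene-wise dispersions under
#' an intercept-only NB model, fits the parametric mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu`, and applies the closed-form integral transform
#' of the NB variance function
#' `v(q) = q*(1 + a1) + a0*q^2`, i.e.
#' `f(q) = log2((1 + a1 + 2*a0*q + 2*sqrt(a0*q*(1 + a1 + a0*q)))/(4*a0))`,
#' which is monotone in the counts and approximately log2 for large counts.
#' If the trend fit fails the transform falls back to `log2(normalized + 1)`
#' with provenance tag `"shifted-log"` and a prominent warning.
#'
#' @param counts matrix or [count_matrix()] of raw counts.
#' @param sf optional precomputed size factors.
#' @param trend optional `c(a0, a1)` to apply a pre-fitted trend instead of
#'   estimating one (the transform is then a pure function of the
#'   normalized counts).
#' @return numeric matrix genes x samples on the variance-stabilized scale,
#'   with attributes `"trend"` (`c(a0, a1)` or `NULL`), `"provenance"`
#'   (`"vst-parametric"` or `"shifted-log"`) and `"size_factors"`.
#' @export
vst <- function(counts, sf = NULL, trend = NULL) {
  y <- .counts_of(counts)
  if (is.null(sf)) sf <- size_factors(y)
  k <- sweep(y, 2L, sf, "/")
  if (is.null(trend)) {
    nz <- rowSums(y) > 0
    yz <- y[nz, , drop = FALSE]
    base_mean <- rowMeans(k[nz, , drop = FALSE])
    vhat <- apply(k[nz, , drop = FALSE], 1L, stats::var)
    alpha0 <- pmin(pmax((vhat - base_mean) / base_mean^2, 1e-8), 10)
    fit <- nb_irls_intercept(yz, log(sf), alpha0)
    alpha_gw <- estimate_dispersion_genewise(yz, fit$mu)
    trend <- fit_dispersion_trend(base_mean, alpha_gw)
  } else {
    stopifnot(length(trend) == 2L, trend[1] > 0, trend[2] >= 0)
  }
  if (is.null(trend)) {
    warning("dispersion trend fit failed; falling back to log2(normalized + 1) ",
            "(provenance 'shifted-log')")
    out <- log2(k + 1)
    attr(out, "trend") <- NULL
    attr(out, "provenance") <- "shifted-log"
    attr(out, "size_factors") <- sf
    return(out)
  }
  a0 <- trend[1]; a1 <- trend[2]
  out <- log2((1 + a1 + 2 * a0 * k +
                 2 * sqrt(a0 * k * (1 + a1 + a0 * k))) / (4 * a0))
  dimnames(out) <- dimnames(k)
  attr(out, "trend") <- trend
  attr(out, "provenance") <- "vst-parametric"
  attr(out, "size_factors") <- sf
  out
}

#' Per-tissue mean expression of each gene
#'
#' @param v numeric matrix genes x samples (typically a [vst()] matrix).
#' @param grouping named character vector sample -> tissue, or a vector
#'   aligned with the columns of `v`.
#' @return numeric matrix genes x tissues of arithmetic means.
#' @export
tissue_means <- function(v, grouping) {
  v <- as.matrix(v)
  if (!is.null(names(grouping))) grouping <- grouping[colnames(v)]
  if (anyNA(grouping)) stop("every sample needs a tissue label")
  tissues <- sort(unique(as.character(grouping)))
  out <- vapply(tissues, function(t)
    rowMeans(v[, grouping == t, drop = FALSE]), numeric(nrow(v)))
  dimnames(out) <- list(rownames(v), tissues)
  out
}

#' Fold change of each tissue against the average tissue
#'
#' For each gene, the ratio between its mean expression in a tissue and the
#' unweighted average of its per-tissue means, so the mean of the result
#' across tissues is exactly 1 for every usable gene. Genes whose
#' cross-tissue average is zero are set to `NA` and logged.
#'
#' @param m genes x tissues matrix from [tissue_means()].
#' @return genes x tissues matrix of fold changes `r`.
#' @export
fold_vs_average <- function(m) {
  avg <- rowMeans(m)
  bad <- avg == 0 | !is.finite(avg)
  if (any(bad))
    log_note(sum(bad), " gene(s) with zero cross-tissue average flagged NA")
  r <- m / avg
  r[bad, ] <- NA_real_
  r
}

#' Pathway-level tissue scores
#'
#' `S[p, t]` is the mean, over the pathway's measurable genes, of the
#' per-gene fold change against the average tissue. Pathways with no
#' measurable gene are dropped with a log entry.
#'
#' @param r genes x tissues fold-change matrix from [fold_vs_average()].
#' @param sig a [metabolic_signature()].
#' @return pathways x tissues numeric matrix.
#' @export
pathway_scores <- function(r, sig) {
  stopifnot(inherits(sig, "metabolic_signature"))
  usable <- rownames(r)[stats::complete.cases(r)]
  rows <- lapply(sig$pathways, function(gs) intersect(gs, usable))
  keep <- lengths(rows) > 0L
  if (any(!keep))
    log_note(sum(!keep), " pathway(s) without measurable genes dropped from scores")
  out <- t(vapply(rows[keep], function(gs)
    colMeans(r[gs, , drop = FALSE]), numeric(ncol(r))))
  dimnames(out) <- list(names(rows)[keep], colnames(r))
  out
}

#' Correlation of pathway scores between normal and cancer tissues
#'
#' For each matched (normal tissue, cancer type) pair, the Spearman
#' correlation across shared pathways between the normal and cancer score
#' vectors, BH-adjusted across pairs. Pairs sharing fewer than
#' `min_pathways` pathways are skipped.
#'
#' @param N,C pathways x tissues score matrices ([pathway_scores()]) for
#'   the normal and cancer compartments.
#' @param pairing data.frame with columns `normal` and `cancer` naming
#'   matched columns of `N` and `C`.
#' @param min_pathways minimum shared pathways per pair (default 5).
#' @return data.frame: `normal`, `cancer`, `n_pathways`, `rho`, `pvalue`,
#'   `padj`.
#' @export
normal_cancer_correlation <- function(N, C, pairing, min_pathways = 5L) {
  stopifnot(all(c("normal", "cancer") %in% names(pairing)))
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    nt <- pairing$normal[i]; ct <- pairing$cancer[i]
    if (!(nt %in% colnames(N)) || !(ct %in% colnames(C)))
      stop("unmatched tissue pairing: ", nt, " / ", ct)
    shared <- intersect(rownames(N), rownames(C))
    if (length(shared) < min_pathways) {
      log_note("pair ", nt, "/", ct, " skipped: only ", length(shared),
               " shared pathways")
      return(NULL)
    }
    sc <- spearman_cor(N[shared, nt], C[shared, ct])
    data.frame(normal = nt, cancer = ct, n_pathways = length(shared),
               rho = sc$rho, pvalue = sc$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable tissue pair")
  out$padj <- bh_adjust(out$pvalue)
  rownames(out) <- NULL
  out
}

#' Cross-pathway diversity of tissue scores
#'
#' Sample standard deviation (n - 1 denominator) of the pathway score
#' distribution of each tissue; a flat score vector means the tissue's
#' metabolism sits at the cross-tissue average everywhere.
#'
#' @param scores pathways x tissues matrix from [pathway_scores()].
#' @return named numeric vector of per-tissue standard deviations.
#' @export
diversity <- function(scores) {
  if (nrow(scores) < 2L) stop("need >= 2 pathways to compute a diversity SD")
  apply(scores, 2L, stats::sd)
}

#' Classify tissue-specific metabolic rewiring
#'
#' Crosses, per (tissue, pathway), the enrichment direction of the pathway
#' in the normal tissue (vs the average of normal tissues) with its
#' direction in the matched cancer (vs that normal tissue): a pathway up in
#' normal but down in cancer is `"lost"`, down in normal but up in cancer
#' is `"gained"`, significant in normal and otherwise unchanged is
#' `"maintained"`, and not significant in normal is `"unchanged"`. Also
#' summarises, per pathway, the fraction of cancers where it moves up or
#' down regardless of normal-tissue status (the tissue-independent view).
#'
#' @param normal_enrich data.frame with columns `tissue`, `pathway`,
#'   `direction` from per-tissue GSEA of normal tissue vs average.
#' @param cancer_enrich same columns, from GSEA of each cancer vs its
#'   matched normal tissue (same `tissue` labels).
#' @param frequency_cut fraction of cancers above which a pathway counts
#'   as commonly rewired (default 0.2).
#' @return list of class `rewiring_classification`: `table` (tissue,
#'   pathway, normal/cancer direction, label), `fractions` (per
#'   normal-status stratum, label fractions summing to 1), and
#'   `tissue_independent` (per pathway `frac_up`, `frac_down`,
#'   `common_up`/`common_down` flags).
#' @export
classify_rewiring <- function(normal_enrich, cancer_enrich, frequency_cut = 0.2) {
  need <- c("tissue", "pathway", "direction")
  stopifnot(all(need %in% names(normal_enrich)), all(need %in% names(cancer_enrich)))
  tn <- unique(normal_enrich$tissue); tc <- unique(cancer_enrich$tissue)
  if (!setequal(tn, tc))
    stop("unmatched tissue pairing between normal and cancer enrichment: ",
         paste(union(setdiff(tn, tc), setdiff(tc, tn)), collapse = ", "))
  grid <- expand.grid(tissue = tn,
                      pathway = unique(c(normal_enrich$pathway, cancer_enrich$pathway)),
                      stringsAsFactors = FALSE)
  key <- function(df) paste(df$tissue, df$pathway, sep = "\r")
  ndir <- stats::setNames(normal_enrich$direction, key(normal_enrich))
  cdir <- stats::setNames(cancer_enrich$direction, key(cancer_enrich))
  grid$normal_direction <- unname(ndir[key(grid)])
  grid$cancer_direction <- unname(cdir[key(grid)])
  grid$normal_direction[is.na(grid$normal_direction)] <- "ns"
  grid$cancer_direction[is.na(grid$cancer_direction)] <- "ns"
  grid$label <- with(grid, ifelse(
    normal_direction == "up" & cancer_direction == "down", "lost",
    ifelse(normal_direction == "down" & cancer_direction == "up", "gained",
    ifelse(normal_direction %in% c("up", "down"), "maintained", "unchanged"))))
  fr <- do.call(rbind, lapply(c("up", "down"), function(st) {
    sub <- grid[grid$normal_direction == st, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    tab <- table(factor(sub$label, levels = c("maintained", "lost", "gained")))
    data.frame(normal_status = st, label = names(tab),
               n = as.integer(tab), fraction = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  n_canc <- length(tn)
  ti <- do.call(rbind, lapply(split(grid, grid$pathway), function(sub) {
    data.frame(pathway = sub$pathway[1],
               frac_up = mean(sub$cancer_direction == "up"),
               frac_down = mean(sub$cancer_direction == "down"),
               stringsAsFactors = FALSE)
  }))
  ti$common_up <- ti$frac_up > frequency_cut
  ti$common_down <- ti$frac_down > frequency_cut
  rownames(ti) <- NULL
  structure(list(table = grid, fractions = fr, tissue_independent = ti,
                 n_cancers = n_canc),
            class = "rewiring_classification")
}
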