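## Tissue-independent clustering of cancer samples on pathway-mean
## expression: PAM (k-medoids) with gap-statistic model selection and
## hypergeometric tissue enrichment of the resulting clusters.

#' Per-sample pathway score matrix
#'
#' Entry (sample, pathway) is the mean variance-stabilized expression of
#' the pathway's measured genes in that sample. Pathways with no measured
#' gene are dropped with a log entry.
#'
#' @param v numeric matrix genes x samples (typically [vst()] output on
#'   the pooled cancer matrix).
#' @param sig a [metabolic_signature()].
#' @return numeric matrix samples x pathways.
#' @export
pathway_score_matrix <- function(v, sig) {
  stopifnot(inherits(sig, "metabolic_signature"))
  v <- as.matrix(v)
  rows <- lapply(sig$pathways, function(gs) intersect(gs, rownames(v)))
  keep <- lengths(rows) > 0L
  if (any(!keep))
    log_note(sum(!keep), " pathway(s) without measured genes dropped")
  out <- vapply(rows[keep], function(gs)
    colMeans(v[gs, , drop = FALSE]), numeric(ncol(v)))
  dimnames(out) <- list(colnames(v), names(rows)[keep])
  out
}

#' k-medoids (PAM) clustering of samples
#'
#' Partitioning around medoids on Euclidean distances (deterministic BUILD
#' initialization followed by SWAP), via the `cluster` package. The trivial
#' `k = n` case (every sample its own medoid, zero cost) is handled
#' directly.
#'
#' @param x numeric matrix samples x features (e.g.
#'   [pathway_score_matrix()]).
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param scale z-score the columns first (default `FALSE`).
#' @return list of class `pam_result`: `k`, `assignment` (named integer),
#'   `medoids` (row indices), `cost` (total distance of samples to their
#'   medoids).
#' @export
pam_cluster <- function(x, k, scale = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1L || k > n) stop("k must be between 1 and the number of samples")
  if (scale) x <- base::scale(x)
  if (k == n) {
    assignment <- stats::setNames(seq_len(n), rownames(x))
    return(structure(list(k = k, assignment = assignment,
                          medoids = seq_len(n), cost = 0),
                     class = "pam_result"))
  }
  fit <- cluster::pam(x, k, metric = "euclidean", keep.diss = FALSE,
                      keep.data = FALSE)
  assignment <- fit$clustering
  names(assignment) <- rownames(x)
  d <- sqrt(rowSums((x - x[fit$id.med[assignment], , drop = FALSE])^2))
  structure(list(k = k, assignment = assignment, medoids = unname(fit$id.med),
                 cost = sum(d)),
            class = "pam_result")
}

#' Gap-statistic selection of the number of clusters
#'
#' Tibshirani gap statistic for PAM: `B` reference datasets uniform over
#' each feature's observed range, `Gap(k) = mean_B log(W*_k) - log(W_k)`,
#' and the 1-SE rule (smallest `k` with `Gap(k) >= Gap(k+1) - SE(k+1)`).
#' Zero-range features are dropped from reference generation with a log
#' entry.
#'
#' @param x numeric matrix samples x features.
#' @param k_max maximum number of clusters to consider (`< nrow(x)`).
#' @param B number of reference datasets (default 50, >= 10).
#' @param seed integer seed for the reference draws.
#' @param scale z-score columns first (default `FALSE`).
#' @return list of class `gap_result`: chosen `k` and `curve`
#'   (data.frame `k`, `logW`, `logWstar`, `gap`, `se`).
#' @export
gap_statistic <- function(x, k_max, B = 50L, seed = 1L, scale = FALSE) {
  x <- as.matrix(x)
  if (k_max >= nrow(x)) stop("k_max must be < number of samples")
  if (B < 10L) stop("B must be >= 10")
  if (scale) x <- base::scale(x)
  rng <- apply(x, 2L, function(col) diff(range(col)))
  if (any(rng == 0)) {
    log_note(sum(rng == 0), " zero-range feature(s) dropped from the gap reference")
    x <- x[, rng > 0, drop = FALSE]
  }
  set.seed(seed)
  gg <- cluster::clusGap(x, FUNcluster = function(x, k) {
    if (k == 1L) list(cluster = rep(1L, nrow(x)))
    else list(cluster = cluster::pam(x, k, metric = "euclidean",
                                     cluster.only = TRUE))
  }, K.max = k_max, B = B, spaceH0 = "original", verbose = FALSE)
  tab <- gg$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  structure(list(k = k,
                 curve = data.frame(k = seq_len(k_max), logW = tab[, "logW"],
                                    logWstar = tab[, "E.logW"],
                                    gap = tab[, "gap"], se = tab[, "SE.sim"])),
            class = "gap_result")
}

#' Hypergeometric tissue enrichment of clusters
#'
#' For each (cluster, cancer type) pair, the upper-tail hypergeometric
#' probability of observing at least the seen number of type members in
#' the cluster, given the cluster size, the type total and the population;
#' BH-adjusted across all pairs. Also returns the proportion of each
#' type's samples falling into each cluster.
#'
#' @param assign named integer vector sample -> cluster.
#' @param labels named character vector sample -> cancer type.
#' @param q_threshold FDR threshold for the `enriched` flag (default 0.05).
#' @return list: `table` (cluster, type, count, cluster_size, type_total,
#'   pvalue, padj, enriched) and `proportions` (type x cluster matrix).
#' @export
tissue_enrichment <- function(assign, labels, q_threshold = 0.05) {
  if (!is.null(names(assign)) && !is.null(names(labels)))
    labels <- labels[names(assign)]
  if (length(assign) != length(labels)) stop("assign and labels must align")
  N <- length(assign)
  tab <- table(type = as.character(labels), cluster = as.character(assign))
  type_tot <- rowSums(tab)
  clus_tot <- colSums(tab)
  grid <- expand.grid(cluster = colnames(tab), type = rownames(tab),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(cl, ty) tab[ty, cl], grid$cluster, grid$type)
  grid$cluster_size <- clus_tot[grid$cluster]
  grid$type_total <- type_tot[grid$type]
  grid$pvalue <- stats::phyper(grid$count - 1, grid$type_total,
                               N - grid$type_total, grid$cluster_size,
                               lower.tail = FALSE)
  grid$padj <- bh_adjust(grid$pvalue)
  grid$enriched <- grid$padj < q_threshold
  rownames(grid) <- NULL
  prop <- sweep(tab, 1L, type_tot, "/")
  list(table = grid, proportions = unclass(prop))
}
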