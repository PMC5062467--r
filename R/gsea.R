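## Directional permutation GSEA on signed gene-level statistics.
##
## The enrichment score is the classic weighted Kolmogorov-Smirnov-like
## running-sum statistic: walking down the ranking, hits increment by
## |s|^weight (normalized over the set) and misses decrement by 1/(N - Nh);
## ES is the maximal signed deviation from zero. The null is built by
## permuting gene labels of the statistic vector; all pathways share the
## same permutations so that p-values are comparable across sets.

# Fast ES given the decreasing sorted weight vector absw = |s|^weight and
# the sorted hit positions. The running sum is piecewise linear between
# hits, so its extremes occur at hit positions (maximum candidates) and
# immediately before hit positions (minimum candidates).
calc_es <- function(absw, pos, N) {
  m <- length(pos)
  w <- absw[pos]
  W <- sum(w)
  if (W <= 0) w <- rep(1 / m, m) else w <- w / W
  hit <- cumsum(w)
  miss <- (pos - seq_len(m)) / (N - m)
  top <- max(hit - miss)
  bottom <- min(c(0, hit[-m]) - miss)
  if (top > -bottom) top else bottom
}

#' Running enrichment score of a gene set
#'
#' @param stats named numeric vector of signed gene-level statistics (the
#'   universe); ties are broken by gene identifier so the ranking is
#'   deterministic.
#' @param geneset character vector of gene identifiers.
#' @param weight exponent on `|stat|` for hit increments; `1` is classic
#'   weighted GSEA, `0` the unweighted Kolmogorov-Smirnov form.
#' @param min_size minimum size of `geneset`'s intersection with the
#'   universe.
#' @return single enrichment score in `[-1, 1]`.
#' @export
running_es <- function(stats, geneset, weight = 1, min_size = 5) {
  r <- rank_stats(stats)
  idx <- which(r$genes %in% geneset)
  if (length(idx) < min_size)
    stop("gene set has ", length(idx), " genes in the universe (< ", min_size, ")")
  if (length(idx) == length(r$genes))
    stop("gene set equals the whole universe; ES undefined")
  calc_es(abs(r$stats)^weight, sort.int(r$rankpos[idx]), length(r$genes))
}

# Canonical deterministic ranking: genes in lexicographic order, then a
# stable decreasing sort of the statistic (ties therefore resolve by gene
# identifier). rankpos[i] = position of canonical gene i in the ranking.
rank_stats <- function(stats) {
  if (is.null(names(stats))) stop("stats must be named by gene")
  stats <- stats[!is.na(stats)]
  ord_canon <- order(names(stats))
  g <- names(stats)[ord_canon]
  s <- unname(stats[ord_canon])
  ord <- order(s, decreasing = TRUE)    # stable: ties keep gene-id order
  rankpos <- integer(length(s))
  rankpos[ord] <- seq_along(s)
  list(genes = g, stats_canon = s, stats = s[ord], rankpos = rankpos)
}

#' Directional permutation p-values for all signature pathways
#'
#' Computes each pathway's enrichment score on the observed ranking and a
#' shared gene-label permutation null; reports one-sided p-values for
#' enrichment at the top (`p_up`) and bottom (`p_down`) of the ranking with
#' the plus-one permutation estimator, BH-adjusted within each direction.
#'
#' @param stats named numeric vector of signed gene-level statistics.
#' @param sig a [metabolic_signature()] (any GMT-backed collection works,
#'   e.g. MSigDB hallmark sets).
#' @param n_perm number of gene-label permutations (>= 100).
#' @param seed integer seed governing the whole permutation block.
#' @param weight ES weight exponent (default 1).
#' @param min_size,max_size pathway size bounds after intersection with the
#'   universe.
#' @param q_threshold FDR threshold for the `direction` call.
#' @return data.frame of class `enrichment_result`: `pathway`, `size`,
#'   `es`, `p_up`, `p_down`, `q_up`, `q_down`, `direction`
#'   (up/down/ns at `q < q_threshold`).
#' @export
permutation_pvalues <- function(stats, sig, n_perm = 1000L, seed = 1L,
                                weight = 1, min_size = 5L, max_size = 500L,
                                q_threshold = 0.05) {
  stopifnot(inherits(sig, "metabolic_signature"))
  if (n_perm < 100L) stop("n_perm must be >= 100 for a usable permutation tail")
  r <- rank_stats(stats)
  N <- length(r$genes)
  absw <- abs(r$stats)^weight

  idx_list <- lapply(sig$pathways, function(gs) which(r$genes %in% gs))
  sizes <- lengths(idx_list)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (any(!keep))
    log_note(sum(!keep), " pathway(s) skipped (outside size bounds [",
             min_size, ", ", max_size, "] or equal to the universe)")
  idx_list <- idx_list[keep]
  P <- length(idx_list)
  if (P == 0L) stop("no pathway passes the size filter")

  obs <- vapply(idx_list, function(idx)
    calc_es(absw, sort.int(r$rankpos[idx]), N), 0)

  set.seed(seed)
  null_ge <- integer(P)   # per pathway: #{null ES >= observed}
  null_le <- integer(P)
  for (b in seq_len(n_perm)) {
    pi_b <- sample.int(N)
    for (p in seq_len(P)) {
      es_b <- calc_es(absw, sort.int(r$rankpos[pi_b[idx_list[[p]]]]), N)
      if (es_b >= obs[p]) null_ge[p] <- null_ge[p] + 1L
      if (es_b <= obs[p]) null_le[p] <- null_le[p] + 1L
    }
  }
  p_up <- (1 + null_ge) / (n_perm + 1)
  p_down <- (1 + null_le) / (n_perm + 1)
  out <- data.frame(
    pathway = names(idx_list), size = unname(sizes[keep]), es = unname(obs),
    p_up = unname(p_up), p_down = unname(p_down),
    q_up = unname(bh_adjust(p_up)), q_down = unname(bh_adjust(p_down)),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$es > 0 & out$q_up < q_threshold, "up",
                   ifelse(out$es < 0 & out$q_down < q_threshold, "down", "ns"))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Promiscuity-corrected GSEA of a differential-expression result
#'
#' Takes the signed Wald/t statistics of a [nb_wald_test()] or
#' [ttest_pipeline()] result, optionally divides them by gene promiscuity
#' (the number of signature pathways each gene belongs to), and runs
#' directional permutation GSEA against the signature. Genes absent from
#' the signature are excluded from the ranking (the analysis concerns
#' signature genes only); the dropped count is logged.
#'
#' @param de a `de_result` data.frame (needs columns `gene` and `stat`).
#' @param sig a [metabolic_signature()].
#' @param prom_correct apply the promiscuity correction (default `TRUE`).
#' @inheritParams permutation_pvalues
#' @return an `enrichment_result` data.frame, see [permutation_pvalues()].
#' @export
gsea_pipeline <- function(de, sig, prom_correct = TRUE, n_perm = 1000L,
                          seed = 1L, weight = 1, min_size = 5L,
                          max_size = 500L, q_threshold = 0.05) {
  stats <- stats::setNames(de$stat, de$gene)
  stats <- stats[!is.na(stats)]
  in_sig <- names(stats) %in% names(sig$gene_index)
  if (any(!in_sig))
    log_note(sum(!in_sig), " gene(s) not in the signature excluded from GSEA input")
  stats <- stats[in_sig]
  if (length(stats) == 0L) stop("no signature gene with a finite statistic")
  if (prom_correct)
    stats <- correct_statistic(stats, compute_promiscuity(sig))
  permutation_pvalues(stats, sig, n_perm = n_perm, seed = seed, weight = weight,
                      min_size = min_size, max_size = max_size,
                      q_threshold = q_threshold)
}
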