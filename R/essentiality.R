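#' Gene-level shRNA essentiality matrix
#'
#' Wraps a gene x cell-line matrix of gene-level essentiality scores
#' (ATARIS convention: lower = more essential) with the cell-line ->
#' tissue-of-origin map.
#'
#' @param scores numeric matrix, genes in rows, cell lines in columns;
#'   `NA` allowed for unscored entries.
#' @param line_tissue named character vector mapping every column to
#'   exactly one tissue.
#' @param higher_is_essential set `TRUE` for screens where larger scores
#'   mean more essential; scores are then negated internally so the ATARIS
#'   convention holds throughout.
#' @return object of class `essentiality_matrix` with elements `scores`
#'   and `tissue`.
#' @export
essentiality_matrix <- function(scores, line_tissue, higher_is_essential = FALSE) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores need gene rownames and cell-line colnames")
  miss <- setdiff(colnames(scores), names(line_tissue))
  if (length(miss) > 0L)
    stop("cell line(s) without tissue: ", paste(utils::head(miss, 5), collapse = ", "))
  if (higher_is_essential) scores <- -scores
  structure(list(scores = scores,
                 tissue = line_tissue[colnames(scores)]),
            class = "essentiality_matrix")
}

#' Per-gene ANOVA of essentiality across tissues
#'
#' One-way analysis of variance of each gene's essentiality score against
#' the tissue of origin of the cell lines, BH-adjusted across genes; genes
#' with adjusted p below `q_threshold` are flagged as tissue-predicted.
#'
#' @param e an [essentiality_matrix()].
#' @param q_threshold FDR flag threshold (default 0.05).
#' @return data.frame: `gene`, `f_stat`, `pvalue`, `padj`,
#'   `tissue_predicted`. Genes testable in fewer than 2 tissues carry `NA`
#'   and are excluded from the BH family.
#' @export
anova_by_tissue <- function(e, q_threshold = 0.05) {
  stopifnot(inherits(e, "essentiality_matrix"))
  tis <- factor(e$tissue)
  if (sum(table(tis) >= 2L) < 2L)
    stop("need >= 2 tissues with >= 2 cell lines each")
  G <- nrow(e$scores)
  fstat <- pval <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- e$scores[g, ]
    ok <- !is.na(y)
    tg <- droplevels(tis[ok])
    if (nlevels(tg) < 2L || sum(ok) - nlevels(tg) < 1L) next
    ft <- tryCatch(stats::oneway.test(y[ok] ~ tg, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || is.na(ft$p.value)) next
    fstat[g] <- unname(ft$statistic)
    pval[g] <- ft$p.value
  }
  padj <- bh_adjust(pval)
  data.frame(gene = rownames(e$scores), f_stat = fstat, pvalue = pval,
             padj = padj,
             tissue_predicted = !is.na(padj) & padj < q_threshold,
             stringsAsFactors = FALSE)
}

#' Top-fraction essential genes per cell line
#'
#' For each cell line, the `floor(fraction * n_scored)` genes with the
#' lowest scores among its non-`NA` genes; ties at the selection boundary
#' are broken by gene identifier so the selection is deterministic.
#'
#' @param e an [essentiality_matrix()].
#' @param fraction fraction of scored genes to call essential (default
#'   0.05, i.e. the top 5%).
#' @return named list, one character vector of essential genes per cell
#'   line, with attribute `"scored_genes"` (the full scored universe).
#' @export
top_essential <- function(e, fraction = 0.05) {
  stopifnot(inherits(e, "essentiality_matrix"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  genes <- rownames(e$scores)
  sets <- lapply(seq_len(ncol(e$scores)), function(j) {
    y <- e$scores[, j]
    ok <- !is.na(y)
    nsel <- floor(fraction * sum(ok))
    if (nsel == 0L) return(character(0))
    ord <- order(y[ok], genes[ok])
    genes[ok][ord[seq_len(nsel)]]
  })
  names(sets) <- colnames(e$scores)
  attr(sets, "scored_genes") <- genes[rowSums(!is.na(e$scores)) > 0L]
  sets
}

#' Tissue occurrence of essential genes and pathway aggregation
#'
#' Combines per-cell-line essential gene sets into per-tissue sets (union
#' over a tissue's cell lines), counts for each gene the number of tissues
#' where it is essential, and averages that occurrence over each pathway's
#' genes present in the scored universe.
#'
#' @param sets per-cell-line essential gene sets from [top_essential()].
#' @param line_tissue named character vector cell line -> tissue.
#' @param sig a [metabolic_signature()].
#' @param universe scored gene universe; defaults to the
#'   `"scored_genes"` attribute of `sets`.
#' @return list of class `occurrence_table`: `gene_occurrence` (named
#'   integer, 0..n_tissues over the universe), `pathway_occurrence`
#'   (data.frame `pathway`, `n_genes`, `mean_occurrence`), `n_tissues`,
#'   and `tissue_sets`.
#' @export
tissue_occurrence <- function(sets, line_tissue, sig, universe = NULL) {
  stopifnot(inherits(sig, "metabolic_signature"))
  if (is.null(universe)) universe <- attr(sets, "scored_genes")
  if (is.null(universe)) stop("provide the scored gene universe")
  miss <- setdiff(names(sets), names(line_tissue))
  if (length(miss) > 0L) stop("cell line(s) without tissue: ",
                              paste(utils::head(miss, 5), collapse = ", "))
  tissues <- unique(unname(line_tissue[names(sets)]))
  tissue_sets <- lapply(tissues, function(t) {
    unique(unlist(sets[names(sets)[line_tissue[names(sets)] == t]]))
  })
  names(tissue_sets) <- tissues
  occ <- stats::setNames(integer(length(universe)), universe)
  for (ts in tissue_sets) {
    hit <- universe %in% ts
    occ[hit] <- occ[hit] + 1L
  }
  rows <- lapply(names(sig$pathways), function(p) {
    gs <- intersect(sig$pathways[[p]], universe)
    if (length(gs) == 0L) return(NULL)
    data.frame(pathway = p, n_genes = length(gs),
               mean_occurrence = mean(occ[gs]), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L)
    log_note(dropped, " pathway(s) without scored genes dropped from occurrence")
  pw <- do.call(rbind, rows)
  rownames(pw) <- NULL
  structure(list(gene_occurrence = occ, pathway_occurrence = pw,
                 n_tissues = length(tissue_sets), tissue_sets = tissue_sets),
            class = "occurrence_table")
}
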