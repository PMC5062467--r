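## TSV loaders for the external dialects the pipeline consumes. All
## loaders accept local files only.

#' Read a gene x sample count matrix from TSV
#'
#' First column = gene identifier, header = sample identifiers.
#'
#' @param path TSV file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Read a sample annotation table from TSV
#'
#' Columns: `sample`, `tissue`, `condition`, optionally `cohort`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "tissue", "condition")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a TCGA-style clinical TSV
#'
#' Columns: `patient`, `vital_status`, `days_to_death`,
#' `days_to_last_followup`, optionally `cohort`.
#'
#' @param path TSV file path.
#' @inheritParams clinical_table
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path, days_per_year = 365.25) {
  clinical_table(read_tsv(path), days_per_year = days_per_year)
}

#' Read an essentiality score matrix and cell-line map from TSV
#'
#' @param scores_path TSV, first column gene id, remaining columns one per
#'   cell line (real scores, blank/NA allowed).
#' @param map_path two-column TSV `cell_line`, `tissue`.
#' @param higher_is_essential see [essentiality_matrix()].
#' @return an [essentiality_matrix()].
#' @export
read_essentiality <- function(scores_path, map_path, higher_is_essential = FALSE) {
  df <- read_tsv(scores_path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  map <- read_tsv(map_path)
  if (!all(c("cell_line", "tissue") %in% names(map)))
    stop("cell-line map needs columns cell_line, tissue")
  essentiality_matrix(m, stats::setNames(map$tissue, map$cell_line),
                      higher_is_essential = higher_is_essential)
}

#' Write a count matrix (with annotations) to TSV
#'
#' @param cm a [count_matrix()].
#' @param counts_path,meta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  stopifnot(inherits(cm, "count_matrix"))
  write_tsv(data.frame(gene = rownames(cm$counts), cm$counts,
                       check.names = FALSE), counts_path)
  write_tsv(cm$samples, meta_path)
  invisible(c(counts_path, meta_path))
}
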