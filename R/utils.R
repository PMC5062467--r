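#' Benjamini-Hochberg adjustment over the non-missing entries
#'
#' Shared multiple-testing routine used by every module. `NA` p-values are
#' excluded from the family (they correspond to untestable genes/pathways)
#' and returned as `NA`; the family size is the number of finite p-values.
#'
#' @param p numeric vector of raw p-values, may contain `NA`.
#' @return numeric vector of BH-adjusted p-values, same length and names.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  names(out) <- names(p)
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Internal condition-light logger: every dropped gene/pathway/cohort goes
# through here so callers can suppressMessages() in bulk runs.
log_note <- function(...) {
  message("[metrewire] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as TSV without quoting or row names (the one tabular
# dialect all exports share).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
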