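#' Metabolic gene signature
#'
#' A `metabolic_signature` maps pathways to gene sets and, inversely, genes
#' to the pathways they belong to. The inverse index is what drives the
#' promiscuity correction: a gene sitting in several pathways cannot be
#' credited in full to each of them.
#'
#' @param pathways named list of character vectors (pathway -> genes).
#'   Gene identifiers are whitespace-trimmed; duplicates within a pathway
#'   are removed with a warning.
#' @return object of class `metabolic_signature` with elements `pathways`
#'   (named list of unique gene vectors) and `gene_index` (named list,
#'   gene -> pathway names).
#' @export
metabolic_signature <- function(pathways) {
  if (length(pathways) == 0L) stop("signature has no pathways")
  if (is.null(names(pathways)) || any(!nzchar(names(pathways))))
    stop("every pathway needs a name")
  if (anyDuplicated(names(pathways)))
    stop("duplicated pathway names: ",
         paste(unique(names(pathways)[duplicated(names(pathways))]), collapse = ", "))
  pathways <- lapply(pathways, function(g) trimws(as.character(g)))
  ndup <- sum(vapply(pathways, anyDuplicated, 0L) > 0L)
  if (ndup > 0L) {
    warning(ndup, " pathway(s) contained duplicated genes; deduplicated")
    pathways <- lapply(pathways, unique)
  }
  if (any(lengths(pathways) == 0L))
    stop("empty pathway gene list: ",
         paste(names(pathways)[lengths(pathways) == 0L], collapse = ", "))
  genes <- unlist(pathways, use.names = FALSE)
  memb <- rep(names(pathways), lengths(pathways))
  gene_index <- split(memb, genes)
  structure(list(pathways = pathways, gene_index = gene_index),
            class = "metabolic_signature")
}

#' @export
print.metabolic_signature <- function(x, ...) {
  cat("metabolic_signature:", length(x$pathways), "pathways,",
      length(x$gene_index), "genes (",
      sum(lengths(x$gene_index) > 1L), "promiscuous )\n")
  invisible(x)
}

#' @export
length.metabolic_signature <- function(x) length(x$pathways)

#' Read a gene-set signature from a GMT file
#'
#' Broad-dialect GMT: one set per line, `name<TAB>description<TAB>gene...`.
#'
#' @param path path to a GMT file.
#' @return a [metabolic_signature()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", bad[1L], " in ", path,
         ": expected >= 3 tab-separated fields")
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  metabolic_signature(sets)
}

#' Write a signature to GMT
#'
#' @param sig a [metabolic_signature()].
#' @param path output file path.
#' @param descriptions optional named character of per-pathway descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sig, path, descriptions = NULL) {
  stopifnot(inherits(sig, "metabolic_signature"))
  desc <- rep("na", length(sig$pathways))
  names(desc) <- names(sig$pathways)
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  lines <- vapply(names(sig$pathways), function(p) {
    paste(c(p, desc[[p]], sig$pathways[[p]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene promiscuity: number of pathways each gene belongs to
#'
#' @param sig a [metabolic_signature()].
#' @return named integer vector, one entry per signature gene, all >= 1.
#' @export
compute_promiscuity <- function(sig) {
  stopifnot(inherits(sig, "metabolic_signature"))
  prom <- lengths(sig$gene_index)
  storage.mode(prom) <- "integer"
  prom
}

#' Promiscuity correction of gene-level statistics
#'
#' Divides each gene's signed statistic (typically an NB Wald statistic) by
#' the number of pathways the gene belongs to, so genes shared across many
#' pathways contribute proportionally less to each. Genes absent from the
#' signature are dropped (the downstream enrichment only concerns signature
#' genes); the dropped count is logged.
#'
#' @param stats named numeric vector of signed gene-level statistics.
#' @param prom named integer promiscuity vector from [compute_promiscuity()].
#' @return named numeric vector of corrected statistics over the genes
#'   present in both inputs.
#' @export
correct_statistic <- function(stats, prom) {
  if (is.null(names(stats))) stop("stats must be named by gene")
  keep <- names(stats) %in% names(prom)
  if (any(!keep))
    log_note(sum(!keep), " gene(s) absent from the signature dropped before correction")
  s <- stats[keep]
  s / as.numeric(prom[names(s)])
}
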