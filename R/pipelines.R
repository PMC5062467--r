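## Orchestration of the three headline analyses. These functions are the
## package's pipeline surface: each wires the module stages together,
## optionally writes all tabular outputs plus a machine-readable run
## manifest to an output directory, and is fully reproducible from the
## single seed.

write_manifest <- function(out_dir, analysis, seed, config, outputs) {
  manifest <- list(analysis = analysis, seed = seed,
                   package = "metrewire",
                   version = as.character(utils::packageVersion("metrewire")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = config, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Cancer-vs-normal enrichment across cohorts
#'
#' Per cohort: NB Wald differential expression of tumor vs normal samples,
#' promiscuity correction, directional permutation GSEA; then a
#' cross-cohort frequency table of how often each pathway is enriched up
#' or down, flagging pathways altered in more than `frequency_cut` of the
#' cohorts.
#'
#' @param cm a [count_matrix()] whose `condition` column distinguishes
#'   `tumor_label` from `normal_label` samples and whose `cohort` column
#'   defines the per-cohort comparisons.
#' @param sig a [metabolic_signature()].
#' @param n_perm,seed,q_threshold GSEA parameters.
#' @param frequency_cut fraction of cohorts above which a pathway counts
#'   as commonly altered (default 0.25).
#' @param tumor_label,normal_label condition labels (defaults
#'   `"tumor"`/`"normal"`).
#' @param out_dir optional directory to write per-cohort TSVs and a run
#'   manifest into.
#' @return list of class `cvn_report`: `enrichment` (named list of
#'   `enrichment_result` per cohort), `de` (named list of `de_result`),
#'   `frequency` (pathway, n_up, n_down, frac_up, frac_down, common_up,
#'   common_down), `n_cohorts`.
#' @export
run_cancer_vs_normal <- function(cm, sig, n_perm = 1000L, seed = 1L,
                                 q_threshold = 0.05, frequency_cut = 0.25,
                                 tumor_label = "tumor", normal_label = "normal",
                                 out_dir = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  cohorts <- unique(cm$samples$cohort)
  enr <- list(); de_list <- list()
  for (ch in cohorts) {
    s <- cm$samples[cm$samples$cohort == ch, , drop = FALSE]
    tum <- s$sample[s$condition == tumor_label]
    nor <- s$sample[s$condition == normal_label]
    if (length(nor) < 2L || length(tum) < 2L) {
      log_note("cohort ", ch, " skipped: missing matched tumor/normal samples")
      next
    }
    de <- nb_wald_test(cm$counts[, c(nor, tum), drop = FALSE], nor, tum)
    enr[[ch]] <- gsea_pipeline(de, sig, prom_correct = TRUE, n_perm = n_perm,
                               seed = seed, q_threshold = q_threshold)
    de_list[[ch]] <- de
  }
  freq <- enrichment_frequency(enr, frequency_cut)
  rep <- structure(list(enrichment = enr, de = de_list, frequency = freq,
                        n_cohorts = length(enr)),
                   class = "cvn_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (ch in names(enr)) {
      f <- file.path(out_dir, paste0("enrichment_", ch, ".tsv"))
      write_tsv(enr[[ch]], f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "pathway_frequency.tsv")
    write_tsv(freq, f)
    write_manifest(out_dir, "cancer_vs_normal", seed,
                   list(n_perm = n_perm, q_threshold = q_threshold,
                        frequency_cut = frequency_cut),
                   basename(c(files, f)))
  }
  rep
}

# Cross-cohort frequency of up/down pathway calls.
enrichment_frequency <- function(enr, frequency_cut) {
  if (length(enr) == 0L)
    return(data.frame(pathway = character(0), n_up = integer(0),
                      n_down = integer(0), frac_up = numeric(0),
                      frac_down = numeric(0), common_up = logical(0),
                      common_down = logical(0)))
  paths <- sort(unique(unlist(lapply(enr, `[[`, "pathway"))))
  n_up <- n_down <- stats::setNames(integer(length(paths)), paths)
  for (e in enr) {
    n_up[e$pathway[e$direction == "up"]] <-
      n_up[e$pathway[e$direction == "up"]] + 1L
    n_down[e$pathway[e$direction == "down"]] <-
      n_down[e$pathway[e$direction == "down"]] + 1L
  }
  out <- data.frame(pathway = paths, n_up = as.integer(n_up),
                    n_down = as.integer(n_down),
                    frac_up = as.numeric(n_up) / length(enr),
                    frac_down = as.numeric(n_down) / length(enr),
                    stringsAsFactors = FALSE)
  out$common_up <- out$frac_up > frequency_cut
  out$common_down <- out$frac_down > frequency_cut
  rownames(out) <- NULL
  out
}

#' Low-vs-high survival enrichment across cohorts
#'
#' Per cohort: stratify patients by the 75th-percentile follow-up rule,
#' drop cohorts with fewer than `min_n` patients in either group, run NB
#' Wald DE of the low- vs high-survival samples, promiscuity-corrected
#' GSEA against the metabolic signature (and optionally any extra GMT,
#' e.g. hallmark sets), and summarise pathway frequencies across cohorts.
#'
#' @param cm a [count_matrix()] whose samples are named by patient.
#' @param clinical a [clinical_table()] covering the cohorts.
#' @param sig a [metabolic_signature()].
#' @param hallmark_sig optional second signature analysed with the same
#'   stratification.
#' @param min_n minimum survival-group size (default 5).
#' @param survival_quantile threshold quantile (default 0.75).
#' @inheritParams run_cancer_vs_normal
#' @return list of class `survival_report`: `groups` (retained cohorts'
#'   `survival_groups`), `enrichment`, `hallmark_enrichment` (or NULL),
#'   `de`, `frequency`.
#' @export
run_survival_analysis <- function(cm, clinical, sig, hallmark_sig = NULL,
                                  min_n = 5L, survival_quantile = 0.75,
                                  n_perm = 1000L, seed = 1L,
                                  q_threshold = 0.05, frequency_cut = 0.25,
                                  out_dir = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- stratify_cohorts(clinical, q = survival_quantile)
  groups <- exclude_cohorts(groups, min_n = min_n)
  enr <- list(); de_list <- list(); hall <- list()
  for (ch in names(groups)) {
    g <- groups[[ch]]
    hi <- intersect(g$high, colnames(cm$counts))
    lo <- intersect(g$low, colnames(cm$counts))
    if (length(hi) < 2L || length(lo) < 2L) {
      log_note("cohort ", ch, " skipped: stratified patients not in count matrix")
      next
    }
    de <- nb_wald_test(cm$counts[, c(hi, lo), drop = FALSE], hi, lo)
    enr[[ch]] <- gsea_pipeline(de, sig, prom_correct = TRUE, n_perm = n_perm,
                               seed = seed, q_threshold = q_threshold)
    if (!is.null(hallmark_sig))
      hall[[ch]] <- gsea_pipeline(de, hallmark_sig, prom_correct = FALSE,
                                  n_perm = n_perm, seed = seed,
                                  q_threshold = q_threshold)
    de_list[[ch]] <- de
  }
  freq <- enrichment_frequency(enr, frequency_cut)
  rep <- structure(list(groups = groups, enrichment = enr,
                        hallmark_enrichment = if (is.null(hallmark_sig)) NULL else hall,
                        de = de_list, frequency = freq),
                   class = "survival_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (ch in names(enr)) {
      f <- file.path(out_dir, paste0("survival_enrichment_", ch, ".tsv"))
      write_tsv(enr[[ch]], f); files <- c(files, f)
      ga <- data.frame(patient = c(groups[[ch]]$high, groups[[ch]]$low),
                       group = rep(c("high", "low"),
                                   c(length(groups[[ch]]$high),
                                     length(groups[[ch]]$low))))
      fg <- file.path(out_dir, paste0("survival_groups_", ch, ".tsv"))
      write_tsv(ga, fg); files <- c(files, fg)
    }
    f <- file.path(out_dir, "survival_pathway_frequency.tsv")
    write_tsv(freq, f)
    write_manifest(out_dir, "survival", seed,
                   list(n_perm = n_perm, min_n = min_n,
                        survival_quantile = survival_quantile,
                        q_threshold = q_threshold,
                        frequency_cut = frequency_cut),
                   basename(c(files, f)))
  }
  rep
}

#' Tissue-specific metabolic rewiring analysis
#'
#' Applies the variance-stabilizing transform independently to the pooled
#' normal and pooled cancer compartments, computes per-tissue gene means,
#' fold changes against the average tissue, pathway scores, the per-pair
#' normal-cancer Spearman correlations and the per-tissue diversity SDs;
#' optionally runs the enrichment-based rewiring classification
#' (per-tissue GSEA of each normal tissue vs the pooled others, and of
#' each cancer vs its matched normal).
#'
#' @param normal_cm,cancer_cm [count_matrix()] objects for the two
#'   compartments; `tissue` labels define the columns of the score
#'   matrices.
#' @param pairing data.frame with columns `normal` and `cancer` matching
#'   tissue labels across compartments.
#' @param sig a [metabolic_signature()].
#' @param classify also run the per-tissue enrichment classification
#'   (default `TRUE`; the expensive part of the analysis).
#' @inheritParams run_cancer_vs_normal
#' @return list of class `rewiring_report`: `scores_normal`,
#'   `scores_cancer` (pathway x tissue), `correlation` (per pair),
#'   `diversity_normal`, `diversity_cancer`, and `classification`
#'   (a [classify_rewiring()] result, or NULL).
#' @export
run_rewiring <- function(normal_cm, cancer_cm, pairing, sig, classify = TRUE,
                         n_perm = 500L, seed = 1L, q_threshold = 0.05,
                         out_dir = NULL) {
  stopifnot(inherits(normal_cm, "count_matrix"), inherits(cancer_cm, "count_matrix"))
  vn <- vst(normal_cm)
  vc <- vst(cancer_cm)
  gn <- stats::setNames(normal_cm$samples$tissue, normal_cm$samples$sample)
  gc_ <- stats::setNames(cancer_cm$samples$tissue, cancer_cm$samples$sample)
  Sn <- pathway_scores(fold_vs_average(tissue_means(vn, gn)), sig)
  Sc <- pathway_scores(fold_vs_average(tissue_means(vc, gc_)), sig)
  corr <- normal_cancer_correlation(Sn, Sc, pairing)
  dn <- diversity(Sn); dc <- diversity(Sc)

  cls <- NULL
  if (classify) {
    norm_rows <- list(); canc_rows <- list()
    for (i in seq_len(nrow(pairing))) {
      nt <- pairing$normal[i]; ct <- pairing$cancer[i]
      ns <- normal_cm$samples$sample[normal_cm$samples$tissue == nt]
      os <- normal_cm$samples$sample[normal_cm$samples$tissue != nt]
      cs <- cancer_cm$samples$sample[cancer_cm$samples$tissue == ct]
      if (length(ns) < 2L || length(os) < 2L || length(cs) < 2L) {
        log_note("pair ", nt, "/", ct, " skipped in classification (too few samples)")
        next
      }
      de_n <- nb_wald_test(normal_cm$counts, os, ns)
      e_n <- gsea_pipeline(de_n, sig, TRUE, n_perm, seed, q_threshold = q_threshold)
      de_c <- nb_wald_test(cbind(normal_cm$counts[, ns, drop = FALSE],
                                 cancer_cm$counts[, cs, drop = FALSE]), ns, cs)
      e_c <- gsea_pipeline(de_c, sig, TRUE, n_perm, seed, q_threshold = q_threshold)
      norm_rows[[nt]] <- data.frame(tissue = nt, pathway = e_n$pathway,
                                    direction = e_n$direction,
                                    stringsAsFactors = FALSE)
      canc_rows[[nt]] <- data.frame(tissue = nt, pathway = e_c$pathway,
                                    direction = e_c$direction,
                                    stringsAsFactors = FALSE)
    }
    if (length(norm_rows) > 0L)
      cls <- classify_rewiring(do.call(rbind, norm_rows),
                               do.call(rbind, canc_rows))
  }
  rep <- structure(list(scores_normal = Sn, scores_cancer = Sc,
                        correlation = corr, diversity_normal = dn,
                        diversity_cancer = dc, classification = cls),
                   class = "rewiring_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.frame(pathway = rownames(Sn), Sn, check.names = FALSE),
              file.path(out_dir, "scores_normal.tsv"))
    write_tsv(data.frame(pathway = rownames(Sc), Sc, check.names = FALSE),
              file.path(out_dir, "scores_cancer.tsv"))
    write_tsv(corr, file.path(out_dir, "normal_cancer_correlation.tsv"))
    write_tsv(data.frame(tissue = c(names(dn), names(dc)),
                         compartment = rep(c("normal", "cancer"),
                                           c(length(dn), length(dc))),
                         sd = c(dn, dc)),
              file.path(out_dir, "diversity.tsv"))
    if (!is.null(cls))
      write_tsv(cls$table, file.path(out_dir, "rewiring_classification.tsv"))
    write_manifest(out_dir, "rewiring", seed,
                   list(n_perm = n_perm, q_threshold = q_threshold,
                        classify = classify),
                   list.files(out_dir, pattern = "[.]tsv$"))
  }
  rep
}
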