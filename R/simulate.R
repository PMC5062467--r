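## Seeded synthetic-data generator. Emulates the statistical structure the
## pipeline assumes about its real inputs — NB-distributed raw counts with
## library-size variation and planted pathway-level fold changes, a
## promiscuous gene-pathway signature, TCGA-style clinical tables with
## death/censoring times, essentiality matrices with tissue-specific
## shifts, and metabolite tables coupled to pathway expression — so every
## stage is testable end-to-end without external downloads.

#' Simulation configuration
#'
#' Bundles the generator's parameters with validated defaults sized for
#' desk-scale runs (a full simulate + DE + GSEA round completes in well
#' under a minute).
#'
#' @param seed integer seed; a fixed seed gives bit-identical outputs.
#' @param n_genes total genes in the expression universe.
#' @param n_pathways number of signature pathways (named `PW01`, ...).
#' @param frac_signature fraction of genes belonging to the signature.
#' @param frac_promiscuous fraction of signature genes placed in more than
#'   one pathway (the observed share of promiscuous metabolic genes is
#'   about 20%).
#' @param n_per_group samples per condition per tissue.
#' @param n_tissues number of tissues in the cohort.
#' @param tissue_effect_sd SD (log2 scale) of per-gene tissue effects.
#' @param cancer_shrink multiplier applied to the tissue effects of the
#'   tumor compartment; values below 1 plant convergence of cancers
#'   towards a common expression landscape.
#' @param mean_log_mu,sd_log_mu log-normal parameters of baseline gene
#'   means.
#' @param trend_a0,trend_a1 dispersion trend `alpha(mu) = a0 + a1/mu`.
#' @param disp_noise_sd log-normal noise SD around the dispersion trend.
#' @param sf_sd log-normal SD of the per-sample library-size factors.
#' @param planted_effects data.frame (`pathway`, `direction`, `lfc`) of
#'   pathway-level fold changes planted in the tumor condition.
#' @param clinical list: `n_patients`, `frac_high`, `frac_low`,
#'   `death_rate` (exponential rate of death times for designated
#'   low-survival patients), `high_followup` and `background_followup`
#'   (uniform ranges, years, for censoring times).
#' @param essentiality list: `n_genes`, `n_tissues`, `lines_per_tissue`,
#'   `n_shifted`, `shift` (SD units), `sigma`, `gene_sd`.
#' @param metabolites data.frame (`pathway`, `metabolite`, `beta`) of
#'   couplings, plus `metabolite_noise_sd`.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_pathways = 60L,
                              frac_signature = 0.8,
                              frac_promiscuous = 0.2,
                              n_per_group = 20L,
                              n_tissues = 1L,
                              tissue_effect_sd = 0.5,
                              cancer_shrink = 1,
                              mean_log_mu = log(100),
                              sd_log_mu = 1.2,
                              trend_a0 = 0.05,
                              trend_a1 = 2,
                              disp_noise_sd = 0.3,
                              sf_sd = 0.15,
                              planted_effects = data.frame(
                                pathway = c("PW01", "PW02", "PW03", "PW04"),
                                direction = c("up", "up", "down", "down"),
                                lfc = c(1.5, 1.5, 1.5, 1.5),
                                stringsAsFactors = FALSE),
                              clinical = list(n_patients = 200L,
                                              frac_high = 0.25,
                                              frac_low = 0.35,
                                              death_rate = 1 / 1.5,
                                              high_followup = c(9, 10),
                                              background_followup = c(0.5, 7)),
                              essentiality = list(n_genes = 600L,
                                                  n_tissues = 5L,
                                                  lines_per_tissue = 10L,
                                                  n_shifted = 30L,
                                                  shift = 3,
                                                  sigma = 1,
                                                  gene_sd = 0.5),
                              metabolites = data.frame(
                                pathway = c("PW01", "PW05"),
                                metabolite = c("met_A", "met_B"),
                                beta = c(1, 0),
                                stringsAsFactors = FALSE),
                              metabolite_noise_sd = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              frac_signature = frac_signature,
              frac_promiscuous = frac_promiscuous,
              n_per_group = as.integer(n_per_group),
              n_tissues = as.integer(n_tissues),
              tissue_effect_sd = tissue_effect_sd,
              cancer_shrink = cancer_shrink,
              mean_log_mu = mean_log_mu, sd_log_mu = sd_log_mu,
              trend_a0 = trend_a0, trend_a1 = trend_a1,
              disp_noise_sd = disp_noise_sd, sf_sd = sf_sd,
              planted_effects = planted_effects, clinical = clinical,
              essentiality = essentiality, metabolites = metabolites,
              metabolite_noise_sd = metabolite_noise_sd)
  stopifnot(cfg$n_genes > 0, cfg$n_pathways > 0,
            cfg$frac_signature > 0, cfg$frac_signature <= 1,
            cfg$frac_promiscuous >= 0, cfg$frac_promiscuous <= 1,
            cfg$trend_a0 > 0, cfg$trend_a1 >= 0, cfg$sf_sd >= 0,
            cfg$n_per_group >= 2, cfg$n_tissues >= 1)
  if (round(cfg$frac_signature * cfg$n_genes) < cfg$n_pathways)
    stop("fewer signature genes than pathways; increase n_genes or ",
         "frac_signature, or decrease n_pathways")
  pw_names <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  if (!all(cfg$planted_effects$pathway %in% pw_names))
    stop("planted pathway beyond n_pathways: ",
         paste(setdiff(cfg$planted_effects$pathway, pw_names), collapse = ", "))
  if (!all(cfg$planted_effects$direction %in% c("up", "down")))
    stop("planted directions must be 'up' or 'down'")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a promiscuous metabolic signature
#'
#' Each signature gene gets one home pathway; a configured fraction is
#' additionally placed in one or two other pathways, reproducing the
#' many-to-many gene-pathway structure (about 20% promiscuous genes by
#' default).
#'
#' @param cfg a [simulation_config()]. The caller is responsible for the
#'   RNG state ([simulate_cohort()] seeds it from `cfg$seed`).
#' @return a [metabolic_signature()].
#' @export
simulate_signature <- function(cfg) {
  n_sig <- round(cfg$frac_signature * cfg$n_genes)
  genes <- sprintf("g%05d", seq_len(n_sig))
  pw <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  home <- sample(rep_len(seq_len(cfg$n_pathways), n_sig))
  sets <- split(genes, factor(home, levels = seq_len(cfg$n_pathways)))
  names(sets) <- pw
  n_prom <- round(cfg$frac_promiscuous * n_sig)
  prom_genes <- sample(genes, n_prom)
  for (g in prom_genes) {
    extra <- 1L + stats::rbinom(1L, 1L, 0.3)
    others <- setdiff(seq_len(cfg$n_pathways), home[match(g, genes)])
    for (p in sample(others, min(extra, length(others))))
      sets[[p]] <- c(sets[[p]], g)
  }
  metabolic_signature(sets)
}

#' Simulate an RNA-seq cohort with planted pathway effects
#'
#' Counts are negative binomial with `variance = mu + alpha * mu^2`,
#' `mu = sf_j * q_g * 2^(effects)`, log-normal baseline means, a
#' `a0 + a1/mu` dispersion trend with log-normal noise, log-normal library
#' size factors, per-tissue gene effects (shrunk in the tumor compartment
#' when `cancer_shrink < 1`), and the configured pathway-level log2 fold
#' changes planted in the tumor condition.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `sim_cohort`: `counts` (a [count_matrix()]),
#'   `signature`, and `truth` (per-gene true LFC, planted table, tissue
#'   effects, dispersions, size factors).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  sig <- simulate_signature(cfg)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  G <- cfg$n_genes

  q <- stats::rlnorm(G, cfg$mean_log_mu, cfg$sd_log_mu)
  alpha <- (cfg$trend_a0 + cfg$trend_a1 / q) *
    stats::rlnorm(G, 0, cfg$disp_noise_sd)

  # per-gene true tumor-vs-normal LFC from the planted pathway effects;
  # a gene in several planted pathways takes the first listed effect
  lfc <- stats::setNames(numeric(G), genes)
  pe <- cfg$planted_effects
  if (nrow(pe) > 0L) for (i in seq_len(nrow(pe))) {
    gs <- sig$pathways[[pe$pathway[i]]]
    gs <- gs[lfc[gs] == 0]
    lfc[gs] <- ifelse(pe$direction[i] == "up", pe$lfc[i], -pe$lfc[i])
  }

  tissues <- sprintf("T%02d", seq_len(cfg$n_tissues))
  delta <- matrix(stats::rnorm(G * cfg$n_tissues, 0, cfg$tissue_effect_sd),
                  G, cfg$n_tissues, dimnames = list(genes, tissues))
  if (cfg$n_tissues == 1L) delta[] <- 0

  n_samp <- 2L * cfg$n_per_group * cfg$n_tissues
  meta <- data.frame(
    sample = sprintf("s%04d", seq_len(n_samp)),
    tissue = rep(tissues, each = 2L * cfg$n_per_group),
    condition = rep(rep(c("normal", "tumor"), each = cfg$n_per_group),
                    cfg$n_tissues),
    stringsAsFactors = FALSE)
  meta$cohort <- meta$tissue
  sf <- stats::rlnorm(n_samp, 0, cfg$sf_sd)

  counts <- matrix(0L, G, n_samp, dimnames = list(genes, meta$sample))
  for (j in seq_len(n_samp)) {
    t_eff <- delta[, meta$tissue[j]]
    if (meta$condition[j] == "tumor")
      t_eff <- cfg$cancer_shrink * t_eff + lfc
    mu_j <- sf[j] * q * 2^t_eff
    counts[, j] <- stats::rnbinom(G, mu = mu_j, size = 1 / alpha)
  }
  storage.mode(counts) <- "integer"
  cm <- count_matrix(counts, meta)
  structure(list(counts = cm, signature = sig,
                 truth = list(lfc = lfc, planted = pe, tissue_effects = delta,
                              dispersion = alpha, size_factors =
                                stats::setNames(sf, meta$sample),
                              baseline_mean = stats::setNames(q, genes))),
            class = "sim_cohort")
}

#' Simulate a TCGA-style clinical table
#'
#' Designated high-survival patients are censored alive late in follow-up
#' (uniform over `high_followup`), designated low-survival patients die
#' early (exponential death times), and background patients are censored
#' alive at intermediate times, so the 75th-percentile rule recovers the
#' designated groups.
#'
#' @param cfg a [simulation_config()].
#' @param cohort cohort label for the emitted table.
#' @return list: `clinical` (a [clinical_table()]) and `truth` (designated
#'   group per patient: high/low/background).
#' @export
simulate_clinical <- function(cfg, cohort = "cohort1") {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  cl <- cfg$clinical
  n <- cl$n_patients
  n_high <- round(cl$frac_high * n)
  n_low <- round(cl$frac_low * n)
  n_bg <- n - n_high - n_low
  group <- sample(rep(c("high", "low", "background"), c(n_high, n_low, n_bg)))
  patient <- sprintf("%s-p%04d", cohort, seq_len(n))
  status <- ifelse(group == "low", "dead", "alive")
  days <- numeric(n)
  days[group == "low"] <- stats::rexp(sum(group == "low"), cl$death_rate) * 365.25
  days[group == "high"] <- stats::runif(sum(group == "high"),
                                        cl$high_followup[1], cl$high_followup[2]) * 365.25
  days[group == "background"] <- stats::runif(sum(group == "background"),
                                              cl$background_followup[1],
                                              cl$background_followup[2]) * 365.25
  df <- data.frame(patient = patient, vital_status = status,
                   days_to_death = ifelse(status == "dead", days, NA),
                   days_to_last_followup = ifelse(status == "alive", days, NA),
                   cohort = cohort, stringsAsFactors = FALSE)
  list(clinical = clinical_table(df),
       truth = stats::setNames(group, patient))
}

#' Simulate a survival cohort: counts plus consistent clinical table
#'
#' All samples are tumors from one cohort; a configured pathway effect is
#' planted between the designated low- and high-survival patients (default:
#' the first planted pathway, downregulated in the low group), and the
#' clinical table is generated so that [stratify()] recovers the designated
#' groups.
#'
#' @param cfg a [simulation_config()].
#' @param cohort cohort label.
#' @param surv_effects data.frame (`pathway`, `direction`, `lfc`):
#'   expression changes of the low-survival group relative to the rest;
#'   defaults to the first configured planted pathway, down at the
#'   configured magnitude.
#' @return list of class `sim_survival_cohort`: `counts`, `clinical`,
#'   `signature`, `truth`.
#' @export
simulate_survival_cohort <- function(cfg, cohort = "cohort1",
                                     surv_effects = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(surv_effects))
    surv_effects <- data.frame(pathway = cfg$planted_effects$pathway[1],
                               direction = "down",
                               lfc = abs(cfg$planted_effects$lfc[1]),
                               stringsAsFactors = FALSE)
  clin <- simulate_clinical(cfg, cohort = cohort)
  set.seed(cfg$seed + 2L)
  sig <- simulate_signature(cfg)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  G <- cfg$n_genes
  q <- stats::rlnorm(G, cfg$mean_log_mu, cfg$sd_log_mu)
  alpha <- (cfg$trend_a0 + cfg$trend_a1 / q) *
    stats::rlnorm(G, 0, cfg$disp_noise_sd)
  lfc <- stats::setNames(numeric(G), genes)
  for (i in seq_len(nrow(surv_effects))) {
    gs <- sig$pathways[[surv_effects$pathway[i]]]
    gs <- gs[lfc[gs] == 0]
    lfc[gs] <- ifelse(surv_effects$direction[i] == "up",
                      surv_effects$lfc[i], -surv_effects$lfc[i])
  }
  patients <- clin$clinical$patient
  low <- names(clin$truth)[clin$truth == "low"]
  sf <- stats::rlnorm(length(patients), 0, cfg$sf_sd)
  counts <- matrix(0L, G, length(patients),
                   dimnames = list(genes, patients))
  for (j in seq_along(patients)) {
    eff <- if (patients[j] %in% low) lfc else 0
    counts[, j] <- stats::rnbinom(G, mu = sf[j] * q * 2^eff, size = 1 / alpha)
  }
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample = patients, tissue = cohort, condition = "tumor",
                     cohort = cohort, stringsAsFactors = FALSE)
  structure(list(counts = count_matrix(counts, meta),
                 clinical = clin$clinical, signature = sig,
                 truth = list(group = clin$truth, lfc = lfc,
                              surv_effects = surv_effects)),
            class = "sim_survival_cohort")
}

#' Simulate a gene-level essentiality matrix with tissue shifts
#'
#' Scores are normal around per-gene baselines (lower = more essential); a
#' designated set of genes is shifted down by `shift` standard deviations
#' in one designated tissue, creating recoverable tissue-specific
#' essentiality.
#'
#' @param cfg a [simulation_config()].
#' @param sig optional [metabolic_signature()] whose genes name the rows;
#'   defaults to a fresh [simulate_signature()] draw.
#' @return list: `essentiality` (an [essentiality_matrix()]) and `truth`
#'   (`shifted_genes`, `shifted_tissue`).
#' @export
simulate_essentiality <- function(cfg, sig = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 3L)
  es <- cfg$essentiality
  if (es$n_tissues < 2L) stop("need >= 2 tissues")
  if (is.null(sig)) sig <- simulate_signature(cfg)
  genes <- utils::head(names(sig$gene_index), es$n_genes)
  G <- length(genes)
  tissues <- sprintf("ET%02d", seq_len(es$n_tissues))
  lines <- sprintf("line%03d", seq_len(es$n_tissues * es$lines_per_tissue))
  line_tissue <- stats::setNames(rep(tissues, each = es$lines_per_tissue), lines)
  base <- stats::rnorm(G, 0, es$gene_sd)
  shifted_genes <- sample(genes, min(es$n_shifted, G))
  shifted_tissue <- tissues[1]
  scores <- matrix(stats::rnorm(G * length(lines), base, es$sigma),
                   G, length(lines), dimnames = list(genes, lines))
  in_shift <- line_tissue[colnames(scores)] == shifted_tissue
  scores[shifted_genes, in_shift] <-
    scores[shifted_genes, in_shift] - es$shift * es$sigma
  list(essentiality = essentiality_matrix(scores, line_tissue),
       truth = list(shifted_genes = shifted_genes,
                    shifted_tissue = shifted_tissue))
}

#' Simulate a metabolite table coupled to pathway expression
#'
#' Each configured metabolite equals `beta` times the per-sample mean
#' log2-normalized expression of its pathway plus Gaussian noise, so
#' positive couplings are recoverable by [pathway_vs_feature()].
#'
#' @param cfg a [simulation_config()].
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @return list: `metabolites` (metabolite x sample matrix) and `truth`
#'   (the coupling table).
#' @export
simulate_metabolites <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(cohort, "sim_cohort"))
  set.seed(cfg$seed + 4L)
  y <- cohort$counts$counts
  sf <- size_factors(y)
  expr <- log2(sweep(y, 2L, sf, "/") + 1)
  pm <- pathway_score_matrix(expr, cohort$signature)  # samples x pathways
  tab <- cfg$metabolites
  met <- t(vapply(seq_len(nrow(tab)), function(i) {
    base <- pm[, tab$pathway[i]]
    tab$beta[i] * base + stats::rnorm(length(base), 0, cfg$metabolite_noise_sd)
  }, numeric(nrow(pm))))
  dimnames(met) <- list(tab$metabolite, rownames(pm))
  list(metabolites = met, truth = tab)
}
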