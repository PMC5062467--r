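small_cfg <- function(seed, n_tissues = 1, ...) {
  simulation_config(seed = seed, n_genes = 500, n_pathways = 12,
                    n_per_group = 8, n_tissues = n_tissues,
                    planted_effects = data.frame(pathway = c("PW01", "PW02"),
                                                 direction = c("up", "down"),
                                                 lfc = c(2, 2)), ...)
}

test_that("cancer-vs-normal pipeline aggregates cohorts into a frequency table", {
  sim <- suppressMessages(simulate_cohort(small_cfg(51, n_tissues = 3)))
  out <- withr::local_tempdir()
  rep1 <- suppressMessages(run_cancer_vs_normal(sim$counts, sim$signature,
                                                n_perm = 499, seed = 2,
                                                out_dir = out))
  expect_equal(rep1$n_cohorts, 3)
  fr <- rep1$frequency
  # the planted pathway is altered in all three cohorts
  expect_equal(fr$n_up[fr$pathway == "PW01"], 3)
  expect_equal(fr$n_down[fr$pathway == "PW02"], 3)
  expect_true(fr$common_up[fr$pathway == "PW01"])
  # outputs and manifest written
  expect_true(file.exists(file.path(out, "pathway_frequency.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2)
  # re-run with the same seed is identical
  rep2 <- suppressMessages(run_cancer_vs_normal(sim$counts, sim$signature,
                                                n_perm = 499, seed = 2))
  expect_identical(rep1$enrichment, rep2$enrichment)
})

test_that("survival pipeline stratifies, excludes small cohorts, finds the planted pathway", {
  cfg <- simulation_config(seed = 61, n_genes = 500, n_pathways = 12,
                           clinical = list(n_patients = 60, frac_high = 0.3,
                                           frac_low = 0.35, death_rate = 1 / 1.5,
                                           high_followup = c(9, 10),
                                           background_followup = c(0.5, 7)))
  sim <- suppressMessages(simulate_survival_cohort(cfg))
  rep <- suppressMessages(run_survival_analysis(sim$counts, sim$clinical,
                                                sim$signature, n_perm = 499,
                                                seed = 3))
  expect_true("cohort1" %in% names(rep$enrichment))
  e <- rep$enrichment$cohort1
  planted <- sim$truth$surv_effects$pathway[1]
  # low-vs-high DE: the planted pathway is downregulated in the low group
  expect_identical(e$direction[e$pathway == planted], "down")
  expect_equal(rep$frequency$n_down[rep$frequency$pathway == planted], 1)
})

test_that("rewiring pipeline: cloned compartments give rho 1 and equal diversity", {
  sim <- suppressMessages(simulate_cohort(small_cfg(71, n_tissues = 4,
                                                    tissue_effect_sd = 0.4)))
  s <- sim$counts$samples
  nm <- count_matrix(sim$counts$counts[, s$sample[s$condition == "normal"]],
                     s[s$condition == "normal", ])
  pairing <- data.frame(normal = unique(s$tissue), cancer = unique(s$tissue))
  rep <- suppressMessages(run_rewiring(nm, nm, pairing, sim$signature,
                                       classify = FALSE))
  expect_equal(rep$correlation$rho, rep(1, 4))
  expect_equal(rep$diversity_normal, rep$diversity_cancer)
})

test_that("planted convergence shrinks cancer diversity below normal in every tissue", {
  sim <- suppressMessages(simulate_cohort(
    small_cfg(81, n_tissues = 4, tissue_effect_sd = 0.8, cancer_shrink = 0.25)))
  s <- sim$counts$samples
  nm <- count_matrix(sim$counts$counts[, s$sample[s$condition == "normal"]],
                     s[s$condition == "normal", ])
  cm <- count_matrix(sim$counts$counts[, s$sample[s$condition == "tumor"]],
                     s[s$condition == "tumor", ])
  pairing <- data.frame(normal = unique(s$tissue), cancer = unique(s$tissue))
  rep <- suppressMessages(run_rewiring(nm, cm, pairing, sim$signature,
                                       classify = FALSE))
  expect_true(all(rep$diversity_cancer < rep$diversity_normal))
})

test_that("TSV loaders round-trip counts, annotations and clinical tables", {
  sim <- suppressMessages(simulate_cohort(small_cfg(91)))
  fc <- withr::local_tempfile(); fm <- withr::local_tempfile()
  write_count_matrix(sim$counts, fc, fm)
  y <- read_counts(fc)
  expect_identical(unname(y), unname(sim$counts$counts))
  meta <- read_sample_meta(fm)
  cm <- count_matrix(y, meta)
  expect_identical(cm$samples$tissue, sim$counts$samples$tissue)
  cl <- simulate_clinical(small_cfg(92))$clinical
  ft <- withr::local_tempfile()
  df <- data.frame(patient = cl$patient, vital_status = cl$status,
                   days_to_death = ifelse(cl$status == "dead",
                                          cl$time_years * 365.25, NA),
                   days_to_last_followup = ifelse(cl$status == "alive",
                                                  cl$time_years * 365.25, NA),
                   cohort = cl$cohort)
  utils::write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  cl2 <- read_clinical(ft)
  expect_equal(cl2$time_years, cl$time_years, tolerance = 1e-9)
})
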