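test_that("the simulator is deterministic and internally consistent", {
  cfg <- simulation_config(seed = 5, n_genes = 400, n_pathways = 12,
                           n_per_group = 6,
                           planted_effects = data.frame(
                             pathway = c("PW01", "PW03"),
                             direction = c("up", "down"), lfc = c(1.5, 1.5)))
  s1 <- suppressMessages(simulate_cohort(cfg))
  s2 <- suppressMessages(simulate_cohort(cfg))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$signature$pathways, s2$signature$pathways)
  # TSV round-trip is byte-identical for the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  m1 <- withr::local_tempfile(); m2 <- withr::local_tempfile()
  write_count_matrix(s1$counts, f1, m1)
  write_count_matrix(s2$counts, f2, m2)
  expect_identical(readLines(f1), readLines(f2))
  # ground truth cross-consistency: planted pathways exist, and their
  # genes carry the planted LFC sign
  planted_other <- function(i) unlist(
    s1$signature$pathways[setdiff(cfg$planted_effects$pathway,
                                  cfg$planted_effects$pathway[i])])
  for (i in seq_len(nrow(cfg$planted_effects))) {
    p <- cfg$planted_effects$pathway[i]
    expect_true(p %in% names(s1$signature$pathways))
    # genes exclusive to this planted pathway carry its effect sign
    # (genes shared between planted pathways take the first listed effect)
    gs <- setdiff(s1$signature$pathways[[p]], planted_other(i))
    sgn <- if (cfg$planted_effects$direction[i] == "up") 1 else -1
    expect_true(all(s1$truth$lfc[gs] * sgn > 0))
  }
  # invalid planted pathway rejected up front
  expect_error(simulation_config(planted_effects = data.frame(
    pathway = "PW99", direction = "up", lfc = 1), n_pathways = 10),
    "beyond n_pathways")
})

test_that("simulated promiscuity matches the configured fraction", {
  cfg <- simulation_config(seed = 11, n_genes = 2000, n_pathways = 60)
  set.seed(cfg$seed)
  sig <- simulate_signature(cfg)
  prom <- compute_promiscuity(sig)
  expect_equal(mean(prom > 1), 0.2, tolerance = 0.02)
  expect_true(all(prom >= 1))
})

test_that("simulated counts match NB moments", {
  # one gene, many samples: empirical mean/variance vs mu and mu + a*mu^2
  set.seed(12)
  mu <- 200; alpha <- 0.1
  draws <- rnbinom(5000, mu = mu, size = 1 / alpha)
  expect_equal(mean(draws), mu, tolerance = 0.05 * mu)
  expect_equal(var(draws), mu + alpha * mu^2, tolerance = 0.05 * (mu + alpha * mu^2))
  # and the generator's own output at default dispersion structure
  cfg <- simulation_config(seed = 13, n_genes = 30, n_pathways = 5,
                           n_per_group = 2500,
                           sf_sd = 0, planted_effects = data.frame(
                             pathway = character(0), direction = character(0),
                             lfc = numeric(0)))
  sim <- suppressMessages(simulate_cohort(cfg))
  y <- sim$counts$counts
  q <- sim$truth$baseline_mean
  a <- sim$truth$dispersion
  rel_mean <- abs(rowMeans(y) - q) / q
  rel_var <- abs(apply(y, 1, var) - (q + a * q^2)) / (q + a * q^2)
  expect_true(mean(rel_mean < 0.05) > 0.9)
  expect_true(mean(rel_var < 0.15) > 0.9)
})

test_that("simulated clinical tables are recovered by stratification", {
  cfg <- simulation_config(seed = 21)
  cl <- simulate_clinical(cfg)
  s <- stratify(cl$clinical)
  des_high <- names(cl$truth)[cl$truth == "high"]
  des_low <- names(cl$truth)[cl$truth == "low"]
  agree <- (sum(s$high %in% des_high) + sum(s$low %in% des_low)) /
    (length(des_high) + length(des_low))
  expect_gte(agree, 0.95)
  # all-alive configuration yields an empty low group
  cfg0 <- simulation_config(seed = 22,
                            clinical = list(n_patients = 40, frac_high = 0.5,
                                            frac_low = 0, death_rate = 1,
                                            high_followup = c(9, 10),
                                            background_followup = c(0.5, 7)))
  cl0 <- simulate_clinical(cfg0)
  expect_length(stratify(cl0$clinical)$low, 0)
  # determinism
  expect_identical(simulate_clinical(cfg)$clinical, cl$clinical)
})

test_that("simulated essentiality plants recoverable tissue shifts", {
  cfg <- simulation_config(seed = 31)
  se <- simulate_essentiality(cfg)
  res <- anova_by_tissue(se$essentiality)
  hit <- res$tissue_predicted[match(se$truth$shifted_genes, res$gene)]
  expect_gte(mean(hit), 0.95)
  # determinism
  se2 <- simulate_essentiality(cfg)
  expect_identical(se$essentiality$scores, se2$essentiality$scores)
})

test_that("simulated metabolites carry the configured couplings", {
  cfg <- simulation_config(seed = 41, n_genes = 500, n_pathways = 12,
                           n_per_group = 15)
  sim <- suppressMessages(simulate_cohort(cfg))
  met <- simulate_metabolites(cfg, sim)
  y <- sim$counts$counts
  expr <- log2(sweep(y, 2, size_factors(y), "/") + 1)
  res <- suppressMessages(pathway_vs_feature(expr, sim$signature,
                                             met$metabolites["met_A", ]))
  expect_gt(res$rho[res$pathway == "PW01"], 0)
  expect_lt(res$padj[res$pathway == "PW01"], 0.05)
  # beta = 0 metabolite is null for its nominal pathway
  res0 <- suppressMessages(pathway_vs_feature(expr, sim$signature,
                                              met$metabolites["met_B", ]))
  expect_gt(res0$pvalue[res0$pathway == "PW05"], 0.01)
})
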