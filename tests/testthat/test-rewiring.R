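test_that("vst is monotone, normalization-invariant, and sqrt-like near zero dispersion", {
  y <- nb_fixture(G = 150, n = 6, seed = 11)
  sf <- size_factors(y)
  v <- suppressMessages(vst(y, sf = sf))
  expect_identical(attr(v, "provenance"), "vst-parametric")
  k <- sweep(y, 2, sf, "/")
  # strictly increasing in normalized counts per gene
  for (g in c(1, 50, 150)) {
    o <- order(k[g, ])
    expect_true(all(diff(v[g, o]) >= 0))
  }
  # doubling a sample's counts and its size factor leaves its VST column
  # unchanged when the same trend is applied (pure-transform invariance)
  tr <- attr(v, "trend")
  y2 <- y; y2[, 3] <- 2L * y2[, 3]
  sf2 <- sf; sf2[3] <- 2 * sf2[3]
  v2 <- vst(y2, sf = sf2, trend = tr)
  expect_equal(v2[, 3], v[, 3], tolerance = 1e-12)
  # near-Poisson trend: correlation with 2*sqrt(normalized count) > 0.999
  vp <- vst(y, sf = sf, trend = c(1e-6, 0))
  expect_gt(cor(as.vector(vp), as.vector(2 * sqrt(k))), 0.999)
})

test_that("tissue means equal the per-gene loop oracle and ignore sample order", {
  y <- nb_fixture(G = 40, n = 5, seed = 12)
  v <- log2(y + 1)
  tis <- setNames(rep(c("liver", "kidney"), each = 5), colnames(y))
  m <- tissue_means(v, tis)
  brute <- matrix(NA_real_, nrow(v), 2, dimnames = list(rownames(v), c("kidney", "liver")))
  for (g in seq_len(nrow(v)))
    for (t in c("kidney", "liver"))
      brute[g, t] <- mean(v[g, names(tis)[tis == t]])
  expect_equal(m, brute[, colnames(m)])
  shuf <- sample(ncol(v))
  expect_equal(tissue_means(v[, shuf], tis[shuf]), m)
  # one sample per tissue: means are that sample's values
  one <- tissue_means(v[, 1:2], setNames(c("a", "b"), colnames(v)[1:2]))
  expect_equal(unname(one[, "a"]), unname(v[, 1]))
})

test_that("fold change vs average tissue obeys the row-mean identity", {
  m <- matrix(c(2, 4, 3, 3, 1, 5), 3, 2, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("t1", "t2")))
  r <- fold_vs_average(m)
  expect_equal(unname(r["gA", ]), c(2 / 3, 4 / 3))
  expect_equal(unname(r["gB", ]), c(1, 1))       # identical means -> 1
  expect_equal(unname(rowMeans(r)), rep(1, 3), tolerance = 1e-12)
  set.seed(13)
  big <- matrix(rlnorm(100 * 5), 100, 5,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("t%d", 1:5)))
  expect_equal(unname(rowMeans(fold_vs_average(big))), rep(1, 100),
               tolerance = 1e-12)
  # zero average: flagged NA and logged
  z <- rbind(big, gz = 0)
  expect_message(rz <- fold_vs_average(z), "zero cross-tissue")
  expect_true(all(is.na(rz["gz", ])))
})

test_that("pathway scores equal the exhaustive nested-loop oracle", {
  set.seed(14)
  r <- matrix(rlnorm(100 * 5), 100, 5,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("t%d", 1:5)))
  sig <- random_signature(n_genes = 100, n_pathways = 10, seed = 14)
  S <- suppressMessages(pathway_scores(r, sig))
  for (p in rownames(S)) {
    for (t in colnames(S)) {
      gs <- intersect(sig$pathways[[p]], rownames(r))
      acc <- 0
      for (g in gs) acc <- acc + r[g, t]
      expect_equal(S[p, t], acc / length(gs))
    }
  }
  # singleton pathway reduces to the gene's own r
  s1 <- metabolic_signature(list(SOLO = "g001"))
  expect_equal(unname(pathway_scores(r, s1)["SOLO", ]), unname(r["g001", ]))
  # constant-r pathway scores 1
  rc <- r; rc[sig$pathways$P01, ] <- 1
  expect_equal(unname(suppressMessages(pathway_scores(rc, sig))["P01", ]),
               rep(1, 5))
})

test_that("normal-cancer correlation handles identity, reversal, and ties", {
  set.seed(15)
  S <- matrix(rlnorm(20 * 2), 20, 2,
              dimnames = list(sprintf("P%02d", 1:20), c("liver", "kidney")))
  pairing <- data.frame(normal = c("liver", "kidney"),
                        cancer = c("liver", "kidney"))
  r_id <- normal_cancer_correlation(S, S, pairing)
  expect_equal(r_id$rho, c(1, 1))
  r_rev <- normal_cancer_correlation(S, -S, pairing)  # antitone scores
  expect_equal(r_rev$rho, c(-1, -1))
  # definitional oracle with midranks (also under ties)
  St <- S; St[1:4, 1] <- St[5, 1]
  r_t <- normal_cancer_correlation(S, St, pairing)
  for (i in 1:2)
    expect_equal(r_t$rho[i], brute_spearman(S[, i], St[, i]), tolerance = 1e-12)
  expect_error(normal_cancer_correlation(S, S,
    data.frame(normal = "liver", cancer = "lung")), "unmatched")
})

test_that("diversity is the sample SD of the pathway score distribution", {
  S <- matrix(c(1, 1, 1, 0, 2, 4), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("t1", "t2")))
  d <- diversity(S)
  expect_equal(unname(d["t1"]), 0)
  expect_equal(unname(d["t2"]), sd(c(0, 2, 4)))
  expect_equal(unname(diversity(rbind(P1 = c(0, 0), P2 = c(2, 2)))[1]), sqrt(2))
  expect_error(diversity(S[1, , drop = FALSE]), ">= 2 pathways")
})

test_that("rewiring classification applies the rule table and partitions", {
  ne <- data.frame(tissue = rep("liver", 4),
                   pathway = c("P1", "P2", "P3", "P4"),
                   direction = c("up", "up", "down", "ns"))
  ce <- data.frame(tissue = rep("liver", 4),
                   pathway = c("P1", "P2", "P3", "P4"),
                   direction = c("down", "ns", "up", "up"))
  cls <- classify_rewiring(ne, ce)
  lab <- setNames(cls$table$label, cls$table$pathway)
  expect_identical(lab[["P1"]], "lost")       # up in normal, down in cancer
  expect_identical(lab[["P2"]], "maintained") # up in normal, ns in cancer
  expect_identical(lab[["P3"]], "gained")     # down in normal, up in cancer
  expect_identical(lab[["P4"]], "unchanged")  # ns in normal
  for (st in unique(cls$fractions$normal_status))
    expect_equal(sum(cls$fractions$fraction[cls$fractions$normal_status == st]), 1)
  expect_error(classify_rewiring(ne, transform(ce, tissue = "lung")), "unmatched")
})
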