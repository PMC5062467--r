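# Independent brute-force oracles and small fixture builders shared across
# the suite. These deliberately re-derive each quantity from its defining
# formula, never through the package's own code paths.

make_sig <- function(...) metabolic_signature(list(...))

random_signature <- function(n_genes = 50, n_pathways = 8, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_pathways), function(i)
    sample(genes, sample(3:10, 1)))
  names(sets) <- sprintf("P%02d", seq_len(n_pathways))
  metabolic_signature(sets)
}

# Full running-sum ES: walk the entire ranking, accumulate hit/miss steps,
# take the signed maximal deviation from zero.
naive_running_es <- function(stats, geneset, weight = 1) {
  stats <- stats[order(names(stats))]               # canonical tie-break
  o <- order(stats, decreasing = TRUE)
  g <- names(stats)[o]
  s <- unname(stats[o])
  hit <- g %in% geneset
  N <- length(s)
  w <- abs(s)^weight
  wh <- sum(w[hit])
  inc <- ifelse(hit, if (wh > 0) w / wh else 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (N - sum(hit)))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

# Literal re-implementation of the stratification rule: explicit type-7
# quantile by hand, then two scans with strict inequalities.
brute_stratify <- function(clin, q = 0.75) {
  valid <- !is.na(clin$status) & !is.na(clin$time_years)
  tt <- sort(clin$time_years[valid])
  n <- length(tt)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  thr <- tt[lo] + (h - lo) * (tt[min(lo + 1, n)] - tt[lo])
  high <- low <- character(0)
  for (i in seq_len(nrow(clin))) {
    if (!valid[i]) next
    if (clin$status[i] == "alive" && clin$time_years[i] > thr)
      high <- c(high, clin$patient[i])
    if (clin$status[i] == "dead" && clin$time_years[i] < thr)
      low <- c(low, clin$patient[i])
  }
  list(high = high, low = low, threshold = thr)
}

random_clinical <- function(n = 30, seed = 1, cohort = "cohort1") {
  set.seed(seed)
  status <- sample(c("alive", "dead"), n, replace = TRUE)
  days <- round(runif(n, 10, 4000), 3)
  clinical_table(data.frame(
    patient = sprintf("p%03d", seq_len(n)),
    vital_status = status,
    days_to_death = ifelse(status == "dead", days, NA),
    days_to_last_followup = ifelse(status == "alive", days, NA),
    cohort = cohort, stringsAsFactors = FALSE))
}

# Midrank-then-Pearson Spearman, straight from the definition.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random NB count fixture with a planted two-group LFC on the first
# `n_de` genes (group B = second half of the columns).
nb_fixture <- function(G = 200, n = 8, seed = 1, disp = 0.1, lfc = 0,
                       n_de = 0, mu_log = log(100), mu_sd = 1.2) {
  set.seed(seed)
  mu <- rlnorm(G, mu_log, mu_sd)
  lv <- c(rep(lfc, n_de), rep(0, G - n_de))
  grp <- rep(0:1, each = n)
  y <- vapply(grp, function(g) rnbinom(G, mu = mu * 2^(lv * g), size = 1 / disp),
              numeric(G))
  dimnames(y) <- list(sprintf("g%04d", seq_len(G)), sprintf("s%03d", seq_len(2 * n)))
  y
}
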