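# Independent oracles and fixture builders shared across the test files.
# Oracles deliberately use different arithmetic routes than the package
# implementation (choose()/dhyper() enumeration, explicit per-cell
# likelihood) so that agreement is evidence, not tautology.

# --- Hardy-Weinberg exact oracle -------------------------------------------
# P(n_het = h | allele counts) via binomial coefficients:
#   P = choose(n, nAA) * choose(n - nAA, h) * 2^h / choose(2n, nA)
oracle_hwe_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  probs <- vapply(hs, function(h) {
    hAA <- (nA - h) / 2
    choose(n, hAA) * choose(n - hAA, h) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  p_obs <- probs[hs == nAa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# --- Fisher 2x2 enumeration oracle -----------------------------------------
oracle_fisher_2x2_p <- function(t) {
  m <- rowSums(t)[1]; n <- rowSums(t)[2]; k <- colSums(t)[1]
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) return(1)
  as_ <- max(0, k - n):min(k, m)
  probs <- dhyper(as_, m, n, k)
  p_obs <- dhyper(t[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Two-locus likelihood and grid-search oracle ---------------------------
# Explicit per-cell genotype-class probabilities (written out by hand, not
# via genotype_class_probs) as a function of f = (f1a, f1b, f5, f15).
oracle_loglik <- function(n, f1a, f1b, f5, f15) {
  # cell probabilities in column-major order of the 3x3 count matrix
  # (rows = 388G dosage, cols = 521C dosage); arguments may be vectors of
  # equal length (or scalars) for vectorized grid evaluation
  probs <- list(
    f1a^2,                         # (0,0)
    2 * f1a * f1b,                 # (1,0)
    f1b^2,                         # (2,0)
    2 * f1a * f5,                  # (0,1)
    2 * (f1a * f15 + f1b * f5),    # (1,1)
    2 * f1b * f15,                 # (2,1)
    f5^2,                          # (0,2)
    2 * f5 * f15,                  # (1,2)
    f15^2)                         # (2,2)
  n_flat <- as.numeric(n)
  ll <- 0
  for (k in 1:9)
    if (n_flat[k] > 0)
      ll <- ll + n_flat[k] * log(pmax(probs[[k]], 1e-300))
  ll
}

# Maximize the two-locus likelihood along the marginal-constrained segment
# f15 = t, f1b = pG - t, f5 = qC - t, f1a = 1 - pG - qC + t (the MLE of
# codominant data preserves the observed allele frequencies; a coarse
# full-simplex sweep confirming this is in the acceptance tests).
# Two-stage grid: 1e-4 sweep, then a 1e-7 refinement around the maximum.
oracle_grid_em <- function(n) {
  N <- sum(n)
  pG <- sum(n * matrix(0:2, 3, 3)) / (2 * N)
  qC <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
  lo <- max(0, pG + qC - 1); hi <- min(pG, qC)
  eval_t <- function(t) oracle_loglik(n, 1 - pG - qC + t, pG - t, qC - t, t)
  if (hi - lo < 1e-12) {
    t_best <- lo
  } else {
    ts <- seq(lo, hi, by = 1e-4)
    t_best <- ts[which.max(eval_t(ts))]
    ts2 <- seq(max(lo, t_best - 2e-4), min(hi, t_best + 2e-4), by = 1e-7)
    t_best <- ts2[which.max(eval_t(ts2))]
  }
  list(f = c(`*1a` = 1 - pG - qC + t_best, `*1b` = pG - t_best,
             `*5` = qC - t_best, `*15` = t_best),
       loglik = eval_t(t_best))
}

# Full-simplex coarse grid (step `by`), used to confirm the constrained
# segment contains the global optimum.
oracle_grid_full_simplex <- function(n, by = 0.02) {
  best <- -Inf; best_f <- NULL
  for (f1a in seq(0, 1, by = by)) for (f1b in seq(0, 1 - f1a, by = by)) {
    f5 <- seq(0, 1 - f1a - f1b, by = by)
    ll <- oracle_loglik(n, f1a, f1b, f5, 1 - f1a - f1b - f5)
    k <- which.max(ll)
    if (length(k) && ll[k] > best) {
      best <- ll[k]
      best_f <- c(f1a, f1b, f5[k], 1 - f1a - f1b - f5[k])
    }
  }
  list(f = best_f, loglik = best)
}

# --- Fixture builders ------------------------------------------------------
make_table <- function(d388, d521, group = "g1") {
  n <- length(d388)
  group <- rep_len(group, n)
  genotype_table(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), group = group,
    dosage_388 = d388, dosage_521 = d521, stringsAsFactors = FALSE))
}

random_two_locus_counts <- function(N) {
  # random genotype table via random haplotype frequencies, so realistic
  f <- as.numeric(rmultinom(1, 20, rep(1, 4))) / 20
  f <- (f + 0.01) / sum(f + 0.01)
  h1 <- sample.int(4, N, TRUE, prob = f)
  h2 <- sample.int(4, N, TRUE, prob = f)
  g388 <- c(0, 1, 0, 1); g521 <- c(0, 0, 1, 1)
  n <- matrix(0L, 3, 3)
  for (s in seq_len(N)) {
    i <- g388[h1[s]] + g388[h2[s]]
    j <- g521[h1[s]] + g521[h2[s]]
    n[i + 1, j + 1] <- n[i + 1, j + 1] + 1L
  }
  n
}

random_simplex4 <- function() {
  x <- rexp(4)
  x / sum(x)
}

write_test_vcf <- function(path, sample_ids, gt388, gt521,
                           ref388 = "A", alt388 = "G",
                           ref521 = "T", alt521 = "C",
                           id388 = "rs2306283", id521 = "rs4149056") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=12>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"),
    paste(c("12", "21329738", id388, ref388, alt388, ".", "PASS", ".", "GT",
            gt388), collapse = "\t"),
    paste(c("12", "21331549", id521, ref521, alt521, ".", "PASS", ".", "GT",
            gt521), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_test_metadata <- function(path, sample_ids, groups) {
  writeLines(c("sample_id\tgroup", paste(sample_ids, groups, sep = "\t")),
             path)
  path
}
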