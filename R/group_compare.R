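# Cross-group significance testing on count tables: Pearson chi-square
# (no continuity correction), 2x2 Fisher exact, and a seeded Monte-Carlo
# Fisher test for larger tables.

as_count_table <- function(t) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t)))
    stop("contingency table must hold non-negative integer counts",
         call. = FALSE)
  if (nrow(t) < 2L || ncol(t) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  t
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic with expected counts from the margins, no continuity
#' correction, df = (r-1)(c-1), upper-tail chi-square p-value.
#'
#' @param t contingency table (matrix of counts, at least 2x2, all margins
#'   positive).
#' @return Test result with method `"chi_square"`, the statistic, df and
#'   p-value.
#' @export
chi_square_test <- function(t) {
  t <- as_count_table(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero margin: use fisher_exact_2x2() or fisher_rxc_montecarlo()",
         call. = FALSE)
  res <- suppressWarnings(chisq.test(t, correct = FALSE))
  new_test_result("chi_square", unname(res$p.value),
                  statistic = unname(res$statistic),
                  df = as.integer(res$parameter))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value defined as the sum, over all tables with the observed
#' margins, of hypergeometric probabilities no larger than the observed
#' table's (with a small relative slack for floating-point ties).
#'
#' @param t 2x2 matrix of counts.
#' @return Test result with method `"fisher_2x2"`. A table with a zero
#'   margin has a single attainable configuration and p = 1.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as_count_table(t)
  if (!all(dim(t) == c(2, 2)))
    stop("fisher_exact_2x2 requires a 2x2 table", call. = FALSE)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    return(new_test_result("fisher_2x2", 1))
  # fisher.test can return 1 + eps through floating-point accumulation
  new_test_result("fisher_2x2", min(1, fisher.test(t)$p.value))
}

# log multiple-hypergeometric probability of a table given its margins
log_table_prob <- function(t) {
  sum(lgamma(rowSums(t) + 1)) + sum(lgamma(colSums(t) + 1)) -
    lgamma(sum(t) + 1) - sum(lgamma(t + 1))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

#' Monte-Carlo Fisher test for an r x c table
#'
#' Estimates the exact-test p-value by sampling tables with the observed
#' margins (Patefield's sequential hypergeometric fill, via
#' [stats::r2dtable()]) and counting those whose multiple-hypergeometric
#' probability does not exceed the observed table's. The estimator is
#' `(1 + hits) / (n_draws + 1)`, never exactly zero, and is deterministic
#' given the seed.
#'
#' @param t contingency table.
#' @param n_draws number of sampled tables (>= 1000).
#' @param seed integer seed for the draw stream.
#' @return Test result with method `"fisher_mc"`, the p estimate and its
#'   binomial Monte-Carlo standard error in `mc_se`.
#' @export
fisher_rxc_montecarlo <- function(t, n_draws = 10000L, seed = 1L) {
  t <- as_count_table(t)
  if (n_draws < 1000L) stop("n_draws must be at least 1000", call. = FALSE)
  lp_obs <- log_table_prob(t)
  slack <- log1p(1e-7)  # relative tolerance for float ties
  hits <- with_seed(seed, {
    sims <- r2dtable(n_draws, rowSums(t), colSums(t))
    sum(vapply(sims, function(s) log_table_prob(s) <= lp_obs + slack,
               logical(1)))
  })
  p <- (1 + hits) / (n_draws + 1)
  new_test_result("fisher_mc", p,
                  mc_se = sqrt(p * (1 - p) / (n_draws + 1)))
}

#' Compare the minor allele frequencies of the two loci
#'
#' Builds the 2x2 table of (variant, ancestral) chromosome counts for the two
#' loci and applies the chi-square test. The two loci are genotyped in the
#' same individuals, so this treats paired chromosomes as independent; the
#' result carries an explicit note to that effect.
#'
#' @param c1,c2 [allele_counts()] for the two loci over the same cohort
#'   scope.
#' @return Test result with method `"chi_square"` and a pairing note.
#' @export
compare_variant_mafs <- function(c1, c2) {
  if ((c1$n_ancestral + c1$n_variant) == 0 ||
      (c2$n_ancestral + c2$n_variant) == 0)
    stop("zero observed chromosomes", call. = FALSE)
  t <- rbind(c(c1$n_variant, c1$n_ancestral),
             c(c2$n_variant, c2$n_ancestral))
  res <- chi_square_test(t)
  res$note <- paste("unpaired comparison of allele counts from the same",
                    "samples; within-sample pairing ignored")
  res
}

#' Choose and run a contingency-table test
#'
#' Default policy: Pearson chi-square when every expected cell count is at
#' least 5; otherwise the exact Fisher test for 2x2 tables, and the seeded
#' Monte-Carlo Fisher test for larger tables. The method actually used is
#' recorded in the result.
#'
#' @param t contingency table.
#' @param min_expected expected-count threshold for the chi-square branch.
#' @param n_draws,seed passed to [fisher_rxc_montecarlo()] when selected.
#' @return Test result from the selected method.
#' @export
select_test <- function(t, min_expected = 5, n_draws = 10000L, seed = 1L) {
  t <- as_count_table(t)
  N <- sum(t)
  expected <- outer(rowSums(t), colSums(t)) / N
  if (N > 0 && all(rowSums(t) > 0) && all(colSums(t) > 0) &&
      all(expected >= min_expected))
    chi_square_test(t)
  else if (all(dim(t) == c(2, 2)))
    fisher_exact_2x2(t)
  else
    fisher_rxc_montecarlo(t, n_draws = n_draws, seed = seed)
}
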