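test_that("allele counting sums dosages over observed chromosomes", {
  tbl <- make_table(c(0L, 1L, 2L), c(0L, 0L, 1L))
  ac <- allele_counts(tbl, "388", "Total")
  expect_equal(ac$n_variant, 3L)
  expect_equal(ac$n_ancestral, 3L)
  expect_equal(ac$n_missing_samples, 0L)

  tbl2 <- make_table(c(NA, NA), c(0L, 1L), group = "g1")
  ac2 <- allele_counts(tbl2, "388", "g1")
  expect_equal(ac2$n_variant + ac2$n_ancestral, 0L)
  expect_equal(ac2$n_missing_samples, 2L)
  expect_error(allele_counts(tbl, "388", "nope"), "unknown group")
})

test_that("allele counts and group sizes satisfy the chromosome identity", {
  set.seed(41)
  d388 <- sample(c(0:2, NA), 200, TRUE)
  d521 <- sample(c(0:2, NA), 200, TRUE)
  tbl <- make_table(d388, d521, group = sample(c("a", "b"), 200, TRUE))
  for (g in c("Total", "a", "b")) for (v in c("388", "521")) {
    ac <- allele_counts(tbl, v, g)
    n_group <- length(slcohap:::group_rows(tbl, g))
    expect_equal(ac$n_ancestral + ac$n_variant,
                 2L * (n_group - ac$n_missing_samples))
  }
})

test_that("minor allele frequency reports the second-most-common allele", {
  tbl <- make_table(rep(0L, 3), rep(0L, 3))
  mk <- function(n_anc, n_var) {
    structure(list(variant = default_variant_specs()$v521, group = "Total",
                   n_ancestral = n_anc, n_variant = n_var,
                   n_missing_samples = 0L, n_samples = (n_anc + n_var) / 2),
              class = "allele_counts")
  }
  m <- minor_allele_frequency(mk(1593L, 507L))
  expect_equal(m$frequency, 507 / 2100, tolerance = 1e-12)
  expect_equal(round_half_up(m$frequency, 2), 0.24)
  expect_equal(m$minor_allele, "C")

  tie <- minor_allele_frequency(mk(50L, 50L))
  expect_equal(tie$frequency, 0.5)
  expect_equal(tie$minor_allele, "C")  # tie reported as the variant allele

  fixed <- minor_allele_frequency(mk(0L, 10L))
  expect_equal(fixed$frequency, 0)
  expect_equal(fixed$minor_allele, "T")  # ancestral is second-most-common

  expect_error(minor_allele_frequency(mk(0L, 0L)), "chromosomes")
})

test_that("HWE exact test equals enumeration and is symmetric", {
  expect_equal(hwe_exact_test(c(0, 0, 25))$p_value, 1)
  # (1,0,1): het in {0,2} with allele counts (2,2):
  # P(h=0) = C(2,1)C(1,0)/C(4,2) = 2/6, P(h=2) = C(2,0)C(2,2)4/C(4,2) = 4/6
  expect_equal(hwe_exact_test(c(1, 0, 1))$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(hwe_exact_test(c(1, 0, 1))$p_value,
               oracle_hwe_p(1, 0, 1), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:200) {
    g <- as.numeric(rmultinom(1, sample(1:50, 1), runif(3, 0.05, 1)))
    p <- hwe_exact_test(g)$p_value
    expect_equal(p, oracle_hwe_p(g[1], g[2], g[3]), tolerance = 1e-12)
    # permutation symmetry in the homozygote classes
    expect_equal(p, hwe_exact_test(c(g[3], g[2], g[1]))$p_value,
                 tolerance = 1e-12)
  }
})

test_that("HWE chi-square variant is available behind the method flag", {
  r <- hwe_exact_test(c(30, 40, 30), method = "chisq")
  expect_equal(r$method, "chi_square")
  expect_equal(r$df, 1L)
  p <- 0.5
  e <- 100 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(r$statistic, sum((c(30, 40, 30) - e)^2 / e),
               tolerance = 1e-12)
})

test_that("count reconstruction recovers integers behind printed percentages", {
  r <- reconstruct_counts(c(3.58, 4.65, 1.32), c(1174, 774, 152))
  expect_equal(r$counts, c(42L, 36L, 2L))
  expect_false(any(r$flagged))

  r2 <- reconstruct_counts(c(52.98, 62.27, 77.63), c(587, 387, 76))
  expect_equal(r2$counts, c(311L, 241L, 59L))

  expect_equal(reconstruct_counts(100, 76)$counts, 76L)

  # self-consistency: recomputing percentages reproduces the input at 2 dp
  set.seed(13)
  for (rep in 1:50) {
    N <- sample(50:2000, 1)
    k <- sample(0:N, 1)
    pct <- round_half_up(100 * k / N, 2)
    r <- reconstruct_counts(pct, N)
    expect_equal(r$counts, k)
    expect_equal(round_half_up(100 * r$counts / N, 2), pct)
  }
})
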