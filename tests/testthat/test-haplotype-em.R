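test_that("star-allele mapping covers exactly the four haplotypes", {
  expect_equal(star_allele("A", "T")$name, "*1a")
  expect_equal(star_allele("G", "T")$name, "*1b")
  s5 <- star_allele("A", "C")
  expect_equal(s5$name, "*5")
  expect_equal(s5$functional_class, "reduced")
  expect_equal(star_allele("G", "C")$name, "*15")
  expect_error(star_allele("T", "C"), "A or G")
  expect_error(star_allele("A", "A"), "T or C")
  st <- star_allele_table()
  expect_identical(st$functional_class,
                   c("functional", "functional", "reduced", "reduced"))
})

test_that("two-locus tabulation excludes and tallies missing samples", {
  tbl <- make_table(c(0L, 1L, 2L), c(0L, 1L, 2L))
  n <- two_locus_counts(tbl)
  expect_equal(diag(n), setNames(c(1L, 1L, 1L), 0:2))
  expect_equal(sum(n), 3L)

  tbl2 <- make_table(c(0L, NA, 1L), c(0L, 1L, NA))
  n2 <- two_locus_counts(tbl2)
  expect_equal(sum(n2), 1L)
  expect_equal(attr(n2, "n_missing"), 2L)

  tbl3 <- make_table(integer(0), integer(0), group = character(0))
  tbl3$groups <- "empty"
  n3 <- two_locus_counts(tbl3, "empty")
  expect_true(all(n3 == 0L))
})

test_that("EM without phase ambiguity equals direct gamete counting", {
  # no double heterozygote: every haplotype is observable
  tbl <- make_table(c(0L, 1L, 2L, 2L, 0L), c(0L, 0L, 1L, 2L, 1L))
  n <- two_locus_counts(tbl)
  fit <- em_haplotype_frequencies(n)
  # hand gamete count: (0,0)->2*1a; (1,0)->1a+1b; (2,1)->1b+15;
  # (2,2)->2*15; (0,1)->1a+5 over 10 chromosomes
  expect_equal(unname(fit$f), c(4, 2, 1, 3) / 10, tolerance = 1e-12)
  expect_equal(fit$n_iter, 1L)
  expect_true(fit$converged)

  n2 <- matrix(0L, 3, 3); n2[1, 1] <- 30L; n2[3, 3] <- 10L
  f2 <- em_haplotype_frequencies(n2)$f
  expect_equal(unname(f2), c(0.75, 0, 0, 0.25), tolerance = 1e-12)
})

test_that("EM matches grid-search likelihood maximization on random tables", {
  set.seed(23)
  for (rep in 1:30) {
    n <- random_two_locus_counts(sample(20:200, 1))
    if (sum(n) == 0 || sum(n) == n[2, 2]) next
    fit <- em_haplotype_frequencies(n)
    grid <- oracle_grid_em(n)
    expect_equal(unname(fit$f), unname(grid$f), tolerance = 1e-3)
    expect_equal(fit$loglik, grid$loglik, tolerance = 1e-6)
  }
})

test_that("EM preserves marginal allele frequencies at every iterate", {
  set.seed(31)
  for (rep in 1:20) {
    n <- random_two_locus_counts(sample(20:150, 1))
    if (sum(n) == 0) next
    N <- sum(n)
    pG <- sum(n * matrix(0:2, 3, 3)) / (2 * N)
    qC <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * N)
    fit <- em_haplotype_frequencies(n)
    ft <- fit$f_trace
    expect_true(all(abs(ft[, 2] + ft[, 4] - pG) < 1e-12))
    expect_true(all(abs(ft[, 3] + ft[, 4] - qC) < 1e-12))
    # monotone log-likelihood along the EM path
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_true(abs(sum(fit$f) - 1) < 1e-12)
  }
})

test_that("EM flags the non-identifiable all-double-heterozygote table", {
  n <- matrix(0L, 3, 3); n[2, 2] <- 40L
  expect_warning(fit <- em_haplotype_frequencies(n), "not identifiable")
  expect_true(fit$converged)
  expect_false(fit$identifiable)
  # marginals still forced: 388G and 521C frequencies are both 0.5
  expect_equal(unname(fit$f[2] + fit$f[4]), 0.5, tolerance = 1e-12)
})

test_that("zero-probability phase denominator falls back to an even split", {
  n <- matrix(0L, 3, 3); n[2, 2] <- 4L; n[1, 1] <- 6L
  fit <- em_haplotype_frequencies(n, init = c(0.5, 0.5, 0, 0))
  expect_true(fit$degenerate_split)
  expect_true(all(fit$f >= 0))
})

test_that("diplotype assignment forces phase except the double heterozygote", {
  expect_equal(assign_diplotype(0, 0)$alleles, c("*1a", "*1a"))
  d21 <- assign_diplotype(2, 1)
  expect_equal(d21$alleles, c("*1b", "*15"))
  expect_equal(d21$phase_posterior, 1)
  expect_false(d21$ambiguous)

  # published pooled haplotype frequencies give the cis phase at ~0.869
  f <- c(0.2324, 0.3495, 0.0381, 0.38)
  d <- assign_diplotype(1, 1, f)
  expect_true(d$ambiguous)
  expect_equal(d$alleles, c("*1a", "*15"))
  expect_equal(d$phase_posterior,
               (0.2324 * 0.38) / (0.2324 * 0.38 + 0.3495 * 0.0381),
               tolerance = 1e-12)

  # trans-favouring frequencies flip the call
  d2 <- assign_diplotype(1, 1, c(0.05, 0.45, 0.45, 0.05))
  expect_equal(d2$alleles, c("*1b", "*5"))

  # exact tie breaks toward *1a/*15
  d3 <- assign_diplotype(1, 1, c(0.25, 0.25, 0.25, 0.25))
  expect_equal(d3$alleles, c("*1a", "*15"))
  expect_equal(d3$phase_posterior, 0.5)

  expect_error(assign_diplotype(NA, 1, f), "missing dosage")
  expect_error(assign_diplotype(1, 1), "frequencies required")
})

test_that("double heterozygote always yields exactly one reduced allele", {
  set.seed(59)
  for (rep in 1:25) {
    f <- random_simplex4()
    d <- assign_diplotype(1, 1, f)
    expect_equal(sum(d$alleles %in% c("*5", "*15")), 1L)
  }
})

test_that("haplotype table converts frequencies to percentages and counts", {
  n <- matrix(0L, 3, 3); n[1, 1] <- 30L; n[3, 3] <- 10L
  fit <- em_haplotype_frequencies(n)
  tab <- haplotype_frequency_table(list(Total = fit), c(Total = 80L))
  expect_equal(tab$pct_Total, c(75, 0, 0, 25))
  expect_equal(tab$count_Total, c(60, 0, 0, 20))
  expect_equal(sum(tab$pct_Total), 100)

  # a *5 frequency of 80/2100 chromosomes prints as 3.81%
  expect_equal(round_half_up(100 * 80 / 2100, 2), 3.81)
})
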