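test_that("chi-square test matches the textbook formula", {
  # identical column proportions: statistic 0, p 1
  r0 <- chi_square_test(rbind(c(10, 20), c(5, 10)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)

  # perfect association: statistic equals N
  r1 <- chi_square_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(r1$statistic, 20, tolerance = 1e-12)
  expect_equal(r1$df, 1L)

  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "zero margin")

  set.seed(11)
  for (rep in 1:50) {
    t <- matrix(rpois(6, 20) + 1, 2, 3)
    r <- chi_square_test(t)
    E <- outer(rowSums(t), colSums(t)) / sum(t)
    expect_equal(r$statistic, sum((t - E)^2 / E), tolerance = 1e-9)
    expect_equal(r$df, 2L)
    expect_equal(r$p_value, pchisq(sum((t - E)^2 / E), 2,
                                   lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("the reconstructed *5 carriage table reproduces the printed p", {
  t <- rbind(c(42, 36, 2), c(1132, 738, 150))
  r <- chi_square_test(t)
  expect_equal(r$df, 2L)
  expect_equal(round_half_up(r$p_value, 4), 0.1195)
})

test_that("Fisher 2x2 equals hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(0, 5), c(5, 0)))$p_value, 2 / 252,
               tolerance = 1e-12)
  # zero margin: single attainable table
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))$p_value, 1)

  set.seed(17)
  for (rep in 1:100) {
    t <- matrix(sample(0:10, 4, TRUE), 2, 2)
    if (sum(t) > 40) next
    expect_equal(fisher_exact_2x2(t)$p_value, oracle_fisher_2x2_p(t),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo Fisher is seeded, consistent and conservative", {
  t <- rbind(c(8, 2), c(3, 9))
  exact <- fisher_exact_2x2(t)$p_value
  mc <- fisher_rxc_montecarlo(t, n_draws = 20000L, seed = 5L)
  expect_equal(mc$method, "fisher_mc")
  expect_lt(abs(mc$p_value - exact), 3 * mc$mc_se + 1e-9)

  # determinism: bit-identical under the same seed, RNG state untouched
  set.seed(123); before <- .Random.seed
  mc2 <- fisher_rxc_montecarlo(t, n_draws = 20000L, seed = 5L)
  expect_identical(mc2$p_value, mc$p_value)
  expect_identical(before, .Random.seed)

  # identical columns: the null is true and the observed table is modal
  t_null <- rbind(c(12, 12), c(8, 8))
  mc3 <- fisher_rxc_montecarlo(t_null, n_draws = 100000L, seed = 2L)
  expect_gte(mc3$p_value, 0.99)

  expect_error(fisher_rxc_montecarlo(t, n_draws = 10L), "at least 1000")
})

test_that("the 388-vs-521 MAF comparison flags its unpaired treatment", {
  mk <- function(n_var, n_anc, which = "v388") {
    structure(list(variant = default_variant_specs()[[which]],
                   group = "Total", n_variant = n_var, n_ancestral = n_anc,
                   n_missing_samples = 0L, n_samples = (n_var + n_anc) / 2),
              class = "allele_counts")
  }
  same <- compare_variant_mafs(mk(500L, 1600L), mk(500L, 1600L, "v521"))
  expect_equal(same$p_value, 1)

  # frequencies 0.49 vs 0.24 on 2100 chromosomes each
  r <- compare_variant_mafs(mk(1029L, 1071L), mk(507L, 1593L, "v521"))
  expect_lt(r$p_value, 0.001)
  expect_match(r$note, "pairing")

  # extreme separation: p decreases monotonically with k
  ps <- vapply(c(5L, 10L, 20L), function(k)
    compare_variant_mafs(mk(k, 0L), mk(0L, k, "v521"))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("test selection follows the expected-count policy", {
  big <- rbind(c(30, 40), c(35, 25))
  expect_equal(select_test(big)$method, "chi_square")

  small22 <- rbind(c(2, 8), c(9, 1))
  expect_equal(select_test(small22)$method, "fisher_2x2")

  small23 <- rbind(c(2, 8, 1), c(9, 1, 7))
  r <- select_test(small23, seed = 4L)
  expect_equal(r$method, "fisher_mc")
  expect_false(is.na(r$mc_se))
})
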