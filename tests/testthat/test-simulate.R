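test_that("cohort presets carry the study group structure", {
  for (preset in c("hf-table", "maf-consistent")) {
    cfg <- qatari_preset(preset)
    labels <- vapply(cfg$groups, `[[`, character(1), "label")
    sizes <- vapply(cfg$groups, `[[`, integer(1), "n_samples")
    expect_equal(labels, c("Bedouin/Arab", "Persian/South Asian", "African"))
    expect_equal(sizes, c(587L, 387L, 76L))
    for (g in cfg$groups)
      expect_lt(abs(sum(g$hap_freqs) - 1), 1e-9)
  }
  bed <- qatari_preset("hf-table")$groups[[1]]
  expect_equal(unname(bed$hap_freqs), c(0.2368, 0.2930, 0.0358, 0.4344),
               tolerance = 1e-12)
  # maf-consistent: f(*5) + f(*15) equals the group's 521C frequency and
  # f(*1b) + f(*15) its 388G frequency
  mc <- qatari_preset("maf-consistent")$groups
  q521 <- c(0.27, 0.22, 0.14); p388 <- c(0.49, 0.48, 0.61)
  for (k in 1:3) {
    expect_equal(unname(mc[[k]]$hap_freqs[3] + mc[[k]]$hap_freqs[4]),
                 q521[k], tolerance = 1e-12)
    expect_equal(unname(mc[[k]]$hap_freqs[2] + mc[[k]]$hap_freqs[4]),
                 p388[k], tolerance = 1e-12)
  }
})

test_that("degenerate generator settings force the expected genotypes", {
  mono <- cohort_config(list(group_config("g", 50, c(1, 0, 0, 0))), seed = 3)
  tbl <- generate_cohort(mono)$table
  expect_true(all(tbl$samples$dosage_388 == 0L))
  expect_true(all(tbl$samples$dosage_521 == 0L))

  inbred <- cohort_config(list(
    group_config("g", 300, c(0.4, 0.3, 0.2, 0.1), inbreeding_f = 1)),
    seed = 4)
  s <- generate_cohort(inbred)$table$samples
  expect_false(any(s$dosage_388 == 1L))
  expect_false(any(s$dosage_521 == 1L))
})

test_that("generation is deterministic and group streams are independent", {
  cfg <- cohort_config(list(
    group_config("a", 40, c(0.4, 0.3, 0.2, 0.1), missing_rate = 0.1),
    group_config("b", 30, c(0.1, 0.2, 0.3, 0.4))), seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table$samples, c2$table$samples)
  expect_identical(c1$truth$haplotype_pairs, c2$truth$haplotype_pairs)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  expect_identical(readLines(file.path(d1, "cohort.vcf")),
                   readLines(file.path(d2, "cohort.vcf")))

  # appending a third group must not perturb the first two groups' draws
  cfg3 <- cohort_config(c(cfg$groups, list(
    group_config("c", 20, c(0.25, 0.25, 0.25, 0.25)))), seed = 42)
  c3 <- generate_cohort(cfg3)
  expect_identical(c3$table$samples[1:70, ], c1$table$samples)
})

test_that("truth bookkeeping tallies every chromosome exactly once", {
  cfg <- cohort_config(list(
    group_config("g", 500, c(0.35, 0.25, 0.15, 0.25))), seed = 9)
  cohort <- generate_cohort(cfg)
  pairs <- cohort$truth$haplotype_pairs
  tally <- table(factor(c(pairs$hap1, pairs$hap2),
                        levels = c("*1a", "*1b", "*5", "*15")))
  expect_equal(sum(tally), 2L * 500L)
  # dosages are the allele content of the truth pair
  carries_G <- c("*1b", "*15"); carries_C <- c("*5", "*15")
  expect_equal(cohort$table$samples$dosage_388,
               (pairs$hap1 %in% carries_G) + (pairs$hap2 %in% carries_G))
  expect_equal(cohort$table$samples$dosage_521,
               (pairs$hap1 %in% carries_C) + (pairs$hap2 %in% carries_C))
})

test_that("missingness hits each locus independently at the set rate", {
  cfg <- cohort_config(list(
    group_config("g", 4000, c(0.4, 0.3, 0.2, 0.1), missing_rate = 0.1)),
    seed = 12)
  s <- generate_cohort(cfg)$table$samples
  for (col in c("dosage_388", "dosage_521")) {
    rate <- mean(is.na(s[[col]]))
    expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  }
})

test_that("inbreeding inflates HWE rejection; random mating does not", {
  hwe_p <- function(f_inbreeding, seed) {
    cfg <- cohort_config(list(
      group_config("g", 2000, c(0.4, 0.3, 0.2, 0.1),
                   inbreeding_f = f_inbreeding)), seed = seed)
    s <- generate_cohort(cfg)$table$samples
    d <- s$dosage_521
    hwe_exact_test(c(sum(d == 0), sum(d == 1), sum(d == 2)))$p_value
  }
  # strong consanguinity at large n: decisive rejection
  expect_lt(hwe_p(0.3, 21), 1e-6)
  # random mating: rejections near the nominal rate (check a few seeds)
  ps <- vapply(1:8, function(s) hwe_p(0, s), numeric(1))
  expect_gte(mean(ps > 0.05), 0.75)
})

test_that("config files parse into simulation configs", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    seed = 7,
    groups = data.frame(label = c("x", "y"), n_samples = c(10L, 20L))),
    path, auto_unbox = TRUE)
  # hap_freqs per group must be present
  expect_error(read_cohort_config(path), class = "slcohap_config_error")

  jsonlite::write_json(list(
    seed = 7,
    groups = list(list(label = "x", n_samples = 10,
                       hap_freqs = c(0.4, 0.3, 0.2, 0.1)),
                  list(label = "y", n_samples = 20,
                       hap_freqs = c(0.25, 0.25, 0.25, 0.25),
                       inbreeding_f = 0.1))),
    path, auto_unbox = TRUE)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$seed, 7L)
  expect_equal(cfg$groups[[2]]$inbreeding_f, 0.1)
})
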