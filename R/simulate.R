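# Synthetic multi-group cohort generator with known haplotype truth: the
# reproducible stand-in for the real exome-derived genotypes.

#' Configure one ancestry group for simulation
#'
#' @param label group name.
#' @param n_samples number of individuals (> 0).
#' @param hap_freqs numeric 4-vector of haplotype frequencies over
#'   (*1a, *1b, *5, *15); must sum to 1 within 1e-9.
#' @param inbreeding_f inbreeding coefficient F in \[0, 1\]: with probability
#'   F an individual's two haplotypes are identical by descent (one draw,
#'   duplicated), otherwise two independent draws (random mating).
#' @param missing_rate per-locus probability that a genotype is set missing.
#' @return A `group_config` object.
#' @export
group_config <- function(label, n_samples, hap_freqs, inbreeding_f = 0,
                         missing_rate = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            n_samples >= 1, length(hap_freqs) == 4L, all(hap_freqs >= 0),
            inbreeding_f >= 0, inbreeding_f <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (abs(sum(hap_freqs) - 1) > 1e-9)
    stop("hap_freqs must sum to 1 (got ", sum(hap_freqs), ")", call. = FALSE)
  structure(list(label = label, n_samples = as.integer(n_samples),
                 hap_freqs = setNames(as.numeric(hap_freqs), hap_names()),
                 inbreeding_f = inbreeding_f, missing_rate = missing_rate),
            class = "group_config")
}

#' Configure a multi-group cohort simulation
#'
#' @param groups list of [group_config()]s with unique labels.
#' @param variants pair of [variant_spec()]s (defaults to the two SLCO1B1
#'   variants).
#' @param seed root integer seed. Each group draws from its own child stream
#'   with seed `(seed + 1000003 * group_index) mod 2147483647`, so adding a
#'   group never perturbs earlier groups' draws.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(groups, variants = default_variant_specs(),
                          seed = 1L) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_config")))
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("group labels must be unique", call. = FALSE)
  structure(list(groups = groups, variants = variants,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

group_child_seed <- function(root_seed, group_index) {
  as.integer((as.double(root_seed) + 1000003 * group_index) %% 2147483647)
}

#' Built-in cohort presets mirroring the published Qatari study structure
#'
#' Both presets use the study's group sizes (Bedouin/Arab 587, Persian/South
#' Asian 387, African 76). They differ in the per-group haplotype
#' frequencies, because the source tables' haplotype-frequency rows and MAF
#' rows are mutually inconsistent (see the methods vignette); neither preset
#' is privileged and callers must name one:
#'
#' * `"hf-table"` — the printed per-group haplotype-frequency percentages.
#' * `"maf-consistent"` — per-group frequencies consistent with the printed
#'   MAFs (388G: 0.49/0.48/0.61; 521C: 0.27/0.22/0.14) under linkage
#'   equilibrium, so that f(*5) + f(*15) equals each group's 521C frequency
#'   and the implied phenotype distribution matches the published counts.
#'
#' Defaults: inbreeding F = 0 and no missingness.
#'
#' @param preset `"hf-table"` or `"maf-consistent"`.
#' @param seed root seed for [cohort_config()].
#' @return A [cohort_config()].
#' @export
qatari_preset <- function(preset = c("hf-table", "maf-consistent"),
                          seed = 1L) {
  preset <- match.arg(preset)
  sizes <- c("Bedouin/Arab" = 587L, "Persian/South Asian" = 387L,
             "African" = 76L)
  freqs <- if (preset == "hf-table") {
    list("Bedouin/Arab" = c(23.68, 29.30, 3.58, 43.44) / 100,
         "Persian/South Asian" = c(24.55, 37.73, 4.65, 33.07) / 100,
         "African" = c(13.16, 64.47, 1.32, 21.05) / 100)
  } else {
    le <- function(p, q) c((1 - p) * (1 - q), p * (1 - q), (1 - p) * q, p * q)
    list("Bedouin/Arab" = le(0.49, 0.27),
         "Persian/South Asian" = le(0.48, 0.22),
         "African" = le(0.61, 0.14))
  }
  groups <- lapply(names(sizes), function(g)
    group_config(g, sizes[[g]], freqs[[g]]))
  cfg <- cohort_config(groups, seed = seed)
  cfg$preset <- preset
  cfg
}

#' Simulate a genotyped cohort with known haplotype truth
#'
#' For each group, haplotype pairs are drawn from the group's frequency
#' vector: with probability `inbreeding_f` one haplotype is drawn and
#' duplicated (identity by descent), otherwise two are drawn independently
#' (random mating). Dosages of 388G and 521C follow from the pair's allele
#' content; each locus is then independently set missing with
#' `missing_rate`. Fully reproducible: one child RNG stream per group,
#' derived from the root seed, with a fixed draw order (IBD flags, first
#' haplotype, second haplotype, missingness masks).
#'
#' @param cfg a [cohort_config()].
#' @return List with `table` (a [genotype_table()]) and `truth`: the config
#'   echo and a data.frame of per-sample haplotype pairs (`hap1`, `hap2`,
#'   star names) before missingness was applied.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  g388 <- hap_carries_388G()
  g521 <- hap_carries_521C()
  per_group <- lapply(seq_along(cfg$groups), function(gi) {
    gc <- cfg$groups[[gi]]
    n <- gc$n_samples
    with_seed(group_child_seed(cfg$seed, gi), {
      ibd <- runif(n) < gc$inbreeding_f
      h1 <- sample.int(4L, n, replace = TRUE, prob = gc$hap_freqs)
      h2 <- sample.int(4L, n, replace = TRUE, prob = gc$hap_freqs)
      h2[ibd] <- h1[ibd]
      miss388 <- runif(n) < gc$missing_rate
      miss521 <- runif(n) < gc$missing_rate
      d388 <- as.integer(g388[h1]) + as.integer(g388[h2])
      d521 <- as.integer(g521[h1]) + as.integer(g521[h2])
      d388[miss388] <- NA_integer_
      d521[miss521] <- NA_integer_
      prefix <- gsub("[^A-Za-z0-9]+", "_", gc$label)
      data.frame(sample_id = sprintf("%s_%05d", prefix, seq_len(n)),
                 group = gc$label,
                 dosage_388 = d388, dosage_521 = d521,
                 hap1 = hap_names()[h1], hap2 = hap_names()[h2],
                 stringsAsFactors = FALSE)
    })
  })
  all <- do.call(rbind, per_group)
  labels <- vapply(cfg$groups, `[[`, character(1), "label")
  table <- genotype_table(all[, c("sample_id", "group",
                                  "dosage_388", "dosage_521")],
                          variants = cfg$variants, groups = labels)
  truth <- list(
    seed = cfg$seed,
    preset = cfg$preset,
    groups = lapply(cfg$groups, unclass),
    haplotype_pairs = all[, c("sample_id", "group", "hap1", "hap2")])
  list(table = table, truth = truth)
}

gt_string <- function(dosage) {
  ifelse(is.na(dosage), "./.", c("0/0", "0/1", "1/1")[dosage + 1L])
}

#' Write a simulated cohort to disk (VCF + metadata + truth)
#'
#' Emits a VCF v4.2 with one record per variant (REF = ancestral allele,
#' ALT = variant allele, GT-only FORMAT, unphased genotypes), a sample
#' metadata table (`sample_id`, `group`, tab-separated), and a truth JSON
#' holding the configuration, seed and per-sample haplotype pairs. Output is
#' byte-deterministic for a given cohort.
#'
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written
#'   (`vcf`, `metadata`, `truth`).
#' @export
write_cohort <- function(cohort, out_dir) {
  table <- cohort$table
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  meta_path <- file.path(out_dir, "samples.tsv")
  truth_path <- file.path(out_dir, "truth.json")

  s <- table$samples
  specs <- table$variants[order(vapply(table$variants, `[[`, integer(1),
                                       "pos"))]
  dosage_col <- function(spec)
    if (spec$rsid == table$variants[[1]]$rsid) s$dosage_388 else s$dosage_521
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=slcohap-simulator",
    sprintf("##contig=<ID=%s>", unique(vapply(specs, `[[`, character(1),
                                              "chrom"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", s$sample_id), collapse = "\t"))
  records <- vapply(specs, function(spec) {
    paste(c(spec$chrom, spec$pos, spec$rsid,
            spec$ancestral_allele, spec$variant_allele,
            ".", "PASS", ".", "GT", gt_string(dosage_col(spec))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, records), vcf_path)

  utils::write.table(s[, c("sample_id", "group")], meta_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(vcf = vcf_path, metadata = meta_path, truth = truth_path))
}
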