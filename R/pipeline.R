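# End-to-end analysis pipeline and command wrappers (simulate / analyze /
# check-tables) with a run manifest. The command wrappers signal classed
# conditions that the CLI script maps to fixed exit codes:
#   slcohap_config_error -> 2, slcohap_variant_error -> 3,
#   slcohap_empty_group -> 4, slcohap_check_failure -> 5.

stop_classed <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the full cohort analysis
#'
#' Executes the published analysis surface on a genotype table: per-scope
#' allele counts, minor allele frequencies and exact Hardy-Weinberg tests
#' for both loci; per-scope EM haplotype-frequency estimation; phenotype
#' frequencies from the 521C dosage; and cross-group tests (per-variant MAF
#' differences, per-haplotype and per-phenotype carriage differences, and
#' the 388-vs-521 MAF comparison), with the test chosen by [select_test()].
#' Scopes are "Total" plus each configured group. A locus with no observed
#' chromosomes in a scope yields an NA MAF row and a warning entry rather
#' than an error.
#'
#' @param table a [genotype_table()] with group labels attached.
#' @param mc_draws draws for any Monte-Carlo Fisher test selected.
#' @param seed seed for Monte-Carlo tests (the only randomness here).
#' @param hwe_method `"exact"` or `"chisq"`, passed to [hwe_exact_test()].
#' @return A list of class `slcohap_analysis`: `groups`, `n_samples`,
#'   `maf` (long data.frame), `hwe`, `em` (per-scope fits), `haplotypes`
#'   (wide percentage table), `phenotypes`, `tests`, `warnings`.
#' @export
analyze_cohort <- function(table, mc_draws = 10000L, seed = 1L,
                           hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  if (length(table$groups) == 0L || all(is.na(table$samples$group)))
    stop_classed("slcohap_empty_group", "no grouped samples to analyze")
  scopes <- c("Total", table$groups)
  warnings <- character(0)

  counts_by <- list()  # [[scope]][[locus]]
  maf_rows <- list(); hwe_rows <- list()
  for (sc in scopes) {
    if (length(group_rows(table, sc)) == 0L)
      stop_classed("slcohap_empty_group", "group has no samples: ", sc)
    for (locus in c("388", "521")) {
      ac <- allele_counts(table, locus, sc)
      counts_by[[sc]][[locus]] <- ac
      lbl <- ac$variant$cdna_label
      if (ac$n_ancestral + ac$n_variant == 0L) {
        warnings <- c(warnings, paste0("no observed chromosomes for ", lbl,
                                       " in ", sc, "; MAF unavailable"))
        maf_rows[[length(maf_rows) + 1L]] <- data.frame(
          variant = lbl, scope = sc, maf = NA_real_,
          minor_allele = NA_character_, n_chromosomes = 0L,
          n_missing = ac$n_missing_samples, stringsAsFactors = FALSE)
        next
      }
      m <- minor_allele_frequency(ac)
      maf_rows[[length(maf_rows) + 1L]] <- data.frame(
        variant = lbl, scope = sc, maf = m$frequency,
        minor_allele = m$minor_allele, n_chromosomes = m$n_chromosomes,
        n_missing = ac$n_missing_samples, stringsAsFactors = FALSE)
      col <- if (locus == "388") "dosage_388" else "dosage_521"
      d <- table$samples[[col]][group_rows(table, sc)]
      d <- d[!is.na(d)]
      g <- c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
      hwe_rows[[length(hwe_rows) + 1L]] <- data.frame(
        variant = lbl, scope = sc,
        p_value = hwe_exact_test(g, method = hwe_method)$p_value,
        stringsAsFactors = FALSE)
    }
  }
  maf <- do.call(rbind, maf_rows)
  hwe <- do.call(rbind, hwe_rows)

  em <- lapply(setNames(scopes, scopes), function(sc) {
    n <- two_locus_counts(table, sc)
    if (sum(n) == 0L) return(NULL)
    withCallingHandlers(
      em_haplotype_frequencies(n),
      warning = function(w) {
        warnings <<- c(warnings, paste0("EM (", sc, "): ",
                                        conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  })
  em <- Filter(Negate(is.null), em)
  haplotypes <- if (length(em)) {
    em_chroms <- vapply(em, function(fit) 2L * fit$n, integer(1))
    haplotype_frequency_table(em, em_chroms)
  } else {
    warnings <- c(warnings,
                  "no samples genotyped at both loci; haplotype table empty")
    data.frame(haplotype = hap_names(), stringsAsFactors = FALSE)
  }

  phenotypes <- phenotype_frequencies(table)

  grp <- table$groups
  tests <- list(maf_across_groups = list(),
                haplotype_across_groups = list(),
                phenotype_across_groups = list(),
                maf_388_vs_521 = NULL)
  if (length(grp) >= 2L) {
    for (locus in c("388", "521")) {
      t <- vapply(grp, function(g) {
        ac <- counts_by[[g]][[locus]]
        c(ac$n_variant, ac$n_ancestral)
      }, integer(2))
      lbl <- counts_by[[grp[1]]][[locus]]$variant$cdna_label
      tests$maf_across_groups[[lbl]] <-
        select_test(t, n_draws = mc_draws, seed = seed)
    }
    for (k in seq_len(4)) {
      hk <- hap_names()[k]
      t <- vapply(grp, function(g) {
        if (is.null(em[[g]])) return(c(0L, 0L))
        cnt <- as.integer(round_half_up(em[[g]]$f[k] * 2 * em[[g]]$n))
        c(cnt, 2L * em[[g]]$n - cnt)
      }, integer(2))
      tests$haplotype_across_groups[[hk]] <-
        select_test(t, n_draws = mc_draws, seed = seed)
    }
    for (cls in c("normal", "intermediate", "low")) {
      t <- vapply(grp, function(g) {
        row <- phenotypes[phenotypes$group == g, ]
        cnt <- row[[paste0("n_", cls)]]
        c(cnt, row$n_classified - cnt)
      }, integer(2))
      tests$phenotype_across_groups[[cls]] <-
        select_test(t, n_draws = mc_draws, seed = seed)
    }
  }
  tot388 <- counts_by[["Total"]][["388"]]
  tot521 <- counts_by[["Total"]][["521"]]
  if (tot388$n_ancestral + tot388$n_variant > 0 &&
      tot521$n_ancestral + tot521$n_variant > 0)
    tests$maf_388_vs_521 <- compare_variant_mafs(tot388, tot521)

  p_or_na <- function(lst, keys)
    vapply(keys, function(k)
      if (!is.null(lst[[k]])) lst[[k]]$p_value else NA_real_, numeric(1))
  maf_labels <- unique(maf$variant)

  structure(list(
    groups = grp,
    n_samples = nrow(table$samples),
    maf = maf, hwe = hwe, em = em, haplotypes = haplotypes,
    phenotypes = phenotypes, tests = tests,
    maf_group_p = p_or_na(tests$maf_across_groups, maf_labels),
    haplotype_group_p = p_or_na(tests$haplotype_across_groups, hap_names()),
    phenotype_group_p = p_or_na(tests$phenotype_across_groups,
                                c("normal", "intermediate", "low")),
    warnings = warnings), class = "slcohap_analysis")
}

#' @export
print.slcohap_analysis <- function(x, ...) {
  cat(sprintf("<slcohap_analysis> %d samples, groups: %s\n", x$n_samples,
              paste(x$groups, collapse = ", ")))
  tot <- x$maf[x$maf$scope == "Total", ]
  for (i in seq_len(nrow(tot)))
    cat(sprintf("  %s MAF (Total): %.4f (%s)\n", tot$variant[i], tot$maf[i],
                tot$minor_allele[i]))
  ph <- x$phenotypes[x$phenotypes$group == "Total", ]
  cat(sprintf("  phenotypes (Total): normal %.2f%%, intermediate %.2f%%, low %.2f%%\n",
              ph$pct_normal, ph$pct_intermediate, ph$pct_low))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(names(h)))
}

write_manifest <- function(out_dir, seed, inputs = character(0),
                           outputs = character(0), timings = list(),
                           warnings = character(0), config = NULL) {
  manifest <- list(
    tool = "slcohap",
    version = as.character(utils::packageVersion("slcohap")),
    seed = seed,
    config = config,
    input_digests = if (length(inputs)) as.list(md5_of(inputs)) else NULL,
    output_digests = if (length(outputs)) as.list(md5_of(outputs)) else NULL,
    timings_sec = timings,
    warnings = warnings)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Parse a cohort simulation config file
#'
#' JSON with fields `seed` and `groups`: each group an object with `label`,
#' `n_samples`, `hap_freqs` (4-vector over *1a, *1b, *5, *15) and optional
#' `inbreeding_f`, `missing_rate`.
#'
#' @param path JSON file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_classed("slcohap_config_error",
                                 "cannot parse config: ",
                                 conditionMessage(e)))
  if (is.null(cfg$groups))
    stop_classed("slcohap_config_error", "config lacks a groups field")
  groups <- lapply(seq_len(nrow(cfg$groups)), function(i) {
    g <- cfg$groups[i, ]
    tryCatch(
      group_config(g$label, g$n_samples, unlist(g$hap_freqs),
                   inbreeding_f = if (!is.null(g$inbreeding_f) &&
                                      !is.na(g$inbreeding_f))
                     g$inbreeding_f else 0,
                   missing_rate = if (!is.null(g$missing_rate) &&
                                      !is.na(g$missing_rate))
                     g$missing_rate else 0),
      error = function(e)
        stop_classed("slcohap_config_error", "bad group config: ",
                     conditionMessage(e)))
  })
  cohort_config(groups, seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
}

#' Simulate a cohort and write it with a run manifest
#'
#' @param preset built-in preset name ([qatari_preset()]); one of `preset`
#'   or `config` is required.
#' @param config path to a config JSON ([read_cohort_config()]) or a
#'   [cohort_config()] object.
#' @param seed optional root-seed override.
#' @param out_dir output directory.
#' @return Invisibly, the paths written (cohort files plus manifest).
#' @export
cmd_simulate <- function(preset = NULL, config = NULL, seed = NULL,
                         out_dir = ".") {
  t0 <- proc.time()[["elapsed"]]
  cfg <- if (!is.null(preset)) {
    if (!preset %in% c("hf-table", "maf-consistent"))
      stop_classed("slcohap_config_error", "unknown preset \"", preset,
                   "\"; available: hf-table, maf-consistent")
    qatari_preset(preset)
  } else if (is.character(config)) {
    read_cohort_config(config)
  } else if (inherits(config, "cohort_config")) {
    config
  } else {
    stop_classed("slcohap_config_error",
                 "one of preset or config is required")
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cohort <- generate_cohort(cfg)
  paths <- write_cohort(cohort, out_dir)
  manifest <- write_manifest(
    out_dir, seed = cfg$seed, outputs = paths,
    timings = list(total = proc.time()[["elapsed"]] - t0),
    config = list(preset = cfg$preset, groups = lapply(cfg$groups, unclass)))
  invisible(c(paths, manifest = manifest))
}

#' Analyze a VCF + metadata pair and write reports with a run manifest
#'
#' @param vcf path to the genotype VCF.
#' @param metadata path to the sample-group table.
#' @param out_dir output directory for the report files.
#' @param mc_draws,seed,hwe_method passed to [analyze_cohort()].
#' @return Invisibly, the [analyze_cohort()] result (reports and manifest
#'   are written to `out_dir`).
#' @export
cmd_analyze <- function(vcf, metadata, out_dir = ".", mc_draws = 10000L,
                        seed = 1L, hwe_method = "exact") {
  t0 <- proc.time()[["elapsed"]]
  groups <- read_sample_groups(metadata)
  table <- tryCatch(
    read_vcf_genotypes(vcf, groups = groups),
    error = function(e) {
      msg <- conditionMessage(e)
      if (grepl("variant not found|REF/ALT mismatch|multi-allelic", msg))
        stop_classed("slcohap_variant_error", msg)
      stop(e)
    })
  t_read <- proc.time()[["elapsed"]] - t0
  results <- analyze_cohort(table, mc_draws = mc_draws, seed = seed,
                            hwe_method = hwe_method)
  t_analyze <- proc.time()[["elapsed"]] - t0 - t_read
  paths <- write_frequency_report(results, out_dir)
  write_manifest(out_dir, seed = seed, inputs = c(vcf, metadata),
                 outputs = paths,
                 timings = list(read = t_read, analyze = t_analyze,
                                total = proc.time()[["elapsed"]] - t0),
                 warnings = results$warnings)
  invisible(results)
}

#' Verify the packaged published tables and their identities
#'
#' Runs [check_reference_tables()]; any failed identity raises a
#' `slcohap_check_failure` condition (the CLI maps it to exit code 5).
#' The known African intermediate typo row is informational, never a
#' failure.
#'
#' @return The check data.frame, invisibly on success.
#' @export
cmd_check_tables <- function() {
  checks <- check_reference_tables()
  failed <- checks$identity[!is.na(checks$pass) & !checks$pass]
  if (length(failed))
    stop_classed("slcohap_check_failure",
                 "reference-table identities failed: ",
                 paste(failed, collapse = ", "))
  invisible(checks)
}
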