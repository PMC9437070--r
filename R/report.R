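# Report formatting and writing: TSV tables shaped like the published MAF /
# haplotype / phenotype tables, plus a full-precision JSON.

#' Round half away from zero
#'
#' Fixed-precision display rounding used throughout the reports (0.24143 at
#' 2 digits prints as "0.24"; .5 cases round away from zero, matching the
#' count reconstruction rule rather than banker's rounding).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric, rounded.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"),
                                 round_half_up(x, digits)))
}

#' Write analysis reports as TSV tables plus a JSON document
#'
#' Emits the reporting surface of [analyze_cohort()]: a MAF table
#' (locus x scope with HWE and cross-group p-values), a haplotype-frequency
#' table, and a phenotype table, with deterministic column order (Total
#' first, then the configured groups) and fixed display rounding
#' (2 decimals for frequencies and percentages, 4 for p-values, both
#' configurable). The JSON carries full precision.
#'
#' @param results result of [analyze_cohort()].
#' @param out_dir output directory (created if needed).
#' @param freq_digits,pct_digits,p_digits display precision.
#' @return Invisibly, named vector of written paths.
#' @export
write_frequency_report <- function(results, out_dir, freq_digits = 2,
                                   pct_digits = 2, p_digits = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scopes <- c("Total", results$groups)

  maf_path <- file.path(out_dir, "maf_table.tsv")
  m <- results$maf
  maf_wide <- data.frame(variant = unique(m$variant))
  for (sc in scopes) {
    v <- m$maf[m$scope == sc][match(maf_wide$variant,
                                    m$variant[m$scope == sc])]
    maf_wide[[sc]] <- fmt_num(v, freq_digits)
  }
  maf_wide$p_value <- fmt_num(
    results$maf_group_p[match(maf_wide$variant,
                              names(results$maf_group_p))], p_digits)
  utils::write.table(maf_wide, maf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  hap_path <- file.path(out_dir, "haplotype_table.tsv")
  h <- results$haplotypes
  hap_wide <- data.frame(haplotype = h$haplotype)
  for (sc in scopes) {
    v <- h[[paste0("pct_", sc)]]
    if (is.null(v)) v <- rep(NA_real_, nrow(h))
    hap_wide[[sc]] <- fmt_num(v, pct_digits)
  }
  hap_wide$p_value <- fmt_num(
    results$haplotype_group_p[match(hap_wide$haplotype,
                                    names(results$haplotype_group_p))],
    p_digits)
  utils::write.table(hap_wide, hap_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  phe_path <- file.path(out_dir, "phenotype_table.tsv")
  p <- results$phenotypes
  phe_wide <- data.frame(phenotype = c("normal", "intermediate", "low"))
  for (sc in scopes) {
    row <- p[p$group == sc, ]
    phe_wide[[sc]] <- fmt_num(
      c(row$pct_normal, row$pct_intermediate, row$pct_low), pct_digits)
  }
  phe_wide$p_value <- fmt_num(
    results$phenotype_group_p[match(phe_wide$phenotype,
                                    names(results$phenotype_group_p))],
    p_digits)
  utils::write.table(phe_wide, phe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(results_to_json(results), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(maf = maf_path, haplotypes = hap_path, phenotypes = phe_path,
              json = json_path))
}

test_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  list(method = x$method, statistic = x$statistic, df = x$df,
       p_value = x$p_value, mc_se = x$mc_se, note = x$note)
}

results_to_json <- function(results) {
  list(
    groups = results$groups,
    n_samples = results$n_samples,
    maf = results$maf,
    hwe = results$hwe,
    haplotypes = results$haplotypes,
    em = lapply(results$em, function(fit)
      list(f = as.list(fit$f), loglik = fit$loglik, n_iter = fit$n_iter,
           converged = fit$converged, identifiable = fit$identifiable,
           n = fit$n)),
    phenotypes = results$phenotypes,
    tests = list(
      maf_across_groups = lapply(results$tests$maf_across_groups,
                                 test_to_list),
      haplotype_across_groups = lapply(
        results$tests$haplotype_across_groups, test_to_list),
      phenotype_across_groups = lapply(
        results$tests$phenotype_across_groups, test_to_list),
      maf_388_vs_521 = test_to_list(results$tests$maf_388_vs_521)),
    warnings = results$warnings)
}
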