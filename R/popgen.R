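# Allele counting, minor allele frequency, Hardy-Weinberg exact test, and
# reconstruction of integer counts from published percentages.

new_test_result <- function(method, p_value, statistic = NA_real_,
                            df = NA_integer_, mc_se = NA_real_, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, mc_se = mc_se, note = note),
            class = "slcohap_test")
}

#' @export
print.slcohap_test <- function(x, ...) {
  cat(sprintf("<test:%s> p = %.4g", x$method, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(", statistic = %.4g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %d", x$df))
  if (!is.na(x$mc_se)) cat(sprintf(", mc_se = %.2g", x$mc_se))
  cat("\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Count ancestral and variant chromosomes at one locus
#'
#' Chromosome counts use only samples genotyped at the locus: the denominator
#' is 2 x (non-missing samples), so frequencies refer to chromosomes actually
#' observed. Samples missing the locus are tallied in `n_missing_samples`.
#'
#' @param table a [genotype_table()].
#' @param variant which locus: `"388"` / `"521"`, or an rsID matching one of
#'   the table's variant specs.
#' @param group group label or "Total".
#' @return An `allele_counts` object: the variant spec, group, integer
#'   chromosome counts `n_ancestral` / `n_variant`, `n_missing_samples` and
#'   `n_samples` (non-missing samples counted).
#' @export
allele_counts <- function(table, variant = c("388", "521"), group = "Total") {
  if (length(variant) > 1L) variant <- variant[1]
  spec_idx <- switch(variant,
    "388" = 1L, "521" = 2L,
    {
      hit <- which(vapply(table$variants, function(v) v$rsid == variant,
                          logical(1)))
      if (length(hit) != 1L)
        stop("variant must be \"388\", \"521\" or a known rsID", call. = FALSE)
      hit
    })
  col <- if (spec_idx == 1L) "dosage_388" else "dosage_521"
  rows <- group_rows(table, group)
  d <- table$samples[[col]][rows]
  miss <- sum(is.na(d))
  d <- d[!is.na(d)]
  structure(
    list(variant = table$variants[[spec_idx]], group = group,
         n_variant = as.integer(sum(d)),
         n_ancestral = as.integer(2L * length(d) - sum(d)),
         n_missing_samples = as.integer(miss),
         n_samples = length(d)),
    class = "allele_counts")
}

#' Minor allele frequency of an allele-count pair
#'
#' The minor allele is the second-most-common allele; on an exact 50/50 tie
#' the cDNA variant allele is reported as minor (documented, arbitrary).
#'
#' @param counts an [allele_counts()] object.
#' @return List with `frequency` (minor-allele frequency on observed
#'   chromosomes), `minor_allele` (nucleotide, cDNA orientation) and
#'   `n_chromosomes`.
#' @export
minor_allele_frequency <- function(counts) {
  tot <- counts$n_ancestral + counts$n_variant
  if (tot == 0L) stop("no observed chromosomes", call. = FALSE)
  if (counts$n_variant <= counts$n_ancestral)
    list(frequency = counts$n_variant / tot,
         minor_allele = counts$variant$variant_allele,
         n_chromosomes = tot)
  else
    list(frequency = counts$n_ancestral / tot,
         minor_allele = counts$variant$ancestral_allele,
         n_chromosomes = tot)
}

# log P(n_het = h | allele counts nA, na) under HWE, conditional on alleles:
# P = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!  with nAA=(nA-h)/2 etc.
hwe_log_prob <- function(h, nA, na) {
  n <- (nA + na) / 2
  nAA <- (nA - h) / 2
  naa <- (na - h) / 2
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
    h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(nA + na + 1)
}

#' Exact conditional Hardy-Weinberg test for a biallelic locus
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts (same parity), computes each configuration's conditional probability
#' under Hardy-Weinberg equilibrium, and sums the probabilities no larger than
#' that of the observed configuration (two-sided exact test, no mid-p).
#'
#' @param g genotype counts: either a length-3 vector
#'   `(n_hom_ancestral, n_het, n_hom_variant)` or three separate arguments.
#' @param n_het,n_hom_variant optional, when `g` is given as the first count.
#' @param method `"exact"` (default) or `"chisq"` for the 1-df goodness-of-fit
#'   approximation.
#' @return A test result with `method` `"hwe_exact"` (or `"chi_square"`) and
#'   the p-value; monomorphic data give p = 1.
#' @examples
#' hwe_exact_test(c(0, 0, 25))$p_value  # 1: only one attainable configuration
#' @export
hwe_exact_test <- function(g, n_het = NULL, n_hom_variant = NULL,
                           method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (!is.null(n_het)) g <- c(g, n_het, n_hom_variant)
  g <- as.integer(g)
  if (length(g) != 3L || any(g < 0L))
    stop("genotype counts must be 3 non-negative integers", call. = FALSE)
  n <- sum(g)
  if (n == 0L) stop("no genotyped samples", call. = FALSE)
  nA <- 2L * g[1] + g[2]
  na <- 2L * g[3] + g[2]
  if (method == "chisq") {
    p <- (nA / (2 * n))
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(new_test_result("chi_square", 1, statistic = 0,
                                            df = 1L))
    stat <- sum((g - e)^2 / e)
    return(new_test_result("chi_square", pchisq(stat, 1, lower.tail = FALSE),
                           statistic = stat, df = 1L))
  }
  hs <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  lp <- hwe_log_prob(hs, nA, na)
  lp_obs <- hwe_log_prob(g[2], nA, na)
  p <- sum(exp(lp[lp <= lp_obs + 1e-12]))
  new_test_result("hwe_exact", min(1, max(0, p)))
}

#' Recover integer counts behind printed percentages
#'
#' Published tables print percentages over known denominators; multiplying
#' back and rounding to the nearest integer (half away from zero) recovers the
#' underlying counts exactly whenever the printed value really is
#' `100 * count / denominator` rounded to the printed precision. Cells whose
#' back-calculated value sits more than 0.5 from an integer are flagged: they
#' cannot come from any integer count and indicate a typo in the source table.
#'
#' @param percentages numeric vector in \[0, 100\].
#' @param denominators positive integer vector, recycled against
#'   `percentages`.
#' @return List with `counts` (integer), `residuals`
#'   (`|count - p*N/100|`), and `flagged` (logical, residual > 0.5).
#' @examples
#' reconstruct_counts(c(3.58, 4.65, 1.32), c(1174, 774, 152))$counts
#' @export
reconstruct_counts <- function(percentages, denominators) {
  stopifnot(all(percentages >= 0), all(percentages <= 100),
            all(denominators > 0))
  x <- percentages * denominators / 100
  counts <- as.integer(sign(x) * floor(abs(x) + 0.5))
  res <- abs(counts - x)
  list(counts = counts, residuals = res, flagged = res > 0.5)
}
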