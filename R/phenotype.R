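# CPIC diplotype -> OATP1B1 transport-phenotype classification.
# Normal = no reduced-function allele, intermediate = one, low = two.
# Reduced-function star alleles are those carrying 521C (*5 and *15), so the
# phenotype is a function of the 521C dosage alone; the diplotype route is
# retained and must agree (a tested invariant).

reduced_alleles <- function() c("*5", "*15")

#' Phenotype class of a star-allele diplotype
#'
#' @param d a `diplotype` from [assign_diplotype()], or a character pair of
#'   star-allele names.
#' @return "normal", "intermediate" or "low" according to the number of
#'   reduced-function alleles (*5, *15) in the pair.
#' @examples
#' phenotype_of(c("*1a", "*1b"))  # "normal"
#' phenotype_of(c("*1b", "*15"))  # "intermediate"
#' phenotype_of(c("*5", "*15"))   # "low"
#' @export
phenotype_of <- function(d) {
  alleles <- if (inherits(d, "diplotype")) d$alleles else as.character(d)
  stopifnot(length(alleles) == 2L, all(alleles %in% hap_names()))
  c("normal", "intermediate", "low")[
    sum(alleles %in% reduced_alleles()) + 1L]
}

#' Phenotype class from the 521C dosage
#'
#' Because both reduced-function alleles carry 521C and both functional
#' alleles carry 521T, the phenotype is determined by the unphased c.521
#' genotype alone: 0 copies of C is normal, 1 intermediate, 2 low. This is
#' the route used for headline phenotype frequencies (no dependence on phase
#' inference).
#'
#' @param dosage_521 integer 0..2; missing is an error (filter upstream).
#' @return "normal", "intermediate" or "low".
#' @export
phenotype_from_dosage <- function(dosage_521) {
  if (any(is.na(dosage_521)))
    stop("missing 521 dosage: exclude before phenotype calling",
         call. = FALSE)
  stopifnot(all(dosage_521 %in% 0:2))
  c("normal", "intermediate", "low")[dosage_521 + 1L]
}

#' Per-group OATP1B1 phenotype counts and frequencies
#'
#' Classifies every sample genotyped at c.521 via [phenotype_from_dosage()]
#' and tabulates counts and percentages per group and pooled ("Total").
#' Samples missing the c.521 genotype are excluded and reported.
#'
#' @param table a [genotype_table()].
#' @return data.frame, one row per group plus "Total": `n_normal`,
#'   `n_intermediate`, `n_low`, `n_excluded`, `n_classified` and percentage
#'   columns (`pct_*`, of classified samples).
#' @export
phenotype_frequencies <- function(table) {
  scopes <- c("Total", table$groups)
  rows <- lapply(scopes, function(g) {
    d <- table$samples$dosage_521[group_rows(table, g)]
    excl <- sum(is.na(d))
    d <- d[!is.na(d)]
    cls <- tabulate(d + 1L, nbins = 3L)
    n_cl <- length(d)
    data.frame(group = g,
               n_normal = cls[1], n_intermediate = cls[2], n_low = cls[3],
               n_excluded = excl, n_classified = n_cl,
               pct_normal = if (n_cl) 100 * cls[1] / n_cl else NA_real_,
               pct_intermediate = if (n_cl) 100 * cls[2] / n_cl else NA_real_,
               pct_low = if (n_cl) 100 * cls[3] / n_cl else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phenotype nomenclature mapping
#'
#' The package reports the 2014-era terms normal/intermediate/low function;
#' later CPIC nomenclature uses normal/decreased/poor. This table maps
#' between the two for downstream relabelling.
#'
#' @return data.frame with columns `label_2014` and `label_current`.
#' @export
phenotype_label_map <- function() {
  data.frame(
    label_2014 = c("normal", "intermediate", "low"),
    label_current = c("normal function", "decreased function",
                      "poor function"),
    stringsAsFactors = FALSE)
}
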