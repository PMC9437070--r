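#' Construct a genotype table
#'
#' The central data container: one row per sample with its group label and
#' the dosages of the cDNA variant alleles 388G and 521C (0, 1, 2 or NA for a
#' missing genotype), plus the pair of variant specs the dosages refer to.
#'
#' @param samples data.frame with columns `sample_id`, `group`, `dosage_388`,
#'   `dosage_521`. Dosages must be 0, 1, 2 or NA.
#' @param variants list of two [variant_spec()]s (c.388A>G first).
#' @param groups optional character vector fixing the group order; defaults to
#'   order of first appearance. Samples with `NA` group are allowed (e.g.
#'   before metadata attachment) but excluded from per-group analyses.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, variants = default_variant_specs(),
                           groups = NULL) {
  need <- c("sample_id", "group", "dosage_388", "dosage_521")
  if (!all(need %in% names(samples)))
    stop("samples must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  samples <- samples[, need]
  rownames(samples) <- NULL
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in genotype table", call. = FALSE)
  for (col in c("dosage_388", "dosage_521")) {
    d <- samples[[col]]
    if (!all(is.na(d) | d %in% 0:2))
      stop(col, " must be 0, 1, 2 or NA", call. = FALSE)
    samples[[col]] <- as.integer(d)
  }
  if (is.null(groups))
    groups <- unique(samples$group[!is.na(samples$group)])
  bad <- setdiff(samples$group[!is.na(samples$group)], groups)
  if (length(bad))
    stop("sample group(s) not in configured groups: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  stopifnot(length(variants) == 2L,
            inherits(variants[[1]], "variant_spec"),
            inherits(variants[[2]], "variant_spec"))
  structure(list(variants = variants, samples = samples,
                 groups = as.character(groups)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples, %d groups (%s)\n",
              nrow(x$samples), length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  variants: %s, %s\n",
              x$variants[[1]]$rsid, x$variants[[2]]$rsid))
  invisible(x)
}

# Rows of the sample table belonging to `group` ("Total" pools all groups;
# samples with NA group never count).
group_rows <- function(table, group) {
  s <- table$samples
  if (identical(group, "Total")) which(!is.na(s$group))
  else {
    if (!group %in% table$groups)
      stop("unknown group label: ", group, call. = FALSE)
    which(!is.na(s$group) & s$group == group)
  }
}

#' Cross-tabulate the two-locus genotype classes of a group
#'
#' Builds the 3x3 table n[i, j] of samples with i copies of 388G and j copies
#' of 521C (i, j in 0..2), the sufficient statistic for haplotype-frequency
#' EM. Samples missing either locus are excluded and tallied.
#'
#' @param table a [genotype_table()].
#' @param group group label, or "Total" to pool all groups.
#' @return A 3x3 integer matrix with dimnames `g388` = 0:2, `g521` = 0:2 and
#'   attributes `group` and `n_missing` (samples dropped for missingness at
#'   either locus).
#' @export
two_locus_counts <- function(table, group = "Total") {
  rows <- group_rows(table, group)
  s <- table$samples[rows, ]
  ok <- !is.na(s$dosage_388) & !is.na(s$dosage_521)
  n <- matrix(0L, 3, 3, dimnames = list(g388 = 0:2, g521 = 0:2))
  if (any(ok)) {
    tab <- table(factor(s$dosage_388[ok], levels = 0:2),
                 factor(s$dosage_521[ok], levels = 0:2))
    n[] <- as.integer(tab)
  }
  attr(n, "group") <- group
  attr(n, "n_missing") <- sum(!ok)
  n
}
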