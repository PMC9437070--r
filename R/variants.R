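#' Describe one of the two SLCO1B1 variants
#'
#' A variant spec ties an rsID to its genomic location and to the cDNA-oriented
#' ancestral/variant alleles used throughout the package. Alleles are given in
#' cDNA orientation (the orientation in which c.388A>G and c.521T>C are named),
#' and the mapping onto VCF REF/ALT is handled explicitly at read time so that
#' strand or allele mix-ups fail loudly instead of silently flipping dosages.
#'
#' @param rsid dbSNP identifier, e.g. "rs2306283".
#' @param chrom chromosome name as it appears in the VCF.
#' @param pos 1-based genomic coordinate.
#' @param cdna_label cDNA-level name, e.g. "c.388A>G".
#' @param ancestral_allele,variant_allele single nucleotides in cDNA
#'   orientation; must differ.
#' @param effect_label free-text functional annotation
#'   ("increased transport" / "reduced transport").
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(rsid, chrom, pos, cdna_label,
                         ancestral_allele, variant_allele,
                         effect_label = "") {
  stopifnot(is.character(rsid), length(rsid) == 1L,
            length(pos) == 1L, pos >= 1)
  nts <- c("A", "C", "G", "T")
  if (!ancestral_allele %in% nts || !variant_allele %in% nts)
    stop("alleles must be single nucleotides in {A,C,G,T}", call. = FALSE)
  if (ancestral_allele == variant_allele)
    stop("ancestral and variant allele must differ", call. = FALSE)
  structure(
    list(rsid = rsid, chrom = as.character(chrom), pos = as.integer(pos),
         cdna_label = cdna_label,
         ancestral_allele = ancestral_allele,
         variant_allele = variant_allele,
         effect_label = effect_label),
    class = "variant_spec")
}

#' Default variant specifications for the two-SNP SLCO1B1 system
#'
#' c.388A>G (rs2306283, increased transport) and c.521T>C (rs4149056, reduced
#' transport), with GRCh37 coordinates. Coordinates are carried as data and
#' used only as a fallback when a VCF record lacks the rsID.
#'
#' @return A named list with elements `v388` and `v521`, each a
#'   [variant_spec()].
#' @export
default_variant_specs <- function() {
  list(
    v388 = variant_spec("rs2306283", "12", 21329738L, "c.388A>G",
                        ancestral_allele = "A", variant_allele = "G",
                        effect_label = "increased transport"),
    v521 = variant_spec("rs4149056", "12", 21331549L, "c.521T>C",
                        ancestral_allele = "T", variant_allele = "C",
                        effect_label = "reduced transport")
  )
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s (%s) %s:%d %s>%s [%s]\n",
              x$rsid, x$cdna_label, x$chrom, x$pos,
              x$ancestral_allele, x$variant_allele, x$effect_label))
  invisible(x)
}

#' Map a two-locus allele combination to its SLCO1B1 star allele
#'
#' The four haplotypes over c.388 (A/G) and c.521 (T/C) carry fixed star
#' names: 388A+521T is *1a (reference), 388G+521T is *1b, 388A+521C is *5 and
#' 388G+521C is *15. Alleles carrying 521C (*5, *15) are reduced-function.
#'
#' @param a388 nucleotide at c.388, "A" or "G".
#' @param a521 nucleotide at c.521, "T" or "C".
#' @return A `star_allele` object: name, the two alleles, and
#'   `functional_class` ("functional" or "reduced").
#' @examples
#' star_allele("A", "T")$name   # "*1a"
#' star_allele("G", "C")$name   # "*15"
#' @export
star_allele <- function(a388, a521) {
  if (!a388 %in% c("A", "G")) stop("a388 must be A or G", call. = FALSE)
  if (!a521 %in% c("T", "C")) stop("a521 must be T or C", call. = FALSE)
  name <- if (a388 == "A" && a521 == "T") "*1a"
          else if (a388 == "G" && a521 == "T") "*1b"
          else if (a388 == "A" && a521 == "C") "*5"
          else "*15"
  structure(
    list(name = name, allele_388 = a388, allele_521 = a521,
         functional_class = if (a521 == "C") "reduced" else "functional"),
    class = "star_allele")
}

# Haplotype bookkeeping used everywhere: index 1..4 = *1a, *1b, *5, *15.
# carries_388G / carries_521C give each haplotype's allele content.
hap_names <- function() c("*1a", "*1b", "*5", "*15")
hap_carries_388G <- function() c(FALSE, TRUE, FALSE, TRUE)
hap_carries_521C <- function() c(FALSE, FALSE, TRUE, TRUE)

#' Table of the four star alleles
#'
#' @return A data.frame with one row per star allele: name, alleles at both
#'   positions, and functional class.
#' @export
star_allele_table <- function() {
  data.frame(
    name = hap_names(),
    allele_388 = ifelse(hap_carries_388G(), "G", "A"),
    allele_521 = ifelse(hap_carries_521C(), "C", "T"),
    functional_class = ifelse(hap_carries_521C(), "reduced", "functional"),
    stringsAsFactors = FALSE)
}
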