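# VCF genotype ingestion (via vcfR) and sample-group metadata reading.

#' Default cDNA-to-VCF allele orientation map
#'
#' States, per rsID, which VCF allele carries the cDNA variant allele.
#' `"ALT"` (the default for both loci) means REF must equal the spec's
#' ancestral allele and ALT its variant allele; `"REF"` means the reverse,
#' in which case variant dosage is `2 - (ALT count)`. Any other REF/ALT
#' combination is a hard error — the reader never flips alleles silently.
#'
#' @return Named character vector, rsID -> "ALT" or "REF".
#' @export
default_allele_map <- function() {
  c(rs2306283 = "ALT", rs4149056 = "ALT")
}

parse_gt_dosage <- function(gt) {
  # GT strings like 0/0, 0|1, ./., possibly with trailing subfields
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    if (length(x) != 2L || any(x == ".")) NA_integer_
    else sum(as.integer(x))
  }, integer(1))
}

find_vcf_record <- function(fix, spec) {
  hit <- which(!is.na(fix[, "ID"]) & fix[, "ID"] == spec$rsid)
  if (length(hit) == 0L)
    hit <- which(fix[, "CHROM"] == spec$chrom &
                 as.integer(fix[, "POS"]) == spec$pos)
  if (length(hit) == 0L)
    stop("variant not found in VCF: ", spec$rsid, " (", spec$chrom, ":",
         spec$pos, ")", call. = FALSE)
  if (length(hit) > 1L)
    stop("multiple VCF records match ", spec$rsid, call. = FALSE)
  hit
}

#' Read the two SLCO1B1 genotypes from a VCF
#'
#' Locates each variant by rsID (fallback: chromosome and position), checks
#' REF/ALT against the declared cDNA orientation, and converts GT fields to
#' dosages of the cDNA variant allele. Missing genotypes (`./.`) become NA at
#' that locus only. Sample order is preserved.
#'
#' @param vcf_path path to a VCF v4.x file (GT field required).
#' @param specs pair of [variant_spec()]s (c.388A>G first).
#' @param allele_map orientation map as from [default_allele_map()].
#' @param groups optional mapping from [read_sample_groups()]; when given,
#'   group labels are attached and VCF samples absent from the metadata are
#'   excluded with a warning.
#' @return A [genotype_table()]. Without `groups`, all group labels are NA.
#' @export
read_vcf_genotypes <- function(vcf_path, specs = default_variant_specs(),
                               allele_map = default_allele_map(),
                               groups = NULL) {
  stopifnot(length(specs) == 2L)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no genotype (GT) data", call. = FALSE)

  dosages <- lapply(specs, function(spec) {
    i <- find_vcf_record(fix, spec)
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt))
      stop("multi-allelic record at ", spec$rsid,
           ": split the VCF before reading", call. = FALSE)
    orient <- allele_map[[spec$rsid]]
    if (is.null(orient) || !orient %in% c("ALT", "REF"))
      stop("allele_map must assign \"ALT\" or \"REF\" to ", spec$rsid,
           call. = FALSE)
    want_ref <- if (orient == "ALT") spec$ancestral_allele else
      spec$variant_allele
    want_alt <- if (orient == "ALT") spec$variant_allele else
      spec$ancestral_allele
    if (ref != want_ref || alt != want_alt)
      stop("REF/ALT mismatch at ", spec$rsid, ": VCF has ", ref, ">", alt,
           ", allele map expects ", want_ref, ">", want_alt,
           " (refusing to flip alleles silently)", call. = FALSE)
    alt_count <- parse_gt_dosage(gt[i, ])
    if (orient == "ALT") alt_count else 2L - alt_count
  })

  samples <- data.frame(sample_id = colnames(gt),
                        group = NA_character_,
                        dosage_388 = dosages[[1]],
                        dosage_521 = dosages[[2]],
                        stringsAsFactors = FALSE)
  tbl <- genotype_table(samples, variants = specs,
                        groups = character(0))
  if (!is.null(groups)) tbl <- attach_sample_groups(tbl, groups)
  tbl
}

#' Read the sample-to-ancestry-group metadata table
#'
#' @param path delimited text file (tab or comma separated) with header
#'   columns `sample_id` and `group`.
#' @return Named character vector mapping sample_id to group label, with the
#'   groups' first-appearance order in attribute `"groups"`.
#' @export
read_sample_groups <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty metadata file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have header columns sample_id and group",
         call. = FALSE)
  if (nrow(df) == 0L) stop("metadata file has no rows: ", path, call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  m <- setNames(df$group, df$sample_id)
  attr(m, "groups") <- unique(df$group)
  m
}

#' Attach group labels from a metadata mapping to a genotype table
#'
#' VCF samples absent from the metadata are excluded with one warning giving
#' the count; the number is also recorded in attribute `"n_unmatched"`.
#'
#' @param table a [genotype_table()].
#' @param groups mapping from [read_sample_groups()].
#' @return The relabelled [genotype_table()].
#' @export
attach_sample_groups <- function(table, groups) {
  s <- table$samples
  matched <- s$sample_id %in% names(groups)
  if (any(!matched))
    warning(sum(!matched), " VCF sample(s) absent from metadata; excluded",
            call. = FALSE)
  s <- s[matched, , drop = FALSE]
  s$group <- unname(groups[s$sample_id])
  order_groups <- attr(groups, "groups")
  if (is.null(order_groups)) order_groups <- unique(s$group)
  out <- genotype_table(s, variants = table$variants,
                        groups = intersect(order_groups, s$group))
  attr(out, "n_unmatched") <- sum(!matched)
  out
}
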