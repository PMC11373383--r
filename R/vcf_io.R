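#' Read a VCF into a haplotype-level SNP matrix
#'
#' Builds the ternary haplotype matrix used for scanning from a VCF (plain
#' or bgzipped).  Only biallelic SNP records are used; multiallelic records
#' are skipped with a reported count.  Genotypes are expanded to haplotypes
#' (phase is not required -- allele counts, not phase, feed the DAF), and
#' missing genotype calls become the missing state.
#'
#' Polarization: by default the ALT allele is treated as derived.  When an
#' ancestral-allele INFO tag is present (`AA=`), records whose ancestral
#' allele equals ALT are flipped so that 1 always means derived.  This
#' convention is logged; simulated training data are intrinsically
#' polarized, empirical data generally are not.
#'
#' @param path VCF file.
#' @param chrom optional chromosome name; defaults to the first seen, and
#'   records on other chromosomes are dropped.
#' @param quiet suppress the polarization/skip messages.
#' @return an [snp_matrix] with 1-based bp positions and `chrom` set.
#' @export
read_vcf_windows <- function(path, chrom = NULL, quiet = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_fmt("read_vcf_windows requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  keep_chrom <- if (is.null(chrom)) unname(fix[1L, "CHROM"]) else chrom
  on_chrom <- fix[, "CHROM"] == keep_chrom
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L & fix[, "ALT"] != "."
  n_multi <- sum(on_chrom & !biallelic)
  if (n_multi > 0L && !quiet)
    message(sprintf("read_vcf_windows: skipped %d non-biallelic-SNP records",
                    n_multi))
  keep <- on_chrom & biallelic
  if (!any(keep)) stop_fmt("no biallelic SNP records on chromosome %s",
                           keep_chrom)
  pos <- as.integer(fix[keep, "POS"])
  if (is.unsorted(pos)) stop_fmt("VCF positions are not sorted")

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ploidy <- max(lengths(strsplit(gt[1L, ], "[|/]")))
  hap <- matrix(NA_integer_, nrow = ncol(gt) * ploidy, ncol = nrow(gt))
  for (s in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, s], "[|/]")
    for (p in seq_len(ploidy)) {
      a <- vapply(parts, function(x) if (length(x) >= p) x[p] else ".", "")
      ai <- suppressWarnings(as.integer(a))  # "." -> NA (missing)
      hap[(s - 1L) * ploidy + p, ] <- ai
    }
  }

  # polarize by AA tag where available
  info <- fix[keep, "INFO"]
  aa <- sub(".*\\bAA=([^;]+).*", "\\1", info)
  aa[!grepl("\\bAA=", info)] <- NA
  alt <- fix[keep, "ALT"]
  flip <- !is.na(aa) & toupper(aa) == toupper(alt)
  if (any(flip)) {
    hap[, flip] <- 1L - hap[, flip]
    if (!quiet)
      message(sprintf(
        "read_vcf_windows: polarized %d records by AA tag (ALT ancestral)",
        sum(flip)))
  } else if (!quiet) {
    message("read_vcf_windows: no usable AA tags; treating ALT as derived")
  }
  snp_matrix(hap, pos, chrom = keep_chrom)
}
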