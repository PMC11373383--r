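#' SNP window container
#'
#' An `snp_matrix` holds a window of haplotype data: an N x W matrix of
#' allele states (rows are sampled haplotypes, columns are segregating
#' sites) together with the W site coordinates.  States are coded
#' `0` (ancestral), `1` (derived) and `NA` (missing).  Coordinates are
#' fractional positions in `[0, 1]` for coalescent-simulator output and
#' 1-based base-pair positions for VCF input.
#'
#' @param alleles integer (or coercible) N x W matrix with entries 0, 1 or NA.
#' @param positions numeric vector of length W, nondecreasing.
#' @param label optional class label, `"neutral"` or `"sweep"`.
#' @param scenario optional scenario tag (e.g. `"D1"`).
#' @param chrom optional chromosome / contig name.
#'
#' @return an object of class `snp_matrix`.
#' @export
#' @examples
#' m <- snp_matrix(rbind(c(0, 1, 1), c(1, 1, 0)), c(0.1, 0.5, 0.9))
#' compute_daf(m)
snp_matrix <- function(alleles, positions, label = NULL, scenario = NULL,
                       chrom = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 1L || ncol(alleles) < 1L)
    stop_fmt("snp_matrix needs at least one sample and one SNP")
  if (length(positions) != ncol(alleles))
    stop_fmt("positions length (%d) != number of SNPs (%d)",
             length(positions), ncol(alleles))
  if (is.unsorted(positions, na.rm = FALSE))
    stop_fmt("positions must be nondecreasing")
  bad <- !(alleles %in% c(0L, 1L) | is.na(alleles))
  if (any(bad))
    stop_fmt("allele states must be 0, 1 or NA (missing)")
  if (!is.null(label))
    label <- match.arg(label, c("neutral", "sweep"))
  structure(list(alleles = alleles, positions = as.double(positions),
                 label = label, scenario = scenario, chrom = chrom),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d haplotypes x %d SNPs", nrow(x$alleles),
              ncol(x$alleles)))
  if (!is.null(x$label)) cat(", label:", x$label)
  if (!is.null(x$scenario)) cat(", scenario:", x$scenario)
  nmiss <- sum(is.na(x$alleles))
  if (nmiss > 0) cat(sprintf(", %d missing calls", nmiss))
  cat("\n")
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$alleles)

#' Extract the central window of a replicate
#'
#' Training windows are taken from the middle of each simulated region, where
#' the selected site is placed: the `width` contiguous columns whose center is
#' closest to the midpoint of the segregating sites (ties resolved toward the
#' lower index).
#'
#' @param x an [snp_matrix].
#' @param width window width in SNPs (default 128).
#' @return an [snp_matrix] with `width` columns; label and metadata carried over.
#' @export
extract_center_window <- function(x, width = 128L) {
  stopifnot(inherits(x, "snp_matrix"))
  S <- ncol(x$alleles)
  if (S < width)
    stop_fmt("replicate has %d SNPs, fewer than window width %d", S, width)
  # 0-based start minimizing |window center - S/2|, ties to the lower index
  start <- (S - width + 1L) %/% 2L
  idx <- seq.int(start + 1L, start + width)
  snp_matrix(x$alleles[, idx, drop = FALSE], x$positions[idx],
             label = x$label, scenario = x$scenario, chrom = x$chrom)
}
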