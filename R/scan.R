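# Sliding-window genome scanning: classify every fixed-width SNP window of
# a region and report per-window sweep probabilities.  Windows live in
# SNP-index space (the model consumes fixed 128-SNP windows; variable SNP
# density is carried by the distance channel).

#' Window offsets for a sliding scan
#'
#' Complete windows at SNP offsets `0, step, 2*step, ...` while
#' `offset + width <= total SNPs`; no partial trailing window is emitted.
#'
#' @param x an [snp_matrix] (or an integer SNP count).
#' @param width window width in SNPs.
#' @param step step between window starts in SNPs (typically < width).
#' @return data.frame with 0-based half-open `snp_start` / `snp_end`.
#' @export
sliding_windows <- function(x, width = 128L, step = 32L) {
  S <- if (inherits(x, "snp_matrix")) ncol(x$alleles) else as.integer(x)
  stopifnot(width >= 1L, step >= 1L)
  if (width > S) {
    warning(sprintf("window width %d exceeds %d available SNPs", width, S))
    return(data.frame(snp_start = integer(0), snp_end = integer(0)))
  }
  starts <- seq.int(0L, S - width, by = step)
  data.frame(snp_start = starts, snp_end = starts + width)
}

#' Scan a region for selective sweeps
#'
#' Featurizes every sliding window of `x`, classifies it with a trained 1D
#' model, and reports the sweep-class probability per window.  With
#' `reuse = TRUE` (default) the per-locus DAF and distance values are
#' computed once for the whole region and shared across overlapping
#' windows; the result is bit-identical to the window-by-window path.
#'
#' @param object a fitted `sweep_nn` with `"daf"` input (or a checkpoint
#'   path).
#' @param x an [snp_matrix] covering the region to scan.
#' @param step SNP step between windows.
#' @param reuse share overlapping feature computations.
#' @return data.frame of scan records: window index, 0-based half-open SNP
#'   bounds, 1-based inclusive bp bounds (when bp positions are available;
#'   fractional coordinates are reported as-is), and `p_sweep`.
#' @export
scan_genome <- function(object, x, step = 32L, reuse = TRUE) {
  if (is.character(object)) object <- read_checkpoint(object)
  stopifnot(inherits(object, "sweep_nn"), inherits(x, "snp_matrix"))
  if (object$input_kind != "daf")
    stop_fmt("scanning requires a 1D (daf-input) model")
  W <- object$spec$input_width
  win <- sliding_windows(x, width = W, step = step)
  n <- nrow(win)
  chrom <- x$chrom %||% "sim"
  if (n == 0L)
    return(data.frame(chrom = character(0), window_index = integer(0),
                      snp_start = integer(0), snp_end = integer(0),
                      bp_start = numeric(0), bp_end = numeric(0),
                      p_sweep = numeric(0)))

  feats <- vector("list", n)
  if (reuse) {
    daf_all <- compute_daf(x)
    dist_all <- compute_distances(x$positions) / object$scale
    for (i in seq_len(n)) {
      idx <- (win$snp_start[i] + 1L):win$snp_end[i]
      d <- dist_all[idx]
      d[W] <- 0  # window-final distance is 0 by definition
      feats[[i]] <- feature_matrix(daf_all[idx], d)
    }
  } else {
    for (i in seq_len(n)) {
      idx <- (win$snp_start[i] + 1L):win$snp_end[i]
      sub <- snp_matrix(x$alleles[, idx, drop = FALSE], x$positions[idx])
      feats[[i]] <- featurize(sub, scale = object$scale)
    }
  }
  p <- predict(object, prepare_input(feats, "daf"), type = "prob")
  data.frame(chrom = chrom, window_index = seq_len(n) - 1L,
             snp_start = win$snp_start, snp_end = win$snp_end,
             bp_start = x$positions[win$snp_start + 1L],
             bp_end = x$positions[win$snp_end],
             p_sweep = p[, "sweep"])
}

#' Write scan records as TSV
#'
#' @param records data.frame from [scan_genome()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(records, path) {
  out <- records[, c("chrom", "bp_start", "bp_end", "snp_start", "snp_end",
                     "p_sweep")]
  out$p_sweep <- sprintf("%.6f", out$p_sweep)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
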