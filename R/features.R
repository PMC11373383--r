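#' Per-locus derived allele frequency
#'
#' The DAF at a locus is the count of derived alleles divided by the number
#' of non-missing alleles at that locus; missing calls shrink the
#' denominator, so a locus typed in n of N haplotypes with k derived copies
#' has DAF k/n.
#'
#' @param x an [snp_matrix].
#' @return numeric vector of length W with values in `[0, 1]`.
#' @export
compute_daf <- function(x) {
  stopifnot(inherits(x, "snp_matrix"))
  a <- x$alleles
  n_obs <- colSums(!is.na(a))
  if (any(n_obs == 0L))
    stop_fmt("locus %d is entirely missing; DAF undefined",
             which(n_obs == 0L)[1L])
  colSums(a, na.rm = TRUE) / n_obs
}

#' Inter-SNP distances
#'
#' `D[i] = P[i+1] - P[i]` for all but the last SNP, whose distance is defined
#' as 0.  Distances are invariant under translation of all positions, which
#' is what makes the representation reusable across overlapping windows.
#'
#' @param positions nondecreasing numeric vector.
#' @return nonnegative numeric vector of the same length, last element 0.
#' @export
compute_distances <- function(positions) {
  if (length(positions) < 1L) stop_fmt("empty position vector")
  if (is.unsorted(positions)) stop_fmt("positions must be nondecreasing")
  c(diff(positions), 0)
}

#' Fused sample-size-invariant feature matrix
#'
#' Stacks the DAF vector and the (optionally rescaled) inter-SNP distance
#' vector into a 2 x W matrix, the input consumed by the 1D classifier.
#' The shape depends only on the window width W, never on the number of
#' haplotypes, and is unchanged by any permutation of the sample rows.
#'
#' @param x an [snp_matrix].
#' @param scale positive divisor applied to distances.  Simulator positions
#'   (already fractional in `[0, 1]`) use `scale = 1`; base-pair positions
#'   from a VCF should be divided by the region length used in training so
#'   the two coordinate scales match.
#' @return a `feature_matrix`: 2 x W numeric matrix, rows `daf` and `dist`.
#' @export
featurize <- function(x, scale = 1) {
  stopifnot(inherits(x, "snp_matrix"), scale > 0)
  feature_matrix(compute_daf(x), compute_distances(x$positions) / scale,
                 label = x$label)
}

#' Default distance divisor for a training set
#'
#' Five times the mean positive inter-SNP distance across the windows, used
#' as the default distance divisor when fitting, so that scaled distances
#' average 0.2.  This makes the distance channel visible next to the
#' frequency channel (raw simulator distances are O(1e-4) and would carry
#' almost no gradient) while keeping it small enough that its heavy right
#' tail cannot dominate training: distances are continuous and effectively
#' unique per window, and at full O(1) scale a high-capacity model can
#' fingerprint training windows through them instead of generalizing.  The
#' fitted value is stored in the model and reused for prediction and
#' scanning, so train and scan scales always match whether positions are
#' fractional (simulator) or base pairs (VCF).
#'
#' @param windows list of [snp_matrix] objects.
#' @return a single positive scale factor.
#' @export
distance_scale <- function(windows) {
  if (inherits(windows, "snp_matrix")) windows <- list(windows)
  d <- unlist(lapply(windows, function(w) {
    if (!inherits(w, "snp_matrix")) return(numeric(0))
    dd <- compute_distances(w$positions)
    dd[dd > 0]
  }))
  if (length(d) == 0L || mean(d) <= 0) 1 else 5 * mean(d)
}

#' Construct a feature matrix directly
#'
#' @param daf numeric vector of derived allele frequencies in `[0, 1]`.
#' @param dist nonnegative distance vector of the same length; last entry 0.
#' @param label optional class label.
#' @return 2 x W matrix of class `feature_matrix`.
#' @export
feature_matrix <- function(daf, dist, label = NULL) {
  if (length(daf) != length(dist))
    stop_fmt("daf and dist lengths differ (%d vs %d)", length(daf),
             length(dist))
  if (any(daf < 0 | daf > 1)) stop_fmt("DAF values must lie in [0, 1]")
  if (any(dist < 0)) stop_fmt("distances must be nonnegative")
  if (dist[length(dist)] != 0) stop_fmt("last distance must be 0")
  f <- rbind(daf = as.double(daf), dist = as.double(dist))
  structure(f, class = c("feature_matrix", "matrix"), label = label)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> 2 x %d (daf, dist)", ncol(x)))
  lb <- attr(x, "label")
  if (!is.null(lb)) cat(", label:", lb)
  cat("\n")
  invisible(x)
}
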