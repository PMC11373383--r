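# Binary window format (.sfw)
#
# Layout (all integers unsigned little-endian):
#   magic   4 bytes  "SFWF"
#   version u32      format version, currently 1
#   mode    u8       0 = raw alleles + distances, 1 = DAF + distances
#   bits    u8       allele bits per state (1 or 2); DAF mode writes 1
#   pad     u16      zero
#   W       u32      window width (SNPs)
#   N       u32      sample size (raw mode; 0 in DAF mode)
#   n_win   u32      number of window records
# followed by n_win fixed-size records:
#   raw: W float32 distances, then W bit-packed allele columns
#        (ceil(N*bits/8) bytes per column, sample 0 in the least significant
#        bits, trailing bits zero; 2-bit codes 00 ancestral, 01 derived,
#        10 missing, 11 reserved)
#   daf: W float32 DAFs, then W float32 distances

SFW_MAGIC <- charToRaw("SFWF")
SFW_HEADER_BYTES <- 24L

#' Per-window payload size of the binary format
#'
#' Raw windows cost `W * (4 + ceiling(N * bits / 8))` bytes (4 bytes of
#' single-precision distance per SNP plus the bit-packed allele column);
#' frequency windows cost `W * (4 + 4)` bytes regardless of sample size,
#' which is what makes the DAF representation scale-free: at the 1000
#' Genomes sample size (N = 2504) it is a 97.5% reduction.
#'
#' @param W window width in SNPs.
#' @param N sample size (ignored in `"daf"` mode).
#' @param mode `"raw"` or `"daf"`.
#' @param allele_bits 1 (no missing data) or 2 (ternary states), raw mode only.
#' @return payload size in bytes for one window.
#' @export
#' @examples
#' payload_bytes(128, 128, "raw")   # 2560
#' payload_bytes(128, 128, "daf")   # 1024
payload_bytes <- function(W, N, mode = c("raw", "daf"), allele_bits = 1L) {
  mode <- match.arg(mode)
  if (W < 1L || (mode == "raw" && N < 1L))
    stop_fmt("W and N must be positive (got W=%s, N=%s)", W, N)
  if (!allele_bits %in% c(1L, 2L)) stop_fmt("allele_bits must be 1 or 2")
  if (mode == "daf") return(W * 8)
  W * (4 + ceiling(N * allele_bits / 8))
}

pack_column <- function(states, bits) {
  # states: integer codes 0/1/2, length N; returns raw vector
  N <- length(states)
  if (bits == 1L) {
    padded <- c(states, integer(-N %% 8L))
    packBits(as.logical(padded), type = "raw")  # first sample -> bit 0
  } else {
    padded <- c(states, integer(-N %% 4L))
    m <- matrix(padded, nrow = 4L)
    as.raw(m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] + 64L * m[4L, ])
  }
}

unpack_column <- function(bytes, N, bits) {
  if (bits == 1L) {
    as.integer(rawToBits(bytes))[seq_len(N)]
  } else {
    v <- as.integer(bytes)
    codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
    codes[seq_len(N)]
  }
}

#' Write windows to the bit-packed binary format
#'
#' @param windows list of [snp_matrix] (raw mode) or [feature_matrix]
#'   objects (DAF mode; raw windows are featurized on the fly).  All windows
#'   must share the width W, and in raw mode the sample size N.
#' @param path output file.
#' @param mode `"raw"` stores distances plus bit-packed alleles; `"daf"`
#'   stores single-precision DAF and distance vectors.
#' @param allele_bits 1 or 2 bits per allele state in raw mode.  Windows with
#'   missing data require `allele_bits = 2`.
#' @return invisibly, the number of bytes written.
#' @export
write_sfw <- function(windows, path, mode = c("raw", "daf"),
                      allele_bits = 1L) {
  mode <- match.arg(mode)
  if (inherits(windows, c("snp_matrix", "feature_matrix")))
    windows <- list(windows)
  if (length(windows) == 0L) stop_fmt("no windows to write")
  con <- file(path, "wb")
  on.exit(close(con))

  if (mode == "daf") {
    feats <- lapply(windows, function(w)
      if (inherits(w, "feature_matrix")) w else featurize(w))
    Ws <- vapply(feats, ncol, 0L)
    if (length(unique(Ws)) > 1L)
      stop_fmt("windows have differing widths: %s",
               paste(unique(Ws), collapse = ", "))
    W <- Ws[1L]; N <- 0L; allele_bits <- 1L
  } else {
    ok <- vapply(windows, inherits, TRUE, what = "snp_matrix")
    if (!all(ok)) stop_fmt("raw mode requires snp_matrix windows")
    Ws <- vapply(windows, function(w) ncol(w$alleles), 0L)
    Ns <- vapply(windows, function(w) nrow(w$alleles), 0L)
    if (length(unique(Ws)) > 1L || length(unique(Ns)) > 1L)
      stop_fmt("raw mode requires homogeneous W and N across windows")
    W <- Ws[1L]; N <- Ns[1L]
    has_missing <- any(vapply(windows, function(w) anyNA(w$alleles), TRUE))
    if (has_missing && allele_bits == 1L)
      stop_fmt(paste("windows contain missing data; 1-bit packing cannot",
                     "represent them -- use allele_bits = 2"))
  }

  writeBin(SFW_MAGIC, con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(as.integer(mode == "daf"), con, size = 1L)
  writeBin(as.integer(allele_bits), con, size = 1L)
  writeBin(0L, con, size = 2L, endian = "little")
  writeBin(as.integer(W), con, size = 4L, endian = "little")
  writeBin(as.integer(N), con, size = 4L, endian = "little")
  writeBin(length(windows), con, size = 4L, endian = "little")

  if (mode == "daf") {
    for (f in feats) {
      writeBin(as.double(f["daf", ]), con, size = 4L, endian = "little")
      writeBin(as.double(f["dist", ]), con, size = 4L, endian = "little")
    }
  } else {
    for (w in windows) {
      writeBin(compute_distances(w$positions), con, size = 4L,
               endian = "little")
      codes <- w$alleles
      codes[is.na(codes)] <- 2L
      packed <- lapply(seq_len(W), function(j)
        pack_column(codes[, j], bits = allele_bits))
      writeBin(do.call(c, packed), con)
    }
  }
  invisible(SFW_HEADER_BYTES +
              length(windows) * payload_bytes(W, max(N, 1L), mode,
                                              allele_bits))
}

#' Read the bit-packed binary window format
#'
#' Lossless inverse of [write_sfw()]: allele states are recovered exactly and
#' DAF/distance values to full single precision.
#'
#' @param path file written by [write_sfw()].
#' @return list with `header` (list of format fields) and `windows` (list of
#'   [snp_matrix] or [feature_matrix] objects).
#' @export
read_sfw <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(magic, SFW_MAGIC))
    stop_fmt("bad magic at byte 0: not an sfw file")
  version <- readBin(con, "integer", size = 4L, endian = "little")
  if (version != 1L) stop_fmt("unsupported sfw version %d (byte 4)", version)
  mode_i <- readBin(con, "integer", size = 1L, signed = FALSE)
  bits <- readBin(con, "integer", size = 1L, signed = FALSE)
  readBin(con, "integer", size = 2L, endian = "little")
  W <- readBin(con, "integer", size = 4L, endian = "little")
  N <- readBin(con, "integer", size = 4L, endian = "little")
  n_win <- readBin(con, "integer", size = 4L, endian = "little")
  mode <- if (mode_i == 1L) "daf" else "raw"
  per <- payload_bytes(W, max(N, 1L), mode, bits)
  expected <- SFW_HEADER_BYTES + n_win * per
  if (sz < expected)
    stop_fmt("truncated file: expected %d bytes, found %d (record size %d)",
             expected, sz, per)

  windows <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    if (mode == "daf") {
      daf <- readBin(con, "double", n = W, size = 4L, endian = "little")
      dist <- readBin(con, "double", n = W, size = 4L, endian = "little")
      windows[[i]] <- feature_matrix(daf, dist)
    } else {
      dist <- readBin(con, "double", n = W, size = 4L, endian = "little")
      bpc <- as.integer(ceiling(N * bits / 8))
      bytes <- readBin(con, "raw", n = W * bpc)
      codes <- matrix(vapply(seq_len(W), function(j)
        unpack_column(bytes[seq.int((j - 1L) * bpc + 1L, j * bpc)], N, bits),
        integer(N)), nrow = N)
      codes[codes == 2L] <- NA_integer_
      # positions are reconstructed from distances up to translation
      pos <- cumsum(c(0, dist[-W]))
      windows[[i]] <- snp_matrix(codes, pos)
    }
  }
  list(header = list(version = version, mode = mode, allele_bits = bits,
                     W = W, N = N, n_windows = n_win),
       windows = windows)
}
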