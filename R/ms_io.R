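#' Parse ms-dialect simulator output
#'
#' Reads the text format produced by Hudson's ms and its descendants
#' (mssel, msHOT, mbs, and this package's own simulation bridge): a command
#' line, then one block per replicate introduced by `//`, containing
#' `segsites: k`, a `positions:` line with k fractional coordinates, and one
#' k-character 0/1 row per sampled haplotype.
#'
#' @param input path to a file, or a character vector of lines (anything of
#'   length > 1, or containing a newline, is treated as text).
#' @return list of [snp_matrix] objects, one per replicate, in file order.
#'   A `segsites: 0` block (ms convention for monomorphic replicates) yields
#'   a zero-column matrix.
#' @export
parse_ms <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  starts <- which(trimws(lines) == "//")
  if (length(starts) == 0L)
    stop_fmt("no '//' replicate delimiters found in ms input")
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[seq.int(starts[r], ends[r])]
    base_line <- starts[r]
    seg_i <- grep("^segsites:", trimws(block))
    if (length(seg_i) != 1L)
      stop_fmt("replicate %d (line %d): missing 'segsites:' line",
               r, base_line)
    k <- suppressWarnings(as.integer(sub("^segsites:\\s*", "",
                                         trimws(block[seg_i]))))
    if (is.na(k) || k < 0L)
      stop_fmt("replicate %d (line %d): unreadable segsites count",
               r, base_line + seg_i - 1L)
    if (k == 0L) {
      # ms convention: a monomorphic replicate has no positions or rows
      out[[r]] <- structure(list(alleles = matrix(integer(), 0L, 0L),
                                 positions = numeric(0), label = NULL,
                                 scenario = NULL, chrom = NULL),
                            class = "snp_matrix")
      next
    }
    pos_i <- grep("^positions:", trimws(block))
    if (length(pos_i) != 1L)
      stop_fmt("replicate %d (line %d): missing 'positions:' line",
               r, base_line)
    pos <- suppressWarnings(as.double(strsplit(
      trimws(sub("^positions:\\s*", "", trimws(block[pos_i]))),
      "\\s+")[[1L]]))
    if (length(pos) != k || anyNA(pos))
      stop_fmt("replicate %d (line %d): positions count %d != segsites %d",
               r, base_line + pos_i - 1L, length(pos), k)
    rows <- block[-seq_len(pos_i)]
    rows <- rows[nzchar(trimws(rows))]
    rows <- rows[!startsWith(trimws(rows), "//")]
    if (length(rows) == 0L)
      stop_fmt("replicate %d (line %d): no haplotype rows", r, base_line)
    for (j in seq_along(rows)) {
      if (nchar(rows[j]) != k)
        stop_fmt("replicate %d (line %d): row length %d != segsites %d",
                 r, base_line + pos_i + j - 1L, nchar(rows[j]), k)
      if (grepl("[^01]", rows[j]))
        stop_fmt("replicate %d (line %d): non-0/1 character in haplotype row",
                 r, base_line + pos_i + j - 1L)
    }
    al <- matrix(as.integer(charToRaw(paste0(rows, collapse = ""))) - 48L,
                 nrow = length(rows), ncol = k, byrow = TRUE)
    out[[r]] <- snp_matrix(al, pos)
  }
  nonempty <- vapply(out, function(m) ncol(m$alleles) > 0L, TRUE)
  n_hap <- vapply(out[nonempty], function(m) nrow(m$alleles), 0L)
  if (length(unique(n_hap)) > 1L)
    stop_fmt("haplotype count varies across replicates (%s)",
             paste(unique(n_hap), collapse = ", "))
  out
}

#' Write windows as ms-dialect text
#'
#' @param windows list of [snp_matrix] objects with a common sample size.
#' @param path output file path, or `NULL` to return the lines invisibly.
#' @param cmdline text placed on the first (command) line.
#' @return invisibly, the character vector written.
#' @export
write_ms <- function(windows, path = NULL, cmdline = "dafsweep simulate") {
  if (inherits(windows, "snp_matrix")) windows <- list(windows)
  n <- if (length(windows)) nrow(windows[[1L]]$alleles) else 0L
  lines <- c(sprintf("%s %d %d", cmdline, n, length(windows)), "")
  for (m in windows) {
    rows <- apply(m$alleles, 1L, function(v) {
      if (anyNA(v)) stop_fmt("ms text cannot encode missing alleles")
      rawToChar(as.raw(v + 48L))
    })
    lines <- c(lines, "//", sprintf("segsites: %d", ncol(m$alleles)),
               paste("positions:",
                     paste(sprintf("%.8f", m$positions), collapse = " ")),
               rows, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
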