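# Genomic interval model and interval algebra.
#
# Interval sets are plain data.frames with columns chrom / start / end /
# strand, 0-based half-open ([start, end)) everywhere inside the package.
# Heavy lifting (merge, overlap queries) is delegated to IRanges /
# GenomicRanges after a coordinate-convention shift at the boundary.

#' Construct a set of genomic intervals
#'
#' Builds the package's standard interval container: a data.frame with
#' columns `chrom`, `start`, `end`, `strand` using 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive, as in BED).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, 0-based exclusive end coordinates.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unknown). Recycled.
#' @param ... Further equal-length vectors appended as annotation columns.
#' @return A data.frame of intervals sorted input order (not resorted).
#' @examples
#' genomic_intervals("chr1", c(0L, 100L), c(50L, 200L))
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  validate_intervals(x)
  x
}

#' Validate an interval data.frame
#'
#' Checks the container invariants: required columns present,
#' `0 <= start < end`, and strand in `{+, -, *}`.
#'
#' @param x Interval data.frame.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$start < 0)) stop("negative start coordinate")
    if (any(x$start >= x$end)) stop("interval with start >= end")
    if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
  }
  invisible(x)
}

#' Sort intervals by (chrom, start, end)
#'
#' @param x Interval data.frame.
#' @return The same rows reordered lexicographically by chromosome, then
#'   start, then end.
#' @export
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

## 0-based half-open -> 1-based closed GRanges
.as_gr <- function(x) {
  if (!nrow(x)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand %in% c("+", "-"), x$strand, "*")
    } else "*")
}

.from_gr <- function(gr) {
  if (!length(gr)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = {
               s <- as.character(GenomicRanges::strand(gr))
               ifelse(s == "*", "*", s)
             },
             stringsAsFactors = FALSE)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Collapses intervals on the same chromosome separated by at most `gap`
#' base pairs into single intervals. With `gap = 0`, two intervals merge
#' iff they overlap or abut; the union of covered bases is preserved.
#' The operation is idempotent.
#'
#' @param x Interval data.frame (may be unsorted and overlapping).
#' @param gap Maximum separation in bp allowed between merged intervals
#'   (non-negative integer).
#' @return Sorted, pairwise non-overlapping interval data.frame.
#' @examples
#' merge_intervals(genomic_intervals("c", c(10L, 15L), c(20L, 30L)))
#' @export
merge_intervals <- function(x, gap = 0) {
  if (gap < 0) stop("gap must be >= 0")
  validate_intervals(x)
  if (!nrow(x)) return(sort_intervals(x[, c("chrom", "start", "end", "strand")]))
  gr <- GenomicRanges::reduce(.as_gr(x), min.gapwidth = gap + 1,
                              ignore.strand = TRUE)
  sort_intervals(.from_gr(gr))
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair (i, j) with `a[i, ]` and `b[j, ]` on the same
#' chromosome sharing at least `min_overlap` base pairs. The relation is
#' symmetric: (i, j) is reported from (a, b) iff (j, i) from (b, a).
#'
#' @param a,b Interval data.frames.
#' @param min_overlap Minimum overlap in bp (>= 1).
#' @return data.frame with columns `query` (row index in `a`), `subject`
#'   (row index in `b`) and `overlap` (bp shared).
#' @export
intersect_intervals <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  validate_intervals(a); validate_intervals(b)
  if (!nrow(a) || !nrow(b))
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  ga <- .as_gr(a); gb <- .as_gr(b)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap,
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  data.frame(query = qi, subject = si, overlap = as.integer(ov))
}

#' Base-pair intersection of two interval sets
#'
#' Returns the genomic regions covered by both `a` and `b`, as a sorted
#' non-overlapping interval set. Used to define replicate-shared regions.
#'
#' @param a,b Interval data.frames.
#' @return Interval data.frame of the covered-base intersection.
#' @export
intersect_regions <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (!nrow(a) || !nrow(b))
    return(genomic_intervals(character(), integer(), integer()))
  gr <- suppressWarnings(GenomicRanges::intersect(
    GenomicRanges::reduce(.as_gr(a), ignore.strand = TRUE),
    GenomicRanges::reduce(.as_gr(b), ignore.strand = TRUE),
    ignore.strand = TRUE))
  sort_intervals(.from_gr(gr))
}

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column tab-delimited narrowPeak (BED6+4) format into a
#' peak-call table. Column 10 is the summit offset from `start`; the
#' sentinel value -1 (no summit called) is replaced by the interval
#' midpoint.
#'
#' @param path Path to a narrowPeak file.
#' @return data.frame with columns chrom, start, end, name, score,
#'   strand, signal, pvalue, qvalue, summit_offset. Zero rows for an
#'   empty file.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit_offset")
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), strand = character(),
                      signal = numeric(), pvalue = numeric(),
                      qvalue = numeric(), summit_offset = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10))
    stop("narrowPeak parse error at line ", which(nf != 10)[1],
         ": expected 10 tab-delimited fields, got ", nf[nf != 10][1])
  m <- do.call(rbind, parts)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("narrowPeak parse error at line ", which(is.na(v))[1],
           ": non-numeric ", what)
    v
  }
  out <- data.frame(chrom = m[, 1], start = num(2, "start"),
                    end = num(3, "end"), name = m[, 4],
                    score = num(5, "score"), strand = m[, 6],
                    signal = num(7, "signalValue"),
                    pvalue = num(8, "pValue"), qvalue = num(9, "qValue"),
                    summit_offset = num(10, "peak"),
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop("narrowPeak validation error at line ", bad[1], ": start >= end")
  if (any(out$qvalue < 0 & out$qvalue != -1))
    stop("narrowPeak validation error: negative qValue")
  nosum <- out$summit_offset < 0
  out$summit_offset[nosum] <-
    floor((out$end[nosum] - out$start[nosum]) / 2)
  if (any(out$summit_offset >= out$end - out$start))
    stop("narrowPeak validation error: summit offset outside interval")
  out$strand[!out$strand %in% c("+", "-")] <- "*"
  out
}

#' Write a narrowPeak file
#'
#' @param x Peak table as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  strand <- if ("strand" %in% names(x)) ifelse(x$strand %in% c("+", "-"), x$strand, ".") else rep(".", nrow(x))
  df <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                   if ("name" %in% names(x)) x$name else ".",
                   if ("score" %in% names(x)) x$score else 0,
                   strand,
                   if ("signal" %in% names(x)) x$signal else 0,
                   if ("pvalue" %in% names(x)) x$pvalue else -1,
                   if ("qvalue" %in% names(x)) x$qvalue else -1,
                   format_coord(x$summit_offset))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED file (BED3+)
#'
#' First three columns become chrom/start/end; a sixth column matching
#' `+`/`-` is used as strand; all remaining columns are preserved as
#' character columns named `V4`, `V5`, ...
#'
#' @param path Path to a tab-delimited BED file.
#' @return Interval data.frame.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    return(genomic_intervals(character(), integer(), integer()))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 3) stop("BED requires at least 3 columns")
  x <- data.frame(chrom = tab[[1]],
                  start = as.numeric(tab[[2]]),
                  end = as.numeric(tab[[3]]),
                  strand = if (ncol(tab) >= 6 && all(tab[[6]] %in% c("+", "-", ".")))
                    ifelse(tab[[6]] == ".", "*", tab[[6]]) else "*",
                  stringsAsFactors = FALSE)
  extras <- setdiff(seq_len(ncol(tab)), c(1:3, if (ncol(tab) >= 6) 6))
  for (j in extras) x[[paste0("V", j)]] <- tab[[j]]
  validate_intervals(x)
  x
}

#' Write intervals as BED
#'
#' Writes chrom/start/end, then any annotation columns in order, with
#' strand (as `.` for unknown) in the sixth position when at least five
#' columns are emitted. Extra columns are written as-is, so string
#' annotations round-trip through [read_bed()].
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  if (!nrow(x)) { writeLines(character(), path); return(invisible(path)) }
  extras <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                    stringsAsFactors = FALSE)
  if (length(extras) || any(x$strand != "*")) {
    name <- if (length(extras)) as.character(x[[extras[1]]]) else "."
    out[[4]] <- name
    out[[5]] <- if (length(extras) >= 2) as.character(x[[extras[2]]]) else "0"
    out[[6]] <- ifelse(x$strand == "*", ".", x$strand)
    for (e in extras[-(1:2)]) out[[ncol(out) + 1]] <- as.character(x[[e]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Built-in MHC region masks
#'
#' The three fixed hg19 region masks used for stratified summaries: the
#' extended MHC (chr6:29,580,000-33,100,000), the classical MHC class II
#' region (chr6:32,400,000-33,100,000) and the MHC class I region
#' (chr6:29,640,000-31,325,000). Printed 1-based inclusive boundaries are
#' converted to the package's 0-based half-open convention on
#' construction.
#'
#' @return Interval data.frame with a `name` column
#'   (`MHC`, `MHC_classII`, `MHC_classI`).
#' @export
region_masks <- function() {
  genomic_intervals(
    chrom = rep("chr6", 3),
    start = c(29580000, 32400000, 29640000) - 1,
    end = c(33100000, 33100000, 31325000),
    name = c("MHC", "MHC_classII", "MHC_classI"))
}
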