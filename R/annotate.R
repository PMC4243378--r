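# Gene association of binding intervals by TSS distance.
#
# A BI is associated with a gene when the distance from the gene's TSS to
# the nearest BI edge is strictly below 10 kb (either side). Distance is
# 0 when the TSS lies inside the BI, and signed by gene-strand
# orientation: negative means the BI lies upstream (5') of the TSS.

#' Read gene models with a single TSS per record
#'
#' Accepts BED6 (TSS = start for `+` strand genes, end - 1 for `-`)
#' or a 4-column table `gene_id  chrom  tss  strand`.
#'
#' @param path Path to the tab-delimited file.
#' @param format `"bed"` or `"tss"`.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path, format = c("bed", "tss")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- read_bed(path)
    if (!"V4" %in% names(bed)) stop("BED6 gene file requires a name column")
    if (any(bed$strand == "*")) stop("gene records require strand + or -")
    data.frame(gene_id = bed$V4, chrom = bed$chrom,
               tss = ifelse(bed$strand == "+", bed$start, bed$end - 1),
               strand = bed$strand, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(tab) != 4) stop("TSS table requires 4 columns")
    g <- data.frame(gene_id = tab[[1]], chrom = tab[[2]],
                    tss = as.numeric(tab[[3]]), strand = tab[[4]],
                    stringsAsFactors = FALSE)
    if (!all(g$strand %in% c("+", "-"))) stop("strand must be + or -")
    g
  }
}

#' Associate binding intervals with genes by TSS distance
#'
#' Emits one association per (BI, gene) pair whose TSS-to-nearest-edge
#' distance is strictly less than `max_dist` bp (many-to-many preserved).
#' Associations with `|distance| <= proximal_dist` are classed
#' `proximal`, the rest `distal`.
#'
#' @param bis BI data.frame (row order defines the `bi` index).
#' @param genes Gene table with `gene_id`, `chrom`, `tss`, `strand`.
#' @param max_dist Association radius in bp, exclusive (default 10000).
#' @param proximal_dist Proximal cutoff in bp, inclusive (default 2000).
#' @return data.frame with columns `gene_id`, `bi` (row index into
#'   `bis`), `distance` (signed bp; 0 if the TSS is inside the BI;
#'   negative when the BI is upstream of the TSS on the gene strand) and
#'   `class` (`proximal`/`distal`).
#' @export
associate_genes <- function(bis, genes, max_dist = 10000,
                            proximal_dist = 2000) {
  validate_intervals(bis)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (!nrow(bis) || !nrow(genes)) {
    return(data.frame(gene_id = character(), bi = integer(),
                      distance = numeric(), class = character()))
  }
  # TSS as 1 bp intervals padded by max_dist - 1 so that a findOverlaps
  # hit is exactly "nearest edge strictly closer than max_dist"
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$tss - (max_dist - 1)),
                    end = genes$tss + max_dist,
                    strand = "*", stringsAsFactors = FALSE)
  hits <- intersect_intervals(win, bis, min_overlap = 1)
  if (!nrow(hits)) {
    return(data.frame(gene_id = character(), bi = integer(),
                      distance = numeric(), class = character()))
  }
  gi <- hits$query; bi <- hits$subject
  tss <- genes$tss[gi]
  s <- bis$start[bi]; e <- bis$end[bi]
  raw <- ifelse(tss >= s & tss < e, 0,
                ifelse(tss < s, s - tss, tss - (e - 1)))
  # genomic sign: positive when BI lies right of the TSS
  gsign <- ifelse(raw == 0, 0, ifelse(tss < s, 1, -1))
  dist <- ifelse(genes$strand[gi] == "+", gsign * raw, -gsign * raw)
  keep <- raw < max_dist
  out <- data.frame(gene_id = genes$gene_id[gi], bi = bi,
                    distance = dist,
                    class = ifelse(abs(dist) <= proximal_dist,
                                   "proximal", "distal"),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$gene_id, out$bi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the BI pattern of each associated gene
#'
#' @param associations Output of [associate_genes()].
#' @return data.frame with columns `gene_id` and `pattern`, one of
#'   `single_proximal` (only proximal BIs), `single_distal` (only distal)
#'   or `both`; plus an attribute-free `fractions` column is not added —
#'   compute fractions from the table.
#' @export
classify_gene_pattern <- function(associations) {
  if (!nrow(associations)) {
    return(data.frame(gene_id = character(), pattern = character()))
  }
  sp <- split(associations$class, associations$gene_id)
  pattern <- vapply(sp, function(cl) {
    has_p <- "proximal" %in% cl; has_d <- "distal" %in% cl
    if (has_p && has_d) "both"
    else if (has_p) "single_proximal"
    else "single_distal"
  }, character(1))
  data.frame(gene_id = names(sp), pattern = unname(pattern),
             stringsAsFactors = FALSE)
}

#' Histogram of signed TSS distances
#'
#' @param associations Output of [associate_genes()].
#' @param breaks Sorted, strictly increasing bin edges covering all
#'   distances; bins are left-closed, right-open except the last
#'   (right-closed).
#' @return data.frame with `lower`, `upper`, `count`; counts sum to
#'   `nrow(associations)`.
#' @export
distance_histogram <- function(associations, breaks) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  d <- associations$distance
  if (length(d) && (any(d < breaks[1]) || any(d > breaks[length(breaks)])))
    stop("distances outside the bin range")
  counts <- if (length(d)) {
    tab <- table(cut(d, breaks = breaks, right = FALSE,
                     include.lowest = TRUE))
    # cut(right = FALSE) leaves the maximum out of the last bin; fold it in
    tab[length(tab)] <- tab[length(tab)] + sum(d == breaks[length(breaks)])
    as.integer(tab)
  } else rep(0L, length(breaks) - 1)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             count = counts)
}
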