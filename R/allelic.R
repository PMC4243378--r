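# Allele-specific binding (ASB) at heterozygous SNPs and a simplified
# single-marker eQTL association used for trans-network integration.
#
# ASB is quantified per individual as the fraction of quality-filtered
# ChIP-seq reads carrying allele A at a heterozygous site; the headline
# cross-individual test is a one-sample t-test of the fractions against
# 0.5, with per-individual exact binomial tests reported alongside.

#' Count allele-supporting reads at a SNP
#'
#' Tallies reads covering a biallelic SNV by observed base, after
#' mapping- and base-quality filters and duplicate exclusion. Bases
#' matching neither allele are counted separately.
#'
#' @param path BAM file, or SAM file (converted on the fly).
#' @param snp List or one-row data.frame with `snp_id`, `chrom`, `pos`
#'   (0-based), `allele_a`, `allele_b` (distinct single nucleotides).
#' @param min_base_quality,min_map_quality Phred thresholds (default 20).
#' @return One-row data.frame: `snp_id`, `count_a`, `count_b`,
#'   `count_other`, `depth` (usable depth = a + b + other).
#' @export
count_alleles <- function(path, snp, min_base_quality = 20,
                          min_map_quality = 20) {
  a <- toupper(snp$allele_a); b <- toupper(snp$allele_b)
  if (a == b || nchar(a) != 1 || nchar(b) != 1)
    stop("SNP alleles must be two distinct single nucleotides")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!snp$chrom %in% names(hdr))
    stop("SNP chromosome ", snp$chrom, " absent from alignment header")
  if (snp$pos < 0 || snp$pos >= hdr[[snp$chrom]])
    stop("SNP position off reference sequence ", snp$chrom)
  pos1 <- snp$pos + 1
  which <- GenomicRanges::GRanges(snp$chrom,
                                  IRanges::IRanges(pos1, pos1))
  sbp <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE),
    which = which, mapqFilter = min_map_quality)
  pp <- Rsamtools::PileupParam(
    max_depth = 1e6, min_base_quality = min_base_quality,
    min_mapq = min_map_quality, min_nucleotide_depth = 0,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    include_deletions = FALSE, include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  pu <- pu[pu$pos == pos1, , drop = FALSE]
  tally <- function(nt) sum(pu$count[pu$nucleotide == nt])
  count_a <- tally(a); count_b <- tally(b)
  other <- sum(pu$count) - count_a - count_b
  data.frame(snp_id = snp$snp_id, count_a = count_a, count_b = count_b,
             count_other = other, depth = sum(pu$count),
             stringsAsFactors = FALSE)
}

#' Cross-individual allele-specific binding test
#'
#' Per individual, the allele-A fraction `f = count_a / (count_a +
#' count_b)` and an exact two-sided binomial test against 0.5; across
#' individuals, a two-sided one-sample t-test of the fractions against
#' 0.5 is the headline p-value. Individuals with zero usable depth are
#' excluded.
#'
#' @param counts data.frame with columns `individual`, `count_a`,
#'   `count_b` (one row per individual).
#' @return Object of class `asb_result`: `fractions` (per-individual
#'   table with `f` and `binom_p`), `mean_pct`, `sd_pct` (n-1
#'   denominator), `p_value` (cross-individual t-test), `n`.
#' @export
asb_test <- function(counts) {
  stopifnot(all(c("count_a", "count_b") %in% names(counts)))
  use <- counts$count_a + counts$count_b >= 1
  counts <- counts[use, , drop = FALSE]
  if (nrow(counts) < 2)
    stop("asb_test requires >= 2 individuals with nonzero depth")
  n <- counts$count_a + counts$count_b
  f <- counts$count_a / n
  binom_p <- vapply(seq_along(f), function(i)
    stats::binom.test(counts$count_a[i], n[i], p = 0.5)$p.value,
    numeric(1))
  counts$f <- f
  counts$binom_p <- binom_p
  if (stats::sd(f) == 0) {
    if (all(f == 0.5)) {
      p <- 1
    } else {
      warning("all allele fractions identical and != 0.5; ",
              "cross-individual p reported at machine floor")
      p <- .Machine$double.xmin
    }
  } else {
    p <- stats::t.test(f, mu = 0.5)$p.value
  }
  structure(list(fractions = counts, mean_pct = 100 * mean(f),
                 sd_pct = 100 * stats::sd(f), p_value = p,
                 n = nrow(counts)),
            class = "asb_result")
}

#' @export
print.asb_result <- function(x, ...) {
  cat(sprintf("ASB across %d individuals: %.1f%% (SD %.1f) allele A, p = %.3g\n",
              x$n, x$mean_pct, x$sd_pct, x$p_value))
  invisible(x)
}

#' Allelic PWM score difference
#'
#' Scores two windows that differ at exactly one position (the two
#' alleles of a SNP) against a PWM; a positive delta means the reference
#' window is the better predicted binding site.
#'
#' @param pwm A `pwm` object.
#' @param ref_window,alt_window Equal-length windows (= PWM length)
#'   differing at exactly one position.
#' @return List with `score_ref`, `score_alt`, `delta = score_ref -
#'   score_alt`.
#' @export
allele_pwm_delta <- function(pwm, ref_window, alt_window) {
  r <- strsplit(toupper(ref_window), "")[[1]]
  a <- strsplit(toupper(alt_window), "")[[1]]
  if (length(r) != length(a))
    stop("ref and alt windows must have equal length")
  ndiff <- sum(r != a)
  if (ndiff != 1)
    stop("windows must differ at exactly 1 position, found ", ndiff)
  s_ref <- match_score(pwm, ref_window)
  s_alt <- match_score(pwm, alt_window)
  list(score_ref = s_ref, score_alt = s_alt, delta = s_ref - s_alt)
}

#' Single-marker eQTL association
#'
#' Ordinary least squares of an expression trait on genotype dosage plus
#' optional covariates (e.g. major expression principal components); the
#' slope's two-sided t-test gives the p-value. The association is
#' labelled cis when the gene TSS lies within `cis_window` bp of the SNP
#' on the same chromosome.
#'
#' @param dosage Numeric vector of allele dosages (0/1/2) per individual.
#' @param expression Numeric expression values, same length.
#' @param covariates Optional numeric matrix (individuals x covariates).
#' @param snp_id,gene_id Optional labels.
#' @param snp_chrom,snp_pos,gene_chrom,gene_tss Optional positions for
#'   the cis/trans label.
#' @param cis_window Cis window in bp (default 1e6).
#' @return Object of class `eqtl_result`: `beta`, `se`, `p_value`, `n`,
#'   `cis` (logical or NA), `snp_id`, `gene_id`.
#' @export
eqtl_association <- function(dosage, expression, covariates = NULL,
                             snp_id = NA_character_,
                             gene_id = NA_character_,
                             snp_chrom = NULL, snp_pos = NULL,
                             gene_chrom = NULL, gene_tss = NULL,
                             cis_window = 1e6) {
  n <- length(dosage)
  stopifnot(length(expression) == n)
  if (length(unique(dosage)) < 2)
    stop("dosage is constant; slope undefined")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(1, dosage, covariates)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
    fit <- stats::lm(expression ~ dosage + covariates)
  } else {
    fit <- stats::lm(expression ~ dosage)
  }
  co <- summary(fit)$coefficients["dosage", ]
  cis <- NA
  if (!is.null(snp_chrom) && !is.null(gene_chrom))
    cis <- identical(snp_chrom, gene_chrom) &&
      abs(gene_tss - snp_pos) <= cis_window
  structure(list(beta = unname(co[1]), se = unname(co[2]),
                 p_value = unname(co[4]), n = n, cis = cis,
                 snp_id = snp_id, gene_id = gene_id),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat(sprintf("eQTL %s ~ %s: beta = %.3f (SE %.3f), p = %.3g, %s\n",
              x$gene_id, x$snp_id, x$beta, x$se, x$p_value,
              if (is.na(x$cis)) "cis/trans unknown"
              else if (x$cis) "cis" else "trans"))
  invisible(x)
}

#' Integrate trans-eQTL genes with binding evidence
#'
#' Filters the trans associations of one SNP at a p-value threshold and
#' flags each passing gene by membership in the BI-associated gene set.
#'
#' @param eqtl_results data.frame with columns `gene_id`, `p_value`,
#'   `cis` (logical).
#' @param p_threshold Keep trans genes with `p_value < p_threshold`.
#' @param bi_gene_set Character vector of BI-associated gene ids.
#' @return List with `table` (gene_id, p_value, supported) and counts
#'   `n_supported`, `n_unsupported`.
#' @export
integrate_trans_network <- function(eqtl_results, p_threshold,
                                    bi_gene_set) {
  if (!nrow(eqtl_results)) {
    tab <- data.frame(gene_id = character(), p_value = numeric(),
                      supported = logical())
    return(list(table = tab, n_supported = 0L, n_unsupported = 0L))
  }
  stopifnot(all(c("gene_id", "p_value", "cis") %in% names(eqtl_results)))
  keep <- !eqtl_results$cis & eqtl_results$p_value < p_threshold
  tab <- eqtl_results[keep, c("gene_id", "p_value"), drop = FALSE]
  tab$supported <- tab$gene_id %in% bi_gene_set
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_supported = sum(tab$supported),
       n_unsupported = sum(!tab$supported))
}
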