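# Synthetic-data generators with serialized ground truth.
#
# Each generator is a pure function of (parameters, seed), so every
# pipeline stage can be tested against known truth: planted consensus
# binding intervals with replicate peak noise, promoter tri-motif
# modules, DE p-values enriched in a target set, allelic read counts at a
# heterozygous SNP with a planted ratio, and a cis-eSNP with a mediated
# trans gene set.

#' Generate a toy genome with gene models
#'
#' Contigs are i.i.d. uniform nucleotide sequences; genes are placed on
#' random strands with at least 5 kb spacing and a 20 kb margin from
#' contig ends (room for 10 kb promoter windows).
#'
#' @param n_contigs Number of contigs (default 2).
#' @param contig_len Contig length in bp (>= 50000; default 500000).
#' @param n_genes Total genes (default 200).
#' @param seed Integer seed.
#' @return List with `genome` (`DNAStringSet`) and `genes` (data.frame
#'   `gene_id`, `chrom`, `tss`, `strand`).
#' @export
generate_genome <- function(n_contigs = 2, contig_len = 500000,
                            n_genes = 200, seed = 1) {
  if (contig_len < 50000) stop("contig_len must be >= 50 kb")
  set.seed(seed)
  genome <- Biostrings::DNAStringSet(vapply(seq_len(n_contigs), function(i)
    paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
          collapse = ""), character(1)))
  names(genome) <- paste0("contig_", seq_len(n_contigs))
  if (n_genes == 0) {
    return(list(genome = genome,
                genes = data.frame(gene_id = character(),
                                   chrom = character(), tss = numeric(),
                                   strand = character())))
  }
  margin <- 10200   # room for 10 kb promoter windows at both ends
  step <- 5000
  slots_per <- floor((contig_len - 2 * margin - step) / step) + 1
  if (n_genes > slots_per * n_contigs)
    stop("genes do not fit with the required spacing")
  per <- diff(round(seq(0, n_genes, length.out = n_contigs + 1)))
  rows <- list()
  gid <- 0L
  for (ci in seq_len(n_contigs)) {
    if (!per[ci]) next
    slots <- sort(sample.int(slots_per, per[ci]))
    # exact 5 kb grid with one random phase per contig keeps the
    # >= 5 kb spacing guarantee
    tss <- margin + (slots - 1) * step + sample.int(4000, 1)
    strand <- sample(c("+", "-"), per[ci], replace = TRUE)
    rows[[ci]] <- data.frame(
      gene_id = paste0("gene_", gid + seq_len(per[ci])),
      chrom = names(genome)[ci], tss = tss, strand = strand,
      stringsAsFactors = FALSE)
    gid <- gid + per[ci]
  }
  list(genome = genome, genes = do.call(rbind, rows))
}

#' Bundled synthetic PWMs for the RFX5 / CREB / NF-Y module
#'
#' Reads the three toy JASPAR-format matrices shipped with the package
#' (synthetic matrices built around the field consensus motifs: the RFX
#' X-box, the CRE palindrome and the CCAAT box), in module order.
#'
#' @return Named list of three `pwm` objects (`RFX5`, `CREB`, `NFY`).
#' @export
enhmap_pwms <- function() {
  files <- c(RFX5 = "pwm_rfx5_synthetic.jaspar",
             CREB = "pwm_creb_synthetic.jaspar",
             NFY = "pwm_nfy_synthetic.jaspar")
  pwms <- lapply(files, function(f)
    read_pwm(system.file("extdata", f, package = "enhmap",
                         mustWork = TRUE)))
  for (nm in names(pwms)) pwms[[nm]]$name <- nm
  pwms
}

#' Plant ordered tri-motif modules into promoter windows
#'
#' Writes the three motif strings, in order and separated by `spacing`
#' bp, at a random offset inside the `[TSS - 300, TSS)` window of each
#' selected promoter (regulatory modules of this kind sit within ~300 bp
#' of the transcription start).
#'
#' @param genome `DNAStringSet`.
#' @param genes Gene table.
#' @param promoter_ids Gene ids receiving a module.
#' @param motifs Character vector of three motif sequences (5'-to-3'
#'   module order).
#' @param spacing Fixed spacer length in bp between motifs (default 10).
#' @param seed Integer seed.
#' @param offsets Optional fixed module offset(s) within the 300 bp
#'   window (0-based, recycled); random when NULL.
#' @return List with `genome` (modified) and `truth`: data.frame
#'   `gene_id`, `chrom` and absolute 0-based starts `start_1..start_3` of
#'   the planted motifs.
#' @export
plant_modules <- function(genome, genes, promoter_ids, motifs,
                          spacing = 10, seed = 1, offsets = NULL) {
  stopifnot(length(motifs) == 3)
  set.seed(seed)
  if (!length(promoter_ids))
    return(list(genome = genome,
                truth = data.frame(gene_id = character())))
  lens <- nchar(motifs)
  total <- sum(lens) + 2 * spacing
  if (total > 300) stop("module too long for a 300 bp promoter window")
  sel <- genes[match(promoter_ids, genes$gene_id), , drop = FALSE]
  if (anyNA(sel$gene_id)) stop("unknown promoter gene id")
  win <- data.frame(chrom = sel$chrom, start = sel$tss - 300,
                    end = sel$tss, strand = "*")
  if (any(win$start < 0)) stop("promoter window off contig")
  ov <- intersect_intervals(win, win, min_overlap = 1)
  if (any(ov$query != ov$subject))
    stop("planted promoter windows collide")
  offs <- if (is.null(offsets))
    sample.int(300 - total + 1, nrow(sel), replace = TRUE) - 1L
  else rep_len(as.integer(offsets), nrow(sel))
  if (any(offs < 0 | offs > 300 - total))
    stop("module offset outside the promoter window")
  starts <- matrix(0, nrow(sel), 3)
  for (i in seq_len(nrow(sel))) {
    s <- sel$tss[i] - 300 + offs[i]
    chrom <- sel$chrom[i]
    pos <- s
    for (k in 1:3) {
      starts[i, k] <- pos
      Biostrings::subseq(genome[[chrom]], start = pos + 1,
                         width = lens[k]) <- Biostrings::DNAString(motifs[k])
      pos <- pos + lens[k] + spacing
    }
  }
  truth <- data.frame(gene_id = sel$gene_id, chrom = sel$chrom,
                      start_1 = starts[, 1], start_2 = starts[, 2],
                      start_3 = starts[, 3], stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Simulate per-individual peak calls from true binding intervals
#'
#' Every true BI emits one peak per individual with Gaussian endpoint
#' jitter (clamped to a quarter of the BI width per side, preserving at
#' least 50% reciprocal overlap with the truth), independently dropped
#' with probability `fn_rate`. Spurious individual-specific peaks are
#' added at `fp_rate` per 100 kb, confined to alternating 1 kb parity
#' bins per individual (and away from true BIs) so that false positives
#' can never form a replicate consensus.
#'
#' @param truth_bis data.frame `chrom`, `start`, `end`, `condition`, `tf`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param jitter_sd Endpoint jitter SD in bp (default 20).
#' @param fp_rate Spurious peaks per individual per 100 kb (default 0.5).
#' @param fn_rate Per-individual drop probability of a true peak
#'   (default 0).
#' @param fp_width Width of spurious peaks in bp (default 300, < 1000).
#' @param seed Integer seed.
#' @return Peak data.frame ready for [derive_binding_intervals()], with a
#'   logical `is_spurious` column and `truth_bi` (row index into
#'   `truth_bis`, NA for spurious peaks).
#' @export
generate_peaks <- function(truth_bis, contig_lengths, jitter_sd = 20,
                           fp_rate = 0.5, fn_rate = 0, fp_width = 300,
                           seed = 1) {
  set.seed(seed)
  stopifnot(fp_width < 1000)
  conds <- unique(truth_bis[, c("condition", "tf")])
  rows <- list()
  for (ind in 1:2) {
    for (g in seq_len(nrow(conds))) {
      sel <- which(truth_bis$condition == conds$condition[g] &
                     truth_bis$tf == conds$tf[g])
      for (i in sel) {
        if (stats::runif(1) < fn_rate) next
        w <- truth_bis$end[i] - truth_bis$start[i]
        clamp <- floor(w / 4)
        ds <- max(-clamp, min(clamp, round(stats::rnorm(1, 0, jitter_sd))))
        de <- max(-clamp, min(clamp, round(stats::rnorm(1, 0, jitter_sd))))
        s <- truth_bis$start[i] + ds
        e <- truth_bis$end[i] + de
        rows[[length(rows) + 1]] <- data.frame(
          chrom = truth_bis$chrom[i], start = s, end = e,
          summit_offset = floor((e - s) / 2),
          score = stats::runif(1, 30, 100),
          individual = paste0("ind", ind),
          condition = conds$condition[g], tf = conds$tf[g],
          is_spurious = FALSE, truth_bi = i,
          stringsAsFactors = FALSE)
      }
      # spurious, individual-specific peaks
      for (chrom in names(contig_lengths)) {
        clen <- contig_lengths[[chrom]]
        n_fp <- stats::rpois(1, fp_rate * clen / 1e5)
        if (!n_fp) next
        bins <- seq(0, clen - 1000, by = 1000)
        parity_ok <- (bins / 1000) %% 2 == (ind - 1)
        tb <- truth_bis[truth_bis$chrom == chrom, , drop = FALSE]
        clear <- vapply(bins, function(b)
          !any(tb$start - 1000 < b + 1000 & tb$end + 1000 > b),
          logical(1))
        cand <- bins[parity_ok & clear]
        if (!length(cand)) next
        picks <- sample(cand, min(n_fp, length(cand)))
        for (b in picks) {
          s <- b + sample.int(1000 - fp_width, 1)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, start = s, end = s + fp_width,
            summit_offset = floor(fp_width / 2),
            score = stats::runif(1, 30, 60),
            individual = paste0("ind", ind),
            condition = conds$condition[g], tf = conds$tf[g],
            is_spurious = TRUE, truth_bi = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), summit_offset = numeric(),
                      score = numeric(), individual = character(),
                      condition = character(), tf = character(),
                      is_spurious = logical(), truth_bi = integer()))
  }
  peaks <- do.call(rbind, rows)
  peaks$strand <- "*"
  peaks$qvalue <- stats::runif(nrow(peaks), 2, 10)
  rownames(peaks) <- NULL
  peaks
}

#' Simulate a differential-expression p-value table
#'
#' Background genes draw p ~ Uniform(0,1); target genes draw
#' p ~ Beta(shape, 1) with shape < 1 concentrating mass near 0
#' (shape = 1 reproduces the null).
#'
#' @param genes Gene table or character vector of gene ids.
#' @param target_set Gene ids in the enriched set.
#' @param shape Beta shape parameter for targets (default 0.2).
#' @param seed Integer seed.
#' @return data.frame `gene_id`, `p_value`.
#' @export
generate_expression <- function(genes, target_set, shape = 0.2, seed = 1) {
  set.seed(seed)
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  stopifnot(all(target_set %in% ids))
  p <- stats::runif(length(ids))
  tgt <- ids %in% target_set
  p[tgt] <- stats::rbeta(sum(tgt), shape, 1)
  data.frame(gene_id = ids, p_value = p, stringsAsFactors = FALSE)
}

#' Simulate allelic read counts at a heterozygous SNP
#'
#' Per individual, `count_a ~ Binomial(depth, ratio)`. Optionally emits a
#' minimal SAM file per individual with reads spanning the SNP carrying
#' the drawn bases, to exercise [count_alleles()] end to end.
#'
#' @param ratio True allele-A fraction (default 0.661).
#' @param depth Reads per individual (default 100).
#' @param n_individuals Number of heterozygous individuals (default 5).
#' @param seed Integer seed.
#' @param snp SNP descriptor (list with `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`); a default on `contig_1` is used if NULL.
#' @param chrom_len Reference length for SAM emission (default 500000).
#' @param sam_dir If non-NULL, write one SAM per individual here.
#' @return List with `counts` (data.frame `individual`, `snp_id`,
#'   `count_a`, `count_b`), `snp`, `ratio`, and `sam_paths` (or NULL).
#' @export
generate_allelic_reads <- function(ratio = 0.661, depth = 100,
                                   n_individuals = 5, seed = 1,
                                   snp = NULL, chrom_len = 500000,
                                   sam_dir = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  set.seed(seed)
  if (is.null(snp))
    snp <- list(snp_id = "snp_sim_1", chrom = "contig_1",
                pos = floor(chrom_len / 2), allele_a = "A",
                allele_b = "G")
  count_a <- stats::rbinom(n_individuals, depth, ratio)
  counts <- data.frame(individual = paste0("ind", seq_len(n_individuals)),
                       snp_id = snp$snp_id, count_a = count_a,
                       count_b = depth - count_a,
                       stringsAsFactors = FALSE)
  sam_paths <- NULL
  if (!is.null(sam_dir)) {
    dir.create(sam_dir, showWarnings = FALSE, recursive = TRUE)
    sam_paths <- vapply(seq_len(n_individuals), function(i) {
      p <- file.path(sam_dir, paste0("ind", i, ".sam"))
      write_allelic_sam(counts$count_a[i], counts$count_b[i], snp,
                        chrom_len, p)
      p
    }, character(1))
  }
  list(counts = counts, snp = snp, ratio = ratio, sam_paths = sam_paths)
}

#' Write a minimal SAM file of reads spanning one SNP
#'
#' Emits single-end, high-quality (MAPQ 60, base quality 40) reads whose
#' base at the SNP position carries the requested allele; other bases are
#' random. Uses the current RNG state.
#'
#' @param n_a,n_b Number of reads carrying allele A / allele B.
#' @param snp SNP descriptor (see [generate_allelic_reads()]).
#' @param chrom_len Reference contig length for the header.
#' @param path Output SAM path.
#' @param read_len Read length (default 50).
#' @return `path`, invisibly.
#' @export
write_allelic_sam <- function(n_a, n_b, snp, chrom_len, path,
                              read_len = 50) {
  pos1 <- snp$pos + 1
  alleles <- c(rep(toupper(snp$allele_a), n_a),
               rep(toupper(snp$allele_b), n_b))
  n <- length(alleles)
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", snp$chrom, "\tLN:",
                    format(chrom_len, scientific = FALSE)))
  if (n) {
    offs <- sample.int(read_len, n, replace = TRUE) - 1L
    starts <- pmax(1L, pmin(pos1 - offs,
                            as.integer(chrom_len) - read_len + 1L))
    recs <- vapply(seq_len(n), function(i) {
      sq <- sample(c("A", "C", "G", "T"), read_len, replace = TRUE)
      sq[pos1 - starts[i] + 1] <- alleles[i]
      paste("read", snp$snp_id, i, sep = "_") |>
        paste(0, snp$chrom, starts[i], 60, paste0(read_len, "M"),
              "*", 0, 0, paste(sq, collapse = ""),
              strrep("I", read_len), sep = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate genotype dosages and a mediated expression structure
#'
#' Draws Hardy-Weinberg genotypes at one eSNP; the cis trait ("CIITA")
#' is `beta_cis * dosage + noise`; each trans gene is `beta_trans * cis
#' trait + noise` (mediation); null genes are pure noise.
#'
#' @param n Individuals (default 281).
#' @param maf Minor-allele frequency (0 < maf < 0.5; default 0.3).
#' @param beta_cis Cis effect size (default 0.5).
#' @param trans_genes Character vector of trans gene ids.
#' @param beta_trans Trans (mediated) effect size (default 2).
#' @param noise_sd Residual SD (default 1).
#' @param null_genes Character vector of unaffected gene ids.
#' @param seed Integer seed.
#' @return List with `dosage` (length-n integer vector), `expression`
#'   (n x genes matrix; first column `CIITA`), and `truth` (the planted
#'   parameters).
#' @export
generate_genotypes_expression <- function(n = 281, maf = 0.3,
                                          beta_cis = 0.5,
                                          trans_genes = paste0("trans_", 1:12),
                                          beta_trans = 2, noise_sd = 1,
                                          null_genes = paste0("null_", 1:20),
                                          seed = 1) {
  if (maf <= 0 || maf >= 0.5) stop("maf must be in (0, 0.5)")
  set.seed(seed)
  dosage <- stats::rbinom(n, 2, maf)
  ciita <- beta_cis * dosage + stats::rnorm(n, 0, noise_sd)
  expr <- matrix(NA_real_, n, 1 + length(trans_genes) + length(null_genes),
                 dimnames = list(NULL, c("CIITA", trans_genes, null_genes)))
  expr[, "CIITA"] <- ciita
  for (g in trans_genes)
    expr[, g] <- beta_trans * ciita + stats::rnorm(n, 0, noise_sd)
  for (g in null_genes)
    expr[, g] <- stats::rnorm(n, 0, noise_sd)
  list(dosage = dosage, expression = expr,
       truth = list(maf = maf, beta_cis = beta_cis,
                    beta_trans = beta_trans, noise_sd = noise_sd,
                    trans_genes = trans_genes, null_genes = null_genes))
}
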