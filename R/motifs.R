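# PWM parsing, MATCH-style matrix-similarity scoring, and the ordered
# RFX5 -> CREB -> NF-Y tri-motif module search in summit-centred segments.
#
# The similarity score of a window against a PWM is the
# information-weighted, min-max normalised MATCH score:
#   score = (Current - Min) / (Max - Min),  Current = sum_i I(i) f(i, b_i)
# with I(i) = sum_b f(i,b) ln(4 f(i,b)), and Min/Max the per-position
# worst/best attainable contributions. Scores live in [0, 1]; the
# consensus scores 1 and the per-position-worst sequence scores 0.

.PWM_BASES <- c("A", "C", "G", "T")

#' Build a PWM from a count (or frequency) matrix
#'
#' Columns are positions; rows A, C, G, T. Counts are converted to column
#' frequencies, a pseudocount of 0.01 is added to every frequency cell
#' and columns are renormalised, then the per-position information
#' vector `I(i) = sum_b f(i,b) ln(4 f(i,b))` is computed.
#'
#' @param counts Numeric 4 x L matrix (rows in A, C, G, T order).
#' @param name Motif name.
#' @param pseudocount Frequency added to every cell before
#'   renormalisation (default 0.01).
#' @return Object of class `pwm`: list with `name`, `mat` (4 x L
#'   frequency matrix), `info` (length-L information vector), `length`.
#' @export
make_pwm <- function(counts, name = "pwm", pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4)
    stop("PWM matrix must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("negative PWM counts")
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("PWM column with zero total count")
  f <- sweep(counts, 2, cs, "/") + pseudocount
  f <- sweep(f, 2, colSums(f), "/")
  rownames(f) <- .PWM_BASES
  info <- colSums(f * log(4 * f))
  structure(list(name = name, mat = f, info = info, length = ncol(f)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- length", x$length,
      "- total information", round(sum(x$info), 3), "nats\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A `pwm` object.
#' @return Character string of per-position most-frequent bases (ties to
#'   the first of A, C, G, T).
#' @export
pwm_consensus <- function(pwm) {
  paste(.PWM_BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Read a JASPAR-style PWM file
#'
#' Expects a `>identifier name` header line followed by four rows
#' `A [ 4 19 0 ... ]` (brackets optional) in A, C, G, T order.
#'
#' @param path Path to the matrix file.
#' @param pseudocount Passed to [make_pwm()].
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- "pwm"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) != 4)
    stop("JASPAR matrix must have exactly 4 base rows, found ",
         length(lines))
  rows <- lapply(lines, function(l) {
    l <- gsub("[][]", " ", l)
    toks <- strsplit(l, "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!toks[1] %in% .PWM_BASES)
      stop("PWM row must start with a base letter: ", l)
    list(base = toks[1],
         counts = suppressWarnings(as.numeric(toks[-1])))
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (!identical(bases, .PWM_BASES))
    stop("PWM rows must appear in A, C, G, T order")
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  if (anyNA(counts)) stop("non-numeric PWM count")
  make_pwm(counts, name = name, pseudocount = pseudocount)
}

## encode an ACGTN string as integer codes 1..4 (N and others = 5)
.encode_seq <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  code <- match(v, .PWM_BASES)
  code[is.na(code)] <- 5L
  code
}

## per-position contribution lookup: 5 x L (row 5 = N -> per-position min)
.contrib_matrix <- function(pwm) {
  w <- pwm$mat * rep(pwm$info, each = 4)
  rbind(w, apply(w, 2, min))
}

#' MATCH matrix-similarity score of a single window
#'
#' @param pwm A `pwm` object.
#' @param window Character string of length `pwm$length` over
#'   `{A,C,G,T,N}` (case-insensitive). `N` contributes the per-position
#'   minimum.
#' @return Score in `[0, 1]`; 0 is returned for a zero-information
#'   (degenerate) matrix.
#' @export
match_score <- function(pwm, window) {
  code <- .encode_seq(window)
  if (length(code) != pwm$length)
    stop("window length ", length(code), " != PWM length ", pwm$length)
  w <- .contrib_matrix(pwm)
  cur <- sum(w[cbind(code, seq_len(pwm$length))])
  lo <- sum(w[5, ]); hi <- sum(apply(w[1:4, , drop = FALSE], 2, max))
  if (hi <= lo) return(0)
  (cur - lo) / (hi - lo)
}

#' Score a PWM at every start position of a sequence
#'
#' @param pwm A `pwm` object.
#' @param sequence Character string (length >= PWM length).
#' @return Numeric vector of match scores, element `k` for the window
#'   starting at 0-based offset `k - 1`.
#' @export
pwm_scan <- function(pwm, sequence) {
  code <- .encode_seq(sequence)
  L <- pwm$length
  n <- length(code) - L + 1
  if (n < 1) stop("sequence shorter than PWM")
  w <- .contrib_matrix(pwm)
  lo <- sum(w[5, ]); hi <- sum(apply(w[1:4, , drop = FALSE], 2, max))
  idx <- outer(seq_len(n) - 1L, seq_len(L), "+")
  cur <- matrix(w[cbind(as.vector(code[idx]),
                        rep(seq_len(L), each = n))], nrow = n)
  cur <- rowSums(cur)
  if (hi <= lo) return(rep(0, n))
  (cur - lo) / (hi - lo)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Best ordered tri-motif module placement in a segment
#'
#' Searches all placements of the three PWMs (given in module order,
#' canonically RFX5, CREB, NF-Y) with strictly increasing, non-overlapping
#' starts on one orientation of the segment. Both orientations are
#' evaluated and the placement maximising the average of the three match
#' scores is returned; ties are broken by leftmost first-motif start,
#' then second, then third, then forward orientation.
#'
#' @param segment Character string (typically 150 bp).
#' @param pwms List of three `pwm` objects in required 5'-to-3' order.
#' @return List of class `module_hit`: `placements` (data.frame motif /
#'   start (0-based, on the scanned orientation) / score), `orientation`
#'   (`"+"` forward, `"-"` reverse complement), `order_valid`,
#'   `avg_score`.
#' @export
best_ordered_module <- function(segment, pwms) {
  stopifnot(length(pwms) == 3)
  lens <- vapply(pwms, `[[`, numeric(1), "length")
  n <- nchar(segment)
  if (sum(lens) > n)
    stop("combined PWM length ", sum(lens),
         " exceeds segment length ", n)
  best <- NULL
  for (orient in c("+", "-")) {
    s <- if (orient == "+") segment else .revcomp(segment)
    sc <- lapply(pwms, pwm_scan, sequence = s)
    hit <- .ordered_dp(sc, lens)
    if (is.null(hit)) next
    hit$orientation <- orient
    if (is.null(best) || hit$avg_score > best$avg_score)
      best <- hit
  }
  if (is.null(best)) {
    return(structure(list(placements = NULL, orientation = "+",
                          order_valid = FALSE, avg_score = 0),
                     class = "module_hit"))
  }
  names(best$scores) <- NULL
  placements <- data.frame(
    motif = vapply(pwms, `[[`, character(1), "name"),
    start = best$starts, score = best$scores,
    stringsAsFactors = FALSE)
  structure(list(placements = placements, orientation = best$orientation,
                 order_valid = TRUE, avg_score = best$avg_score),
            class = "module_hit")
}

#' @export
print.module_hit <- function(x, ...) {
  cat("module hit: avg score", round(x$avg_score, 4),
      "orientation", x$orientation, "\n")
  if (!is.null(x$placements)) print(x$placements)
  invisible(x)
}

## smallest index k >= j attaining max(v[j:n]), for every j
.suffix_argmax <- function(v) {
  n <- length(v)
  arg <- integer(n)
  arg[n] <- n
  if (n >= 2) for (j in (n - 1):1)
    arg[j] <- if (v[j] >= v[arg[j + 1]]) j else arg[j + 1]
  arg
}

## dynamic programme over ordered non-overlapping placements; returns the
## lexicographically smallest (start1, start2, start3) among maximisers
.ordered_dp <- function(scores, lens) {
  n3 <- length(scores[[3]])
  arg3 <- .suffix_argmax(scores[[3]])
  best3 <- scores[[3]][arg3]
  n2 <- length(scores[[2]])
  v2 <- rep(-Inf, n2)
  ok2 <- seq_len(n2)[seq_len(n2) + lens[2] <= n3]
  v2[ok2] <- scores[[2]][ok2] + best3[ok2 + lens[2]]
  if (!length(ok2)) return(NULL)
  arg23 <- .suffix_argmax(v2)
  best23 <- v2[arg23]
  n1 <- length(scores[[1]])
  v1 <- rep(-Inf, n1)
  ok1 <- seq_len(n1)[seq_len(n1) + lens[1] <= n2]
  v1[ok1] <- scores[[1]][ok1] + best23[ok1 + lens[1]]
  if (!length(ok1) || !any(is.finite(v1))) return(NULL)
  p1 <- which(v1 == max(v1))[1]
  p2 <- arg23[p1 + lens[1]]
  p3 <- arg3[p2 + lens[2]]
  sc <- c(scores[[1]][p1], scores[[2]][p2], scores[[3]][p3])
  list(starts = as.integer(c(p1, p2, p3) - 1L), scores = sc,
       avg_score = mean(sc))
}

.load_genome <- function(genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract fixed-width segments centred on BI summits
#'
#' Extracts the `[summit - flank, summit + flank)` window for every BI
#' with a representative summit. Segments truncated by contig ends are
#' dropped with a warning.
#'
#' @param bis BI data.frame with a `summit` column (absolute 0-based).
#' @param genome `DNAStringSet` (names = chromosomes) or FASTA path.
#' @param flank Half-width in bp (default 75, i.e. 150 bp segments).
#' @return data.frame with `segment_id`, `chrom`, `start`, `end`,
#'   `sequence` (uppercase).
#' @export
extract_segments <- function(bis, genome, flank = 75) {
  genome <- .load_genome(genome)
  stopifnot("summit" %in% names(bis))
  n <- nrow(bis)
  keep <- logical(n); seqs <- character(n)
  starts <- bis$summit - flank; ends <- bis$summit + flank
  for (i in seq_len(n)) {
    chrom <- bis$chrom[i]
    if (!chrom %in% names(genome)) next
    clen <- Biostrings::width(genome[chrom])
    if (starts[i] < 0 || ends[i] > clen) next
    seqs[i] <- toupper(as.character(
      Biostrings::subseq(genome[[chrom]], start = starts[i] + 1,
                         width = 2 * flank)))
    keep[i] <- TRUE
  }
  if (any(!keep))
    warning(sum(!keep), " segment(s) dropped: summit window off contig")
  data.frame(segment_id = paste0("seg_", which(keep)),
             chrom = bis$chrom[keep], start = starts[keep],
             end = ends[keep], sequence = seqs[keep],
             stringsAsFactors = FALSE)
}

#' Random control segments from gene promoter windows
#'
#' For each of `n_genes` genes sampled without replacement, one segment
#' of `seg_len` bp is drawn uniformly from the strand-oriented window
#' spanning `upstream` bp 5' to `downstream` bp 3' of the TSS. Segments
#' from minus-strand genes are reverse-complemented (reported 5'-to-3').
#' Genes whose window leaves the contig are resampled (with a message).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param genome `DNAStringSet` or FASTA path.
#' @param n_genes Number of control genes to sample (default 1000).
#' @param upstream,downstream Window extent around the TSS in bp
#'   (defaults 10000 and 150).
#' @param seg_len Segment length in bp (default 150).
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with `segment_id`, `gene_id`, `chrom`, `start`,
#'   `end` (genome coordinates), `sequence` (oriented 5'-to-3').
#' @export
control_segments <- function(genes, genome, n_genes = 1000,
                             upstream = 10000, downstream = 150,
                             seg_len = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- .load_genome(genome)
  if (nrow(genes) < n_genes)
    stop("fewer than n_genes genes available")
  win_len <- upstream + downstream
  pool <- sample(nrow(genes))
  out <- list(); taken <- 0L; k <- 0L
  while (taken < n_genes && k < length(pool)) {
    k <- k + 1L
    gi <- pool[k]
    chrom <- genes$chrom[gi]; tss <- genes$tss[gi]
    strand <- genes$strand[gi]
    if (!chrom %in% names(genome)) next
    clen <- Biostrings::width(genome[chrom])
    offset <- sample.int(win_len - seg_len + 1, 1) - 1L
    if (strand == "+") {
      s <- tss - upstream + offset
    } else {
      s <- tss + upstream - offset - seg_len + 1
    }
    e <- s + seg_len
    if (s < 0 || e > clen) {
      message("control segment for ", genes$gene_id[gi],
              " off contig; gene resampled")
      next
    }
    sq <- toupper(as.character(
      Biostrings::subseq(genome[[chrom]], start = s + 1, width = seg_len)))
    if (strand == "-") sq <- .revcomp(sq)
    taken <- taken + 1L
    out[[taken]] <- data.frame(
      segment_id = paste0("ctrl_", taken), gene_id = genes$gene_id[gi],
      chrom = chrom, start = s, end = e, sequence = sq,
      stringsAsFactors = FALSE)
  }
  if (taken < n_genes)
    stop("could not place ", n_genes, " control segments")
  do.call(rbind, out)
}

#' Score segments for the ordered tri-motif module
#'
#' @param segments Segment data.frame with a `sequence` column.
#' @param pwms List of three `pwm` objects in module order.
#' @return The input with columns `avg_score` and `order_valid` added,
#'   plus per-motif scores named after each PWM.
#' @export
score_segments <- function(segments, pwms) {
  hits <- lapply(segments$sequence, best_ordered_module, pwms = pwms)
  segments$avg_score <- vapply(hits, `[[`, numeric(1), "avg_score")
  segments$order_valid <- vapply(hits, `[[`, logical(1), "order_valid")
  for (j in seq_along(pwms)) {
    segments[[paste0("score_", pwms[[j]]$name)]] <-
      vapply(hits, function(h)
        if (h$order_valid) h$placements$score[j] else NA_real_, numeric(1))
  }
  segments
}

#' Mann-Whitney comparison of two score groups
#'
#' Standard two-sided rank-sum test (exact where possible, tie-corrected
#' normal approximation otherwise), with group medians reported.
#'
#' @param scores_a,scores_b Non-empty numeric vectors.
#' @return List with `statistic` (U), `p_value`, `median_a`, `median_b`.
#' @export
compare_score_groups <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b))
    stop("both score groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, alternative = "two.sided"))
  p <- wt$p.value
  # fully tied samples make the tie-corrected normal approximation 0/0;
  # there is no evidence against equality, so report p = 1
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = p,
       median_a = stats::median(scores_a),
       median_b = stats::median(scores_b))
}
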