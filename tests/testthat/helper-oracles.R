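# Brute-force oracles, independent of the package's interval / DP
# machinery, used to validate the fast implementations on random inputs.

# random interval set on one toy chromosome
rand_intervals <- function(n, chrom = "c1", max_pos = 10000,
                           max_width = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals(chrom, start, start + width)
}

# per-base boolean-array merge oracle (single chromosome groups)
oracle_merge <- function(x, gap = 0) {
  out <- list()
  for (chrom in sort(unique(x$chrom))) {
    xi <- x[x$chrom == chrom, , drop = FALSE]
    L <- max(xi$end) + 1
    cov <- logical(L)
    for (i in seq_len(nrow(xi))) cov[(xi$start[i] + 1):xi$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
    if (gap > 0 && nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        if (runs$start[i] - merged$end[nrow(merged)] <= gap)
          merged$end[nrow(merged)] <- runs$end[i]
        else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    if (nrow(runs))
      out[[chrom]] <- data.frame(chrom = chrom, start = runs$start,
                                 end = runs$end, strand = "*")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# quadratic all-pairs overlap oracle
oracle_pairs <- function(a, b, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      rows[[length(rows) + 1]] <- data.frame(query = i, subject = j,
                                             overlap = ov)
  }
  if (!length(rows))
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  do.call(rbind, rows)
}

# per-base consensus oracle: maximal runs covered by both individuals
oracle_consensus <- function(p1, p2, chrom = "c1") {
  L <- max(c(p1$end, p2$end)) + 1
  c1 <- logical(L); c2 <- logical(L)
  for (i in seq_len(nrow(p1))) c1[(p1$start[i] + 1):p1$end[i]] <- TRUE
  for (i in seq_len(nrow(p2))) c2[(p2$start[i] + 1):p2$end[i]] <- TRUE
  both <- c1 & c2
  if (!any(both))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(chrom = chrom, start = starts[r$values] - 1,
             end = ends[r$values])
}

# quadratic TSS-distance association oracle
oracle_associate <- function(bis, genes, max_dist = 10000,
                             proximal_dist = 2000) {
  rows <- list()
  for (j in seq_len(nrow(genes))) for (i in seq_len(nrow(bis))) {
    if (bis$chrom[i] != genes$chrom[j]) next
    t <- genes$tss[j]; s <- bis$start[i]; e <- bis$end[i]
    raw <- if (t >= s && t < e) 0 else if (t < s) s - t else t - (e - 1)
    if (raw >= max_dist) next
    sign_g <- if (raw == 0) 0 else if (t < s) 1 else -1
    d <- if (genes$strand[j] == "+") sign_g * raw else -sign_g * raw
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = genes$gene_id[j], bi = i, distance = d,
      class = if (abs(d) <= proximal_dist) "proximal" else "distal")
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), bi = integer(),
                      distance = numeric(), class = character()))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$bi), , drop = FALSE]
}

# exhaustive ordered-placement module oracle (small instances only)
oracle_module <- function(segment, pwms) {
  lens <- vapply(pwms, `[[`, numeric(1), "length")
  best <- -Inf
  for (orient in c("+", "-")) {
    s <- if (orient == "+") segment else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(segment)))
    n <- nchar(s)
    pos <- expand.grid(p1 = seq_len(n - lens[1] + 1),
                       p2 = seq_len(n - lens[2] + 1),
                       p3 = seq_len(n - lens[3] + 1))
    pos <- pos[pos$p2 >= pos$p1 + lens[1] & pos$p3 >= pos$p2 + lens[2], ]
    if (!nrow(pos)) next
    sc <- lapply(1:3, function(k) {
      starts <- sort(unique(pos[[k]]))
      v <- vapply(starts, function(p)
        match_score(pwms[[k]], substr(s, p, p + lens[k] - 1)), numeric(1))
      v[match(pos[[k]], starts)]
    })
    avg <- (sc[[1]] + sc[[2]] + sc[[3]]) / 3
    best <- max(best, max(avg))
  }
  best
}

# exact Mann-Whitney two-sided p by enumeration (no ties, small groups)
oracle_mw_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  vals <- c(a, b)
  stopifnot(!anyDuplicated(vals))
  r <- rank(vals)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  list(U = u_obs, p = p)
}

# small random PWM for oracle comparisons
rand_pwm <- function(L = 4, name = "toy") {
  make_pwm(matrix(sample.int(20, 4 * L, replace = TRUE), 4, L),
           name = name)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
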