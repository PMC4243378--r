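toy_counts <- matrix(c(2, 1, 1, 0,
                       4, 0, 0, 0,
                       1, 1, 1, 1), 4, 3)

test_that("PWM construction normalises columns and computes information", {
  p <- make_pwm(toy_counts, name = "toy")
  expect_equal(colSums(p$mat), rep(1, 3))
  # frozen hand-computed values: f = (counts/colsum + 0.01)/1.04,
  # I = sum f ln(4f)
  expect_equal(p$info, c(0.299058531652, 1.223895502372, 0),
               tolerance = 1e-10)
  expect_true(all(p$info >= 0))
  expect_error(make_pwm(toy_counts[1:3, ]), "4 rows")
})

test_that("JASPAR parsing round-trips counts with brackets and header", {
  f <- withr::local_tempfile()
  writeLines(c(">MA0000.1 toy",
               "A [ 2 4 1 ]", "C [ 1 0 1 ]", "G [ 1 0 1 ]",
               "T [ 0 0 1 ]"), f)
  p <- read_pwm(f)
  expect_equal(p$length, 3)
  expect_equal(p$mat, make_pwm(toy_counts)$mat)
  writeLines(c(">x", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(read_pwm(f), "4 base rows")
})

test_that("match_score is min-max normalised, case-insensitive, and exact on enumeration", {
  p <- make_pwm(toy_counts)
  cons <- pwm_consensus(p)
  expect_equal(match_score(p, cons), 1)
  expect_equal(match_score(p, tolower(cons)), 1)
  # per-position worst bases score 0
  w <- p$mat * rep(p$info, each = 4)
  worst <- c("A", "C", "G", "T")[apply(w, 2, which.min)]
  expect_equal(match_score(p, paste(worst, collapse = "")), 0)
  expect_error(match_score(p, "AC"), "length")

  # brute-force check over all 64 3-mers: scores in [0,1], min/max attained
  kmers <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                             b2 = c("A", "C", "G", "T"),
                             b3 = c("A", "C", "G", "T")), 1, paste,
                 collapse = "")
  sc <- vapply(kmers, match_score, numeric(1), pwm = p)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(max(sc), 1)
  expect_equal(min(sc), 0)
  # direct-formula oracle
  w <- p$mat * rep(p$info, each = 4)
  lo <- sum(apply(w, 2, min)); hi <- sum(apply(w, 2, max))
  oracle <- vapply(kmers, function(k) {
    b <- match(strsplit(k, "")[[1]], c("A", "C", "G", "T"))
    (sum(w[cbind(b, 1:3)]) - lo) / (hi - lo)
  }, numeric(1))
  expect_equal(sc, oracle)
})

test_that("N windows never beat the worst-base substitution", {
  set.seed(5)
  p <- rand_pwm(6)
  for (i in 1:10) {
    s <- strsplit(rand_seq(6), "")[[1]]
    j <- sample(6, 1)
    sN <- s; sN[j] <- "N"
    worst <- c("A", "C", "G", "T")[which.min(p$mat[, j])]
    sW <- s; sW[j] <- worst
    expect_lte(match_score(p, paste(sN, collapse = "")),
               match_score(p, paste(sW, collapse = "")) + 1e-12)
  }
})

test_that("ordered module search equals the exhaustive-placement oracle", {
  set.seed(19)
  pwms <- list(rand_pwm(4, "m1"), rand_pwm(4, "m2"), rand_pwm(4, "m3"))
  for (rep in 1:20) {
    seg <- rand_seq(40)
    hit <- best_ordered_module(seg, pwms)
    expect_true(hit$order_valid)
    expect_equal(hit$avg_score, oracle_module(seg, pwms),
                 tolerance = 1e-12)
    # placements are ordered and non-overlapping
    st <- hit$placements$start
    expect_true(all(diff(st) >= 4))
  }
  expect_error(best_ordered_module(rand_seq(10), pwms), "exceeds")
})

test_that("planted consensus modules score 1 and all-N segments score 0", {
  pwms <- enhmap_pwms()
  cons <- vapply(pwms, pwm_consensus, character(1))
  seg <- paste0(strrep("T", 20), cons[1], strrep("T", 10), cons[2],
                strrep("T", 10), cons[3], strrep("T", 20))
  seg <- paste0(seg, strrep("T", 150 - nchar(seg)))
  hit <- best_ordered_module(seg, pwms)
  expect_equal(hit$avg_score, 1)
  expect_true(hit$order_valid)
  expect_equal(hit$orientation, "+")
  expect_equal(hit$placements$start, c(20, 20 + 14 + 10, 20 + 14 + 10 + 8 + 10))

  hitN <- best_ordered_module(strrep("N", 150), pwms)
  expect_equal(hitN$avg_score, 0)

  # scrambling one motif strictly lowers the module score
  seg_scramble <- sub(cons[2], paste(rev(strsplit(cons[2], "")[[1]]),
                                     collapse = ""), seg, fixed = TRUE)
  expect_lt(best_ordered_module(seg_scramble, pwms)$avg_score, 1)
})

test_that("module search finds reverse-orientation modules", {
  pwms <- enhmap_pwms()
  cons <- vapply(pwms, pwm_consensus, character(1))
  fwd <- paste0(strrep("T", 20), cons[1], strrep("T", 10), cons[2],
                strrep("T", 10), cons[3], strrep("T", 58))
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd)))
  hit <- best_ordered_module(rev, pwms)
  expect_equal(hit$avg_score, 1)
  expect_equal(hit$orientation, "-")
})

test_that("segment extraction is summit-centred and drops contig edges", {
  genome <- Biostrings::DNAStringSet(c(c1 = rand_seq(10000)))
  bis <- genomic_intervals("c1", c(900, 0), c(1100, 50))
  bis$summit <- c(1000, 10)
  expect_warning(segs <- extract_segments(bis, genome), "dropped")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 925)
  expect_equal(segs$end, 1075)
  expect_equal(segs$sequence,
               toupper(as.character(Biostrings::subseq(genome[[1]], 926, 1075))))
  expect_equal(nchar(segs$sequence), 150)
})

test_that("control segments are reproducible, 150 bp, and uniform in the window", {
  set.seed(2)
  g <- generate_genome(n_contigs = 1, contig_len = 200000, n_genes = 30,
                       seed = 2)
  a <- control_segments(g$genes, g$genome, n_genes = 20, seed = 99)
  b <- control_segments(g$genes, g$genome, n_genes = 20, seed = 99)
  expect_identical(a, b)
  expect_true(all(nchar(a$sequence) == 150))
  expect_true(all(a$end - a$start == 150))
  expect_error(control_segments(g$genes, g$genome, n_genes = 500),
               "fewer")

  # start-offset uniformity over the 10,001 valid window offsets for one
  # plus-strand gene
  gene <- g$genes[g$genes$strand == "+", ][1, , drop = FALSE]
  genes1 <- do.call(rbind, replicate(10000, gene, simplify = FALSE))
  genes1$gene_id <- paste0("g", 1:10000)
  segs <- control_segments(genes1, g$genome, n_genes = 10000, seed = 4)
  offs <- segs$start - (gene$tss - 10000)
  expect_true(all(offs >= 0 & offs <= 10000))
  cs <- chisq.test(table(cut(offs, breaks = seq(-0.5, 10000.5,
                                                length.out = 11))))
  expect_gt(cs$p.value, 0.01)
})

test_that("Mann-Whitney comparison matches exact enumeration for small groups", {
  res <- compare_score_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_error(compare_score_groups(numeric(), 1:3), "non-empty")

  x <- c(0.3, 0.3, 0.3); expect_gt(compare_score_groups(x, x)$p_value, 0.99)

  set.seed(13)
  for (rep in 1:10) {
    a <- round(runif(sample(3:5, 1)), 6)
    b <- round(runif(sample(3:5, 1)), 6)
    want <- oracle_mw_exact(a, b)
    got <- compare_score_groups(a, b)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p)
  }
})
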