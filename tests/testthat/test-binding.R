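# helpers to build peak tables for one (condition, factor) group
peak_row <- function(start, end, individual, score = 50,
                     condition = "naive", tf = "CIITA") {
  data.frame(chrom = "c1", start = start, end = end,
             summit_offset = floor((end - start) / 2), score = score,
             individual = individual, condition = condition, tf = tf,
             stringsAsFactors = FALSE)
}

test_that("BI derivation takes the replicate intersection", {
  pk <- rbind(peak_row(100, 300, "ind1"), peak_row(250, 400, "ind2"))
  bis <- derive_binding_intervals(pk)
  expect_equal(nrow(bis), 1)
  expect_equal(bis$start, 250)
  expect_equal(bis$end, 300)

  pk <- rbind(peak_row(100, 200, "ind1"), peak_row(300, 400, "ind2"))
  expect_equal(nrow(derive_binding_intervals(pk)), 0)

  expect_error(derive_binding_intervals(peak_row(1, 10, "ind1")),
               "exactly 2")
})

test_that("BI derivation matches the per-base consensus oracle and ignores order", {
  set.seed(11)
  for (rep in 1:15) {
    p1 <- rand_intervals(30, max_pos = 100000, max_width = 800)
    p2 <- rand_intervals(30, max_pos = 100000, max_width = 800)
    pk <- rbind(
      cbind(p1[, 1:3], summit_offset = floor((p1$end - p1$start) / 2),
            score = runif(30, 1, 100), individual = "ind1",
            condition = "naive", tf = "CIITA"),
      cbind(p2[, 1:3], summit_offset = floor((p2$end - p2$start) / 2),
            score = runif(30, 1, 100), individual = "ind2",
            condition = "naive", tf = "CIITA"))
    got <- derive_binding_intervals(pk)
    want <- oracle_consensus(p1, p2)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # shuffle invariance
    got2 <- derive_binding_intervals(pk[sample(nrow(pk)), ])
    expect_equal(got2$start, got$start)
    # every BI carries peaks from both individuals
    expect_true(all(vapply(got$member_peaks, function(ix)
      setequal(unique(pk$individual[ix]), c("ind1", "ind2")),
      logical(1))))
  }
})

test_that("representative summit comes from the highest-scoring member peak", {
  pk <- rbind(peak_row(100, 300, "ind1", score = 10),
              peak_row(150, 350, "ind2", score = 90))
  bis <- derive_binding_intervals(pk)
  expect_equal(bis$summit, 150 + 100)  # ind2 peak midpoint
})

test_that("CE-mark classification matches the all-pairs oracle", {
  ci <- genomic_intervals("c1", 10, 50, condition = "naive", tf = "CIITA")
  rf <- genomic_intervals("c1", 40, 90, condition = "naive", tf = "RFX5")
  res <- classify_ce_marks(ci, rf)
  expect_true(res$bis$is_ce_mark)
  expect_equal(unname(res$counts["ce"]), 1)

  rf2 <- genomic_intervals("c1", 500, 600)
  expect_false(classify_ce_marks(ci, rf2)$bis$is_ce_mark)

  set.seed(21)
  for (rep in 1:10) {
    ci <- rand_intervals(40)
    rf <- rand_intervals(40)
    mo <- sample(c(1, 25), 1)
    res <- classify_ce_marks(ci, rf, min_overlap = mo)
    want <- oracle_pairs(ci, rf, min_overlap = mo)
    expect_equal(which(res$bis$is_ce_mark), sort(unique(want$query)))
    expect_equal(unname(res$counts["ce"] + res$counts["ciita_only"]),
                 nrow(ci))
  }
})

test_that("CE fraction is non-increasing in min_overlap", {
  set.seed(31)
  ci <- rand_intervals(60)
  rf <- rand_intervals(60)
  fr <- vapply(c(1, 10, 50, 200), function(mo)
    mean(classify_ce_marks(ci, rf, min_overlap = mo)$bis$is_ce_mark),
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("DCS counts distinct co-incident tracks", {
  bi <- genomic_intervals("c1", 1000, 1400)
  tracks <- lapply(1:6, function(i) genomic_intervals("c1", 1200, 1300))
  names(tracks) <- c("DHS", "RFX5", "CREB1", "ATF1", "NFYA", "NFYB")
  expect_equal(compute_dcs(bi, tracks)$dcs, 6)
  far <- lapply(tracks, function(t) genomic_intervals("c1", 9000, 9100))
  expect_equal(compute_dcs(bi, far)$dcs, 0)
  expect_error(compute_dcs(bi, list()), "track")

  set.seed(41)
  bis <- rand_intervals(30)
  tr <- lapply(1:6, function(i) rand_intervals(20))
  names(tr) <- names(tracks)
  got <- compute_dcs(bis, tr)$dcs
  want <- vapply(seq_len(nrow(bis)), function(i)
    sum(vapply(tr, function(t)
      nrow(oracle_pairs(bis[i, ], t)) > 0, logical(1))), numeric(1))
  expect_equal(got, want)
})

test_that("condition-specific classification matches pairwise overlap", {
  a <- genomic_intervals("c1", c(0, 1000), c(100, 1100))
  res <- classify_condition_specific(list(naive = a, ifng = a))
  expect_true(all(res$naive$specificity == "shared"))
  b <- genomic_intervals("c1", c(5000, 7000), c(5100, 7100))
  res <- classify_condition_specific(list(naive = a, ifng = b))
  expect_true(all(res$naive$specificity == "condition_specific"))
  expect_error(classify_condition_specific(list(naive = a)), ">= 2")

  set.seed(51)
  x <- rand_intervals(30); y <- rand_intervals(30)
  res <- classify_condition_specific(list(naive = x, ifng = y))
  want <- oracle_pairs(x, y)
  expect_equal(which(res$naive$specificity == "shared"),
               sort(unique(want$query)))
})

test_that("region-stratified summary counts respect mask membership", {
  empty <- genomic_intervals(character(), integer(), integer(),
                             condition = character(), tf = character())
  s <- summarize_bis(empty)
  expect_true(all(s$counts$n == 0))

  bi <- genomic_intervals("chr6", 32500000, 32500400,
                          condition = "naive", tf = "CIITA")
  bi$is_ce_mark <- TRUE
  s <- summarize_bis(bi)
  n_of <- function(str) s$counts$n[s$counts$stratum == str]
  expect_equal(n_of("genome_wide"), 1)
  expect_equal(n_of("MHC"), 1)
  expect_equal(n_of("MHC_classII"), 1)
  expect_equal(n_of("MHC_classI"), 0)
  expect_equal(n_of("outside_MHC"), 0)
  # within-MHC + outside-MHC partition the genome-wide count
  expect_equal(n_of("MHC") + n_of("outside_MHC"), n_of("genome_wide"))
})

test_that("planted consensus peak pairs produce exactly K BIs despite spurious peaks", {
  set.seed(61)
  for (rep in 1:5) {
    K <- sample(5:40, 1)
    starts <- sort(sample(seq(2000, 400000, by = 2000), K))
    truth <- data.frame(chrom = "contig_1", start = starts,
                        end = starts + 400, condition = "naive",
                        tf = "CIITA", stringsAsFactors = FALSE)
    pk <- generate_peaks(truth, c(contig_1 = 500000), jitter_sd = 15,
                         fp_rate = 2, fn_rate = 0, seed = rep)
    bis <- derive_binding_intervals(pk)
    expect_equal(nrow(bis), K)
    # spurious peaks never contribute
    sp <- which(pk$is_spurious)
    expect_false(any(vapply(bis$member_peaks, function(ix)
      any(ix %in% sp), logical(1))))
  }
})
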