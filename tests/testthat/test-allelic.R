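toy_snp <- list(snp_id = "rs_test", chrom = "c1", pos = 5000,
                allele_a = "A", allele_b = "G")

test_that("allele counting from SAM honours planted counts and filters", {
  dir <- withr::local_tempdir()
  set.seed(1)
  sam <- file.path(dir, "ind.sam")
  write_allelic_sam(10, 0, toy_snp, 20000, sam)
  cc <- count_alleles(sam, toy_snp)
  expect_equal(cc$count_a, 10)
  expect_equal(cc$count_b, 0)
  expect_equal(cc$count_other, 0)

  # planted 66:34 split recovered exactly
  write_allelic_sam(66, 34, toy_snp, 20000, sam)
  cc <- count_alleles(sam, toy_snp)
  expect_equal(cc$count_a, 66)
  expect_equal(cc$count_b, 34)
  expect_equal(cc$depth, 100)

  # no covering reads -> zero counts
  far <- list(snp_id = "rs2", chrom = "c1", pos = 15000,
              allele_a = "A", allele_b = "G")
  cc0 <- count_alleles(sam, far)
  expect_equal(cc0$count_a + cc0$count_b, 0)

  expect_error(count_alleles(sam, list(snp_id = "x", chrom = "c1",
                                       pos = 999999, allele_a = "A",
                                       allele_b = "G")), "off reference")
  expect_error(count_alleles(sam, list(snp_id = "x", chrom = "c1",
                                       pos = 10, allele_a = "A",
                                       allele_b = "A")), "distinct")
})

test_that("asb_test reports fractions, SD and the cross-individual t-test", {
  cts <- data.frame(individual = paste0("i", 1:4),
                    count_a = c(50, 50, 50, 50),
                    count_b = c(50, 50, 50, 50))
  r <- asb_test(cts)
  expect_equal(r$mean_pct, 50)
  expect_equal(r$p_value, 1)

  cts <- data.frame(individual = paste0("i", 1:3),
                    count_a = c(10, 20, 30), count_b = c(0, 0, 0))
  expect_warning(r <- asb_test(cts), "machine floor")
  expect_equal(r$mean_pct, 100)
  expect_equal(r$sd_pct, 0)
  expect_lt(r$p_value, 1e-300)

  expect_error(asb_test(data.frame(individual = "i1", count_a = 3,
                                   count_b = 2)), ">= 2")
})

test_that("asb_test is label-symmetric", {
  set.seed(12)
  cts <- data.frame(individual = paste0("i", 1:5),
                    count_a = rbinom(5, 100, 0.66))
  cts$count_b <- 100 - cts$count_a
  r1 <- asb_test(cts)
  swapped <- data.frame(individual = cts$individual,
                        count_a = cts$count_b, count_b = cts$count_a)
  r2 <- asb_test(swapped)
  expect_equal(r1$mean_pct, 100 - r2$mean_pct)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("allelic PWM delta favours the better-matching allele", {
  # toy NF-KB matrix with consensus GGGGAAATGTCT; probes span an A/G SNP
  nfkb <- make_pwm(local({
    m <- matrix(1, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- strsplit("GGGGAAATGTCT", "")[[1]]
    for (i in 1:12) m[cons[i], i] <- 17
    m
  }), name = "NFKB_toy")
  a_probe <- "AGCTGAAAAGGGGAAATGTCTGAAA"
  g_probe <- "AGCTGAAAAGGGGGAATGTCTGAAA"
  # windows over the motif match within each probe
  ref <- substr(a_probe, 10, 21)
  alt <- substr(g_probe, 10, 21)
  d <- allele_pwm_delta(nfkb, ref, alt)
  expect_gt(d$delta, 0)
  expect_equal(d$score_ref, 1)

  expect_error(allele_pwm_delta(nfkb, ref, ref), "exactly 1")
  expect_error(allele_pwm_delta(nfkb, ref, substr(alt, 1, 11)),
               "equal length")
})

test_that("eQTL association recovers exact and planted slopes", {
  expect_error(eqtl_association(rep(1, 30), rnorm(30)), "constant")

  set.seed(44)
  d <- rbinom(100, 2, 0.4)
  # exact fits trigger summary.lm's perfect-fit warning; irrelevant here
  fit <- suppressWarnings(eqtl_association(d, 2 * d))
  expect_equal(fit$beta, 2)
  expect_lt(fit$p_value, 1e-12)

  # covariates enter the model; rank deficiency is an error
  cov <- cbind(rnorm(100))
  fit2 <- suppressWarnings(
    eqtl_association(d, 2 * d + cov[, 1], covariates = cov))
  expect_equal(fit2$beta, 2, tolerance = 1e-8)
  expect_error(eqtl_association(d, rnorm(100),
                                covariates = cbind(d, d)),
               "rank-deficient")

  # cis labelling by the 1 Mb rule
  fit3 <- suppressWarnings(
    eqtl_association(d, 2 * d, snp_chrom = "chr16", snp_pos = 1e6,
                     gene_chrom = "chr16", gene_tss = 15e5))
  expect_true(fit3$cis)
  fit4 <- suppressWarnings(
    eqtl_association(d, 2 * d, snp_chrom = "chr16", snp_pos = 1e6,
                     gene_chrom = "chr16", gene_tss = 3e6))
  expect_false(fit4$cis)
})

test_that("eQTL p-values are uniform under dosage permutation", {
  set.seed(55)
  d <- rbinom(120, 2, 0.3)
  y <- 0.8 * d + rnorm(120)
  ps <- vapply(1:1000, function(i)
    eqtl_association(sample(d), y)$p_value, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("trans-network integration flags BI-supported genes", {
  res <- data.frame(gene_id = character(), p_value = numeric(),
                    cis = logical())
  out <- integrate_trans_network(res, 1e-3, c("a"))
  expect_equal(nrow(out$table), 0)

  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    p_value = c(1e-6, 1e-5, 0.5, 1e-8),
                    cis = c(FALSE, FALSE, FALSE, TRUE))
  out <- integrate_trans_network(res, 1e-3, c("a", "zzz"))
  expect_equal(nrow(out$table), 2)  # c fails threshold, d is cis
  expect_equal(out$n_supported, 1)
  expect_equal(out$n_unsupported, 1)
  out_all <- integrate_trans_network(res, 1.0, character())
  expect_equal(nrow(out_all$table), 3)
})
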