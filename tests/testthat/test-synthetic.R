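test_that("genome generation is reproducible, spaced, and compositionally uniform", {
  g1 <- generate_genome(1, 100000, 10, seed = 3)
  g2 <- generate_genome(1, 100000, 10, seed = 3)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes, g2$genes)
  expect_error(generate_genome(1, 40000, 5), "50 kb")

  g0 <- generate_genome(1, 100000, 0, seed = 1)
  expect_equal(nrow(g0$genes), 0)

  # >= 5 kb TSS spacing
  g <- generate_genome(2, 500000, 180, seed = 5)
  sp <- unlist(lapply(split(g$genes$tss, g$genes$chrom),
                      function(t) diff(sort(t))))
  expect_true(all(sp >= 5000))

  # ~25% base composition over 1 Mb
  comp <- Biostrings::alphabetFrequency(g$genome, as.prob = TRUE,
                                        collapse = TRUE)[c("A", "C", "G", "T")]
  expect_true(all(abs(comp - 0.25) < 0.01))
})

test_that("module planting writes exact consensus at recorded offsets", {
  g <- generate_genome(1, 100000, 12, seed = 9)
  pwms <- enhmap_pwms()
  cons <- vapply(pwms, pwm_consensus, character(1))
  ids <- g$genes$gene_id[1:4]
  pl <- plant_modules(g$genome, g$genes, ids, cons, spacing = 10,
                      seed = 10)
  expect_equal(nrow(pl$truth), 4)
  for (i in 1:4) {
    for (k in 1:3) {
      s <- pl$truth[[paste0("start_", k)]][i]
      window <- as.character(Biostrings::subseq(
        pl$genome[[pl$truth$chrom[i]]], s + 1, width = nchar(cons[k])))
      expect_equal(window, unname(cons[k]))
      expect_equal(match_score(pwms[[k]], window), 1)
    }
  }
  # empty selection leaves the genome unchanged
  pl0 <- plant_modules(g$genome, g$genes, character(), cons, seed = 10)
  expect_identical(as.character(pl0$genome), as.character(g$genome))
})

test_that("noiseless peaks round-trip to the exact truth; fn_rate 1 gives none", {
  truth <- data.frame(chrom = "contig_1",
                      start = c(10000, 30000, 77000),
                      end = c(10400, 30500, 77380),
                      condition = "naive", tf = "CIITA",
                      stringsAsFactors = FALSE)
  pk <- generate_peaks(truth, c(contig_1 = 100000), jitter_sd = 0,
                       fp_rate = 0, fn_rate = 0, seed = 1)
  bis <- derive_binding_intervals(pk)
  expect_equal(bis$start, truth$start)
  expect_equal(bis$end, truth$end)

  pk_none <- generate_peaks(truth, c(contig_1 = 100000), fn_rate = 1,
                            fp_rate = 0, seed = 1)
  expect_equal(sum(!pk_none$is_spurious), 0)
})

test_that("DE generator: shape 1 is null, tiny shape is near-total enrichment", {
  ids <- paste0("g", 1:2000)
  tgt <- sample(ids, 100)
  null_pv <- generate_expression(ids, tgt, shape = 1, seed = 2)
  r <- rank_expression(null_pv)
  e <- ecdf_enrichment(r, tgt, n_boot = 5, n_mc = 500, seed = 2)
  expect_gt(e$p_value, 0.001)

  sharp <- generate_expression(ids, tgt, shape = 0.01, seed = 2)
  r2 <- rank_expression(sharp)
  u_t <- r2$u[match(tgt, r2$gene_id)]
  expect_gt(mean(u_t <= 0.06), 0.95)
})

test_that("allelic generator hits the planted ratio and SAM emission matches counts", {
  al <- generate_allelic_reads(ratio = 1.0, depth = 50,
                               n_individuals = 3, seed = 3)
  expect_true(all(al$counts$count_a == 50))

  dir <- withr::local_tempdir()
  al <- generate_allelic_reads(ratio = 0.661, depth = 80,
                               n_individuals = 2, seed = 4,
                               chrom_len = 50000, sam_dir = dir)
  for (i in 1:2) {
    cc <- count_alleles(al$sam_paths[i], al$snp)
    expect_equal(cc$count_a, al$counts$count_a[i])
    expect_equal(cc$count_b, al$counts$count_b[i])
  }
})

test_that("genotype/expression generator plants HW dosages and mediated trans effects", {
  gx <- generate_genotypes_expression(n = 500, maf = 0.3, beta_cis = 0.5,
                                      noise_sd = 0.01, seed = 6)
  expect_true(all(gx$dosage %in% 0:2))
  expect_lt(abs(mean(gx$dosage) / 2 - 0.3), 0.05)
  fit <- eqtl_association(gx$dosage, gx$expression[, "CIITA"])
  expect_equal(fit$beta, 0.5, tolerance = 0.01)
  # mediation: trans gene ~ dosage slope is beta_trans * beta_cis
  fit_t <- eqtl_association(gx$dosage, gx$expression[, "trans_1"])
  expect_equal(fit_t$beta, gx$truth$beta_trans * 0.5, tolerance = 0.05)

  # null cis effect gives uniform p over replicates
  ps <- vapply(1:200, function(i) {
    g0 <- generate_genotypes_expression(n = 60, beta_cis = 0,
                                        trans_genes = character(),
                                        null_genes = "n1", seed = 1000 + i)
    eqtl_association(g0$dosage, g0$expression[, "CIITA"])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
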