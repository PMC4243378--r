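# End-to-end orchestration on synthetic data: simulate a study with
# known truth, run every stage (BI derivation, CE-marks, DCS, gene
# annotation, module scan, eCDF enrichment, ASB, eQTL integration), and
# produce a machine-readable summary.

## independent generator-side arithmetic for truth gene associations
## (plain quadratic loop, no interval machinery)
.truth_associations <- function(bis, genes, max_dist = 10000,
                                proximal_dist = 2000) {
  rows <- list()
  for (i in seq_len(nrow(bis))) {
    for (j in seq_len(nrow(genes))) {
      if (bis$chrom[i] != genes$chrom[j]) next
      t <- genes$tss[j]; s <- bis$start[i]; e <- bis$end[i]
      raw <- if (t >= s && t < e) 0 else if (t < s) s - t else t - (e - 1)
      if (raw >= max_dist) next
      gsign <- if (raw == 0) 0 else if (t < s) 1 else -1
      d <- if (genes$strand[j] == "+") gsign * raw else -gsign * raw
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = genes$gene_id[j], bi = i, distance = d,
        class = if (abs(d) <= proximal_dist) "proximal" else "distal",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), bi = integer(),
                      distance = numeric(), class = character()))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$bi), , drop = FALSE]
}

#' Simulate a complete synthetic study with ground truth
#'
#' Builds a toy genome with genes, plants ordered RFX5-CREB-NF-Y modules
#' into a subset of promoters, lays out true CIITA and RFX5 binding
#' intervals across two conditions (with a shared core and
#' condition-specific additions, and an RFX5-co-incident CE fraction),
#' simulates per-individual peak calls with configurable noise, feature
#' tracks for DCS, a DE p-value table enriched in CE-associated genes,
#' allelic read counts at a heterozygous SNP, and a cis-eSNP with a
#' mediated trans gene set. All ground truth is returned alongside.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param n_contigs,contig_len,n_genes Genome scale (defaults 2 x 500 kb,
#'   200 genes).
#' @param n_bi_genes Genes receiving a condition-2 CIITA BI (default 45).
#' @param n_shared Condition-1 CIITA BIs shared with condition 2
#'   (default 24); plus `n_cond1_own` (default 6) unique to condition 1.
#' @param ce_fraction Fraction of CIITA BIs with an exactly co-incident
#'   RFX5 BI (default 0.6).
#' @param n_module_genes Promoters receiving a planted tri-motif module
#'   (default 25); the first `n_known` (default 10) form the known-target
#'   list.
#' @param jitter_sd,fp_rate,fn_rate Peak noise (defaults 20 bp, 0.5 per
#'   100 kb, 0); set all to 0 for a noiseless round trip.
#' @param de_shape Beta shape for target-gene DE p-values (default 0.2).
#' @param asb_ratio,asb_depth,asb_n Allelic simulation (defaults 0.661,
#'   100, 5).
#' @param eqtl_n,eqtl_maf,beta_cis,beta_trans,eqtl_noise_sd eQTL
#'   simulation (defaults 281, 0.3, 0.5, 0.5, 1).
#' @param n_trans_supported,n_trans_unsupported Trans genes inside /
#'   outside the BI-associated gene set (defaults 8 and 4).
#' @return List of class `enhmap_sim` with elements `genome`, `genes`,
#'   `pwms`, `peaks`, `tracks`, `expression`, `known_targets`, `allelic`,
#'   `eqtl`, and `truth` (BIs, associations, CE genes, module placements,
#'   planted parameters, seeds).
#' @export
simulate_study <- function(seed = 1, n_contigs = 2, contig_len = 500000,
                           n_genes = 180, n_bi_genes = 45, n_shared = 24,
                           n_cond1_own = 6, ce_fraction = 0.6,
                           n_module_genes = 25, n_known = 10,
                           jitter_sd = 20, fp_rate = 0.5, fn_rate = 0,
                           de_shape = 0.2, asb_ratio = 0.661,
                           asb_depth = 100, asb_n = 5, eqtl_n = 281,
                           eqtl_maf = 0.3, beta_cis = 0.5,
                           beta_trans = 2, eqtl_noise_sd = 1,
                           n_trans_supported = 8,
                           n_trans_unsupported = 4) {
  g <- generate_genome(n_contigs, contig_len, n_genes, seed = seed)
  genes <- g$genes
  pwms <- enhmap_pwms()
  consensus <- vapply(pwms, pwm_consensus, character(1))
  mod_total <- sum(nchar(consensus)) + 2 * 10
  set.seed(seed + 11)
  bi_gene_ids <- sample(genes$gene_id, n_bi_genes)
  module_genes <- bi_gene_ids[seq_len(min(n_module_genes, n_bi_genes))]
  known_targets <- module_genes[seq_len(min(n_known, length(module_genes)))]
  planted <- plant_modules(g$genome, genes, module_genes, consensus,
                           spacing = 10, seed = seed + 12,
                           offsets = (300 - mod_total) %/% 2)
  genome <- planted$genome

  # --- truth BIs ------------------------------------------------------
  # rejection placement: distinct BIs of the same (condition, tf) keep a
  # >= 1.2 kb gap so that jittered replicate peaks can never merge
  # neighbouring truth BIs
  set.seed(seed + 13)
  width <- 400
  min_gap <- 1200
  conflicts <- function(chrom, start, placed) {
    any(placed$chrom == chrom &
          placed$start - min_gap < start + width &
          placed$end + min_gap > start)
  }
  place <- function(chrom, propose, placed) {
    for (try in 1:100) {
      s <- propose()
      if (!conflicts(chrom, s, placed)) return(s)
    }
    stop("could not place a truth BI without conflicts")
  }
  sel <- genes[match(bi_gene_ids, genes$gene_id), ]
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  bi_start <- numeric(n_bi_genes)
  for (i in seq_len(n_bi_genes)) {
    tss <- sel$tss[i]
    prop <- if (sel$gene_id[i] %in% module_genes) {
      function() tss - 350                  # covers the promoter window
    } else if (stats::runif(1) < 0.7) {
      function() tss + sample(-1800:1400, 1)             # proximal-ish
    } else {
      function() tss + sample(c(-8000:-3000, 2600:8000), 1)  # distal
    }
    bi_start[i] <- place(sel$chrom[i], prop, placed)
    placed <- rbind(placed, data.frame(chrom = sel$chrom[i],
                                       start = bi_start[i],
                                       end = bi_start[i] + width))
  }
  ciita2 <- data.frame(chrom = sel$chrom, start = bi_start,
                       end = bi_start + width, condition = "ifng",
                       tf = "CIITA", stringsAsFactors = FALSE)
  shared_idx <- seq_len(min(n_shared, n_bi_genes))
  ciita1 <- ciita2[shared_idx, , drop = FALSE]
  ciita1$condition <- "naive"
  # condition-1-only BIs near genes without a condition-2 BI; these may
  # not collide with ANY condition-2 BI either, so that they are truly
  # condition specific
  own_genes <- sample(setdiff(genes$gene_id, bi_gene_ids), n_cond1_own)
  osel <- genes[match(own_genes, genes$gene_id), ]
  own_start <- numeric(n_cond1_own)
  for (i in seq_len(n_cond1_own)) {
    tss <- osel$tss[i]
    own_start[i] <- place(osel$chrom[i],
                          function() tss + sample(-1500:1500, 1), placed)
    placed <- rbind(placed, data.frame(chrom = osel$chrom[i],
                                       start = own_start[i],
                                       end = own_start[i] + width))
  }
  ciita1 <- rbind(ciita1, data.frame(
    chrom = osel$chrom, start = own_start, end = own_start + width,
    condition = "naive", tf = "CIITA", stringsAsFactors = FALSE))
  ciita <- rbind(ciita1, ciita2)
  # RFX5: exactly co-incident with a CE fraction of CIITA BIs, plus a
  # few RFX5-only sites
  rfx5 <- list()
  ce_flag <- logical(nrow(ciita))
  for (cond in c("naive", "ifng")) {
    idx <- which(ciita$condition == cond)
    n_ce <- round(ce_fraction * length(idx))
    ce_idx <- idx[seq_len(n_ce)]
    ce_flag[ce_idx] <- TRUE
    r <- ciita[ce_idx, , drop = FALSE]
    r$tf <- "RFX5"
    ro_genes <- sample(setdiff(genes$gene_id,
                               c(bi_gene_ids, own_genes)), 4)
    rsel <- genes[match(ro_genes, genes$gene_id), ]
    placed_r <- rbind(placed,
                      r[, c("chrom", "start", "end"), drop = FALSE])
    rs <- numeric(4)
    for (i in 1:4) {
      tss <- rsel$tss[i]
      rs[i] <- place(rsel$chrom[i],
                     function() tss + sample(-1500:1500, 1), placed_r)
      placed_r <- rbind(placed_r, data.frame(chrom = rsel$chrom[i],
                                             start = rs[i],
                                             end = rs[i] + width))
    }
    rfx5[[cond]] <- rbind(r, data.frame(
      chrom = rsel$chrom, start = rs, end = rs + width,
      condition = cond, tf = "RFX5", stringsAsFactors = FALSE))
  }
  truth_bis <- rbind(ciita, do.call(rbind, rfx5))
  rownames(truth_bis) <- NULL
  truth_bis$is_ce_mark <- c(ce_flag, rep(NA, nrow(truth_bis) - nrow(ciita)))

  contig_lengths <- stats::setNames(Biostrings::width(genome),
                                    names(genome))
  peaks <- generate_peaks(truth_bis, contig_lengths,
                          jitter_sd = jitter_sd, fp_rate = fp_rate,
                          fn_rate = fn_rate, seed = seed + 14)

  # --- feature tracks for DCS ----------------------------------------
  pad <- function(x, by) {
    x$start <- pmax(0, x$start - by); x$end <- x$end + by
    x[, c("chrom", "start", "end")]
  }
  ce_bis <- ciita[ce_flag, , drop = FALSE]
  tracks <- list(
    DHS = merge_intervals(genomic_intervals(
      truth_bis$chrom, pmax(0, truth_bis$start - 200),
      truth_bis$end + 200)),
    RFX5 = merge_intervals(genomic_intervals(
      ce_bis$chrom, ce_bis$start, ce_bis$end)))
  for (nm in c("CREB1", "ATF1", "NFYA", "NFYB"))
    tracks[[nm]] <- merge_intervals(genomic_intervals(
      ce_bis$chrom, pmax(0, ce_bis$start - 50), ce_bis$end + 50))

  # --- truth associations & DE table ---------------------------------
  truth_assoc <- .truth_associations(ciita, genes)
  ce_genes <- unique(truth_assoc$gene_id[ce_flag[truth_assoc$bi]])
  expression <- generate_expression(genes, ce_genes, shape = de_shape,
                                    seed = seed + 15)

  # --- allelic + eQTL -------------------------------------------------
  allelic <- generate_allelic_reads(ratio = asb_ratio, depth = asb_depth,
                                    n_individuals = asb_n,
                                    seed = seed + 16,
                                    chrom_len = contig_len)
  bi_gene_universe <- unique(truth_assoc$gene_id)
  trans_supported <- sample(bi_gene_universe,
                            min(n_trans_supported,
                                length(bi_gene_universe)))
  trans_unsupported <- paste0("ext_gene_", seq_len(n_trans_unsupported))
  eqtl <- generate_genotypes_expression(
    n = eqtl_n, maf = eqtl_maf, beta_cis = beta_cis,
    trans_genes = c(trans_supported, trans_unsupported),
    beta_trans = beta_trans, noise_sd = eqtl_noise_sd,
    seed = seed + 17)

  structure(list(
    genome = genome, genes = genes, pwms = pwms, peaks = peaks,
    tracks = tracks, expression = expression,
    known_targets = known_targets, allelic = allelic, eqtl = eqtl,
    truth = list(
      bis = truth_bis, ciita_ce_flag = ce_flag,
      associations = truth_assoc, ce_genes = ce_genes,
      module_genes = module_genes, module_placements = planted$truth,
      known_targets = known_targets,
      trans_supported = trans_supported,
      trans_unsupported = trans_unsupported,
      asb_ratio = asb_ratio, beta_cis = beta_cis, seed = seed)),
    class = "enhmap_sim")
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes BI derivation, CE-mark classification, DCS computation,
#' condition-specificity, region-stratified summaries, gene association
#' and pattern classification, the summit-centred tri-motif module scan
#' with a random control set, eCDF enrichment of DE genes in CE-mark
#' genes, the cross-individual ASB test, and the cis/trans eQTL
#' integration. Deterministic given the simulation and `seed`.
#'
#' @param sim An `enhmap_sim` object from [simulate_study()].
#' @param control_n Control segments for the module scan (default 50).
#' @param n_boot Bootstrap replicates for the enrichment band
#'   (default 200).
#' @param n_mc Monte-Carlo replicates for the enrichment p (default
#'   2000).
#' @param trans_p_threshold Trans integration p threshold (default 3e-4).
#' @param seed Integer seed for the stochastic stages.
#' @return List of class `enhmap_run` with per-stage results and a flat
#'   `summary` list suitable for JSON serialisation.
#' @export
run_pipeline <- function(sim, control_n = 50, n_boot = 200, n_mc = 2000,
                         trans_p_threshold = 3e-4, seed = 1) {
  stopifnot(inherits(sim, "enhmap_sim"))
  bis <- derive_binding_intervals(sim$peaks)
  conditions <- unique(bis$condition)
  ce_by_cond <- list()
  for (cond in conditions) {
    ci <- bis[bis$condition == cond & bis$tf == "CIITA", , drop = FALSE]
    rf <- bis[bis$condition == cond & bis$tf == "RFX5", , drop = FALSE]
    ce_by_cond[[cond]] <- classify_ce_marks(ci, rf)
  }
  ciita_bis <- do.call(rbind, lapply(ce_by_cond, `[[`, "bis"))
  rownames(ciita_bis) <- NULL
  ciita_bis <- compute_dcs(ciita_bis, sim$tracks)
  cond_spec <- classify_condition_specific(
    lapply(conditions, function(cond)
      ciita_bis[ciita_bis$condition == cond, , drop = FALSE]) |>
      stats::setNames(conditions))
  bi_summary <- summarize_bis(ciita_bis)

  assoc <- associate_genes(ciita_bis, sim$genes)
  patterns <- classify_gene_pattern(assoc)

  # module scan: known-target BIs vs random control segments
  known_bi <- unique(assoc$bi[assoc$gene_id %in% sim$known_targets])
  segs <- extract_segments(ciita_bis[known_bi, , drop = FALSE],
                           sim$genome)
  segs <- score_segments(segs, sim$pwms)
  ctrl <- control_segments(sim$genes, sim$genome, n_genes = control_n,
                           seed = seed + 101)
  ctrl <- score_segments(ctrl, sim$pwms)
  module_test <- compare_score_groups(segs$avg_score, ctrl$avg_score)

  ranking <- rank_expression(sim$expression)
  sets <- split_target_sets(assoc, ciita_bis$is_ce_mark,
                            sim$known_targets)
  enr <- ecdf_enrichment(ranking, sets$ce_genes, n_boot = n_boot,
                         n_mc = n_mc, seed = seed + 102)

  asb <- asb_test(sim$allelic$counts)

  eq <- sim$eqtl
  cis_fit <- eqtl_association(eq$dosage, eq$expression[, "CIITA"],
                              snp_id = sim$allelic$snp$snp_id,
                              gene_id = "CIITA")
  gene_ids <- setdiff(colnames(eq$expression), "CIITA")
  eqtl_results <- do.call(rbind, lapply(gene_ids, function(g) {
    fit <- eqtl_association(eq$dosage, eq$expression[, g], gene_id = g)
    data.frame(gene_id = g, p_value = fit$p_value, beta = fit$beta,
               cis = FALSE, stringsAsFactors = FALSE)
  }))
  bi_gene_set <- unique(assoc$gene_id)
  trans <- integrate_trans_network(eqtl_results, trans_p_threshold,
                                   bi_gene_set)

  summary <- list(
    n_bis = nrow(bis),
    n_ciita_bis = nrow(ciita_bis),
    n_ce_marks = sum(ciita_bis$is_ce_mark),
    ce_fraction = mean(ciita_bis$is_ce_mark),
    dcs_gt4_fraction = mean(ciita_bis$dcs > 4),
    n_condition_specific = sum(vapply(cond_spec, function(x)
      sum(x$specificity == "condition_specific"), numeric(1))),
    n_associations = nrow(assoc),
    n_genes_associated = length(unique(assoc$gene_id)),
    fraction_bis_with_gene = length(unique(assoc$bi)) / nrow(ciita_bis),
    pattern_counts = as.list(table(patterns$pattern)),
    module_median_target = module_test$median_a,
    module_median_control = module_test$median_b,
    module_p = module_test$p_value,
    enrichment_D = enr$D,
    enrichment_p = enr$p_value,
    asb_mean_pct = asb$mean_pct,
    asb_sd_pct = asb$sd_pct,
    asb_p = asb$p_value,
    eqtl_cis_beta = cis_fit$beta,
    eqtl_cis_p = cis_fit$p_value,
    trans_supported = trans$n_supported,
    trans_unsupported = trans$n_unsupported)

  structure(list(bis = bis, ciita_bis = ciita_bis,
                 ce_counts = lapply(ce_by_cond, `[[`, "counts"),
                 condition_specific = cond_spec,
                 bi_summary = bi_summary, associations = assoc,
                 patterns = patterns, module_segments = segs,
                 control_segments = ctrl, module_test = module_test,
                 enrichment = enr, target_sets = sets, asb = asb,
                 eqtl_cis = cis_fit, eqtl_results = eqtl_results,
                 trans = trans, summary = summary),
            class = "enhmap_run")
}

#' @export
print.enhmap_run <- function(x, ...) {
  s <- x$summary
  cat("enhmap pipeline run\n")
  cat(sprintf("  BIs: %d (%d CIITA, %d CE-marks, CE fraction %.2f)\n",
              s$n_bis, s$n_ciita_bis, s$n_ce_marks, s$ce_fraction))
  cat(sprintf("  gene associations: %d (%d genes, %.0f%% of CIITA BIs)\n",
              s$n_associations, s$n_genes_associated,
              100 * s$fraction_bis_with_gene))
  cat(sprintf("  module scan: target median %.3f vs control %.3f (p = %.3g)\n",
              s$module_median_target, s$module_median_control, s$module_p))
  cat(sprintf("  DE enrichment: D = %.3f (p = %.3g)\n",
              s$enrichment_D, s$enrichment_p))
  cat(sprintf("  ASB: %.1f%% (SD %.1f), p = %.3g\n",
              s$asb_mean_pct, s$asb_sd_pct, s$asb_p))
  cat(sprintf("  cis-eQTL: beta = %.3f (p = %.3g); trans supported %d / %d\n",
              s$eqtl_cis_beta, s$eqtl_cis_p, s$trans_supported,
              s$trans_supported + s$trans_unsupported))
  invisible(x)
}

#' Write a pipeline summary as JSON
#'
#' @param run An `enhmap_run` object (or its `summary` list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(run, path) {
  s <- if (inherits(run, "enhmap_run")) run$summary else run
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
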