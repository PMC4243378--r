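# Rank-based (eCDF) enrichment of differentially expressed genes within
# binding-interval-associated gene sets.
#
# All genes are ranked by DE p-value (smallest p = rank 1, average ranks
# on ties); each gene's rank-quantile is u = rank / N. A target set drawn
# at random has rank-quantiles uniform on (0, 1], so its eCDF tracks the
# diagonal; enrichment for small p-values lifts the eCDF above it. The
# deviation statistic D = sup_u (F(u) - u) is calibrated by Monte-Carlo
# draws of equally sized uniform samples.

#' Rank genes by differential-expression p-value
#'
#' @param pvalues data.frame with columns `gene_id` and `p_value`
#'   (p in \[0, 1\]), or a named numeric vector.
#' @return data.frame `gene_id`, `p_value`, `rank` (average-rank ties),
#'   `u` (rank / N).
#' @export
rank_expression <- function(pvalues) {
  if (is.numeric(pvalues) && !is.null(names(pvalues)))
    pvalues <- data.frame(gene_id = names(pvalues), p_value = unname(pvalues))
  stopifnot(all(c("gene_id", "p_value") %in% names(pvalues)))
  p <- pvalues$p_value
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]")
  r <- rank(p, ties.method = "average")
  data.frame(gene_id = as.character(pvalues$gene_id), p_value = p,
             rank = r, u = r / length(r), stringsAsFactors = FALSE)
}

#' Read a tab-delimited gene / p-value table
#'
#' @param path Two-column file (`gene_id`, `p_value`), no header.
#' @return data.frame ready for [rank_expression()].
#' @export
read_pvalue_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"))
  data.frame(gene_id = tab[[1]], p_value = tab[[2]],
             stringsAsFactors = FALSE)
}

## eCDF of x evaluated at grid points (proportion of x <= grid)
.ecdf_at <- function(x, grid) {
  findInterval(grid, sort(x)) / length(x)
}

#' eCDF enrichment of a gene set in a DE ranking
#'
#' Computes the empirical CDF of the target genes' rank-quantiles on a
#' fixed grid, a pointwise bootstrap percentile confidence band
#' (resampling the target set with replacement), and the one-sided
#' deviation statistic `D = sup_u (F(u) - u)` with a Monte-Carlo p-value
#' from uniform samples of the same size.
#'
#' @param ranking Output of [rank_expression()].
#' @param target_set Character vector of gene ids (>= 5, all present in
#'   the ranking).
#' @param n_boot Bootstrap replicates for the band (default 1000).
#' @param alpha Band level is `1 - alpha` (default 0.05).
#' @param n_mc Monte-Carlo replicates for D's null (default 10000; 0
#'   skips the p-value).
#' @param grid Evaluation grid on (0, 1] (default 101 equispaced points).
#' @param seed Optional integer seed.
#' @return Object of class `ecdf_enrichment`: list with `grid`, `ecdf`,
#'   `lower`, `upper`, `D`, `p_value`, `n_target`, `n_genes`, `n_boot`,
#'   `alpha`.
#' @export
ecdf_enrichment <- function(ranking, target_set, n_boot = 1000,
                            alpha = 0.05, n_mc = 10000,
                            grid = seq(0, 1, length.out = 101),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("gene_id", "u") %in% names(ranking)))
  target_set <- unique(as.character(target_set))
  missing <- setdiff(target_set, ranking$gene_id)
  if (length(missing))
    stop("target genes absent from ranking: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  if (length(target_set) < 5) stop("target set must contain >= 5 genes")
  u <- ranking$u[match(target_set, ranking$gene_id)]
  m <- length(u)
  Fhat <- .ecdf_at(u, grid)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot))
    boot[b, ] <- .ecdf_at(u[sample.int(m, m, replace = TRUE)], grid)
  lower <- apply(boot, 2, stats::quantile, probs = alpha / 2, names = FALSE)
  upper <- apply(boot, 2, stats::quantile, probs = 1 - alpha / 2,
                 names = FALSE)
  D <- .sup_deviation(u)
  p <- NA_real_
  if (n_mc > 0) {
    d0 <- vapply(seq_len(n_mc), function(i)
      .sup_deviation(stats::runif(m)), numeric(1))
    p <- (sum(d0 >= D) + 1) / (n_mc + 1)
  }
  structure(list(grid = grid, ecdf = Fhat, lower = lower, upper = upper,
                 D = D, p_value = p, n_target = m,
                 n_genes = nrow(ranking), n_boot = n_boot, alpha = alpha),
            class = "ecdf_enrichment")
}

## one-sided sup of F(u) - u; attained just after a jump, so evaluated at
## the sorted sample points as i/m - u_(i)
.sup_deviation <- function(u) {
  u <- sort(u)
  m <- length(u)
  max(seq_len(m) / m - u)
}

#' @export
print.ecdf_enrichment <- function(x, ...) {
  cat("eCDF enrichment:", x$n_target, "target genes of", x$n_genes, "\n")
  cat("  D =", signif(x$D, 4),
      if (!is.na(x$p_value)) paste(" Monte-Carlo p =", signif(x$p_value, 3))
      else "", "\n")
  invisible(x)
}

#' Plot an eCDF enrichment result
#'
#' Draws the target-set eCDF with its confidence band against the
#' no-enrichment diagonal.
#'
#' @param x An `ecdf_enrichment` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ecdf_enrichment <- function(x, ...) {
  graphics::plot(x$grid, x$ecdf, type = "s", xlab = "rank quantile u",
                 ylab = "eCDF of target-set ranks", ylim = c(0, 1), ...)
  graphics::lines(x$grid, x$lower, lty = 3)
  graphics::lines(x$grid, x$upper, lty = 3)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Null coverage of the eCDF confidence band
#'
#' Simulation check of the pointwise bootstrap percentile band: under a
#' uniform null (all DE p-values Uniform(0,1), a random target set), the
#' no-enrichment diagonal should fall inside the nominal `1 - alpha` band
#' at any fixed evaluation point in about `1 - alpha` of replicates.
#'
#' @param n_rep Null replicates (default 1000).
#' @param n_genes Genes per replicate (default 10000).
#' @param n_target Target-set size (default 200).
#' @param n_boot Bootstrap resamples per band (default 1000).
#' @param alpha Band level is `1 - alpha` (default 0.05).
#' @param grid_point Evaluation point in (0, 1) (default 0.5, the median
#'   grid point).
#' @param seed Integer seed.
#' @return Fraction of replicates with `grid_point` inside
#'   `[lower, upper]` at `grid_point`.
#' @export
band_null_coverage <- function(n_rep = 1000, n_genes = 10000,
                               n_target = 200, n_boot = 1000,
                               alpha = 0.05, grid_point = 0.5,
                               seed = 1) {
  set.seed(seed)
  ids <- paste0("g", seq_len(n_genes))
  hits <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ranking <- rank_expression(
      data.frame(gene_id = ids, p_value = stats::runif(n_genes)))
    e <- ecdf_enrichment(ranking, sample(ids, n_target),
                         n_boot = n_boot, alpha = alpha, n_mc = 0,
                         grid = grid_point)
    hits[i] <- e$lower[1] <= grid_point && grid_point <= e$upper[1]
  }
  mean(hits)
}

#' Split BI-associated genes into enrichment target sets
#'
#' Builds the four gene sets compared in the enrichment analysis: genes
#' associated with a CE-mark BI, genes associated only with CIITA BIs
#' lacking RFX5 support (disjoint from the first), and the known / novel
#' partition of all BI-associated genes given a known-target list.
#'
#' @param associations Output of [associate_genes()].
#' @param ce_flags Logical vector, `is_ce_mark` per BI (indexed by the
#'   `bi` column of `associations`).
#' @param known_targets Character vector of known target gene ids (may be
#'   empty).
#' @return Named list of character vectors: `ce_genes`,
#'   `ciita_only_genes`, `known_targets`, `novel_targets`.
#' @export
split_target_sets <- function(associations, ce_flags,
                              known_targets = character()) {
  if (!nrow(associations)) {
    return(list(ce_genes = character(), ciita_only_genes = character(),
                known_targets = character(), novel_targets = character()))
  }
  ce_genes <- unique(associations$gene_id[ce_flags[associations$bi]])
  all_genes <- unique(associations$gene_id)
  ciita_only <- setdiff(all_genes, ce_genes)
  known <- intersect(all_genes, known_targets)
  novel <- setdiff(all_genes, known)
  list(ce_genes = ce_genes, ciita_only_genes = ciita_only,
       known_targets = known, novel_targets = novel)
}
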