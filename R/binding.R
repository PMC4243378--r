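# Replicate-consensus binding intervals (BIs) and their classification.
#
# A BI is a genomic region supported by enriched ChIP-seq peaks for the
# same factor in BOTH individuals of a cell type/condition. The consensus
# footprint is the base-pair intersection of the two individuals' peak
# sets; contiguous shared regions are then merged. A CIITA BI co-incident
# with RFX5 binding is a CE-mark (CIITA enhanceosome mark).

#' Derive replicate-consensus binding intervals
#'
#' For every (condition, factor) group the two individuals' peak sets are
#' intersected at the base-pair level; contiguous or overlapping shared
#' regions are merged (gap 0) into binding intervals. Each BI records its
#' contributing member peaks and a representative summit: the summit of
#' the member peak with the highest score (ties broken by leftmost
#' summit).
#'
#' @param peaks data.frame of peak calls with columns `chrom`, `start`,
#'   `end`, `summit_offset`, `score`, `individual`, `condition`, `tf`
#'   (factor name, e.g. "CIITA" or "RFX5").
#' @return data.frame of BIs with columns `chrom`, `start`, `end`,
#'   `strand`, `condition`, `tf`, `summit` (absolute coordinate),
#'   `n_member_peaks`, and a list-column `member_peaks` of row indices
#'   into `peaks`. Sorted and non-overlapping within (condition, tf).
#' @export
derive_binding_intervals <- function(peaks) {
  need <- c("chrom", "start", "end", "summit_offset", "score",
            "individual", "condition", "tf")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  validate_intervals(peaks)
  groups <- unique(peaks[, c("condition", "tf")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    cond <- groups$condition[g]; fac <- groups$tf[g]
    sel <- which(peaks$condition == cond & peaks$tf == fac)
    grp <- peaks[sel, , drop = FALSE]
    inds <- sort(unique(grp$individual))
    if (length(inds) != 2)
      stop("group (", cond, ", ", fac, ") has ", length(inds),
           " individuals; exactly 2 required")
    p1 <- grp[grp$individual == inds[1], , drop = FALSE]
    p2 <- grp[grp$individual == inds[2], , drop = FALSE]
    shared <- intersect_regions(p1, p2)
    if (!nrow(shared)) next
    bis <- merge_intervals(shared, gap = 0)
    hits <- intersect_intervals(bis, grp, min_overlap = 1)
    members <- split(sel[hits$subject], hits$query)
    summit <- numeric(nrow(bis))
    for (i in seq_len(nrow(bis))) {
      mi <- members[[as.character(i)]]
      mp <- peaks[mi, , drop = FALSE]
      abs_summit <- mp$start + mp$summit_offset
      best <- order(-mp$score, abs_summit)[1]
      summit[i] <- abs_summit[best]
    }
    bis$condition <- cond
    bis$tf <- fac
    bis$summit <- summit
    bis$n_member_peaks <- vapply(seq_len(nrow(bis)), function(i)
      length(members[[as.character(i)]]), integer(1))
    bis$member_peaks <- I(lapply(seq_len(nrow(bis)), function(i)
      members[[as.character(i)]]))
    # consensus invariant: both individuals contribute to every BI
    ok <- vapply(bis$member_peaks, function(mi)
      length(unique(peaks$individual[mi])) == 2, logical(1))
    stopifnot(all(ok))
    out[[length(out) + 1]] <- bis
  }
  if (!length(out)) {
    return(genomic_intervals(character(), integer(), integer(),
                             condition = character(), tf = character(),
                             summit = numeric(),
                             n_member_peaks = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify CE-marks among CIITA binding intervals
#'
#' A CIITA BI is a CE-mark iff it shares at least `min_overlap` bp with
#' any RFX5 BI of the same condition.
#'
#' @param ciita_bis,rfx5_bis BI data.frames from
#'   [derive_binding_intervals()] for the two factors in one condition.
#' @param min_overlap Minimum co-incidence overlap in bp (default 1).
#' @return List with `bis` (the CIITA BIs plus logical column
#'   `is_ce_mark`) and `counts`, a named integer vector with elements
#'   `ciita_only`, `rfx5_only` and `ce`.
#' @export
classify_ce_marks <- function(ciita_bis, rfx5_bis, min_overlap = 1) {
  validate_intervals(ciita_bis)
  validate_intervals(rfx5_bis)
  hits <- intersect_intervals(ciita_bis, rfx5_bis, min_overlap = min_overlap)
  flag <- rep(FALSE, nrow(ciita_bis))
  flag[unique(hits$query)] <- TRUE
  rfx5_hit <- rep(FALSE, nrow(rfx5_bis))
  rfx5_hit[unique(hits$subject)] <- TRUE
  ciita_bis$is_ce_mark <- flag
  counts <- c(ciita_only = sum(!flag),
              rfx5_only = sum(!rfx5_hit),
              ce = sum(flag))
  list(bis = ciita_bis, counts = counts)
}

#' Data coincidence scores
#'
#' The DCS of a BI is the number of distinct feature tracks (typically
#' DHS, RFX5, CREB1, ATF1, NFYA, NFYB) with at least 1 bp overlap.
#'
#' @param bis BI data.frame.
#' @param tracks Named list of interval data.frames, one per track.
#' @return `bis` with an integer column `dcs` added
#'   (`0 <= dcs <= length(tracks)`).
#' @export
compute_dcs <- function(bis, tracks) {
  if (!length(tracks)) stop("compute_dcs requires at least one track")
  validate_intervals(bis)
  dcs <- rep(0L, nrow(bis))
  for (tr in tracks) {
    hits <- intersect_intervals(bis, tr, min_overlap = 1)
    got <- rep(0L, nrow(bis))
    got[unique(hits$query)] <- 1L
    dcs <- dcs + got
  }
  bis$dcs <- dcs
  bis
}

#' Classify condition-shared vs condition-specific BIs
#'
#' A BI is condition-specific iff no BI from any other condition in the
#' supplied set overlaps it by at least 1 bp.
#'
#' @param bis_by_condition Named list (>= 2 conditions) of BI data.frames
#'   for the same cell type.
#' @return The same list with a `specificity` column added to each
#'   element, values `"shared"` or `"condition_specific"`.
#' @export
classify_condition_specific <- function(bis_by_condition) {
  if (length(bis_by_condition) < 2)
    stop("need >= 2 conditions to classify condition specificity")
  out <- bis_by_condition
  for (k in seq_along(bis_by_condition)) {
    others <- do.call(rbind, lapply(bis_by_condition[-k], function(x)
      x[, c("chrom", "start", "end"), drop = FALSE]))
    this <- bis_by_condition[[k]]
    spec <- rep("condition_specific", nrow(this))
    if (nrow(others)) {
      others$strand <- "*"
      hits <- intersect_intervals(this, others, min_overlap = 1)
      spec[unique(hits$query)] <- "shared"
    }
    out[[k]]$specificity <- spec
  }
  out
}

#' Stratified binding-interval summary
#'
#' Counts BIs per condition and factor genome-wide, within each region
#' mask (>= 1 bp overlap), and outside the extended MHC; reports CE-mark
#' fractions per stratum when `is_ce_mark` is present.
#'
#' @param bis BI data.frame, optionally with `is_ce_mark`.
#' @param masks Region masks as from [region_masks()] (a `name` column is
#'   required; a mask named `MHC` defines the "outside MHC" stratum).
#' @return List with `counts` — a long data.frame (condition, tf,
#'   stratum, n, n_ce, ce_fraction) — and `strata`, the stratum names.
#' @export
summarize_bis <- function(bis, masks = region_masks()) {
  validate_intervals(masks)
  if (!"name" %in% names(masks)) stop("masks require a 'name' column")
  has_ce <- "is_ce_mark" %in% names(bis)
  in_mask <- function(mask_rows) {
    if (!nrow(bis)) return(logical(0))
    hits <- intersect_intervals(bis, mask_rows, min_overlap = 1)
    flag <- rep(FALSE, nrow(bis))
    flag[unique(hits$query)] <- TRUE
    flag
  }
  strata <- list(genome_wide = rep(TRUE, nrow(bis)))
  for (i in seq_len(nrow(masks)))
    strata[[masks$name[i]]] <- in_mask(masks[i, , drop = FALSE])
  if ("MHC" %in% masks$name)
    strata$outside_MHC <- !strata$MHC
  combos <- if (nrow(bis)) unique(bis[, c("condition", "tf")]) else
    data.frame(condition = character(), tf = character())
  rows <- list()
  for (s in names(strata)) {
    for (g in seq_len(nrow(combos))) {
      sel <- strata[[s]] & bis$condition == combos$condition[g] &
        bis$tf == combos$tf[g]
      n_ce <- if (has_ce) sum(bis$is_ce_mark[sel]) else NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        condition = combos$condition[g], tf = combos$tf[g], stratum = s,
        n = sum(sel), n_ce = n_ce,
        ce_fraction = if (has_ce && sum(sel)) n_ce / sum(sel) else NA_real_)
    }
    if (!nrow(combos))
      rows[[length(rows) + 1]] <- data.frame(
        condition = NA_character_, tf = NA_character_, stratum = s,
        n = 0L, n_ce = NA_integer_, ce_fraction = NA_real_)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, strata = names(strata))
}
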