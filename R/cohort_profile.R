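#' Sample-level coverage QC
#'
#' A sample passes coverage QC when at least `min_exon_fraction` of the
#' panel's non-excluded exons have mean coverage of at least
#' `min_exon_depth` reads (defaults 0.85 and 50; both thresholds are
#' inclusive). Exons absent from the coverage table count as depth 0.
#'
#' @param coverage Data frame from [read_exon_coverage()].
#' @param models Named list of [gene_model()] objects (defines the panel
#'   exon set and exclusions).
#' @param panel A [panel_config()] carrying the thresholds.
#' @param sample_id Optional sample label.
#' @return List of class `sample_qc`: `sample_id`, `n_exons`,
#'   `n_at_depth`, `fraction_exons_at_depth`, `pass`.
#' @export
coverage_qc <- function(coverage, models, panel, sample_id = NA_character_) {
  stopifnot(inherits(panel, "panel_config"))
  want <- do.call(rbind, lapply(models, function(m) {
    ex <- setdiff(m$exons$exon, m$excluded_exons)
    data.frame(gene = m$gene, exon_index = ex)
  }))
  depth <- rep(0, nrow(want))
  if (nrow(coverage)) {
    idx <- match(paste(want$gene, want$exon_index),
                 paste(coverage$gene, coverage$exon_index))
    hit <- !is.na(idx)
    depth[hit] <- coverage$mean_depth[idx[hit]]
  }
  n_ok <- sum(depth >= panel$min_exon_depth)
  frac <- n_ok / nrow(want)
  structure(list(sample_id = sample_id, n_exons = nrow(want),
                 n_at_depth = n_ok, fraction_exons_at_depth = frac,
                 pass = frac >= panel$min_exon_fraction),
            class = "sample_qc")
}

#' Sequencing-metric QC
#'
#' Gates precomputed run metrics with the standard thresholds for this
#' assay: fraction of Q30 bases > 0.75, mean base quality > 30, fraction
#' of perfect index reads > 0.85.
#'
#' @param q30_fraction,mean_base_quality,perfect_index_fraction Scalars.
#' @return List with per-metric pass flags and overall `pass`.
#' @export
seq_metrics_qc <- function(q30_fraction, mean_base_quality,
                           perfect_index_fraction) {
  flags <- c(q30 = q30_fraction > 0.75,
             base_quality = mean_base_quality > 30,
             perfect_index = perfect_index_fraction > 0.85)
  list(flags = flags, pass = all(flags))
}

#' Build the healthy-control reference splicing profile
#'
#' Aggregates control quantifications per event. Two summaries are kept,
#' matching how controls are reported versus tested: median and
#' interquartile range over the controls in which the event was detected
#' (PSI > 0), and mean/SD over all controls with PSI 0 assigned where the
#' event was not detected. The full zero-assigned PSI vector per event is
#' retained for the one-sample t test. Events detected in no control are
#' absent from the profile (a patient may still present them as novel).
#'
#' @param quants Long quantification data frame over the QC-passing
#'   control samples ([quantify_cohort()]).
#' @return Object of class `control_profile`: list with `stats` (one row
#'   per event), `psi` (events x controls matrix, zero-assigned) and
#'   `n_controls`.
#' @export
build_profile <- function(quants) {
  samples <- unique(quants$sample_id)
  n <- length(samples)
  if (n < 2L) stop("at least 2 QC-passing controls are required")
  m <- psi_matrix(quants, zero_missing = TRUE)
  detected <- rowSums(m > 0) > 0
  m <- m[detected, , drop = FALSE]
  if (!nrow(m)) stop("no events detected in any control")
  stats <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    d <- v[v > 0]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(
      key = rownames(m)[i],
      n_controls = n, n_detected = length(d),
      detection_frequency = length(d) / n,
      median_psi = q[2], iqr_lo = q[1], iqr_hi = q[3],
      mean_psi = mean(v), sd_psi = stats::sd(v)
    )
  }))
  stats$gene <- sub(":.*$", "", stats$key)
  stats$event <- sub("^[^:]*:", "", stats$key)
  stats <- stats[, c("key", "gene", "event", "n_controls", "n_detected",
                     "detection_frequency", "median_psi", "iqr_lo", "iqr_hi",
                     "mean_psi", "sd_psi")]
  rownames(stats) <- NULL
  structure(list(stats = stats, psi = m, n_controls = n),
            class = "control_profile")
}

#' @export
print.control_profile <- function(x, ...) {
  cat(sprintf("control_profile: %d events over %d controls\n",
              nrow(x$stats), x$n_controls))
  invisible(x)
}

#' Control count threshold for a common event
#'
#' The number of controls that must show PSI at or above the PSI cutoff
#' for an event to count as common: `floor(freq_min * n_controls)` under
#' the default rule (so 5% of 345 controls is a threshold of 17), or
#' `ceiling` under the strict rule.
#'
#' @param n_controls Number of controls in the profile.
#' @param freq_min Minimum control frequency (default 0.05).
#' @param rule `"floor"` (default) or `"ceiling"`.
#' @return Integer threshold.
#' @export
common_event_threshold <- function(n_controls, freq_min = 0.05,
                                   rule = c("floor", "ceiling")) {
  rule <- match.arg(rule)
  thr <- freq_min * n_controls
  as.integer(if (rule == "floor") floor(thr) else ceiling(thr))
}

#' Common alternative-splicing events of the control population
#'
#' Events with PSI at or above `psi_min` in at least
#' [common_event_threshold()] controls.
#'
#' @param profile A [build_profile()] result.
#' @param psi_min PSI cutoff (percent, default 5).
#' @param freq_min Minimum control frequency (default 0.05).
#' @param rule Threshold rounding rule, see [common_event_threshold()].
#' @return Subset of `profile$stats` with an extra column
#'   `n_at_psi_min`.
#' @export
common_events <- function(profile, psi_min = 5, freq_min = 0.05,
                          rule = c("floor", "ceiling")) {
  stopifnot(inherits(profile, "control_profile"))
  thr <- common_event_threshold(profile$n_controls, freq_min, match.arg(rule))
  n_at <- rowSums(profile$psi >= psi_min)
  out <- profile$stats
  out$n_at_psi_min <- as.integer(n_at[match(out$key, rownames(profile$psi))])
  out[out$n_at_psi_min >= thr, , drop = FALSE]
}

#' Number of splicing events detected in one sample
#'
#' Events with PSI at or above `psi_min` and region coverage of at least
#' `min_region_reads` reads (defaults 5% and 50x).
#'
#' @param sample_quants Quantification rows of one sample.
#' @param psi_min PSI cutoff (percent).
#' @param min_region_reads Region coverage cutoff (reads).
#' @return Integer count.
#' @export
per_sample_event_count <- function(sample_quants, psi_min = 5,
                                   min_region_reads = 50) {
  psi <- sample_quants$psi
  sum(!is.na(psi) & psi >= psi_min &
        sample_quants$region_reads >= min_region_reads)
}

#' Per-sample event counts by gene
#'
#' @param quants Long quantification data frame.
#' @param genes Character vector of panel genes (zero-filled for genes
#'   without events).
#' @param psi_min,min_region_reads Gates as in [per_sample_event_count()].
#' @return Data frame `sample_id`, `gene`, `n_events`.
#' @export
count_events_by_gene <- function(quants, genes, psi_min = 5,
                                 min_region_reads = 50) {
  samples <- unique(quants$sample_id)
  grid <- expand.grid(sample_id = samples, gene = genes,
                      stringsAsFactors = FALSE)
  ok <- !is.na(quants$psi) & quants$psi >= psi_min &
    quants$region_reads >= min_region_reads
  tab <- table(factor(quants$sample_id[ok], levels = samples),
               factor(quants$gene[ok], levels = genes))
  grid$n_events <- as.integer(tab[cbind(match(grid$sample_id, samples),
                                        match(grid$gene, genes))])
  grid
}

#' Correlation between per-gene event count and exon number
#'
#' Pearson correlation between each gene's median per-sample event count
#' and its exon count, with a two-sided p value from the t transform.
#'
#' @param gene_counts Data frame `sample_id`, `gene`, `n_events`
#'   ([count_events_by_gene()]).
#' @param models Named list of [gene_model()] objects.
#' @return List `r`, `p`, `n_genes`, `medians` (per-gene median counts),
#'   `exon_counts`; `r` and `p` are `NA` with a `reason` when either
#'   vector has zero variance.
#' @export
exon_count_correlation <- function(gene_counts, models) {
  genes <- names(models)
  if (length(genes) < 3L) stop("need at least 3 genes")
  med <- vapply(genes, function(g) {
    stats::median(gene_counts$n_events[gene_counts$gene == g])
  }, numeric(1))
  nex <- vapply(models, function(m) nrow(m$exons), numeric(1))
  if (stats::sd(med) == 0 || stats::sd(nex) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_genes = length(genes),
                medians = med, exon_counts = nex,
                reason = "zero variance in counts or exon numbers"))
  }
  ct <- stats::cor.test(med, nex, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_genes = length(genes),
       medians = med, exon_counts = nex, reason = NA_character_)
}

#' Pairwise t tests of event counts between metadata groups
#'
#' Two-sample two-sided Welch t tests of per-sample event counts between
#' every pair of groups (e.g. ethnicity or batch). Groups with fewer than
#' two samples are skipped with a warning.
#'
#' @param counts Numeric vector of per-sample event counts.
#' @param groups Factor or character vector (same length) of group labels.
#' @return Data frame `group1`, `group2`, `t`, `p`.
#' @export
group_event_count_tests <- function(counts, groups) {
  stopifnot(length(counts) == length(groups))
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping groups with fewer than 2 samples: ",
            paste(small, collapse = ", "))
  }
  keep <- sort(names(sizes)[sizes >= 2])
  if (length(keep) < 2L) stop("need at least 2 groups with >= 2 samples")
  pairs <- utils::combn(keep, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    tt <- stats::t.test(counts[groups == g1], counts[groups == g2])
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), p = tt$p.value)
  }))
}
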