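# helper: fabricate a long quantification table from a PSI matrix
quants_from_matrix <- function(mat, region = 100L) {
  do.call(rbind, lapply(colnames(mat), function(s) {
    data.frame(sample_id = s, gene = sub(":.*", "", rownames(mat)),
               event = sub("^[^:]*:", "", rownames(mat)),
               alt_reads = 0L, region_reads = region, psi = mat[, s])
  }))
}

test_that("coverage QC applies the inclusive 85%-of-exons-at-50x rule", {
  # 20-exon panel gene
  starts <- seq(1, by = 1000, length.out = 20)
  m <- gene_model("G", "chr1", "+", starts, starts + 99, "T")
  panel <- panel_config("G", "T")
  cov <- data.frame(gene = "G", exon_index = 1:20, mean_depth = 200)
  cov$mean_depth[1:3] <- 10
  r <- coverage_qc(cov, list(G = m), panel, "S")   # 17/20 = 0.85 exactly
  expect_true(r$pass)
  expect_equal(r$fraction_exons_at_depth, 0.85)
  cov$mean_depth[4] <- 49.9                         # 16/20 = 0.80
  expect_false(coverage_qc(cov, list(G = m), panel)$pass)
  cov$mean_depth <- 0
  r0 <- coverage_qc(cov, list(G = m), panel)
  expect_false(r0$pass)
  expect_equal(r0$fraction_exons_at_depth, 0)
  # missing rows count as depth 0; excluded exons leave the denominator
  mx <- gene_model("G", "chr1", "+", starts, starts + 99, "T",
                   excluded_exons = 18:20)
  r2 <- coverage_qc(data.frame(gene = "G", exon_index = 1:15,
                               mean_depth = 60), list(G = mx), panel)
  expect_equal(r2$n_exons, 17L)
  expect_equal(r2$n_at_depth, 15L)
})

test_that("sequencing-metric QC gates on the assay thresholds", {
  expect_true(seq_metrics_qc(0.80, 34, 0.9)$pass)
  expect_false(seq_metrics_qc(0.75, 34, 0.9)$pass)  # strict >
  expect_false(seq_metrics_qc(0.80, 30, 0.9)$pass)
})

test_that("the control profile separates detected-only and zero-assigned stats", {
  mat <- matrix(c(10, 20, 30, 0), 1, 4,
                dimnames = list("G:e1", paste0("C", 1:4)))
  p <- build_profile(quants_from_matrix(mat))
  s <- p$stats
  expect_equal(s$n_detected, 3L)
  expect_equal(s$detection_frequency, 0.75)
  expect_equal(s$median_psi, 20)        # detected controls only
  expect_equal(s$mean_psi, 15)          # zero-assigned over all 4
  expect_equal(s$sd_psi, sd(c(10, 20, 30, 0)))
  # constant detected PSI: IQR width zero
  mat2 <- matrix(38.69, 1, 3, dimnames = list("G:e1", paste0("C", 1:3)))
  s2 <- build_profile(quants_from_matrix(mat2))$stats
  expect_equal(s2$median_psi, 38.69)
  expect_equal(s2$iqr_hi - s2$iqr_lo, 0)
  # fewer than two controls is an error
  expect_error(build_profile(quants_from_matrix(mat[, 1, drop = FALSE])),
               "at least 2")
})

test_that("profile statistics match an independent brute-force pass", {
  set.seed(91)
  mat <- matrix(round(pmax(0, rnorm(8 * 30, 8, 10)), 2), 8, 30,
                dimnames = list(paste0("G:", letters[1:8]), paste0("C", 1:30)))
  p <- build_profile(quants_from_matrix(mat))
  for (i in seq_len(nrow(p$stats))) {
    v <- mat[p$stats$key[i], ]
    d <- v[v > 0]
    expect_equal(p$stats$n_detected[i], length(d))
    expect_equal(p$stats$median_psi[i], median(d))
    expect_equal(p$stats$iqr_lo[i], unname(quantile(d, 0.25)))
    expect_equal(p$stats$mean_psi[i], mean(v))
    expect_equal(p$stats$sd_psi[i], sd(v))
  }
  # mean over all controls never exceeds mean over detected
  expect_true(all(p$stats$mean_psi <=
                    vapply(p$stats$key, function(k) {
                      v <- mat[k, ]; mean(v[v > 0])
                    }, numeric(1)) + 1e-12))
})

test_that("the common-event filter reproduces the count thresholds", {
  expect_equal(common_event_threshold(345, 0.05), 17L)  # floor(17.25)
  expect_equal(common_event_threshold(100, 0.05), 5L)
  expect_equal(common_event_threshold(345, 0.05, rule = "ceiling"), 18L)
  # event at exactly 17/345 retained, 16/345 excluded
  mat <- rbind(matrix(0, 2, 345))
  rownames(mat) <- c("G:at17", "G:at16")
  colnames(mat) <- paste0("C", 1:345)
  mat["G:at17", 1:17] <- 6
  mat["G:at16", 1:16] <- 6
  mat[, 345] <- pmax(mat[, 345], 1e-9)  # keep both events in the profile
  ce <- common_events(build_profile(quants_from_matrix(mat)))
  expect_equal(ce$event, "at17")
  expect_equal(ce$n_at_psi_min, 17L)
})

test_that("common_events is monotone in both thresholds", {
  set.seed(7)
  mat <- matrix(rbinom(5 * 40, 20, 0.3) * rbinom(5 * 40, 1, 0.6), 5, 40,
                dimnames = list(paste0("G:", letters[1:5]), paste0("C", 1:40)))
  mat[1, ] <- pmax(mat[1, ], 1)
  p <- build_profile(quants_from_matrix(mat))
  base <- common_events(p, psi_min = 5, freq_min = 0.05)$key
  expect_true(all(common_events(p, psi_min = 8)$key %in% base))
  expect_true(all(common_events(p, freq_min = 0.2)$key %in% base))
})

test_that("per-sample event counts gate on PSI and coverage jointly", {
  q <- data.frame(sample_id = "S", gene = "G", event = c("a", "b", "c"),
                  alt_reads = 0L, region_reads = c(60L, 60L, 40L),
                  psi = c(6, 4, 80))
  expect_equal(per_sample_event_count(q), 1L)  # only 'a' passes both gates
  expect_equal(per_sample_event_count(q[0, ]), 0L)
  expect_equal(per_sample_event_count(q, psi_min = 0, min_region_reads = 0), 3L)
})

test_that("event-count/exon-number correlation matches closed-form Pearson", {
  mk <- function(n) {
    starts <- seq(1, by = 1000, length.out = n)
    gene_model(paste0("G", n), "chr1", "+", starts, starts + 99,
               paste0("T", n))
  }
  models <- list(G2 = mk(2), G1 = suppressWarnings(mk(1)), G3 = mk(3))
  # per-gene medians (1, 2, 3) against exon counts (2, 1, 3): r = 0.5
  counts <- data.frame(sample_id = "S1",
                       gene = c("G2", "G1", "G3"), n_events = c(1L, 2L, 3L))
  r <- exon_count_correlation(counts, models)
  expect_equal(r$r, 0.5)
  expect_equal(r$p, cor.test(c(1, 2, 3), c(2, 1, 3))$p.value)
  # proportional medians: perfect correlation
  counts2 <- transform(counts, n_events = c(4L, 2L, 6L))
  expect_equal(exon_count_correlation(counts2, models)$r, 1)
  # constant medians: undefined, flagged
  counts3 <- transform(counts, n_events = 2L)
  r3 <- exon_count_correlation(counts3, models)
  expect_true(is.na(r3$r))
  expect_match(r3$reason, "variance")
})

test_that("group comparisons run all pairwise t tests", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- c("a", "a", "a", "b", "b", "b")
  out <- group_event_count_tests(x, g)
  expect_equal(nrow(out), 1L)
  expect_equal(out$p, 1)  # identical distributions
  set.seed(5)
  y <- c(rnorm(50, 10), rnorm(50, 20), rnorm(4, 15))
  gy <- rep(c("a", "b", "c"), c(50, 50, 4))
  out2 <- group_event_count_tests(y, gy)
  expect_equal(nrow(out2), 3L)  # three pairwise comparisons
  expect_lt(out2$p[out2$group1 == "a" & out2$group2 == "b"], 1e-6)
  expect_warning(group_event_count_tests(c(y, 30), c(gy, "tiny")), "tiny")
})

test_that("events counted by gene are zero-filled", {
  q <- data.frame(sample_id = c("S1", "S1", "S2"), gene = c("A", "A", "B"),
                  event = c("e1", "e2", "e3"), alt_reads = 0L,
                  region_reads = 100L, psi = c(10, 2, 50))
  cc <- count_events_by_gene(q, genes = c("A", "B", "C"))
  expect_equal(cc$n_events[cc$sample_id == "S1" & cc$gene == "A"], 1L)
  expect_equal(cc$n_events[cc$sample_id == "S2" & cc$gene == "B"], 1L)
  expect_true(all(cc$n_events[cc$gene == "C"] == 0L))
})
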