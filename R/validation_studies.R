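# Seed-reproducible simulation studies validating the statistical behavior
# of the pipeline. These run entirely in memory on synthetic cohorts.

#' PSI parameter-recovery study
#'
#' Simulates a control cohort carrying the default event catalog,
#' quantifies every catalog event in every sample with the package's PSI
#' machinery, and measures how often the estimate falls within two
#' binomial standard errors of the sample's true PSI
#' (`SE = 100 * sqrt(p(1-p)/D)` at the cell's region depth; cells whose
#' event is absent have true PSI 0).
#'
#' @param seed Master seed.
#' @param n_controls Cohort size (default 200).
#' @param n_genes Panel size (default 5; four catalog events per gene).
#' @param coverage_mean,coverage_dispersion Depth model.
#' @return List `fraction_within_2se`, `n_cells`, `n_carrier_cells`,
#'   `carrier_fraction_within_2se`.
#' @export
psi_recovery_study <- function(seed = 1L, n_controls = 200L, n_genes = 5L,
                               coverage_mean = 500, coverage_dispersion = 8) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           n_controls = n_controls, n_patients = 0L,
                           coverage_mean = coverage_mean,
                           coverage_dispersion = coverage_dispersion)
  models <- simulate_models(cfg)
  rcat <- realize_catalog(models, default_event_catalog(models))
  n_within <- 0L; n_cells <- 0L
  c_within <- 0L; c_cells <- 0L
  for (i in seq_len(n_controls)) {
    smp <- simulate_sample(models, rcat, cfg, sprintf("C%03d", i),
                           sample_index = i)
    q <- quantify_sample(rcat, smp$junctions, sprintf("C%03d", i))
    key <- paste(q$gene, q$event)
    tkey <- paste(smp$truth$gene, smp$truth$event)
    true <- smp$truth$true_psi[match(key, tkey)]
    depth <- smp$truth$region_depth[match(key, tkey)]
    true[is.na(true)] <- 0
    depth[is.na(depth)] <- q$region_reads[is.na(depth)]
    ok <- !is.na(q$psi)
    se <- 100 * sqrt(true / 100 * (1 - true / 100) / pmax(depth, 1))
    within <- abs(q$psi - true) <= 2 * se
    n_within <- n_within + sum(within[ok])
    n_cells <- n_cells + sum(ok)
    carrier <- ok & true > 0
    c_within <- c_within + sum(within[carrier])
    c_cells <- c_cells + sum(carrier)
  }
  list(fraction_within_2se = n_within / n_cells, n_cells = n_cells,
       n_carrier_cells = c_cells,
       carrier_fraction_within_2se = c_within / max(c_cells, 1L))
}

#' Null-cohort calibration study
#'
#' Simulates patients from exactly the same generative process as the
#' controls (same event catalog, frequencies, PSI distributions and
#' coverage: no aberrant events) and measures the rate of significant
#' aberrant-splicing calls among patient events passing the PSI and
#' coverage gates. Under a well-calibrated test this rate would not
#' exceed `alpha`.
#'
#' @param seed Master seed.
#' @param n_controls,n_patients Cohort sizes (defaults 100 and 100).
#' @param n_genes Panel size (default 10; four catalog events per gene).
#' @param alpha Significance level (default 0.05).
#' @return List `rate`, `n_gate_passing`, `n_significant`, `alpha`.
#' @export
null_calibration_study <- function(seed = 1L, n_controls = 100L,
                                   n_patients = 100L, n_genes = 10L,
                                   alpha = 0.05) {
  cfg <- simulation_config(seed = seed, n_genes = n_genes,
                           n_controls = n_controls, n_patients = 0L)
  models <- simulate_models(cfg)
  rcat <- realize_catalog(models, default_event_catalog(models))
  ctrl <- do.call(rbind, lapply(seq_len(n_controls), function(i) {
    smp <- simulate_sample(models, rcat, cfg, sprintf("C%03d", i),
                           sample_index = i)
    quantify_sample(rcat, smp$junctions, sprintf("C%03d", i))
  }))
  profile <- build_profile(ctrl)
  n_tests <- 0L; n_sig <- 0L
  for (i in seq_len(n_patients)) {
    idx <- n_controls + i
    smp <- simulate_sample(models, rcat, cfg, sprintf("P%03d", i),
                           sample_index = idx)
    q <- quantify_sample(rcat, smp$junctions, sprintf("P%03d", i))
    calls <- call_aberrant(q, profile, alpha = alpha)
    gate <- calls$patient_psi >= 5 & calls$patient_region_reads >= 50
    n_tests <- n_tests + sum(gate)
    n_sig <- n_sig + sum(calls$significant & gate)
  }
  list(rate = n_sig / n_tests, n_gate_passing = n_tests,
       n_significant = n_sig, alpha = alpha)
}

#' Spike-in power study
#'
#' Builds a control profile from a simulated cohort, then repeatedly
#' presents a patient carrying a heterozygous-variant-like event absent
#' from every control (true PSI 30 by default, measured at fixed
#' coverage), and measures how often the event is called significant.
#'
#' @param seed Master seed.
#' @param n_replicates Number of simulated patients (default 200).
#' @param n_controls Control cohort size (default 100).
#' @param true_psi Spike-in true PSI in percent (default 30).
#' @param depth Region coverage of the spiked event (default 200 reads).
#' @return List `power`, `n_replicates`, `n_called`.
#' @export
spikein_power_study <- function(seed = 1L, n_replicates = 200L,
                                n_controls = 100L, true_psi = 30,
                                depth = 200L) {
  cfg <- simulation_config(seed = seed, n_genes = 1L,
                           n_controls = n_controls, n_patients = 0L)
  models <- simulate_models(cfg)
  rcat <- realize_catalog(models, default_event_catalog(models))
  ctrl <- do.call(rbind, lapply(seq_len(n_controls), function(i) {
    smp <- simulate_sample(models, rcat, cfg, sprintf("C%03d", i),
                           sample_index = i)
    quantify_sample(rcat, smp$junctions, sprintf("C%03d", i))
  }))
  profile <- build_profile(ctrl)
  # variant-driven event: frameshifting 17-nt partial skip, absent from
  # the control catalog
  spike <- realize_catalog(models, data.frame(
    gene = names(models)[1], type = "ESP", target = 4L, del_len = 17L,
    ins_len = 0L, offset = 0L, freq = 0, shape1 = 1, shape2 = 1))
  stopifnot(!spike$name %in% profile$stats$event)
  ubi <- rcat[1, ]  # ubiquitous common event rides along in the family
  set.seed(.sub_seed(seed, 424243L, 0L))
  called <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    alt <- stats::rbinom(1, depth, true_psi / 100)
    ubi_psi <- 100 * stats::rbeta(1, ubi$shape1, ubi$shape2)
    ubi_depth <- stats::rnbinom(1, mu = cfg$coverage_mean,
                                size = cfg$coverage_dispersion)
    q <- data.frame(
      sample_id = "P", gene = spike$gene,
      event = c(spike$name, ubi$name),
      alt_reads = c(alt, round(ubi_depth * ubi_psi / 100)),
      region_reads = c(depth, ubi_depth),
      psi = c(100 * alt / depth, ubi_psi))
    calls <- call_aberrant(q, profile)
    called[r] <- calls$significant[calls$event == spike$name]
  }
  list(power = mean(called), n_replicates = n_replicates,
       n_called = sum(called))
}
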