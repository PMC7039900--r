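#' Diagnostic-yield arithmetic
#'
#' Relative increase in the diagnostic rate when RNA evidence is added to
#' DNA panel testing: `100 * (n_after - n_before) / n_before`, reported to
#' one decimal. `n_before` counts patients positive on DNA alone,
#' `n_after` patients positive after incorporating RNA.
#'
#' @param n_before Positive patients before RNA data (>= 1).
#' @param n_after Positive patients after RNA data (>= `n_before`).
#' @return Object of class `cohort_yield`: `n_positive_before`,
#'   `n_positive_after`, `n_rna_attributable`,
#'   `relative_increase_percent` (one decimal).
#' @export
#' @examples
#' diagnostic_yield(77, 84)$relative_increase_percent  # 9.1
diagnostic_yield <- function(n_before, n_after) {
  n_before <- as.integer(n_before)
  n_after <- as.integer(n_after)
  if (is.na(n_before) || n_before < 1L) {
    stop("n_before must be a positive integer (relative increase undefined)")
  }
  if (is.na(n_after) || n_after < n_before) {
    stop("n_after must be >= n_before")
  }
  structure(list(
    n_positive_before = n_before,
    n_positive_after = n_after,
    n_rna_attributable = n_after - n_before,
    relative_increase_percent = round(100 * (n_after - n_before) / n_before, 1)
  ), class = "cohort_yield")
}

#' @export
print.cohort_yield <- function(x, ...) {
  cat(sprintf(
    "diagnostic yield: %d -> %d positives (+%d attributable to RNA), +%.1f%% relative\n",
    x$n_positive_before, x$n_positive_after, x$n_rna_attributable,
    x$relative_increase_percent))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param gtf Annotation path.
#' @param panel A [panel_config()] object or path to a panel JSON.
#' @param control_junctions,control_coverage Named character vectors of
#'   per-control file paths (names are sample ids).
#' @param patient_junctions,patient_coverage Same for patients (may be
#'   empty).
#' @param out_dir Output directory.
#' @param psi_min,freq_min,min_region_reads,alpha Analysis thresholds
#'   (defaults 5, 0.05, 50, 0.05).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gtf, panel, control_junctions, control_coverage,
                            patient_junctions = character(),
                            patient_coverage = character(),
                            out_dir = "spliceprofiler_out",
                            psi_min = 5, freq_min = 0.05,
                            min_region_reads = 50, alpha = 0.05) {
  if (is.character(panel)) panel <- read_panel_config(panel)
  stopifnot(inherits(panel, "panel_config"))
  cfg <- list(gtf = gtf, panel = panel,
              control_junctions = control_junctions,
              control_coverage = control_coverage,
              patient_junctions = patient_junctions,
              patient_coverage = patient_coverage,
              out_dir = out_dir, psi_min = psi_min, freq_min = freq_min,
              min_region_reads = min_region_reads, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

# config straight from a simulate_cohort() result
#' Pipeline configuration from a simulated cohort
#'
#' @param sim Result of [simulate_cohort()].
#' @param out_dir Output directory (default `<sim dir>/out`).
#' @param ... Threshold overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_simulation <- function(sim, out_dir = file.path(sim$dir, "out"),
                                            ...) {
  ctrl <- sim$metadata$sample_id[sim$metadata$role == "control"]
  pat <- sim$metadata$sample_id[sim$metadata$role == "patient"]
  pipeline_config(
    gtf = sim$paths$gtf, panel = sim$paths$panel,
    control_junctions = sim$paths$junctions[ctrl],
    control_coverage = sim$paths$coverage[ctrl],
    patient_junctions = sim$paths$junctions[pat],
    patient_coverage = sim$paths$coverage[pat],
    out_dir = out_dir, ...)
}

#' Run the whole splicing-profile pipeline
#'
#' Executes QC, event detection, PSI quantification, control-profile
#' construction and per-patient aberrant-splicing calling, writing every
#' result as TSV (plus a JSON summary) under the configured output
#' directory. All inputs are checked before any output is written; reruns
#' on identical inputs reproduce identical outputs.
#'
#' Outputs: `qc_report.tsv`, `event_catalog.tsv`, `quantifications.tsv`,
#' `psi_matrix.tsv`, `region_reads.tsv`, `control_profile.tsv`,
#' `common_events.tsv`, `event_counts.tsv`, `calls_<patient>.tsv`,
#' `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit progress messages with gate counts.
#' @return Invisibly, a list with `qc`, `catalog`, `quants`, `profile`,
#'   `common`, `calls` (named by patient) and `summary`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  inputs <- c(config$gtf, config$control_junctions, config$control_coverage,
              config$patient_junctions, config$patient_coverage)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (length(config$control_junctions) < 2L) {
    stop("need at least 2 control samples")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  models <- load_gene_models(config$gtf, config$panel)
  say("loaded %d gene models from %s", length(models), config$gtf)

  # sample QC on coverage tables
  all_cov <- c(config$control_coverage, config$patient_coverage)
  roles <- c(rep("control", length(config$control_coverage)),
             rep("patient", length(config$patient_coverage)))
  qc <- do.call(rbind, lapply(seq_along(all_cov), function(i) {
    s <- names(all_cov)[i]
    r <- coverage_qc(read_exon_coverage(all_cov[i]), models, config$panel,
                     sample_id = s)
    data.frame(sample_id = s, role = roles[i], n_exons = r$n_exons,
               n_at_depth = r$n_at_depth,
               fraction_exons_at_depth = r$fraction_exons_at_depth,
               pass = r$pass)
  }))
  write_tsv(qc, file.path(config$out_dir, "qc_report.tsv"))
  say("coverage QC: %d/%d controls pass, %d/%d patients pass",
      sum(qc$pass[qc$role == "control"]), sum(qc$role == "control"),
      sum(qc$pass[qc$role == "patient"]), sum(qc$role == "patient"))

  ctrl_pass <- qc$sample_id[qc$role == "control" & qc$pass]
  pat_pass <- qc$sample_id[qc$role == "patient" & qc$pass]
  if (length(ctrl_pass) < 2L) {
    stop("fewer than 2 controls passed coverage QC; cannot build a profile")
  }
  for (s in setdiff(qc$sample_id, c(ctrl_pass, pat_pass))) {
    say("sample %s failed coverage QC and is excluded", s)
  }

  jx_ctrl <- lapply(config$control_junctions[ctrl_pass], read_junctions)
  jx_pat <- lapply(config$patient_junctions[pat_pass], read_junctions)

  catalog <- build_event_catalog(models, c(jx_ctrl, jx_pat))
  say("event catalog: %d events across %d genes",
      nrow(catalog), length(unique(catalog$gene)))
  write_tsv(catalog[, setdiff(names(catalog), "target_exon")],
            file.path(config$out_dir, "event_catalog.tsv"))

  quants <- quantify_cohort(catalog, c(jx_ctrl, jx_pat))
  write_tsv(transform(quants, psi = round(psi, 2)),
            file.path(config$out_dir, "quantifications.tsv"))
  pm <- psi_matrix(quants)
  write_tsv(data.frame(event = rownames(pm), round(pm, 2),
                       check.names = FALSE),
            file.path(config$out_dir, "psi_matrix.tsv"))
  rm_ <- psi_matrix(transform(quants, psi = region_reads))
  write_tsv(data.frame(event = rownames(rm_), rm_, check.names = FALSE),
            file.path(config$out_dir, "region_reads.tsv"))

  ctrl_quants <- quants[quants$sample_id %in% ctrl_pass, , drop = FALSE]
  profile <- build_profile(ctrl_quants)
  write_tsv(transform(profile$stats,
                      median_psi = round(median_psi, 2),
                      iqr_lo = round(iqr_lo, 2), iqr_hi = round(iqr_hi, 2),
                      mean_psi = round(mean_psi, 4),
                      sd_psi = round(sd_psi, 4)),
            file.path(config$out_dir, "control_profile.tsv"))
  common <- common_events(profile, psi_min = config$psi_min,
                          freq_min = config$freq_min)
  write_tsv(transform(common,
                      median_psi = round(median_psi, 2),
                      iqr_lo = round(iqr_lo, 2), iqr_hi = round(iqr_hi, 2),
                      mean_psi = round(mean_psi, 4),
                      sd_psi = round(sd_psi, 4)),
            file.path(config$out_dir, "common_events.tsv"))
  say("control profile: %d events, %d common (PSI>=%g in >=%d controls)",
      nrow(profile$stats), nrow(common), config$psi_min,
      common_event_threshold(profile$n_controls, config$freq_min))

  counts <- vapply(split(quants, quants$sample_id), per_sample_event_count,
                   numeric(1), psi_min = config$psi_min,
                   min_region_reads = config$min_region_reads)
  write_tsv(data.frame(sample_id = names(counts),
                       n_events = as.integer(counts)),
            file.path(config$out_dir, "event_counts.tsv"))

  calls <- list()
  for (s in pat_pass) {
    pc <- call_aberrant(quants[quants$sample_id == s, , drop = FALSE],
                        profile, alpha = config$alpha,
                        psi_min = config$psi_min,
                        min_region_reads = config$min_region_reads)
    say("%s: %d events detected, %d tested, %d significant (%d novel)",
        s, nrow(pc), sum(pc$tested), sum(pc$significant),
        sum(pc$novel_in_patient & pc$significant))
    out <- transform(pc, patient_psi = round(patient_psi, 2),
                     control_mean_psi = round(control_mean_psi, 4),
                     control_sd_psi = round(control_sd_psi, 4),
                     t_statistic = round(t_statistic, 4))
    write_tsv(out, file.path(config$out_dir, paste0("calls_", s, ".tsv")))
    calls[[s]] <- pc
  }

  summary <- list(
    n_controls_input = length(config$control_junctions),
    n_controls_pass = length(ctrl_pass),
    n_patients_input = length(config$patient_junctions),
    n_patients_pass = length(pat_pass),
    n_events_catalog = nrow(catalog),
    n_events_profile = nrow(profile$stats),
    n_events_common = nrow(common),
    per_patient = lapply(calls, function(pc) {
      list(detected = nrow(pc), tested = sum(pc$tested),
           significant = sum(pc$significant),
           novel_significant = sum(pc$novel_in_patient & pc$significant))
    })
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, catalog = catalog, quants = quants,
                 profile = profile, common = common, calls = calls,
                 summary = summary))
}
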