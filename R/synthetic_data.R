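#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' study design this package targets, at desk scale: a targeted capture
#' panel sequenced deep (negative-binomial junction depth around 500x), a
#' healthy-control cohort in which common alternative events recur at low
#' PSI — including one ubiquitous in-frame partial exon skip with mean PSI
#' near 39% — and patient samples carrying heterozygous-variant-driven
#' events at PSI 20-60%. Junction reads supporting an event are binomial
#' in the region depth at the sample's true PSI.
#'
#' @param seed Master seed; every random stream derives from it.
#' @param n_genes Number of panel genes.
#' @param exon_count_range,exon_length_range,intron_length_range Integer
#'   ranges (min, max) drawn uniformly per gene/exon/intron.
#' @param n_controls,n_patients Cohort sizes.
#' @param coverage_mean,coverage_dispersion Negative-binomial depth model
#'   (mean and size) for per-region junction depth.
#' @param spikein_psi_range PSI range (percent) of patient spike-in events.
#' @param qc_fail_fraction Fraction of controls rendered QC-failing by
#'   zeroing 20% of their exon depths.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 6L,
                              exon_count_range = c(8L, 12L),
                              exon_length_range = c(80L, 250L),
                              intron_length_range = c(300L, 3000L),
                              n_controls = 100L, n_patients = 2L,
                              coverage_mean = 500, coverage_dispersion = 8,
                              spikein_psi_range = c(20, 60),
                              qc_fail_fraction = 0) {
  stopifnot(n_genes >= 1, n_controls >= 2, n_patients >= 0,
            coverage_mean > 0, coverage_dispersion > 0,
            qc_fail_fraction >= 0, qc_fail_fraction <= 1)
  rng_ok <- function(r) length(r) == 2 && r[1] >= 1 && r[2] >= r[1]
  if (!rng_ok(exon_count_range) || !rng_ok(exon_length_range) ||
      !rng_ok(intron_length_range)) {
    stop("degenerate range: ranges must be (min, max) with 1 <= min <= max")
  }
  if (exon_count_range[1] < 8) {
    stop("exon_count_range minimum below 8: the default event catalog ",
         "places events on exons 3-5 and introns 6-7")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    spikein_psi_range = as.numeric(spikein_psi_range),
    qc_fail_fraction = qc_fail_fraction
  ), class = "sim_config")
}

# deterministic sub-seed so per-sample / per-event streams are independent:
# adding samples or events never perturbs draws of existing ones
.sub_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed %% 100000L) * 19993 + i * 7919 + j * 101 + 17) %%
               2147483647)
}

#' Simulate panel gene models
#'
#' Draws exon and intron lengths uniformly within the configured ranges.
#' Genes alternate strand and each sits on its own chromosome.
#' Deterministic under the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return Named list of [gene_model()] objects.
#' @export
simulate_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.sub_seed(cfg$seed, 0L, 0L))
  # sample() treats a length-1 vector as 1:n; draw from ranges explicitly
  draw <- function(rng, n) rng[1] + sample.int(rng[2] - rng[1] + 1L, n,
                                               replace = TRUE) - 1L
  models <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    n_ex <- draw(cfg$exon_count_range, 1L)
    ex_w <- draw(cfg$exon_length_range, n_ex)
    in_w <- draw(cfg$intron_length_range, n_ex - 1L)
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- 10001L
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_w[i] - 1L
      if (i < n_ex) pos <- ends[i] + in_w[i] + 1L
    }
    models[[g]] <- gene_model(
      gene = sprintf("TSG%02d", g), chrom = paste0("chr", g),
      strand = if (g %% 2 == 1) "+" else "-",
      exon_starts = starts, exon_ends = ends,
      transcript_id = sprintf("SIMTX%02d.1", g)
    )
  }
  names(models) <- vapply(models, `[[`, character(1), "gene")
  models
}

#' Write gene models as a GTF annotation
#'
#' Emits transcript and exon records via `rtracklayer`; the file loads
#' back into identical models with [load_gene_models()].
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  grl <- lapply(models, function(m) {
    ex <- m$exons[order(m$exons$start), ]
    n <- nrow(ex)
    gr <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(start = c(min(ex$start), ex$start),
                                end = c(max(ex$end), ex$end)),
      strand = m$strand)
    S4Vectors::mcols(gr)$type <- c("transcript", rep("exon", n))
    S4Vectors::mcols(gr)$source <- "spliceprofiler"
    S4Vectors::mcols(gr)$gene_id <- m$gene
    S4Vectors::mcols(gr)$gene_name <- m$gene
    S4Vectors::mcols(gr)$transcript_id <- m$transcript_id
    gr
  })
  gr <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Panel configuration matching simulated models
#'
#' @param models Named list of [gene_model()] objects.
#' @param ... Passed to [panel_config()] (thresholds, exclusions).
#' @return A [panel_config()].
#' @export
panel_from_models <- function(models, ...) {
  panel_config(genes = vapply(models, `[[`, character(1), "gene"),
               transcript_ids = vapply(models, `[[`, character(1),
                                       "transcript_id"),
               ...)
}

#' Default common-event catalog for simulated models
#'
#' Each gene carries four recurring alternative events placed on disjoint
#' exons/introns: a ubiquitous in-frame 42-nt partial skip of exon 3
#' (frequency 1, Beta-distributed PSI with mean ~39%), a full skip of
#' exon 5 (frequency 0.3, low PSI), an 8-nt frameshifting partial
#' retention of intron 6 (frequency 0.15), and a 63-nt in-frame cryptic
#' exon in intron 7 (frequency 0.1).
#'
#' @param models Named list of [gene_model()] objects.
#' @return Data frame of event templates (`gene`, `type`, `target`,
#'   `del_len`, `ins_len`, `offset`, `freq`, `shape1`, `shape2`).
#' @export
default_event_catalog <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(
      gene = m$gene,
      type = c("ESP", "ESF", "IP", "IC"),
      target = c(3L, 5L, 6L, 7L),
      del_len = c(42L, 0L, 0L, 0L),
      ins_len = c(0L, 0L, 8L, 63L),
      offset = c(0L, 0L, 0L, 100L),
      freq = c(1.0, 0.3, 0.15, 0.1),
      shape1 = c(12, 2, 1.5, 2),
      shape2 = c(19, 30, 40, 38)
    )
  }))
}

# genomic junction intervals implementing one event template
.template_junctions <- function(model, type, target, del_len, ins_len, offset) {
  cj <- canonical_junctions(model)
  plus <- model$strand == "+"
  if (type == "ESF") {
    i1 <- cj[cj$intron == target - 1L, ]
    i2 <- cj[cj$intron == target, ]
    data.frame(start = min(i1$start, i2$start), end = max(i1$end, i2$end))
  } else if (type == "ESP") {
    # delete the first del_len transcript bases of exon `target`
    i1 <- cj[cj$intron == target - 1L, ]
    if (plus) data.frame(start = i1$start, end = i1$end + del_len)
    else data.frame(start = i1$start - del_len, end = i1$end)
  } else if (type == "IP") {
    # retain the last ins_len intronic bases of intron `target`
    i1 <- cj[cj$intron == target, ]
    if (plus) data.frame(start = i1$start, end = i1$end - ins_len)
    else data.frame(start = i1$start + ins_len, end = i1$end)
  } else if (type == "IC") {
    # cryptic exon of ins_len at `offset` from the intron's 5' end
    i1 <- cj[cj$intron == target, ]
    if (plus) {
      data.frame(start = c(i1$start, i1$start + offset + ins_len),
                 end = c(i1$start + offset - 1L, i1$end))
    } else {
      data.frame(start = c(i1$start, i1$end - offset + 1L),
                 end = c(i1$end - offset - ins_len, i1$end))
    }
  } else stop("unknown template type: ", type)
}

#' Realize an event catalog against simulated models
#'
#' Converts event templates to concrete junctions, classifies them with
#' the package's own event engine, and returns the catalog annotated with
#' the resulting event name and junction keys — guaranteeing that
#' simulated junctions and detected events agree by construction.
#'
#' @param models Named list of [gene_model()] objects.
#' @param catalog Template data frame ([default_event_catalog()]).
#' @return Catalog with added columns `name`, `supporting`, `denominator`,
#'   `chrom`, `strand`, `frame`.
#' @export
realize_catalog <- function(models, catalog) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    tpl <- catalog[i, ]
    m <- models[[tpl$gene]]
    if (is.null(m)) stop("catalog gene not in models: ", tpl$gene)
    jx <- .template_junctions(m, tpl$type, tpl$target, tpl$del_len,
                              tpl$ins_len, tpl$offset)
    jdf <- data.frame(chrom = m$chrom, intron_start = jx$start,
                      intron_end = jx$end, strand = m$strand,
                      motif = 0L, annotated = 0L, unique_reads = 10L,
                      multimapped_reads = 0L, overhang = 50L)
    ev <- detect_events(m, jdf)
    if (nrow(ev) != 1L || ev$type != tpl$type) {
      stop("template for ", tpl$gene, "/", tpl$type,
           " did not realize into a single event of its type")
    }
    cbind(tpl, data.frame(name = ev$name, supporting = ev$supporting,
                          denominator = ev$denominator, chrom = m$chrom,
                          strand = m$strand, frame = ev$frame))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.parse_keys <- function(keys) {
  parts <- strsplit(keys, "[:-]")
  data.frame(chrom = vapply(parts, `[`, character(1), 1),
             start = as.integer(vapply(parts, `[`, character(1), 2)),
             end = as.integer(vapply(parts, `[`, character(1), 3)))
}

#' Simulate one sample's junction and coverage tables
#'
#' Canonical junction depths are negative-binomial. For each catalog
#' event the sample carries (Bernoulli in the event frequency for cohort
#' events; forced for spike-ins), a region depth `D` is drawn, alternative
#' reads are `Binomial(D, PSI/100)`, the supporting junction(s) receive
#' the alternative reads and the replaced canonical junctions `D - alt`,
#' so estimated PSI is binomial around the truth. Exon depths are the
#' mean of adjacent junction totals. Random streams are split per sample
#' and per event from the master seed.
#'
#' @param models Named list of [gene_model()] objects.
#' @param rcat Realized catalog ([realize_catalog()]).
#' @param cfg A [simulation_config()].
#' @param sample_id Sample label.
#' @param sample_index Integer index driving this sample's random stream.
#' @param spike_rows Integer indices of `rcat` rows forced as spike-ins
#'   (PSI drawn uniformly from `cfg$spikein_psi_range`).
#' @param qc_fail Zero out 20% of exon depths to force coverage QC failure.
#' @return List `junctions` (SJ dialect data frame), `coverage` (per-exon
#'   depth data frame), `truth` (data frame `sample_id`, `gene`, `event`,
#'   `true_psi`, `is_spikein`).
#' @export
simulate_sample <- function(models, rcat, cfg, sample_id, sample_index,
                            spike_rows = integer(), qc_fail = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  # baseline canonical depths, one stream per sample
  set.seed(.sub_seed(cfg$seed, sample_index, 0L))
  canon <- list()
  for (m in models) {
    cj <- canonical_junctions(m)
    d <- stats::rnbinom(nrow(cj), mu = cfg$coverage_mean,
                        size = cfg$coverage_dispersion)
    canon[[m$gene]] <- structure(as.integer(d), names = cj$key)
  }
  alt_counts <- structure(integer(), names = character())
  truth <- NULL
  for (e in seq_len(nrow(rcat))) {
    set.seed(.sub_seed(cfg$seed, sample_index, e))
    spiked <- e %in% spike_rows
    if (spiked) {
      psi <- stats::runif(1, cfg$spikein_psi_range[1], cfg$spikein_psi_range[2])
    } else {
      carrier <- stats::rbinom(1, 1, rcat$freq[e]) == 1
      psi <- if (carrier) 100 * stats::rbeta(1, rcat$shape1[e], rcat$shape2[e])
             else 0
    }
    if (psi <= 0) next
    D <- stats::rnbinom(1, mu = cfg$coverage_mean,
                        size = cfg$coverage_dispersion)
    alt <- if (D > 0) stats::rbinom(1, D, psi / 100) else 0L
    truth <- rbind(truth, data.frame(
      sample_id = sample_id, gene = rcat$gene[e], event = rcat$name[e],
      true_psi = psi, region_depth = D, is_spikein = spiked))
    if (alt < 1L) next
    for (k in strsplit(rcat$supporting[e], ",")[[1]]) {
      alt_counts[k] <- if (is.na(alt_counts[k])) as.integer(alt) else
        alt_counts[[k]] + as.integer(alt)
    }
    for (k in strsplit(rcat$denominator[e], ",")[[1]]) {
      canon[[rcat$gene[e]]][k] <- as.integer(D - alt)
    }
  }
  # assemble the junction table
  jx_rows <- list()
  for (m in models) {
    cj <- canonical_junctions(m)
    jx_rows[[m$gene]] <- data.frame(
      chrom = m$chrom, intron_start = cj$start, intron_end = cj$end,
      strand = m$strand, motif = 1L, annotated = 1L,
      unique_reads = as.integer(canon[[m$gene]][cj$key]),
      multimapped_reads = 0L, overhang = 75L)
  }
  jx <- do.call(rbind, jx_rows)
  if (length(alt_counts)) {
    ak <- .parse_keys(names(alt_counts))
    gene_of <- vapply(ak$chrom, function(ch) {
      names(models)[vapply(models, function(m) m$chrom == ch, logical(1))][1]
    }, character(1))
    jx <- rbind(jx, data.frame(
      chrom = ak$chrom, intron_start = ak$start, intron_end = ak$end,
      strand = vapply(models[gene_of], `[[`, character(1), "strand"),
      motif = 1L, annotated = 0L, unique_reads = as.integer(alt_counts),
      multimapped_reads = 0L, overhang = 60L))
  }
  jx <- jx[order(jx$chrom, jx$intron_start, jx$intron_end), ]
  rownames(jx) <- NULL
  # per-exon coverage: mean of totals on adjacent junctions
  totals <- structure(jx$unique_reads,
                      names = junction_key(jx$chrom, jx$intron_start,
                                           jx$intron_end))
  cov_rows <- lapply(models, function(m) {
    cj <- canonical_junctions(m)
    tot <- canon[[m$gene]][cj$key]
    # add alternative reads that traverse each canonical region
    for (k in names(alt_counts)) {
      ak <- .parse_keys(k)
      if (ak$chrom == m$chrom) {
        ov <- cj$start <= ak$end & cj$end >= ak$start
        tot[ov] <- tot[ov] + alt_counts[[k]]
      }
    }
    n <- nrow(m$exons)
    depth <- vapply(seq_len(n), function(i) {
      adj <- c(if (i > 1L) tot[i - 1L], if (i < n) tot[i])
      round(mean(adj))
    }, numeric(1))
    data.frame(gene = m$gene, exon_index = seq_len(n), mean_depth = depth)
  })
  cov <- do.call(rbind, cov_rows)
  rownames(cov) <- NULL
  if (qc_fail) {
    set.seed(.sub_seed(cfg$seed, sample_index, 99991L))
    kill <- sample(nrow(cov), ceiling(0.2 * nrow(cov)))
    cov$mean_depth[kill] <- 0
  }
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(), gene = character(),
                        event = character(), true_psi = numeric(),
                        region_depth = integer(), is_spikein = logical())
  }
  list(junctions = jx, coverage = cov, truth = truth)
}

#' Materialize a full synthetic cohort on disk
#'
#' Simulates gene models, a control cohort carrying the common-event
#' catalog, and patient samples each spiked with one variant-driven event
#' (a 17-nt frameshifting partial skip of exon 4 of one gene, absent from
#' controls), then writes every pipeline input dialect: `models.gtf`,
#' `panel.json`, per-sample `junctions/<id>.SJ.tab` and
#' `coverage/<id>.tsv`, `metadata.tsv` and `truth.tsv`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `models`, `catalog` (realized,
#'   spike rows flagged by `spikein`), `truth`, `metadata` and the file
#'   `paths`.
#' @export
simulate_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "junctions"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  models <- simulate_models(cfg)
  gtf <- file.path(dir, "models.gtf")
  write_models_gtf(models, gtf)
  panel <- panel_from_models(models)
  write_panel_config(panel, file.path(dir, "panel.json"))

  rcat <- realize_catalog(models, default_event_catalog(models))
  rcat$spikein <- FALSE
  spike_tpl <- do.call(rbind, lapply(seq_len(max(cfg$n_patients, 1L)), function(i) {
    g <- names(models)[(i - 1L) %% length(models) + 1L]
    data.frame(gene = g, type = "ESP", target = 4L, del_len = 17L,
               ins_len = 0L, offset = 0L, freq = 0, shape1 = 1, shape2 = 1)
  }))
  spike_tpl <- spike_tpl[!duplicated(spike_tpl$gene), , drop = FALSE]
  if (cfg$n_patients > 0) {
    rspike <- realize_catalog(models, spike_tpl)
    rspike$spikein <- TRUE
    rcat <- rbind(rcat, rspike)
  }

  n_fail <- round(cfg$qc_fail_fraction * cfg$n_controls)
  ids <- c(sprintf("CTRL%03d", seq_len(cfg$n_controls)),
           if (cfg$n_patients > 0) sprintf("PAT%03d", seq_len(cfg$n_patients)))
  roles <- c(rep("control", cfg$n_controls), rep("patient", cfg$n_patients))
  truth <- NULL
  paths <- list(gtf = gtf, panel = file.path(dir, "panel.json"),
                junctions = character(), coverage = character())
  for (i in seq_along(ids)) {
    is_patient <- roles[i] == "patient"
    spike_rows <- integer()
    if (is_patient) {
      pg <- names(models)[(i - cfg$n_controls - 1L) %% length(models) + 1L]
      spike_rows <- which(rcat$spikein & rcat$gene == pg)
    }
    smp <- simulate_sample(models, rcat, cfg, ids[i], sample_index = i,
                           spike_rows = spike_rows,
                           qc_fail = (!is_patient && i <= n_fail))
    jp <- file.path(dir, "junctions", paste0(ids[i], ".SJ.tab"))
    cp <- file.path(dir, "coverage", paste0(ids[i], ".tsv"))
    write_junctions(smp$junctions, jp)
    write_exon_coverage(smp$coverage, cp)
    paths$junctions[ids[i]] <- jp
    paths$coverage[ids[i]] <- cp
    truth <- rbind(truth, smp$truth)
  }
  set.seed(.sub_seed(cfg$seed, 999983L, 0L))
  metadata <- data.frame(
    sample_id = ids, role = roles,
    age_range = sample(c("20-30", "30-40", "40-50", "50-60"), length(ids),
                       replace = TRUE, prob = c(0.15, 0.55, 0.2, 0.1)),
    gender = sample(c("F", "M"), length(ids), replace = TRUE,
                    prob = c(0.6, 0.4)),
    ethnicity = sample(c("Caucasian", "Hispanic", "Asian", "Other"),
                       length(ids), replace = TRUE,
                       prob = c(0.55, 0.2, 0.15, 0.1)),
    batch = sample(c("B1", "B2", "B3"), length(ids), replace = TRUE))
  write_tsv(metadata, file.path(dir, "metadata.tsv"))
  if (!is.null(truth)) write_tsv(truth, file.path(dir, "truth.tsv"))
  paths$metadata <- file.path(dir, "metadata.tsv")
  paths$truth <- file.path(dir, "truth.tsv")
  invisible(list(dir = dir, models = models, catalog = rcat, truth = truth,
                 metadata = metadata, paths = paths, config = cfg))
}

#' Fast single-event PSI measurement simulator
#'
#' Draws `n` independent measurements of one splicing event at a given
#' true PSI under the package's quantification model: region depth `D`
#' negative-binomial, alternative reads `Binomial(D, PSI/100)`, estimated
#' PSI `100 * alt / D`. This is the in-memory equivalent of simulating and
#' quantifying a single-junction event, used for statistical validation
#' at scale.
#'
#' @param n Number of measurements (samples).
#' @param true_psi True PSI (percent).
#' @param coverage_mean,coverage_dispersion Negative-binomial depth model.
#' @return Data frame `depth`, `alt_reads`, `region_reads`, `psi`
#'   (`NA` where depth is 0).
#' @export
simulate_psi_measurements <- function(n, true_psi, coverage_mean = 500,
                                      coverage_dispersion = 8) {
  stopifnot(true_psi >= 0, true_psi <= 100)
  D <- stats::rnbinom(n, mu = coverage_mean, size = coverage_dispersion)
  alt <- stats::rbinom(n, D, true_psi / 100)
  data.frame(depth = D, alt_reads = alt, region_reads = D,
             psi = ifelse(D > 0, 100 * alt / D, NA_real_))
}
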