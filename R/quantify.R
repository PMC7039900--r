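# unique-read counts keyed by junction interval
.junction_count_map <- function(junctions) {
  if (!nrow(junctions)) return(structure(integer(), names = character()))
  k <- junction_key(junctions$chrom, junctions$intron_start,
                    junctions$intron_end)
  counts <- tapply(junctions$unique_reads, k, sum)
  structure(as.integer(counts), names = names(counts))
}

.lookup_counts <- function(keys, count_map) {
  v <- count_map[keys]
  v[is.na(v)] <- 0L
  as.integer(v)
}

#' Alternative-read support of an event in one sample
#'
#' The unique read count of the event's supporting junction; cryptic-exon
#' (IC) events are supported by two junctions, whose counts are averaged
#' (rounded), since each included cryptic exon contributes one read to each
#' flank.
#'
#' @param event One-row event data frame.
#' @param junctions Junction data frame for the sample.
#' @return Non-negative integer.
#' @export
event_alt_reads <- function(event, junctions) {
  cm <- .junction_count_map(junctions)
  keys <- strsplit(event$supporting, ",")[[1]]
  v <- .lookup_counts(keys, cm)
  if (length(v) > 1L) as.integer(round(mean(v))) else v
}

#' Total reads in the region covering an event
#'
#' The PSI denominator: alternative reads plus canonical support, where
#' canonical support is the rounded mean of unique reads over the
#' canonical junctions the event replaces (one junction for ESP/IP and for
#' the host intron of an IC; `k + 1` junctions for a `k`-exon skip).
#' Junctions absent from the sample count as zero.
#'
#' @param event One-row event data frame.
#' @param junctions Junction data frame for the sample.
#' @return Non-negative integer.
#' @export
region_reads <- function(event, junctions) {
  cm <- .junction_count_map(junctions)
  alt <- event_alt_reads(event, junctions)
  canon <- .lookup_counts(strsplit(event$denominator, ",")[[1]], cm)
  alt + as.integer(round(mean(canon)))
}

#' Percent spliced in (PSI) of one event in one sample
#'
#' PSI is the percentage of reads in the event region supporting the
#' non-canonical event: `100 * alt_reads / region_reads`. When the region
#' has no reads the event is not assessable and PSI is `NA`.
#'
#' @param event One-row event data frame.
#' @param junctions Junction data frame for the sample.
#' @param sample_id Optional sample label carried into the result.
#' @return One-row data frame with `sample_id`, `gene`, `event`,
#'   `alt_reads`, `region_reads`, `psi`.
#' @export
compute_psi <- function(event, junctions, sample_id = NA_character_) {
  alt <- event_alt_reads(event, junctions)
  region <- region_reads(event, junctions)
  data.frame(
    sample_id = sample_id, gene = event$gene, event = event$name,
    alt_reads = alt, region_reads = region,
    psi = if (region > 0L) 100 * alt / region else NA_real_
  )
}

#' Quantify an event catalog in one sample
#'
#' Computes PSI for every catalog event from the sample's junction counts.
#' Events with zero supporting reads get PSI 0 (equivalent to absent) when
#' canonical coverage exists, and `NA` when the whole region is uncovered.
#'
#' @param events Event catalog data frame (see [build_event_catalog()]).
#' @param junctions Junction data frame for the sample.
#' @param sample_id Sample label.
#' @return Data frame, one row per event: `sample_id`, `gene`, `event`,
#'   `alt_reads`, `region_reads`, `psi` (percentage in `[0, 100]` or `NA`).
#' @export
quantify_sample <- function(events, junctions, sample_id = NA_character_) {
  if (!nrow(events)) {
    return(data.frame(sample_id = character(), gene = character(),
                      event = character(), alt_reads = integer(),
                      region_reads = integer(), psi = numeric()))
  }
  cm <- .junction_count_map(junctions)
  alt <- vapply(seq_len(nrow(events)), function(i) {
    v <- .lookup_counts(strsplit(events$supporting[i], ",")[[1]], cm)
    if (length(v) > 1L) as.integer(round(mean(v))) else v
  }, integer(1))
  canon <- vapply(seq_len(nrow(events)), function(i) {
    v <- .lookup_counts(strsplit(events$denominator[i], ",")[[1]], cm)
    as.integer(round(mean(v)))
  }, integer(1))
  region <- alt + canon
  data.frame(
    sample_id = sample_id, gene = events$gene, event = events$name,
    alt_reads = alt, region_reads = region,
    psi = ifelse(region > 0L, 100 * alt / region, NA_real_)
  )
}

#' Quantify an event catalog across samples
#'
#' @param events Event catalog data frame.
#' @param junction_sets Named list of per-sample junction data frames.
#' @return Long data frame of per-sample quantifications (rows =
#'   events x samples).
#' @export
quantify_cohort <- function(events, junction_sets) {
  if (is.null(names(junction_sets))) {
    stop("junction_sets must be a named list (names are sample ids)")
  }
  do.call(rbind, lapply(names(junction_sets), function(s) {
    quantify_sample(events, junction_sets[[s]], sample_id = s)
  }))
}

#' PSI matrix (events x samples)
#'
#' Wide export of a long quantification table, suitable for external
#' clustering or heatmap tools. Missing cells get PSI 0 with
#' `zero_missing = TRUE` (the zero-assigned convention) or `NA` otherwise.
#'
#' @param quants Long quantification data frame from [quantify_cohort()].
#' @param zero_missing Replace missing/NA PSI with 0.
#' @return Numeric matrix, rownames `gene:event`, colnames sample ids.
#' @export
psi_matrix <- function(quants, zero_missing = TRUE) {
  rows <- unique(paste0(quants$gene, ":", quants$event))
  cols <- unique(quants$sample_id)
  m <- matrix(if (zero_missing) 0 else NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  idx <- cbind(match(paste0(quants$gene, ":", quants$event), rows),
               match(quants$sample_id, cols))
  v <- quants$psi
  if (zero_missing) v[is.na(v)] <- 0
  m[idx] <- v
  m
}
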