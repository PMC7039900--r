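#' Construct a reference gene model
#'
#' A gene model holds the single designated reference isoform of one panel
#' gene: its ordered exons, strand, and any exons excluded from event
#' analysis (e.g. exons confounded by a highly homologous pseudogene).
#' Exons are stored 5' to 3' in transcript orientation, so for minus-strand
#' genes exon 1 is the interval with the highest genomic coordinate.
#' All coordinates are 1-based inclusive throughout the package.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of genomic exon boundaries
#'   (1-based inclusive). Order does not matter; exons are sorted internally.
#' @param transcript_id Identifier of the designated reference isoform.
#' @param excluded_exons Integer vector of exon indices (in transcript order,
#'   1-based) excluded from event quantification. Excluded exons remain in
#'   the model so transcript coordinates are unaffected; events overlapping
#'   them are dropped downstream.
#'
#' @return An object of class `gene_model`: a list with elements `gene`,
#'   `chrom`, `strand`, `transcript_id`, `exons` (data frame with columns
#'   `exon`, `start`, `end`, `width`, `tx_start`, `tx_end`, ordered 5'->3'),
#'   `excluded_exons` and `transcript_length`.
#' @export
#' @examples
#' m <- gene_model("TSG1", "chr1", "+", c(100, 300, 600), c(199, 399, 699), "TX1.1")
#' m$exons
gene_model <- function(gene, chrom, strand, exon_starts, exon_ends,
                       transcript_id = NA_character_,
                       excluded_exons = integer()) {
  stopifnot(length(gene) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for gene ", gene)
  }
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L) {
    stop("exon_starts and exon_ends must be non-empty and of equal length")
  }
  if (any(exon_ends < exon_starts)) {
    stop("every exon must satisfy start <= end (gene ", gene, ")")
  }
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  n <- length(exon_starts)
  if (n > 1L) {
    gaps <- exon_starts[-1L] - exon_ends[-n]
    if (any(gaps < 2L)) {
      stop("exons overlap or abut (intron length < 1) in gene ", gene)
    }
  }
  # transcript orientation: minus strand lists exons right-to-left
  if (strand == "-") {
    exon_starts <- rev(exon_starts)
    exon_ends <- rev(exon_ends)
  }
  width <- exon_ends - exon_starts + 1L
  tx_end <- cumsum(width)
  tx_start <- tx_end - width + 1L
  excluded_exons <- sort(unique(as.integer(excluded_exons)))
  if (length(excluded_exons) && (min(excluded_exons) < 1L || max(excluded_exons) > n)) {
    stop("excluded_exons outside 1..", n, " for gene ", gene)
  }
  structure(list(
    gene = as.character(gene),
    chrom = as.character(chrom),
    strand = strand,
    transcript_id = as.character(transcript_id),
    exons = data.frame(exon = seq_len(n), start = exon_starts, end = exon_ends,
                       width = width, tx_start = tx_start, tx_end = tx_end),
    excluded_exons = excluded_exons,
    transcript_length = sum(width)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s], %d exons, transcript %d nt\n",
              x$gene, x$transcript_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), x$transcript_length))
  if (length(x$excluded_exons)) {
    cat("  excluded exons:", paste(x$excluded_exons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Panel configuration
#'
#' Describes the gene panel: which reference isoform defines "canonical"
#' for each gene, which exons are excluded from analysis, and the
#' sample-level coverage QC thresholds.
#'
#' @param genes Character vector of gene symbols.
#' @param transcript_ids Character vector (same length) of reference isoform
#'   identifiers; the annotation must contain exactly these transcripts.
#' @param excluded_exons Named list mapping gene symbol to an integer vector
#'   of excluded exon indices (transcript order). Genes not named are
#'   unaffected.
#' @param min_exon_depth Minimum mean per-exon coverage counted as adequate
#'   (reads; default 50).
#' @param min_exon_fraction Minimum fraction of non-excluded panel exons that
#'   must reach `min_exon_depth` for a sample to pass coverage QC
#'   (default 0.85).
#'
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(genes, transcript_ids,
                         excluded_exons = list(),
                         min_exon_depth = 50,
                         min_exon_fraction = 0.85) {
  genes <- as.character(genes)
  transcript_ids <- as.character(transcript_ids)
  if (length(genes) != length(transcript_ids) || !length(genes)) {
    stop("genes and transcript_ids must be non-empty and of equal length")
  }
  if (anyDuplicated(genes)) stop("duplicate gene symbols in panel")
  if (!is.list(excluded_exons) ||
      (length(excluded_exons) && is.null(names(excluded_exons)))) {
    if (length(excluded_exons)) stop("excluded_exons must be a named list")
  }
  unknown <- setdiff(names(excluded_exons), genes)
  if (length(unknown)) {
    stop("excluded_exons names not in panel: ", paste(unknown, collapse = ", "))
  }
  if (!(min_exon_depth > 0)) stop("min_exon_depth must be strictly positive")
  if (!(min_exon_fraction > 0 && min_exon_fraction <= 1)) {
    stop("min_exon_fraction must be in (0, 1]")
  }
  structure(list(
    genes = data.frame(gene = genes, transcript_id = transcript_ids),
    excluded_exons = lapply(excluded_exons, as.integer),
    min_exon_depth = min_exon_depth,
    min_exon_fraction = min_exon_fraction
  ), class = "panel_config")
}

#' Read a panel configuration from JSON
#'
#' The JSON object carries `genes` (array of objects with `gene`,
#' `transcript_id` and optional `excluded_exons`) and optional
#' `min_exon_depth` / `min_exon_fraction` scalars.
#'
#' @param path Path to a JSON file.
#' @return A [panel_config()] object.
#' @export
read_panel_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  g <- x$genes
  if (is.null(g) || !nrow(as.data.frame(g))) stop("panel JSON has no genes")
  g <- as.data.frame(g)
  excl <- list()
  if ("excluded_exons" %in% names(g)) {
    for (i in seq_len(nrow(g))) {
      ee <- g$excluded_exons[[i]]
      if (length(ee)) excl[[g$gene[i]]] <- as.integer(ee)
    }
  }
  panel_config(
    genes = g$gene, transcript_ids = g$transcript_id, excluded_exons = excl,
    min_exon_depth = if (is.null(x$min_exon_depth)) 50 else x$min_exon_depth,
    min_exon_fraction = if (is.null(x$min_exon_fraction)) 0.85 else x$min_exon_fraction
  )
}

#' Write a panel configuration to JSON
#'
#' @param panel A [panel_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "panel_config"))
  genes <- lapply(seq_len(nrow(panel$genes)), function(i) {
    g <- panel$genes$gene[i]
    out <- list(gene = g, transcript_id = panel$genes$transcript_id[i])
    if (!is.null(panel$excluded_exons[[g]])) {
      out$excluded_exons <- I(panel$excluded_exons[[g]])
    }
    out
  })
  jsonlite::write_json(
    list(genes = genes, min_exon_depth = panel$min_exon_depth,
         min_exon_fraction = panel$min_exon_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load panel gene models from a GTF/GFF annotation
#'
#' Reads the annotation with `rtracklayer`, keeps the exon records of each
#' panel gene's designated reference isoform, and builds one [gene_model()]
#' per gene with the panel's exon exclusions applied.
#'
#' @param annotation_path GTF (or GFF) file containing the reference
#'   transcripts named in `panel`.
#' @param panel A [panel_config()] object.
#' @return Named list of `gene_model` objects (names are gene symbols,
#'   panel order).
#' @export
load_gene_models <- function(annotation_path, panel) {
  stopifnot(inherits(panel, "panel_config"))
  gr <- rtracklayer::import(annotation_path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id)) stop("annotation lacks transcript_id attributes")
  is_exon <- !is.na(mc$type) & tolower(as.character(mc$type)) == "exon"
  models <- vector("list", nrow(panel$genes))
  names(models) <- panel$genes$gene
  for (i in seq_len(nrow(panel$genes))) {
    g <- panel$genes$gene[i]
    tx <- panel$genes$transcript_id[i]
    sel <- is_exon & !is.na(mc$transcript_id) & mc$transcript_id == tx
    if (!any(sel)) {
      stop("transcript '", tx, "' for panel gene '", g,
           "' not found in ", annotation_path)
    }
    ex <- gr[sel]
    strand <- as.character(BiocGenerics::strand(ex))[1]
    if (!strand %in% c("+", "-")) {
      stop("transcript '", tx, "' (gene ", g, ") has no defined strand")
    }
    m <- gene_model(
      gene = g,
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = strand,
      exon_starts = BiocGenerics::start(ex),
      exon_ends = BiocGenerics::end(ex),
      transcript_id = tx,
      excluded_exons = if (is.null(panel$excluded_exons[[g]])) integer()
                       else panel$excluded_exons[[g]]
    )
    if (nrow(m$exons) < 2L) {
      warning("gene ", g, " has a single-exon reference isoform; ",
              "junction analysis is degenerate")
    }
    models[[i]] <- m
  }
  models
}

# exon index containing genomic position g, or NA
.exon_index_at <- function(model, g) {
  hit <- which(model$exons$start <= g & model$exons$end >= g)
  if (length(hit)) hit[1] else NA_integer_
}

# transcript position of an exonic genomic position (NA if intronic)
.tx_position <- function(model, g) {
  k <- .exon_index_at(model, g)
  if (is.na(k)) return(NA_integer_)
  e <- model$exons[k, ]
  if (model$strand == "+") e$tx_start + (g - e$start) else e$tx_start + (e$end - g)
}

#' Map a genomic position to transcript (r.-style) coordinates
#'
#' Exonic positions map to their cumulative transcript position (returned as
#' e.g. `"81"`). Intronic positions map to offset notation relative to the
#' nearest exon boundary in transcript orientation: `"80+12"` for the 12th
#' intronic base after the exon ending at transcript position 80, `"81-8"`
#' for the 8th intronic base before the exon starting at transcript
#' position 81. Ties at the intron midpoint use the upstream (`+`) form.
#'
#' @param model A [gene_model()].
#' @param genomic_pos Vector of genomic positions within the gene span.
#' @return Character vector of transcript-coordinate labels.
#' @seealso [transcript_to_genomic()] for the exonic inverse.
#' @export
#' @examples
#' m <- gene_model("G", "chr1", "+", c(1, 101), c(80, 200), "T")
#' genomic_to_transcript(m, c(1, 80, 101, 93))  # "1" "80" "81" "81-8"
genomic_to_transcript <- function(model, genomic_pos) {
  stopifnot(inherits(model, "gene_model"))
  vapply(as.integer(genomic_pos), function(g) {
    if (g < min(model$exons$start) || g > max(model$exons$end)) {
      stop("position ", g, " outside the span of gene ", model$gene)
    }
    t <- .tx_position(model, g)
    if (!is.na(t)) return(as.character(t))
    # intronic: locate the transcript-adjacent exon pair
    ex <- model$exons
    n <- nrow(ex)
    up <- NA_integer_
    for (i in seq_len(n - 1L)) {
      if (model$strand == "+") {
        if (g > ex$end[i] && g < ex$start[i + 1L]) { up <- i; break }
      } else {
        if (g < ex$start[i] && g > ex$end[i + 1L]) { up <- i; break }
      }
    }
    if (is.na(up)) stop("position ", g, " not locatable in gene ", model$gene)
    if (model$strand == "+") {
      d_up <- g - ex$end[up]
      d_down <- ex$start[up + 1L] - g
    } else {
      d_up <- ex$start[up] - g
      d_down <- g - ex$end[up + 1L]
    }
    if (d_up <= d_down) {
      paste0(ex$tx_end[up], "+", d_up)
    } else {
      paste0(ex$tx_start[up + 1L], "-", d_down)
    }
  }, character(1))
}

#' Map an exonic transcript position back to its genomic position
#'
#' Inverse of [genomic_to_transcript()] for exonic positions.
#'
#' @param model A [gene_model()].
#' @param tx_pos Vector of transcript positions in
#'   `1..model$transcript_length`.
#' @return Integer vector of genomic positions.
#' @export
transcript_to_genomic <- function(model, tx_pos) {
  stopifnot(inherits(model, "gene_model"))
  vapply(as.integer(tx_pos), function(t) {
    if (is.na(t) || t < 1L || t > model$transcript_length) {
      stop("transcript position ", t, " outside 1..", model$transcript_length,
           " for gene ", model$gene)
    }
    k <- which(model$exons$tx_start <= t & model$exons$tx_end >= t)[1]
    e <- model$exons[k, ]
    if (model$strand == "+") e$start + (t - e$tx_start) else e$end - (t - e$tx_start)
  }, integer(1))
}
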