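#' Read a splice-junction count table (STAR SJ.out.tab dialect)
#'
#' Nine tab-separated columns per row: chromosome, first intronic base,
#' last intronic base (both 1-based inclusive), strand code (0 undefined,
#' 1 `+`, 2 `-`), intron motif code, annotated flag, uniquely mapping read
#' count, multimapping read count, maximum overhang. Lines starting with
#' `#` are treated as headers and skipped. Rows are returned in file order.
#'
#' Only the uniquely mapping read count feeds quantification downstream;
#' the multimapper count is carried but unused.
#'
#' @param path Path to the junction table.
#' @return Data frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`"+"`, `"-"` or `"*"` for undefined), `motif`, `annotated`,
#'   `unique_reads`, `multimapped_reads`, `overhang`.
#' @export
read_junctions <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      motif = integer(), annotated = integer(),
                      unique_reads = integer(), multimapped_reads = integer(),
                      overhang = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop("malformed junction row at line ", lineno[bad], " of ", path,
         ": expected 9 tab-separated fields, found ", nf[bad])
  }
  m <- do.call(rbind, parts)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2, as.integer))
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1]
    stop("non-integer field in junction row at line ", lineno[bad], " of ", path)
  }
  strand_code <- num[, 3]
  if (any(!strand_code %in% 0:2)) {
    bad <- which(!strand_code %in% 0:2)[1]
    stop("invalid strand code at line ", lineno[bad], " of ", path)
  }
  out <- data.frame(
    chrom = m[, 1],
    intron_start = num[, 1],
    intron_end = num[, 2],
    strand = c("*", "+", "-")[strand_code + 1L],
    motif = num[, 4],
    annotated = num[, 5],
    unique_reads = num[, 6],
    multimapped_reads = num[, 7],
    overhang = num[, 8]
  )
  if (any(out$intron_end < out$intron_start)) {
    bad <- which(out$intron_end < out$intron_start)[1]
    stop("intron_end < intron_start at line ", lineno[bad], " of ", path)
  }
  if (any(out$unique_reads < 0)) stop("negative read count in ", path)
  out
}

#' Write a junction table in the SJ.out.tab dialect
#'
#' Inverse of [read_junctions()]; `read_junctions(write_junctions(x, f))`
#' reproduces `x`.
#'
#' @param junctions Data frame as returned by [read_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  code <- match(junctions$strand, c("*", "+", "-")) - 1L
  if (anyNA(code)) stop("strand must be one of '*', '+', '-'")
  m <- cbind(junctions$chrom, junctions$intron_start, junctions$intron_end,
             code, junctions$motif, junctions$annotated,
             junctions$unique_reads, junctions$multimapped_reads,
             junctions$overhang)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-exon mean-coverage table
#'
#' Tab-separated with a header naming columns `gene`, `exon_index` and
#' `mean_depth`. One row per (gene, exon); duplicates are an error. Exons
#' absent from the table are treated as depth 0 by consumers.
#'
#' @param path Path to the coverage TSV.
#' @return Data frame with columns `gene`, `exon_index`, `mean_depth`.
#' @export
read_exon_coverage <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "exon_index", "mean_depth")
  if (!all(need %in% names(x))) {
    stop("coverage table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  x <- x[, need]
  x$exon_index <- as.integer(x$exon_index)
  x$mean_depth <- as.numeric(x$mean_depth)
  if (any(x$mean_depth < 0, na.rm = TRUE)) stop("negative mean_depth in ", path)
  key <- paste(x$gene, x$exon_index)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, exon) row in ", path, ": ", key[duplicated(key)][1])
  }
  x
}

#' Write a per-exon coverage table
#'
#' @param coverage Data frame with columns `gene`, `exon_index`, `mean_depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_coverage <- function(coverage, path) {
  utils::write.table(coverage[, c("gene", "exon_index", "mean_depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared TSV writer for pipeline outputs (header + tab separation, no quoting)
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
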