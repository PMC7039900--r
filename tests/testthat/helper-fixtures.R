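# shared in-code fixtures: toy models, toy GTF text, random models

# three-exon model: exon widths 80/200/120, plus strand by default
toy_model <- function(strand = "+", gene = "G", chrom = "chr1",
                      excluded = integer()) {
  gene_model(gene, chrom, strand,
             exon_starts = c(1001, 2001, 3001),
             exon_ends = c(1080, 2200, 3120),
             transcript_id = "T1", excluded_exons = excluded)
}

toy_junction <- function(start, end, strand = "+", chrom = "chr1",
                         unique_reads = 10L) {
  data.frame(chrom = chrom, intron_start = start, intron_end = end,
             strand = strand, motif = 0L, annotated = 0L,
             unique_reads = unique_reads, multimapped_reads = 0L,
             overhang = 50L)
}

# minimal GTF text for load_gene_models()
write_toy_gtf <- function(path, strand = "+", gene = "G", tx = "T1",
                          chrom = "chr1",
                          starts = c(1001, 2001, 3001),
                          ends = c(1080, 2200, 3120)) {
  attr9 <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   gene, tx, gene)
  rows <- c(
    sprintf("%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            chrom, min(starts), max(ends), strand, attr9),
    sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
            chrom, starts, ends, strand, attr9))
  writeLines(rows, path)
  path
}

# random multi-exon model for property tests
random_model <- function(seed, n_exons = NULL) {
  set.seed(seed)
  n <- if (is.null(n_exons)) sample(3:10, 1) else n_exons
  w <- sample(50:300, n, replace = TRUE)
  gaps <- sample(100:2000, n - 1, replace = TRUE)
  starts <- integer(n); ends <- integer(n); pos <- 5001L
  for (i in seq_len(n)) {
    starts[i] <- pos; ends[i] <- pos + w[i] - 1L
    if (i < n) pos <- ends[i] + gaps[i] + 1L
  }
  gene_model(paste0("RG", seed), paste0("chr", seed %% 5 + 1),
             if (seed %% 2 == 0) "+" else "-", starts, ends,
             transcript_id = paste0("RT", seed))
}
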