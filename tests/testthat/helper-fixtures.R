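# Small in-code fixture builders shared across test files.

# Shorthand transcript_set from parallel exon vectors.
make_ts <- function(id, starts, ends, strand = "+", chrom = "chr2L",
                    gene_id = id, source = "novel") {
  transcript_set(data.frame(transcript_id = id, gene_id = gene_id,
                            source = source, chrom = chrom, start = starts,
                            end = ends, strand = strand,
                            stringsAsFactors = FALSE))
}

# A tiny annotation (coordinates < 1e4) for per-base oracle comparisons:
# three coding genes with wide introns, mixed strands, non-overlapping.
tiny_genome <- function() {
  transcript_set(rbind(
    data.frame(transcript_id = "t_gA", gene_id = "gA", source = "ucsc",
               chrom = "chrT", start = c(500, 2000), end = c(900, 2500),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(transcript_id = "t_gB", gene_id = "gB", source = "ucsc",
               chrom = "chrT", start = c(3200, 4800), end = c(3700, 5400),
               strand = "-", stringsAsFactors = FALSE),
    data.frame(transcript_id = "t_gC", gene_id = "gC", source = "ucsc",
               chrom = "chrT", start = c(6000, 7500, 8600),
               end = c(6400, 7900, 9000), strand = "+",
               stringsAsFactors = FALSE)))
}

# Independent per-base classification oracle: label every base of the
# transcript against per-gene exon/span base sets and aggregate, mirroring
# the class definitions (exon contact > intronic span overlap > intergenic,
# anchor by max overlap then lexicographic gene id, unknown strand wins).
oracle_classify <- function(lnc_tx_row, lnc_exons, coding) {
  if (lnc_tx_row$strand == "*") return("unknown")
  genes <- gene_table(coding)
  genes <- genes[order(genes$gene_id), ]
  lnc_bases <- unlist(Map(seq, lnc_exons$start, lnc_exons$end - 1))
  span_bases <- seq(lnc_tx_row$start, lnc_tx_row$end - 1)
  exon_bp <- span_bp <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != lnc_tx_row$chrom) next
    ge <- coding$exons[coding$exons$gene_id == genes$gene_id[i], ]
    gene_exon_bases <- unlist(Map(seq, ge$start, ge$end - 1))
    gene_span_bases <- seq(genes$start[i], genes$end[i] - 1)
    exon_bp[i] <- length(intersect(lnc_bases, gene_exon_bases))
    span_bp[i] <- length(intersect(span_bases, gene_span_bases))
  }
  if (any(exon_bp > 0)) {
    hit <- which.max(exon_bp)  # genes sorted by id: ties pick smallest id
    if (lnc_tx_row$strand == genes$strand[hit]) "exonic_sense"
    else "exonic_antisense"
  } else if (any(span_bp > 0)) {
    hit <- which.max(span_bp)
    if (lnc_tx_row$strand == genes$strand[hit]) "intronic_sense"
    else "intronic_antisense"
  } else {
    "intergenic"
  }
}

# Random transcript models over the tiny genome's coordinate range.
random_tiny_transcripts <- function(n, seed = 42) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:3, 1)
    ex_len <- sample(30:300, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(20:200, n_ex - 1, replace = TRUE) else integer()
    start <- sample(0:9000, 1)
    starts <- start + c(0, cumsum(ex_len[-n_ex] + gaps))
    data.frame(transcript_id = sprintf("r%04d", i),
               gene_id = sprintf("r%04d", i), source = "novel",
               chrom = "chrT", start = starts, end = starts + ex_len,
               strand = sample(c("+", "-", "*"), 1),
               stringsAsFactors = FALSE)
  })
  transcript_set(do.call(rbind, rows))
}
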