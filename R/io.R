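#' Read transcript models from a GTF file
#'
#' Parses `exon` features into a [transcript_set()].  Both common attribute
#' dialects are accepted (`key "value";` and `key=value`).  GTF's 1-based
#' closed coordinates are converted to the package's 0-based half-open
#' convention on read; strand `"."` maps to unknown (`"*"`).  The transcript
#' span is always recomputed from the exons; any transcript-level feature
#' lines in the file are ignored.
#'
#' @param path GTF file.
#' @param source Provenance label attached to every transcript (one of
#'   `flybase`, `ucsc`, `young`, `brown`, `novel`).
#' @param strict If `TRUE` (default) malformed lines are errors naming the
#'   line number; if `FALSE` they are skipped with a warning.
#' @return A [transcript_set()].
#' @export
read_gtf <- function(path, source = "novel", strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- vector("list", sum(keep))
  n <- 0L
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    bad <- NULL
    if (length(fields) < 9L) {
      bad <- "fewer than 9 tab-separated fields"
    } else if (fields[3L] == "exon") {
      start1 <- suppressWarnings(as.numeric(fields[4L]))
      end1 <- suppressWarnings(as.numeric(fields[5L]))
      if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1) {
        bad <- "invalid coordinates"
      } else {
        attrs <- .parse_gtf_attrs(fields[9L])
        if (is.null(attrs[["transcript_id"]])) {
          bad <- "exon without transcript_id attribute"
        } else {
          strand <- fields[7L]
          if (!strand %in% c("+", "-", ".")) bad <- "invalid strand"
        }
      }
    }
    if (!is.null(bad)) {
      msg <- paste0("malformed GTF record at line ", i, ": ", bad)
      if (strict) stop(msg) else { warning(msg, "; skipped"); next }
    }
    if (fields[3L] != "exon") next
    n <- n + 1L
    rows[[n]] <- data.frame(
      transcript_id = attrs[["transcript_id"]],
      gene_id = if (is.null(attrs[["gene_id"]])) attrs[["transcript_id"]]
                else attrs[["gene_id"]],
      source = source, chrom = fields[1L],
      start = start1 - 1, end = end1,
      strand = if (fields[7L] == ".") "*" else fields[7L],
      stringsAsFactors = FALSE)
  }
  transcript_set(if (n) do.call(rbind, rows[seq_len(n)]) else NULL)
}

# Accepts both `key "value";` and `key=value;` attribute dialects.
.parse_gtf_attrs <- function(s) {
  out <- list()
  m <- gregexpr("(\\w+)\\s+\"([^\"]*)\"", s, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    for (tok in regmatches(s, gregexpr("(\\w+)\\s+\"([^\"]*)\"", s))[[1L]]) {
      key <- sub("^(\\w+)\\s+.*$", "\\1", tok)
      val <- sub("^\\w+\\s+\"([^\"]*)\"$", "\\1", tok)
      out[[key]] <- val
    }
  }
  for (tok in strsplit(s, ";", fixed = TRUE)[[1L]]) {
    tok <- trimws(tok)
    if (grepl("^\\w+=", tok)) {
      key <- sub("=.*$", "", tok)
      out[[key]] <- sub("^\\w+=", "", tok)
    }
  }
  out
}

#' Write a transcript set as GTF
#'
#' One `exon` line per exon, converting back to 1-based closed coordinates.
#' `read_gtf()` of the result reproduces the set exactly.
#'
#' @param ts A [transcript_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path) {
  stopifnot(inherits(ts, "transcript_set"))
  e <- ts$exons
  lines <- if (nrow(e)) {
    sprintf(
      "%s\tlncCurate\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      e$chrom, as.integer(e$start + 1), as.integer(e$end),
      ifelse(e$strand == "*", ".", e$strand), e$gene_id, e$transcript_id)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' BED3+ records in native 0-based half-open coordinates, tagged with a mark
#' and dataset label.  A strand column (BED6) is parsed but ignored by all
#' downstream peak operations.
#'
#' @param path BED file.
#' @param mark Mark label (e.g. `"H3K4me3"`, `"H3K36me3"`, `"PolII"`,
#'   `"CAGE"`).
#' @param dataset Dataset/stage label.
#' @param strict Malformed records error (default) or are skipped with a
#'   warning.
#' @return Data frame: `chrom`, `start`, `end`, `strand`, `mark`, `dataset`.
#' @export
read_bed <- function(path, mark = NA_character_, dataset = NA_character_,
                     strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  rows <- vector("list", length(keep))
  n <- 0L
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    start <- suppressWarnings(as.numeric(fields[2L]))
    end <- suppressWarnings(as.numeric(fields[3L]))
    if (length(fields) < 3L || is.na(start) || is.na(end) ||
        start < 0 || start >= end) {
      msg <- paste0("malformed BED record at line ", i)
      if (strict) stop(msg) else { warning(msg, "; skipped"); next }
    }
    strand <- if (length(fields) >= 6L && fields[6L] %in% c("+", "-"))
      fields[6L] else "*"
    n <- n + 1L
    rows[[n]] <- data.frame(chrom = fields[1L], start = start, end = end,
                            strand = strand, mark = mark, dataset = dataset,
                            stringsAsFactors = FALSE)
  }
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), mark = character(),
                      dataset = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Write peaks as BED
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optional `strand`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  lines <- if (nrow(peaks)) {
    strand <- if ("strand" %in% names(peaks)) peaks$strand else "*"
    sprintf("%s\t%d\t%d\tpeak%d\t0\t%s", peaks$chrom,
            as.integer(peaks$start), as.integer(peaks$end),
            seq_len(nrow(peaks)), ifelse(strand == "*", ".", strand))
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript lengths from a 2-column TSV or a FASTA file
#'
#' @param path Length table (`id<TAB>length`, no header) or FASTA; FASTA is
#'   detected by content.
#' @return Named numeric vector of transcript lengths.
#' @export
read_transcript_lengths <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
    return(stats::setNames(as.numeric(Biostrings::width(seqs)), ids))
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("length table must have two columns")
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' Read pairwise alignment records (BLAST-like 12-column tabular)
#'
#' Columns follow the standard tabular dialect: query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score.  Overlap fractions are computed as
#' aligned length over transcript length (capped at 1) using the companion
#' length lookup.
#'
#' @param path Tabular alignment file.
#' @param lengths Named numeric vector of transcript lengths (see
#'   [read_transcript_lengths()]); every query and subject id must be present.
#' @return Data frame of alignment records: `query_id`, `subject_id`,
#'   `identity_pct`, `align_length`, `e_value`, `bit_score`,
#'   `overlap_fraction_query`, `overlap_fraction_subject`, `same_loci`
#'   (always `FALSE` on read; locus identity is a coordinate property
#'   recomputed from transcript models where needed).
#' @export
read_alignments <- function(path, lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(alignment_records())
  tab <- utils::read.delim(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("alignment table must have 12 columns")
  ids <- unique(c(tab[[1L]], tab[[2L]]))
  missing <- setdiff(ids, names(lengths))
  if (length(missing)) {
    stop("transcript ids absent from length lookup: ",
         paste(missing, collapse = ", "))
  }
  alignment_records(
    query_id = as.character(tab[[1L]]), subject_id = as.character(tab[[2L]]),
    identity_pct = as.numeric(tab[[3L]]), align_length = as.numeric(tab[[4L]]),
    e_value = as.numeric(tab[[11L]]), bit_score = as.numeric(tab[[12L]]),
    query_length = as.numeric(lengths[tab[[1L]]]),
    subject_length = as.numeric(lengths[tab[[2L]]]))
}

#' Construct alignment records
#'
#' @param query_id,subject_id Transcript ids.
#' @param identity_pct Percent identity in `[0, 100]`.
#' @param align_length Aligned length in bp.
#' @param e_value,bit_score Alignment statistics.
#' @param query_length,subject_length Transcript lengths used to derive the
#'   overlap fractions (aligned length / transcript length, capped at 1).
#' @param same_loci Locus-identity flag (identical chrom, strand, span and
#'   exon boundaries); defaults to `FALSE`.
#' @return Data frame of alignment records.
#' @export
alignment_records <- function(query_id = character(),
                              subject_id = character(),
                              identity_pct = numeric(),
                              align_length = numeric(),
                              e_value = numeric(),
                              bit_score = numeric(),
                              query_length = numeric(),
                              subject_length = numeric(),
                              same_loci = FALSE) {
  df <- data.frame(
    query_id = as.character(query_id), subject_id = as.character(subject_id),
    identity_pct = as.numeric(identity_pct),
    align_length = as.numeric(align_length),
    e_value = as.numeric(e_value),
    bit_score = if (length(bit_score)) as.numeric(bit_score) else
      rep(NA_real_, length(query_id)),
    overlap_fraction_query = pmin(1, as.numeric(align_length) /
                                    as.numeric(query_length)),
    overlap_fraction_subject = pmin(1, as.numeric(align_length) /
                                      as.numeric(subject_length)),
    same_loci = unname(rep_len(same_loci, length(query_id))),
    stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$e_value < 0)) stop("E-values must be non-negative")
    if (any(df$identity_pct < 0 | df$identity_pct > 100)) {
      stop("identity must lie in [0, 100]")
    }
  }
  df
}

#' Read coding-potential scores
#'
#' @param path TSV with header `transcript_id`, `method`, `value`; `method`
#'   is `cpc_label` (value `coding`/`noncoding`) or `cpat_probability`
#'   (numeric value in `[0, 1]`).
#' @return Data frame of score records.
#' @export
read_coding_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "method", "value")
  if (!all(need %in% names(tab))) {
    stop("score table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(tab$method %in% c("cpc_label", "cpat_probability"))) {
    stop("unknown coding-potential method")
  }
  num <- tab$method == "cpat_probability"
  p <- suppressWarnings(as.numeric(tab$value[num]))
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("cpat_probability values must be probabilities in [0, 1]")
  }
  if (!all(tab$value[!num] %in% c("coding", "noncoding"))) {
    stop("cpc_label values must be 'coding' or 'noncoding'")
  }
  tab[c("transcript_id", "method", "value")]
}

#' Read a per-library counts table
#'
#' The table is TSV with header `transcript_id`, `library`, `read_count`,
#' preceded by one comment line per library of the form
#' `#total_mapped=<library>:<count>` carrying the library-wide mapped-read
#' totals (RPKM denominators are library-wide, never re-derived from the
#' transcript subset).
#'
#' @param path Counts TSV.
#' @return List with `counts` (data frame) and `total_mapped` (named numeric).
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#total_mapped=", lines, value = TRUE)
  if (!length(hdr)) stop("counts table lacks '#total_mapped=' headers")
  kv <- sub("^#total_mapped=", "", hdr)
  lib <- sub(":.*$", "", kv)
  tot <- as.numeric(sub("^[^:]*:", "", kv))
  if (any(is.na(tot) | tot <= 0)) stop("total_mapped must be positive")
  body <- lines[!grepl("^#", lines)]
  counts <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  need <- c("transcript_id", "library", "read_count")
  if (!all(need %in% names(counts))) {
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(counts$library %in% lib)) {
    stop("library without a #total_mapped header: ",
         paste(setdiff(unique(counts$library), lib), collapse = ", "))
  }
  list(counts = counts[need], total_mapped = stats::setNames(tot, lib))
}

#' Write a counts table with library totals
#'
#' @param counts Data frame `transcript_id`, `library`, `read_count`.
#' @param total_mapped Named numeric vector of library-wide totals.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, total_mapped, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#total_mapped=%s:%d", names(total_mapped),
                     as.integer(total_mapped)), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path FASTQ file.
#' @return Data frame: `read_id`, `seq`, `qual` (phred+33 encoded string).
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  data.frame(read_id = ids,
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads as FASTQ (phred+33)
#'
#' @param reads Data frame `read_id`, `seq`, `qual`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
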