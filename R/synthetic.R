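#' @name synthetic_data
#' @title Seeded synthetic fixtures with planted ground truth
#'
#' @description
#' A deterministic generator for every input the pipeline consumes: a toy
#' genome annotation with multi-exon coding genes on both strands, lncRNA
#' candidates of every genomic class with planted labels, peak tracks with
#' planted signature truth, paired poly(A)/ribo-zero and developmental-stage
#' count tables with a planted poly(A)-minus subset, FASTQ reads with
#' engineered quality tails, and alignment fixtures realizing each
#' redundancy-rule branch.  One seed fixes every emitted value; each fixture
#' draws from its own substream derived from (seed, fixture name), so adding
#' a fixture never perturbs the others.
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: mean lncRNA
#' length 1008 bp versus mRNA 2869 bp, 94 % of lncRNAs with one to three
#' exons, 8-fold higher mRNA than lncRNA expression, 30 developmental-stage
#' libraries plus the two brain libraries, and a poly(A)-minus subset of
#' roughly 13 % of the brain-expressed lncRNAs (190 of 1464).
#'
#' @param seed Integer master seed.
#' @param n_coding_genes Number of coding genes in the toy annotation.
#' @param n_lnc_per_class Named counts of planted lncRNAs per class.
#' @param chrom,chrom_length Chromosome name and length (bp).
#' @param lnc_length_mean,mrna_length_mean Mean transcript lengths (bp).
#' @param lnc_exon_mass_1to3 Probability mass on 1-3 exons for lncRNAs.
#' @param mrna_to_lnc_expression_ratio Fold difference of mean mRNA over
#'   mean lncRNA expression.
#' @param polya_minus_fraction Fraction of brain-expressed lncRNAs planted
#'   as poly(A)-minus.
#' @param brain_expressed_fraction Fraction of lncRNAs expressed in brain.
#' @param nb_dispersion Negative-binomial dispersion of stage counts.
#' @param n_reads_fastq Number of additional random FASTQ reads beyond the
#'   engineered boundary cases.
#' @param n_stages Number of developmental-stage libraries.
#' @param cage_complete_fraction Fraction of known-strand lncRNAs planted
#'   with a CAGE peak at the 5' end.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_coding_genes = 40,
                       n_lnc_per_class = c(intergenic = 20,
                                           exonic_sense = 8,
                                           exonic_antisense = 12,
                                           intronic_sense = 6,
                                           intronic_antisense = 10,
                                           unknown = 6),
                       chrom = "chr2L",
                       chrom_length = 2e6,
                       lnc_length_mean = 1008,
                       mrna_length_mean = 2869,
                       lnc_exon_mass_1to3 = 0.94,
                       mrna_to_lnc_expression_ratio = 8,
                       polya_minus_fraction = 0.13,
                       brain_expressed_fraction = 1 / 3,
                       nb_dispersion = 0.3,
                       n_reads_fastq = 200,
                       n_stages = 30,
                       cage_complete_fraction = 0.55) {
  classes <- c("intergenic", "exonic_sense", "exonic_antisense",
               "intronic_sense", "intronic_antisense", "unknown")
  stopifnot(all(names(n_lnc_per_class) %in% classes),
            all(n_lnc_per_class >= 0), n_coding_genes >= 0,
            chrom_length > 0, lnc_exon_mass_1to3 >= 0,
            lnc_exon_mass_1to3 <= 1, polya_minus_fraction >= 0,
            polya_minus_fraction <= 1, mrna_to_lnc_expression_ratio > 0,
            nb_dispersion > 0, seed == floor(seed))
  full <- stats::setNames(rep(0L, length(classes)), classes)
  full[names(n_lnc_per_class)] <- n_lnc_per_class
  structure(list(seed = as.integer(seed), n_coding_genes = n_coding_genes,
                 n_lnc_per_class = full, chrom = chrom,
                 chrom_length = chrom_length,
                 lnc_length_mean = lnc_length_mean,
                 mrna_length_mean = mrna_length_mean,
                 lnc_exon_mass_1to3 = lnc_exon_mass_1to3,
                 mrna_to_lnc_expression_ratio = mrna_to_lnc_expression_ratio,
                 polya_minus_fraction = polya_minus_fraction,
                 brain_expressed_fraction = brain_expressed_fraction,
                 nb_dispersion = nb_dispersion,
                 n_reads_fastq = n_reads_fastq, n_stages = n_stages,
                 cage_complete_fraction = cage_complete_fraction),
            class = "sim_config")
}

# Per-fixture substream: seed derived from (master seed, fixture name).
.sim_seed <- function(config, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * (seq_along(codes) * 131)) %% 1000003
  s <- (as.numeric(config$seed %% 65536L) * 1000003 + h) %% 2147483647
  set.seed(as.integer(s))
}

#' Generate the toy coding-gene annotation
#'
#' Non-overlapping multi-exon coding genes on both strands with wide introns
#' and intergenic gaps sized to host planted lncRNAs.
#'
#' @param config A [sim_config()].
#' @return List with `transcripts` (a [transcript_set()], one transcript per
#'   gene, source `ucsc`) and `gaps` (data frame of intergenic intervals,
#'   including the regions before the first and after the last gene).
#' @export
generate_annotation <- function(config) {
  .sim_seed(config, "annotation")
  n <- config$n_coding_genes
  rows <- list()
  cursor <- 5000
  strands <- rep(c("+", "-"), length.out = max(n, 1L))
  gap_rows <- list(data.frame(start = 1000, end = cursor - 1000))
  for (i in seq_len(n)) {
    n_ex <- sample(2:5, 1L)
    target <- max(1200, stats::rnorm(1, config$mrna_length_mean, 400))
    ex_len <- round(stats::runif(n_ex, 0.6, 1.4) * target / n_ex)
    ex_len <- pmax(200, ex_len)
    in_len <- round(stats::runif(max(0, n_ex - 1L), 1500, 2500))
    starts <- cursor + c(0, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    gid <- sprintf("cg%03d", i)
    rows[[i]] <- data.frame(transcript_id = paste0("t_", gid), gene_id = gid,
                            source = "ucsc", chrom = config$chrom,
                            start = starts, end = ends, strand = strands[i],
                            stringsAsFactors = FALSE)
    gene_end <- max(ends)
    # 2 kb margins keep planted peaks, promoters (601 bp windows) and the
    # overhang of exonic lncRNAs from reaching a neighbouring gap's plants
    gap <- round(stats::runif(1, 6500, 9000))
    gap_rows[[i + 1L]] <- data.frame(start = gene_end + 2000,
                                     end = gene_end + gap - 2000)
    cursor <- gene_end + gap
    if (cursor > config$chrom_length - 5000) {
      stop("chromosome too short to pack ", n, " coding genes")
    }
  }
  gap_rows[[length(gap_rows) + 1L]] <-
    data.frame(start = cursor + 2000, end = config$chrom_length - 1000)
  gaps <- do.call(rbind, gap_rows)
  gaps <- gaps[gaps$end - gaps$start >= 2000, , drop = FALSE]
  rownames(gaps) <- NULL
  list(transcripts = transcript_set(if (n) do.call(rbind, rows) else NULL),
       gaps = gaps)
}

# Exon counts with configured mass on 1-3 exons.
.lnc_exon_count <- function(n, mass13, max_exons = 3L) {
  base <- c(0.58, 0.24, 0.18)
  probs <- c(base * mass13, c(0.7, 0.3) * (1 - mass13))
  k <- sample.int(5L, n, replace = TRUE, prob = probs)
  pmin(k, max_exons)
}

# Random lncRNA exon chain fitted into [lo, hi); returns data.frame of exons.
.lnc_structure <- function(lo, hi, n_ex, target_len) {
  avail <- hi - lo
  ex_len <- pmax(120, round(stats::runif(n_ex, 0.6, 1.4) * target_len / n_ex))
  in_len <- if (n_ex > 1L) round(stats::runif(n_ex - 1L, 120, 350)) else numeric()
  span <- sum(ex_len) + sum(in_len)
  if (span > avail - 10) {
    scale <- (avail - 10) / span
    ex_len <- pmax(80, floor(ex_len * scale))
    in_len <- pmax(60, floor(in_len * scale))
    span <- sum(ex_len) + sum(in_len)
  }
  off <- lo + floor(stats::runif(1, 0, max(1, avail - span)))
  starts <- off + c(0, cumsum(ex_len[-n_ex] + in_len))
  data.frame(start = starts, end = starts + ex_len)
}

#' Plant lncRNAs of every genomic class
#'
#' Places lncRNA transcripts realizing exactly the requested geometries:
#' intergenic (inside annotation gaps, one per gap), exonic sense/antisense
#' (first exon overlapping a coding exon), intronic sense/antisense (span
#' contained in a wide intron, no exon contact), and unknown (intergenic
#' placement with strand `*`).  At most one lncRNA is hosted per coding gene
#' and per gap, keeping planted chromatin signals separable.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [generate_annotation()].
#' @return List with `transcripts` (a [transcript_set()]; sources cycle over
#'   the catalogue's provenance labels), `labels` (named planted class per
#'   transcript) and `free_gaps` (gap rows not used for placement).
#' @export
generate_lncrnas <- function(config, annotation) {
  .sim_seed(config, "lncrnas")
  counts <- config$n_lnc_per_class
  coding <- annotation$transcripts
  gaps <- annotation$gaps
  genes <- gene_table(coding)
  sources <- c("flybase", "ucsc", "young", "brown", "novel")

  # hosts: disjoint gene pools for intronic and exonic plants
  n_intronic <- counts[["intronic_sense"]] + counts[["intronic_antisense"]]
  n_exonic <- counts[["exonic_sense"]] + counts[["exonic_antisense"]]
  if (n_intronic + n_exonic > nrow(genes)) {
    stop("not enough coding genes to host exonic/intronic lncRNAs")
  }
  n_gap <- counts[["intergenic"]] + counts[["unknown"]]
  if (n_gap > nrow(gaps)) stop("not enough intergenic gaps")
  host_intronic <- genes$gene_id[seq_len(n_intronic)]
  host_exonic <- genes$gene_id[n_intronic + seq_len(n_exonic)]
  gap_idx <- sample.int(nrow(gaps), n_gap)

  rows <- list(); labels <- character(); ids <- character()
  k <- 0L
  add <- function(exdf, strand, label) {
    k <<- k + 1L
    id <- sprintf("lnc_%s_%02d", label, sum(labels == label) + 1L)
    rows[[k]] <<- data.frame(transcript_id = id, gene_id = id,
                             source = sources[(k - 1L) %% 5L + 1L],
                             chrom = config$chrom, start = exdf$start,
                             end = exdf$end, strand = strand,
                             stringsAsFactors = FALSE)
    labels <<- c(labels, stats::setNames(label, id))
    ids <<- c(ids, id)
  }

  widest_intron <- function(gid) {
    e <- coding$exons[coding$exons$gene_id == gid, ]
    w <- e$start[-1L] - e$end[-nrow(e)]
    j <- which.max(w)
    c(e$end[j], e$start[j + 1L])
  }
  flip <- c("+" = "-", "-" = "+")

  hi <- 0L
  for (label in c("intronic_sense", "intronic_antisense")) {
    for (r in seq_len(counts[[label]])) {
      hi <- hi + 1L
      gid <- host_intronic[hi]
      g <- genes[genes$gene_id == gid, ]
      intron <- widest_intron(gid)
      n_ex <- .lnc_exon_count(1L, config$lnc_exon_mass_1to3, max_exons = 2L)
      ex <- .lnc_structure(intron[1L] + 150, intron[2L] - 150, n_ex,
                           min(config$lnc_length_mean, 900))
      strand <- if (label == "intronic_sense") g$strand else flip[[g$strand]]
      add(ex, strand, label)
    }
  }
  he <- 0L
  for (label in c("exonic_sense", "exonic_antisense")) {
    for (r in seq_len(counts[[label]])) {
      he <- he + 1L
      gid <- host_exonic[he]
      g <- genes[genes$gene_id == gid, ]
      ge <- coding$exons[coding$exons$gene_id == gid, ]
      tgt <- ge[nrow(ge), ]  # last exon: extension leaves the gene span
      ov <- round(stats::runif(1, 80, min(300, tgt$end - tgt$start - 10)))
      len1 <- ov + round(stats::runif(1, 150, 500))
      ex <- data.frame(start = tgt$end - ov, end = tgt$end - ov + len1)
      if (stats::runif(1) > 0.5) {
        gap2 <- round(stats::runif(1, 150, 300))
        len2 <- round(stats::runif(1, 150, 400))
        ex <- rbind(ex, data.frame(start = ex$end[1L] + gap2,
                                   end = ex$end[1L] + gap2 + len2))
      }
      strand <- if (label == "exonic_sense") g$strand else flip[[g$strand]]
      add(ex, strand, label)
    }
  }
  gk <- 0L
  for (label in c("intergenic", "unknown")) {
    for (r in seq_len(counts[[label]])) {
      gk <- gk + 1L
      gp <- gaps[gap_idx[gk], ]
      n_ex <- .lnc_exon_count(1L, config$lnc_exon_mass_1to3)
      target <- min(config$lnc_length_mean,
                    round(stats::rlnorm(1, log(0.85 * config$lnc_length_mean),
                                        0.45)))
      target <- max(220, target)
      ex <- .lnc_structure(gp$start, gp$end, n_ex, target)
      strand <- if (label == "unknown") "*" else sample(c("+", "-"), 1L)
      add(ex, strand, label)
    }
  }
  list(transcripts = transcript_set(do.call(rbind, rows)),
       labels = labels,
       free_gaps = gaps[-gap_idx, , drop = FALSE])
}

#' Plant chromatin-signature truth for lncRNA genes
#'
#' Assigns each known-strand lncRNA gene a signature pattern (cycling over
#' all-three, none, and the mixed patterns) and an expression level planting
#' all four validation groups plus mid-range `none` cases.  Unknown-strand
#' genes get no marks (H3K4me3 is not assessable for them).
#'
#' @param config A [sim_config()].
#' @param lnc lncRNA [transcript_set()] from [generate_lncrnas()].
#' @return Data frame per gene: `gene_id`, `strand`, `k4`, `k36`, `polII`,
#'   `rpkm`, `group` (expected validation group, `NA` for unexpressed or
#'   unknown-strand genes).
#' @export
generate_chromatin_truth <- function(config, lnc) {
  .sim_seed(config, "chromatin_truth")
  gt <- gene_table(lnc)
  patterns <- list(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE),
                   c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE),
                   c(TRUE, TRUE, FALSE))
  levels <- c(15, 2, 6)  # high (> q3), low (< q1), mid
  out <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    if (g$strand == "*") {
      return(data.frame(gene_id = g$gene_id, strand = g$strand, k4 = NA,
                        k36 = FALSE, polII = FALSE, rpkm = 0.5,
                        group = NA_character_, stringsAsFactors = FALSE))
    }
    p <- patterns[[(i - 1L) %% length(patterns) + 1L]]
    rpkm <- levels[(i - 1L) %/% length(patterns) %% length(levels) + 1L]
    rpkm <- rpkm * stats::runif(1, 0.95, 1.05)
    th <- lnc_thresholds()
    group <- if (all(p) && rpkm > th$rpkm_q3) "G1"
      else if (all(p) && rpkm < th$rpkm_q1) "G2"
      else if (!any(p) && rpkm > th$rpkm_q3) "G3"
      else if (!any(p) && rpkm < th$rpkm_q1) "G4"
      else "none"
    data.frame(gene_id = g$gene_id, strand = g$strand, k4 = p[1L],
               k36 = p[2L], polII = p[3L], rpkm = rpkm, group = group,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate peak tracks realizing planted chromatin truth
#'
#' Genes flagged for H3K4me3 get a peak inside their promoter window; genes
#' flagged for H3K36me3 or Pol II get peaks tiling about 70 % and 60 % of
#' their span respectively; unflagged genes get no overlapping peaks.  Decoy
#' peaks of every mark are placed in lncRNA-free gaps, at least 600 bp from
#' any lncRNA span or promoter.  CAGE peaks are placed at the 5' ends of the
#' planted 5'-complete transcripts.
#'
#' @param config A [sim_config()].
#' @param lnc lncRNA [transcript_set()].
#' @param truth Result of [generate_chromatin_truth()].
#' @param free_gaps Gap rows not hosting lncRNAs (see [generate_lncrnas()]).
#' @return List with `peaks` (data frame with `mark`, `dataset`) and `cage`
#'   (named logical planted 5'-completeness per transcript, `NA` for
#'   unknown-strand transcripts).
#' @export
generate_peaks <- function(config, lnc, truth, free_gaps) {
  .sim_seed(config, "peaks")
  gt <- gene_table(lnc)
  th <- lnc_thresholds()
  rows <- list()
  add_peak <- function(start, end, mark) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = config$chrom, start = max(0, start), end = end, strand = "*",
      mark = mark, dataset = "sim", stringsAsFactors = FALSE)
  }
  tile <- function(g, frac, mark) {
    # alternate covered/uncovered segments achieving ~frac coverage
    width <- g$end - g$start
    n_seg <- max(2L, round(width / 400))
    bounds <- round(seq(g$start, g$end, length.out = n_seg + 1L))
    cover <- round(frac * n_seg)
    idx <- seq_len(cover)
    for (j in idx) add_peak(bounds[j], bounds[j + 1L], mark)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    g <- gt[gt$gene_id == tr$gene_id, ]
    if (isTRUE(tr$k4)) {
      tss <- .gene_tss(g)
      pw <- promoter_window(tss, g$strand, th)
      mid <- (pw[1L] + pw[2L]) / 2
      add_peak(round(mid - 80), round(mid + 80), "H3K4me3")
    }
    if (isTRUE(tr$k36)) tile(g, 0.7, "H3K36me3")
    if (isTRUE(tr$polII)) tile(g, 0.6, "PolII")
  }
  # decoys: far from every lncRNA span/promoter, inside free gaps
  decoy_gaps <- free_gaps[free_gaps$end - free_gaps$start >= 2400, ,
                          drop = FALSE]
  marks <- c("H3K4me3", "H3K36me3", "PolII", "CAGE")
  for (j in seq_len(min(6L, nrow(decoy_gaps)))) {
    gp <- decoy_gaps[j, ]
    pos <- round((gp$start + gp$end) / 2)
    for (m in seq_along(marks)) {
      add_peak(pos + 160 * (m - 1L), pos + 160 * (m - 1L) + 120, marks[m])
    }
  }
  # CAGE plants at transcript 5' ends
  tx <- lnc$tx
  cage <- rep(NA, nrow(tx))
  names(cage) <- tx$transcript_id
  known <- which(tx$strand != "*")
  planted <- sample(known,
                    round(config$cage_complete_fraction * length(known)))
  cage[known] <- FALSE
  cage[planted] <- TRUE
  for (i in planted) {
    five <- if (tx$strand[i] == "+") tx$start[i] else tx$end[i] - 1
    add_peak(five - 20, five + 10, "CAGE")
  }
  list(peaks = do.call(rbind, rows), cage = cage)
}

#' Generate expression count tables with planted truth
#'
#' Developmental-stage libraries draw negative-binomial counts whose RPKM
#' means differ by the configured mRNA:lncRNA fold change.  The two brain
#' libraries (poly(A)-enriched and ribo-zero) realize planted
#' brain-expressed and poly(A)-minus flags exactly: poly(A)-minus
#' transcripts get zero poly(A) counts and ribo-zero counts yielding
#' RPKM > 1; other expressed transcripts exceed RPKM 1 in both libraries;
#' unexpressed transcripts stay at or below RPKM 1 everywhere.  For lncRNA
#' genes with planted validation groups the poly(A) brain RPKM is pinned to
#' the planted expression level.
#'
#' @param config A [sim_config()].
#' @param coding,lnc [transcript_set()] objects.
#' @param chromatin_truth Optional result of [generate_chromatin_truth()]
#'   whose `rpkm` column pins brain expression of those genes.
#' @return List with `counts` (long data frame `transcript_id`, `library`,
#'   `read_count`), `total_mapped` (named vector), `biotype`,
#'   `expressed_brain` and `polya_minus` (named planted flags over lncRNA
#'   transcripts), and `stage_mean_rpkm` (planted per-biotype means).
#' @export
generate_expression <- function(config, coding, lnc,
                                chromatin_truth = NULL) {
  .sim_seed(config, "expression")
  tx <- rbind(cbind(coding$tx, biotype = "mRNA"),
              cbind(lnc$tx, biotype = "lncRNA"))
  mu_lnc <- 4
  mu_mrna <- mu_lnc * config$mrna_to_lnc_expression_ratio
  size <- 1 / config$nb_dispersion
  stage_total <- 1e7
  libs <- sprintf("stage_%02d", seq_len(config$n_stages))
  counts <- list()
  for (lib in libs) {
    mu <- ifelse(tx$biotype == "mRNA", mu_mrna, mu_lnc) *
      tx$length * stage_total / 1e9
    counts[[lib]] <- data.frame(transcript_id = tx$transcript_id,
                                library = lib,
                                read_count = stats::rnbinom(nrow(tx),
                                                            mu = mu,
                                                            size = size),
                                stringsAsFactors = FALSE)
  }

  # brain libraries with planted flags
  polya_total <- 2.5e7; ribo_total <- 5e7
  is_lnc <- tx$biotype == "lncRNA"
  lnc_ids <- tx$transcript_id[is_lnc]
  expressed <- stats::setNames(
    stats::runif(length(lnc_ids)) < config$brain_expressed_fraction, lnc_ids)
  pinned <- character()
  if (!is.null(chromatin_truth)) {
    pin <- chromatin_truth[!is.na(chromatin_truth$group) &
                             chromatin_truth$group != "none", ]
    gene_of <- stats::setNames(tx$gene_id[is_lnc], lnc_ids)
    pinned <- lnc_ids[gene_of %in% pin$gene_id]
    expressed[pinned] <- TRUE
  }
  polya_minus <- stats::setNames(rep(FALSE, length(lnc_ids)), lnc_ids)
  free <- setdiff(lnc_ids[expressed], pinned)
  n_pm <- round(config$polya_minus_fraction * length(free))
  polya_minus[sample(free, n_pm)] <- TRUE

  count_for_rpkm <- function(rpkm, len, total) ceiling(rpkm * total * len / 1e9)
  pA <- rz <- numeric(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]; len <- tx$length[i]
    if (!is_lnc[i]) {
      pA[i] <- count_for_rpkm(stats::runif(1, 2, 40), len, polya_total)
      rz[i] <- count_for_rpkm(stats::runif(1, 2, 40), len, ribo_total)
    } else if (polya_minus[id]) {
      pA[i] <- 0
      rz[i] <- count_for_rpkm(stats::runif(1, 2, 8), len, ribo_total)
    } else if (expressed[id]) {
      target <- if (id %in% pinned) {
        gene_of <- tx$gene_id[i]
        chromatin_truth$rpkm[chromatin_truth$gene_id == gene_of]
      } else stats::runif(1, 1.5, 8)
      pA[i] <- count_for_rpkm(target, len, polya_total)
      rz[i] <- count_for_rpkm(stats::runif(1, 1.5, 8), len, ribo_total)
    } else {
      pA[i] <- floor(stats::runif(1, 0, 0.8) * polya_total * len / 1e9)
      rz[i] <- floor(stats::runif(1, 0, 0.8) * ribo_total * len / 1e9)
    }
  }
  counts[["polyA"]] <- data.frame(transcript_id = tx$transcript_id,
                                  library = "polyA", read_count = pA,
                                  stringsAsFactors = FALSE)
  counts[["ribozero"]] <- data.frame(transcript_id = tx$transcript_id,
                                     library = "ribozero", read_count = rz,
                                     stringsAsFactors = FALSE)
  total_mapped <- c(stats::setNames(rep(stage_total, length(libs)), libs),
                    polyA = polya_total, ribozero = ribo_total)
  list(counts = do.call(rbind, counts),
       total_mapped = total_mapped,
       biotype = stats::setNames(tx$biotype, tx$transcript_id),
       expressed_brain = expressed,
       polya_minus = polya_minus,
       stage_mean_rpkm = c(lncRNA = mu_lnc, mRNA = mu_mrna))
}

#' Generate FASTQ reads with engineered trimming fates
#'
#' Emits boundary-case reads whose post-trim fate is known by construction
#' (kept at exactly the minimum length, discarded one base short, a mixed
#' 3' tail trimmed up to the first high-quality base, and a fully low-quality
#' tail), plus random reads with random-length low-quality tails.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (data frame `read_id`, `seq`, `qual`) and
#'   `fates` (named logical over the engineered reads: kept or discarded).
#' @export
generate_reads <- function(config) {
  .sim_seed(config, "reads")
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  q <- function(v) intToUtf8(v + 33L)
  reads <- list(); fates <- logical()
  eng <- function(id, len, quals, kept) {
    reads[[length(reads) + 1L]] <<- data.frame(
      read_id = id, seq = rand_seq(len), qual = q(quals),
      stringsAsFactors = FALSE)
    fates <<- c(fates, stats::setNames(kept, id))
  }
  eng("keep_at_36", 46, rep(30, 46), TRUE)
  eng("drop_at_35", 45, rep(30, 45), FALSE)
  eng("tail_scan_37", 48, c(rep(30, 45), 15, 25, 18), TRUE)
  eng("tail_all_low", 50, c(rep(30, 20), rep(12, 30)), FALSE)
  eng("exact_tail_keep", 47, c(rep(30, 46), 10), TRUE)
  for (i in seq_len(config$n_reads_fastq)) {
    len <- sample(40:80, 1L)
    tail_low <- sample(0:12, 1L)
    quals <- c(round(stats::runif(len - tail_low, 25, 40)),
               if (tail_low) round(stats::runif(tail_low, 2, 20)))
    reads[[length(reads) + 1L]] <- data.frame(
      read_id = sprintf("rand_%04d", i), seq = rand_seq(len),
      qual = q(quals), stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), fates = fates)
}

#' Generate alignment fixtures realizing every redundancy-rule branch
#'
#' Deterministic mini transcript sets plus alignment records covering:
#' same-locus removal, the 50 % overlap rule, the multi-exon exon-count
#' exception, the 90 % rule boundary (0.7 kept, 0.95 removed), the
#' FlyBase-id duplicate, the E-value gate, and the rRNA thresholds
#' ((1e-12, 99.5) removed; (1e-12, 98) and (1e-8, 100) kept).
#'
#' @param config A [sim_config()].
#' @return List of transcript sets, alignment tables, a FlyBase-id map, and
#'   `truth` (planted kept ids per rule).
#' @export
generate_alignment_fixtures <- function(config) {
  chrom <- "chr3R"
  mk <- function(id, source, starts, ends, strand = "+") {
    data.frame(transcript_id = id, gene_id = id, source = source,
               chrom = chrom, start = starts, end = ends, strand = strand,
               stringsAsFactors = FALSE)
  }
  primary <- transcript_set(rbind(
    mk("P1", "flybase", c(1000, 3000), c(1600, 3400)),     # 2 exons, 1000 bp
    mk("P2", "flybase", 10000, 11000)))                    # 1 exon, 1000 bp
  young_primary <- transcript_set(mk("Y1", "young", 50000, 51000))

  ucsc_cand <- transcript_set(rbind(
    mk("U_same", "ucsc", c(1000, 3000), c(1600, 3400)),
    mk("U_60", "ucsc", 20000, 20600),
    mk("U_40", "ucsc", 21000, 21500),
    mk("U_bigE", "ucsc", 22000, 22500)))
  brown_cand <- transcript_set(rbind(
    mk("B_1ex", "brown", 30000, 31000),
    mk("B_3ex", "brown", c(32000, 32500, 33000), c(32300, 32800, 33400)),
    mk("B_2ex", "brown", c(34000, 34700), c(34500, 35200)),
    mk("B_fbdup", "brown", 36000, 36800)))
  young_cand <- transcript_set(rbind(
    mk("YB_07", "brown", 40000, 41000),
    mk("YB_095", "brown", 42000, 43000),
    mk("YB_same", "brown", 50000, 51000)))
  rrna_tx <- transcript_set(rbind(
    mk("R_hit", "novel", 60000, 60800),
    mk("R_id98", "novel", 61000, 61800),
    mk("R_e8", "novel", 62000, 62800)))

  lengths <- c(P1 = 1000, P2 = 1000, Y1 = 1000,
               U_same = 1000, U_60 = 600, U_40 = 500, U_bigE = 500,
               B_1ex = 1000, B_3ex = 1000, B_2ex = 1000, B_fbdup = 800,
               YB_07 = 1000, YB_095 = 1000, YB_same = 1000,
               R_hit = 800, R_id98 = 800, R_e8 = 800,
               rRNA_28S = 4000)
  al <- function(q, s, alen, e = 1e-12, id = 95) {
    alignment_records(q, s, identity_pct = id, align_length = alen,
                      e_value = e, bit_score = 200,
                      query_length = lengths[q], subject_length = lengths[s])
  }
  ucsc_aln <- rbind(al("U_same", "P1", 1000),
                    al("U_60", "P2", 360),    # 0.6 of candidate
                    al("U_40", "P2", 200),    # 0.4: kept
                    al("U_bigE", "P2", 450, e = 1e-5))  # fails E gate
  brown_aln <- rbind(al("B_1ex", "P2", 600),  # single exon, 0.6: removed
                     al("B_3ex", "P1", 600),  # exon counts differ: kept
                     al("B_2ex", "P1", 600))  # same exon count: removed
  young_aln <- rbind(al("YB_07", "Y1", 700),
                     al("YB_095", "Y1", 950),
                     al("YB_same", "Y1", 1000))
  rrna_aln <- rbind(al("R_hit", "rRNA_28S", 700, e = 1e-12, id = 99.5),
                    al("R_id98", "rRNA_28S", 700, e = 1e-12, id = 98),
                    al("R_e8", "rRNA_28S", 700, e = 1e-8, id = 100))
  list(primary = primary, young_primary = young_primary,
       ucsc_candidates = ucsc_cand, brown_candidates = brown_cand,
       young_candidates = young_cand, rrna_transcripts = rrna_tx,
       ucsc_alignments = ucsc_aln, brown_alignments = brown_aln,
       young_alignments = young_aln, rrna_alignments = rrna_aln,
       lengths = lengths,
       flybase_ids = c(B_fbdup = "P1"),
       truth = list(ucsc_kept = c("U_40", "U_bigE"),
                    brown_kept = c("B_3ex"),
                    young_kept = c("YB_07"),
                    rrna_kept = c("R_id98", "R_e8")))
}

#' Generate a discovery-funnel fixture with planted fates
#'
#' Builds assembled transcript sets for two libraries whose union realizes
#' every funnel branch: true novel lncRNAs (surviving all stages, some
#' assembled identically in both libraries to exercise the union collapse),
#' reference-overlapping transcripts, sub-length transcripts, coding-
#' potential failures (including one exactly at the cutoff), rRNA hits,
#' transcripts without read support, and transcripts overlapping a newly
#' annotated coding gene in the sense direction.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [generate_annotation()].
#' @param n_true Number of surviving novel lncRNAs to plant.
#' @return List with `assembled` (list of two transcript sets), `reference`,
#'   `updated_annotation`, `scores`, `rrna_alignments`, `remap_counts`, and
#'   `truth` (`survivors`, plus per-stage planted removals).
#' @export
generate_discovery_fixture <- function(config, annotation, n_true = 20) {
  .sim_seed(config, "discovery")
  reference <- annotation$transcripts
  chrom <- config$chrom
  tail_start <- max(reference$tx$end) + 5000
  cursor <- tail_start
  place <- function(len) {
    s <- cursor
    cursor <<- cursor + len + 600
    c(s, s + len)
  }
  mk1 <- function(id, len, strand = "+") {
    p <- place(len)
    data.frame(transcript_id = id, gene_id = id, source = "novel",
               chrom = chrom, start = p[1L], end = p[2L], strand = strand,
               stringsAsFactors = FALSE)
  }
  rows1 <- list(); rows2 <- list()
  survivors <- sprintf("nov_%02d", seq_len(n_true))
  for (i in seq_len(n_true)) {
    r <- mk1(survivors[i], round(stats::runif(1, 300, 1500)),
             sample(c("+", "-"), 1L))
    rows1[[length(rows1) + 1L]] <- r
    if (i <= n_true / 2) {  # assembled identically in library 2
      r2 <- r; r2$transcript_id <- paste0(r$transcript_id, "_lib2")
      r2$gene_id <- r2$transcript_id
      rows2[[length(rows2) + 1L]] <- r2
    }
  }
  short_ids <- sprintf("short_%d", 1:5)
  for (id in short_ids) rows1[[length(rows1) + 1L]] <-
    mk1(id, round(stats::runif(1, 120, 180)))
  coding_ids <- sprintf("codpot_%d", 1:5)
  for (id in coding_ids) rows1[[length(rows1) + 1L]] <-
    mk1(id, round(stats::runif(1, 400, 1200)))
  rrna_ids <- sprintf("rrna_%d", 1:2)
  for (id in rrna_ids) rows2[[length(rows2) + 1L]] <-
    mk1(id, round(stats::runif(1, 400, 1200)))
  nosupport_ids <- sprintf("nosup_%d", 1:3)
  for (id in nosupport_ids) rows2[[length(rows2) + 1L]] <-
    mk1(id, round(stats::runif(1, 400, 1200)))
  # new coding gene, present only in the updated annotation
  ng <- mk1("t_newgene", 2000, "+")
  ng$gene_id <- "newgene"; ng$source <- "ucsc"
  sense_ids <- sprintf("sense_%d", 1:3)
  sense_rows <- lapply(seq_along(sense_ids), function(j) {
    data.frame(transcript_id = sense_ids[j], gene_id = sense_ids[j],
               source = "novel", chrom = chrom,
               start = ng$start + 100 * j, end = ng$start + 100 * j + 500,
               strand = "+", stringsAsFactors = FALSE)
  })
  rows1 <- c(rows1, sense_rows)
  # reference-overlapping assembled transcripts (dropped at stage 1)
  ref_tx <- reference$tx[1:4, ]
  refover_ids <- sprintf("refover_%d", 1:4)
  for (j in 1:4) {
    rows2[[length(rows2) + 1L]] <- data.frame(
      transcript_id = refover_ids[j], gene_id = refover_ids[j],
      source = "novel", chrom = ref_tx$chrom[j],
      start = ref_tx$start[j] + 10, end = ref_tx$start[j] + 400,
      strand = "+", stringsAsFactors = FALSE)
  }
  lib1 <- transcript_set(do.call(rbind, rows1))
  lib2 <- transcript_set(do.call(rbind, rows2))

  all_ids <- c(lib1$tx$transcript_id, lib2$tx$transcript_id)
  scores <- data.frame(transcript_id = all_ids,
                       method = "cpat_probability",
                       value = "0.05", stringsAsFactors = FALSE)
  scores$value[scores$transcript_id %in% coding_ids] <-
    as.character(c(0.39, 0.5, 0.7, 0.95, 0.39))
  some_cpc <- match(survivors[1:5], scores$transcript_id)
  scores$method[some_cpc] <- "cpc_label"
  scores$value[some_cpc] <- "noncoding"

  lens <- stats::setNames(lib1$tx$length, lib1$tx$transcript_id)
  lens <- c(lens, stats::setNames(lib2$tx$length, lib2$tx$transcript_id),
            rRNA_18S = 2000)
  rrna_aln <- alignment_records(
    query_id = rrna_ids, subject_id = "rRNA_18S", identity_pct = 99.8,
    align_length = 500, e_value = 1e-15, bit_score = 300,
    query_length = lens[rrna_ids], subject_length = 2000)

  supported <- setdiff(all_ids, nosupport_ids)
  remap_counts <- stats::setNames(
    pmax(1, stats::rpois(length(supported), 40)), supported)
  remap_counts <- c(remap_counts,
                    stats::setNames(rep(0, length(nosupport_ids)),
                                    nosupport_ids))
  updated <- transcript_set(rbind(reference$exons, ng))
  list(assembled = list(lib1, lib2), reference = reference,
       updated_annotation = updated, scores = scores,
       rrna_alignments = rrna_aln, remap_counts = remap_counts,
       truth = list(survivors = survivors, short = short_ids,
                    coding = coding_ids, rrna = rrna_ids,
                    nosupport = nosupport_ids, sense = sense_ids,
                    refover = refover_ids))
}

#' Generate RT-qPCR replicate data for the four validation groups
#'
#' Plants 42 assays (11 + 11 + 10 + 10 across G1-G4) with four technical
#' replicates each; one assay in G2 and one in G4 are planted below the
#' whole-body detection cutoff, all others above it, so the planted
#' detection rate is 40/42.
#'
#' @param config A [sim_config()].
#' @param reference_ct Reference-assay Ct (the normalizer is an explicit
#'   input, not guessed).
#' @return Data frame: `target_id`, `group`, `ct1`..`ct4`, `reference_ct`,
#'   `planted_detected`.
#' @export
generate_qpcr <- function(config, reference_ct = 20) {
  .sim_seed(config, "qpcr")
  groups <- rep(c("G1", "G2", "G3", "G4"), times = c(11, 11, 10, 10))
  n <- length(groups)
  detected <- rep(TRUE, n)
  detected[which(groups == "G2")[1L]] <- FALSE
  detected[which(groups == "G4")[1L]] <- FALSE
  rows <- lapply(seq_len(n), function(i) {
    mdc <- if (detected[i]) stats::runif(1, 2.5, 12) else
      stats::runif(1, -4, 1)
    ct_mean <- reference_ct - mdc
    cts <- round(ct_mean + stats::runif(4, -0.2, 0.2), 2)
    cts <- cts - (mean(cts) - ct_mean)  # center replicates on the target Ct
    data.frame(target_id = sprintf("%s_lnc%02d", groups[i], i),
               group = groups[i], ct1 = cts[1L], ct2 = cts[2L],
               ct3 = cts[3L], ct4 = cts[4L], reference_ct = reference_ct,
               planted_detected = detected[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a full fixture directory
#'
#' Materializes every synthetic fixture as plain-text files (GTF, BED, TSV,
#' FASTQ, JSON ground truth) under `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the in-memory fixture bundle (see
#'   [generate_fixtures()]).
#' @export
write_fixtures <- function(config, outdir) {
  fx <- generate_fixtures(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_gtf(fx$annotation$transcripts, p("coding.gtf"))
  write_gtf(fx$lnc$transcripts, p("lncrna.gtf"))
  write_bed(fx$peaks$peaks, p("peaks.bed"))
  write_counts_table(fx$expression$counts, fx$expression$total_mapped,
                     p("counts.tsv"))
  write_fastq(fx$reads$reads, p("reads.fastq"))
  utils::write.table(
    data.frame(id = names(fx$alignments$lengths),
               length = as.numeric(fx$alignments$lengths)),
    p("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  truth <- list(lnc_labels = as.list(fx$lnc$labels),
                cage = as.list(fx$peaks$cage),
                polya_minus = as.list(fx$expression$polya_minus),
                expressed_brain = as.list(fx$expression$expressed_brain),
                read_fates = as.list(fx$reads$fates),
                chromatin = fx$chromatin_truth,
                discovery_survivors = fx$discovery$truth$survivors)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(fx)
}

#' Generate the full in-memory fixture bundle
#'
#' Runs every generator off one master seed and returns all fixtures plus
#' their planted truth.
#'
#' @param config A [sim_config()].
#' @return Named list: `annotation`, `lnc`, `chromatin_truth`, `peaks`,
#'   `expression`, `reads`, `alignments`, `discovery`, `qpcr`.
#' @export
generate_fixtures <- function(config = sim_config()) {
  annotation <- generate_annotation(config)
  lnc <- generate_lncrnas(config, annotation)
  chromatin_truth <- generate_chromatin_truth(config, lnc$transcripts)
  peaks <- generate_peaks(config, lnc$transcripts, chromatin_truth,
                          lnc$free_gaps)
  expression <- generate_expression(config, annotation$transcripts,
                                    lnc$transcripts, chromatin_truth)
  reads <- generate_reads(config)
  alignments <- generate_alignment_fixtures(config)
  discovery <- generate_discovery_fixture(config, annotation)
  qpcr <- generate_qpcr(config)
  list(annotation = annotation, lnc = lnc,
       chromatin_truth = chromatin_truth, peaks = peaks,
       expression = expression, reads = reads, alignments = alignments,
       discovery = discovery, qpcr = qpcr)
}
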