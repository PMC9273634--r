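# --- synthetic mini-genome, transcript models and annotation resources ----
#
# The generator emulates the statistical structure of a case-parent trio
# WGS study at desk scale: a ~23-contig mini-genome (<= 100 kb each) with
# >= 20 protein-coding transcript models on both strands, population
# frequency panels, a pathogenicity score table, craniofacial gene-evidence
# records, gene sets (incl. palate development and neural crest migration)
# and a tissue x stage expression matrix.

.contig_len <- 100000L

# candidate genes mirrored from the craniofacial-evidence literature; the
# 40+ exon transcript emulates a deep-exon titin-like model
.candidate_genes <- c("ACTL6A", "ARHGAP10", "MINK1", "TMEM5", "TTN",
                      "ACAN", "DHRS3", "DLX6", "EPHB2", "FKBP10", "KMT2D",
                      "RECQL4", "SEMA3C", "SEMA4D", "SHH", "TP63", "TULP4")
.extra_genes <- c("MMP9", "JUNB", "JUP", "DNAJC3", "PAX9", "MSX1", "IRF6")

.stop_codons <- c("TAA", "TAG", "TGA")
.all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                 c("A","C","G","T")), 1, paste, collapse = "")
.sense_codons <- setdiff(.all_codons, .stop_codons)

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

.revcomp_chr <- function(x) as.character(reverseComplement(DNAString(x)))

# CDS = ATG + random non-stop codons + stop, with optional pinned codons
.random_cds <- function(n_codons, pinned = list()) {
  codons <- c("ATG", sample(.sense_codons, n_codons - 2L, replace = TRUE),
              sample(.stop_codons, 1L))
  for (idx in names(pinned)) codons[as.integer(idx)] <- pinned[[idx]]
  paste(codons, collapse = "")
}

# split a CDS into n_exons pieces and join with canonical GT..AG introns;
# returns genomic segment + exon coordinates relative to segment start (1-based)
.build_tx_segment <- function(cds, n_exons, strand, intron_min = 80L,
                              intron_max = 300L) {
  L <- nchar(cds)
  stopifnot(L %% 3L == 0L, n_exons >= 1L, L >= 3L * n_exons)
  if (n_exons == 1L) {
    pieces <- L
  } else {
    cuts <- sort(sample(seq_len(L - 1L), n_exons - 1L))
    pieces <- diff(c(0L, cuts, L))
  }
  introns <- if (n_exons > 1L)
    vapply(seq_len(n_exons - 1L), function(i) {
      mid <- .rand_dna(sample(intron_min:intron_max, 1L) - 4L)
      paste0("GT", mid, "AG")
    }, character(1))
  else character(0)
  # transcript-sense layout
  exon_t <- matrix(0L, nrow = n_exons, ncol = 2L)
  off <- 0L; cds_cursor <- 0L
  full <- character(0)
  for (i in seq_len(n_exons)) {
    ex_seq <- substr(cds, cds_cursor + 1L, cds_cursor + pieces[i])
    cds_cursor <- cds_cursor + pieces[i]
    exon_t[i, ] <- c(off + 1L, off + pieces[i])
    full <- c(full, ex_seq)
    off <- off + pieces[i]
    if (i < n_exons) {
      full <- c(full, introns[i])
      off <- off + nchar(introns[i])
    }
  }
  segment <- paste(full, collapse = "")
  Lseg <- nchar(segment)
  if (strand == "+") {
    starts <- exon_t[, 1L]; ends <- exon_t[, 2L]
  } else {
    segment <- .revcomp_chr(segment)
    starts <- Lseg - exon_t[, 2L] + 1L
    ends <- Lseg - exon_t[, 1L] + 1L
    o <- order(starts); starts <- starts[o]; ends <- ends[o]
  }
  list(segment = segment, exon_starts = starts, exon_ends = ends)
}

#' Generate the synthetic annotation resource bundle
#'
#' Builds a deterministic desk-scale stand-in for the external resources a
#' trio DNM pipeline consumes: a mini-genome (chr1-chr22 + chrX, 100 kb
#' contigs), >= 20 all-coding transcript models on both strands (one with
#' >= 40 exons and > 4738 codons to exercise deep-exon truncating variants),
#' three population frequency panels (populated by the cohort generator),
#' a score table, craniofacial evidence records, gene sets including palate
#' development and neural crest migration, and a tissue expression matrix
#' with maxillary/mandibular E10.5 columns.
#'
#' @param seed integer seed; two calls with the same seed give identical
#'   bundles
#' @return list of class `dnm_resources`
#' @export
generate_resources <- function(seed = 1L) {
  set.seed(.seed_stream(seed, 101L))
  genes <- c(.candidate_genes, .extra_genes)
  chroms <- paste0("chr", 1:22)

  # per-gene design: chromosome round-robin, alternating strand
  n_codons <- setNames(sample(120:420, length(genes), replace = TRUE), genes)
  n_codons["TTN"] <- 4800L      # deep-exon model: codon 4738 must exist
  n_codons["SHH"] <- 450L       # codon 362 must exist
  n_exons <- setNames(sample(2:8, length(genes), replace = TRUE), genes)
  n_exons["TTN"] <- 45L
  strands <- setNames(rep(c("+", "-"), length.out = length(genes)), genes)
  gene_chrom <- setNames(rep(chroms, length.out = length(genes)), genes)

  pinned <- list(
    TTN = list(`4738` = "CGA"),   # Arg codon one transition away from TGA
    DHRS3 = list(`37` = "TCG"),   # Ser codon; C>T gives Leu
    SHH = list(`362` = "TCG"))    # Ser codon at the hedgehog-domain position

  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  contig <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) contig[[ch]] <- character(0)

  tx_rows <- list(); peptides <- character(0)
  for (g in genes) {
    ch <- gene_chrom[g]
    cds <- .random_cds(n_codons[g], pinned[[g]] %||% list())
    seg <- .build_tx_segment(cds, n_exons[g], strands[g])
    pad <- sample(1500:3000, 1L)
    offset <- cursor[ch] + pad
    contig[[ch]] <- c(contig[[ch]], .rand_dna(pad), seg$segment)
    tx_rows[[g]] <- data.table(
      gene = g, tx_id = paste0("TX_", g), chrom = ch, strand = strands[g],
      # cursor/offset point at the last base before the segment, so a
      # segment-relative coordinate r maps to genomic position r + offset
      exon_starts = paste(seg$exon_starts + offset, collapse = ","),
      exon_ends = paste(seg$exon_ends + offset, collapse = ","),
      cds_start = min(seg$exon_starts) + offset,
      cds_end = max(seg$exon_ends) + offset,
      n_codons = n_codons[g])
    cursor[ch] <- offset + nchar(seg$segment)
    peptides[paste0("TX_", g)] <- translate_cds(cds)
  }
  # pad contigs to fixed length; transcripts all live below 60 kb so that
  # background variant sites (sampled from 60-100 kb) never collide with CDS
  stopifnot(all(cursor < 60000L))
  seqs <- vapply(chroms, function(ch) {
    body <- paste(contig[[ch]], collapse = "")
    paste0(.rand_dna(1000L), body, .rand_dna(.contig_len - 1000L - nchar(body)))
  }, character(1))
  seqs["chrX"] <- .rand_dna(.contig_len)
  genome <- DNAStringSet(seqs)

  transcripts <- rbindlist(tx_rows)

  evidence <- data.table(
    gene = genes,
    mouse_ko = "none", cnv_report = FALSE, snv_report = FALSE)
  evidence[gene %in% c("ACAN", "DHRS3", "KMT2D", "RECQL4", "SHH", "TP63"),
           mouse_ko := "cleft"]
  evidence[gene == "ACTL6A", mouse_ko := "lethal"]
  evidence[gene %in% c("ARHGAP10", "MINK1", "TMEM5", "TTN", "DLX6", "EPHB2",
                       "SEMA3C", "SEMA4D"), mouse_ko := "craniofacial"]
  evidence[gene %in% .candidate_genes, cnv_report := TRUE]
  evidence[gene %in% c("SHH", "TP63", "TULP4", "FKBP10"), snv_report := TRUE]
  # extra genes carry no craniofacial evidence
  evidence[gene %in% .extra_genes,
           `:=`(mouse_ko = "none", cnv_report = FALSE, snv_report = FALSE)]

  # the annotated universe is mostly genes outside the mini-genome, so that
  # a DNM query (bounded by the 24 transcript genes) can be enriched against
  # a realistic background; padding never reuses transcript genes, keeping
  # the craniofacial terms' overlaps equal to their named members
  pad_pool <- sprintf("GENE%03d", 1:400)
  gene_sets <- list(
    "GO:palate_development" = c("DHRS3", "DLX6", "EPHB2", "SHH", "PAX9",
                                "MSX1", "IRF6", sample(pad_pool, 5L)),
    "GO:neural_crest_migration" = c("SEMA3C", "SEMA4D", "SHH",
                                    sample(pad_pool, 3L)))
  for (k in 1:8) {
    gene_sets[[sprintf("GO:background_process_%02d", k)]] <-
      sample(pad_pool, sample(50:70, 1L))
  }
  gene_sets <- lapply(gene_sets, function(s) sort(unique(toupper(s))))
  attr(gene_sets, "descriptions") <-
    setNames(gsub("GO:", "", names(gene_sets)), names(gene_sets))

  tissues <- c("maxillary_E10.5", "mandibular_E10.5", "frontonasal_E10.5",
               "maxillary_arch_E10.5", "mandibular_arch_E10.5",
               "palate_E13.5", "palate_P0")
  expr_genes <- setdiff(genes, "TULP4")   # ortholog not detected in mouse
  expr <- matrix(round(runif(length(expr_genes) * length(tissues), 50, 400), 1),
                 nrow = length(expr_genes),
                 dimnames = list(expr_genes, tissues))
  cand <- intersect(expr_genes, .candidate_genes)
  # candidates: elevated maxillary vs mandibular signal, high palate signal
  expr[cand, "maxillary_E10.5"] <- round(expr[cand, "mandibular_E10.5"] *
                                           runif(length(cand), 1.5, 3), 1)
  expr[cand, "maxillary_arch_E10.5"] <-
    round(expr[cand, "mandibular_arch_E10.5"] * runif(length(cand), 1.3, 2.5), 1)
  expr[cand, "palate_E13.5"] <- round(runif(length(cand), 500, 900), 1)

  panels <- list(
    thousand_genomes = data.table(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  af = numeric(0)),
    evs = data.table(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0), af = numeric(0)),
    gnomad_afr = data.table(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            af = numeric(0)))

  structure(list(genome = genome, transcripts = transcripts,
                 peptides = peptides, panels = panels,
                 scores = data.table(chrom = character(0), pos = integer(0),
                                     ref = character(0), alt = character(0),
                                     cadd_phred = numeric(0), sift = numeric(0),
                                     polyphen = numeric(0)),
                 evidence = evidence, gene_sets = gene_sets,
                 expression = expr, seed = as.integer(seed)),
            class = "dnm_resources")
}
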