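#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   readDNAStringSet writeXStringSet subseq GENETIC_CODE
#' @importFrom methods as
NULL

# severity ranking used to pick one consequence per variant (lower = worse)
.severity <- c(stop_gained = 1, frameshift_variant = 2,
               splice_donor_variant = 3, splice_acceptor_variant = 3,
               start_lost = 4, missense_variant = 5, synonymous_variant = 6,
               intron_variant = 7, other = 8)

#' Map a consequence term to its impact class
#'
#' Protein-truncating terms (stop gained, start lost, canonical splice site,
#' frameshift) versus missense versus everything else.
#'
#' @param term a consequence term from [call_consequence()]
#' @return "protein_truncating", "missense" or "other"
#' @export
impact_class <- function(term) {
  truncating <- c("stop_gained", "start_lost", "splice_donor_variant",
                  "splice_acceptor_variant", "frameshift_variant")
  vapply(term, function(t) {
    if (!t %in% names(.severity)) stop("unknown consequence term: ", t)
    if (t %in% truncating) "protein_truncating"
    else if (t == "missense_variant") "missense"
    else "other"
  }, character(1), USE.NAMES = FALSE)
}

.tx_exons <- function(tx) {
  data.table(start = as.integer(strsplit(tx$exon_starts, ",")[[1]]),
             end = as.integer(strsplit(tx$exon_ends, ",")[[1]]))
}

# genomic positions of the CDS in transcript (5'->3') order
.cds_positions <- function(tx) {
  ex <- .tx_exons(tx)
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i]))
  pos <- pos[pos >= tx$cds_start & pos <= tx$cds_end]
  if (tx$strand == "-") rev(pos) else pos
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

# coding-strand base at genomic positions for a transcript
.coding_base <- function(genome, tx, gpos) {
  b <- vapply(gpos, function(p)
    as.character(subseq(genome[[tx$chrom]], p, p)), character(1))
  if (tx$strand == "-") unname(.comp[b]) else b
}

#' Extract the spliced coding sequence of a transcript
#'
#' @param tx one-row transcript record
#' @param genome `DNAStringSet` reference
#' @return coding-strand CDS as a character string
#' @export
transcript_cds <- function(tx, genome) {
  paste(.coding_base(genome, tx, .cds_positions(tx)), collapse = "")
}

#' Translate a coding sequence with the standard nuclear code
#'
#' @param cds character CDS (length divisible by 3)
#' @return one-letter peptide string (terminal `*` for a stop codon)
#' @export
translate_cds <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(GENETIC_CODE[codons], collapse = "")
}

.classify_in_tx <- function(chrom, pos, ref, alt, tx, genome) {
  ex <- .tx_exons(tx)
  span_lo <- min(ex$start); span_hi <- max(ex$end)
  if (chrom != tx$chrom || pos < span_lo - 8L || pos > span_hi + 8L)
    return(NULL)
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  res <- function(term, pchange = NA_character_)
    data.table(gene = tx$gene, tx_id = tx$tx_id, consequence = term,
               protein_change = pchange)

  if (!in_exon) {
    # canonical splice sites: first/last 2 intronic bases in transcript sense
    n_ex <- nrow(ex)
    donor <- acceptor <- integer(0)
    if (n_ex > 1L) for (i in seq_len(n_ex - 1L)) {
      up <- ex$end[i] + 1:2            # intron bases next to exon i
      dn <- ex$start[i + 1L] - 1:2     # intron bases next to exon i+1
      if (tx$strand == "+") { donor <- c(donor, up); acceptor <- c(acceptor, dn) }
      else                 { donor <- c(donor, dn); acceptor <- c(acceptor, up) }
    }
    # an indel that touches a splice site also disrupts it
    vspan <- pos:(pos + max(nchar(ref) - 1L, 0L))
    if (any(vspan %in% donor)) return(res("splice_donor_variant"))
    if (any(vspan %in% acceptor)) return(res("splice_acceptor_variant"))
    if (pos >= span_lo && pos <= span_hi) return(res("intron_variant"))
    return(res("other"))
  }

  cds_pos <- .cds_positions(tx)
  idx <- match(pos, cds_pos)
  if (is.na(idx)) return(res("other"))   # exonic but outside the CDS (UTR)

  if (!is_snv) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3L
    codon_no <- (idx - 1L) %/% 3L + 1L
    if (shift != 0L) {
      first <- .codon_aa(tx, genome, cds_pos, codon_no)
      return(res("frameshift_variant",
                 paste0("p.", .aa3[first], codon_no, "fs")))
    }
    return(res("other"))                 # in-frame indel: outside vocabulary
  }

  codon_no <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L + 1L
  cpos <- cds_pos[(3L * (codon_no - 1L) + 1L):(3L * codon_no)]
  ref_codon <- .coding_base(genome, tx, cpos)
  ref_base_coding <- if (tx$strand == "-") .comp[ref] else ref
  alt_base_coding <- if (tx$strand == "-") .comp[alt] else alt
  if (!identical(unname(ref_codon[within]), unname(ref_base_coding)))
    warning("reference allele disagrees with genome at ", chrom, ":", pos)
  alt_codon <- ref_codon
  alt_codon[within] <- alt_base_coding
  ref_aa <- GENETIC_CODE[paste(ref_codon, collapse = "")]
  alt_aa <- GENETIC_CODE[paste(alt_codon, collapse = "")]
  if (codon_no == 1L)
    return(res("start_lost", "p.Met1?"))
  if (ref_aa == alt_aa)
    return(res("synonymous_variant",
               paste0("p.", .aa3[ref_aa], codon_no, .aa3[alt_aa])))
  if (alt_aa == "*")
    return(res("stop_gained", paste0("p.", .aa3[ref_aa], codon_no, "Ter")))
  res("missense_variant", paste0("p.", .aa3[ref_aa], codon_no, .aa3[alt_aa]))
}

.codon_aa <- function(tx, genome, cds_pos, codon_no) {
  cpos <- cds_pos[(3L * (codon_no - 1L) + 1L):(3L * codon_no)]
  GENETIC_CODE[paste(.coding_base(genome, tx, cpos), collapse = "")]
}

#' Annotate a variant against transcript models
#'
#' Classifies the variant against every transcript it overlaps (within 8 bp)
#' and reports the single most severe consequence (severity order:
#' stop_gained > frameshift > canonical splice > start_lost > missense >
#' synonymous > intron > other; ties broken by lowest transcript id). A
#' variant outside all transcripts is classified `other`, never an error.
#'
#' @param chrom,pos,ref,alt the variant (VCF convention)
#' @param transcripts transcript-model `data.table` (see
#'   [read_transcripts()])
#' @param genome `DNAStringSet` reference
#' @return one-row `data.table`: gene, tx_id, consequence, protein_change
#' @export
call_consequence <- function(chrom, pos, ref, alt, transcripts, genome) {
  cand <- transcripts[transcripts$chrom == chrom, ]
  hits <- rbindlist(lapply(seq_len(nrow(cand)), function(i)
    .classify_in_tx(chrom, pos, ref, alt, cand[i, ], genome)))
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.table(gene = NA_character_, tx_id = NA_character_,
                      consequence = "other", protein_change = NA_character_))
  hits$rank <- .severity[hits$consequence]
  hits <- hits[order(hits$rank, hits$tx_id), ]
  hits[1L, c("gene", "tx_id", "consequence", "protein_change")]
}
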