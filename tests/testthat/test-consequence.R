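test_that("deep-exon stop gain is called with the correct protein change", {
  res <- shared_resources()
  tx <- res$transcripts[res$transcripts$gene == "TTN", ]
  cds_pos <- denovotrio:::.cds_positions(tx)
  pos <- cds_pos[3 * 4737 + 1]          # first base of codon 4738 (CGA)
  ann <- call_consequence(tx$chrom, pos, "C", "T", res$transcripts,
                          res$genome)
  expect_identical(ann$consequence, "stop_gained")
  expect_identical(ann$protein_change, "p.Arg4738Ter")
  expect_identical(ann$gene, "TTN")
  expect_identical(impact_class(ann$consequence), "protein_truncating")
})

test_that("missense calls report p.RefPosAlt at the pinned serine codons", {
  res <- shared_resources()
  for (g in c("DHRS3", "SHH")) {
    tx <- res$transcripts[res$transcripts$gene == g, ]
    codon <- if (g == "DHRS3") 37L else 362L
    cds_pos <- denovotrio:::.cds_positions(tx)
    pos <- cds_pos[3 * (codon - 1) + 2]   # TCG -> TTG
    ann <- call_consequence(tx$chrom, pos, "C", "T", res$transcripts,
                            res$genome)
    expect_identical(ann$consequence, "missense_variant")
    expect_identical(ann$protein_change, paste0("p.Ser", codon, "Leu"))
    expect_identical(impact_class(ann$consequence), "missense")
  }
})

test_that("canonical splice, start, synonymous, intron and intergenic
          positions classify correctly", {
  res <- shared_resources()
  tx <- res$transcripts[res$transcripts$gene == "DHRS3", ]  # plus strand
  ex <- denovotrio:::.tx_exons(tx)
  # donor +1 (the G of the GT dinucleotide)
  dpos <- ex$end[1] + 1L
  expect_identical(denovotrio:::.genome_base(res$genome, tx$chrom, dpos), "G")
  ann <- call_consequence(tx$chrom, dpos, "G", "A", res$transcripts, res$genome)
  expect_identical(ann$consequence, "splice_donor_variant")
  # acceptor -1 (the G of AG)
  apos <- ex$start[2] - 1L
  rb <- denovotrio:::.genome_base(res$genome, tx$chrom, apos)
  ann <- call_consequence(tx$chrom, apos, rb,
                          setdiff(c("A", "C", "G", "T"), rb)[1],
                          res$transcripts, res$genome)
  expect_identical(ann$consequence, "splice_acceptor_variant")
  # any SNV in the initiator codon
  cds_pos <- denovotrio:::.cds_positions(tx)
  rb <- denovotrio:::.genome_base(res$genome, tx$chrom, cds_pos[2])
  ann <- call_consequence(tx$chrom, cds_pos[2], rb,
                          setdiff(c("A", "C", "G", "T"), rb)[1],
                          res$transcripts, res$genome)
  expect_identical(ann$consequence, "start_lost")
  expect_identical(ann$protein_change, "p.Met1?")
  # deep intron
  ipos <- ex$end[1] + 20L
  rb <- denovotrio:::.genome_base(res$genome, tx$chrom, ipos)
  ann <- call_consequence(tx$chrom, ipos, rb,
                          setdiff(c("A", "C", "G", "T"), rb)[1],
                          res$transcripts, res$genome)
  expect_identical(ann$consequence, "intron_variant")
  # far outside every transcript: other, never an error
  ann <- call_consequence("chr1", 95000L, "A", "T", res$transcripts,
                          res$genome)
  expect_identical(ann$consequence, "other")
})

test_that("a third-position wobble change is synonymous", {
  res <- shared_resources()
  tx <- res$transcripts[res$transcripts$gene == "SHH", ]
  cds_pos <- denovotrio:::.cds_positions(tx)
  # codon 362 is TCG (Ser); TCG -> TCA is synonymous
  pos <- cds_pos[3 * 361 + 3]
  ann <- call_consequence(tx$chrom, pos, "G", "A", res$transcripts,
                          res$genome)
  expect_identical(ann$consequence, "synonymous_variant")
  expect_identical(impact_class(ann$consequence), "other")
})

test_that("frameshift indels are classified via length mod 3", {
  res <- shared_resources()
  v <- denovotrio:::.plant_frameshift(res)
  ann <- call_consequence(v$chrom, v$pos, v$ref, v$alt, res$transcripts,
                          res$genome)
  expect_identical(ann$consequence, "frameshift_variant")
  expect_match(ann$protein_change, "^p\\..*fs$")
  expect_identical(impact_class("frameshift_variant"), "protein_truncating")
})

test_that("impact classes follow the protein-truncating / missense split", {
  expect_identical(
    impact_class(c("stop_gained", "start_lost", "splice_donor_variant",
                   "splice_acceptor_variant", "frameshift_variant")),
    rep("protein_truncating", 5))
  expect_identical(impact_class("missense_variant"), "missense")
  expect_identical(impact_class(c("synonymous_variant", "intron_variant",
                                  "other")), rep("other", 3))
  expect_error(impact_class("nonsense_term"), "unknown consequence")
})

test_that("translating every fixture CDS reproduces the stored peptide", {
  res <- shared_resources()
  for (i in seq_len(nrow(res$transcripts))) {
    tx <- res$transcripts[i, ]
    pep <- translate_cds(transcript_cds(tx, res$genome))
    expect_identical(pep, unname(res$peptides[tx$tx_id]), info = tx$tx_id)
    expect_identical(substr(pep, 1, 1), "M", info = tx$tx_id)
  }
})

test_that("strand symmetry: mirrored transcript + reverse-complement variant
          give identical protein changes", {
  res <- shared_resources()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in c("DHRS3", "ARHGAP10")) {          # one per strand
    tx <- data.table::as.data.table(res$transcripts)[gene == g]
    L <- length(res$genome[[tx$chrom]])
    mirror_genome <- Biostrings::DNAStringSet(
      setNames(as.character(Biostrings::reverseComplement(
        res$genome[[tx$chrom]])), tx$chrom))
    ex <- denovotrio:::.tx_exons(tx)
    mtx <- data.table::copy(tx)
    mtx$strand <- if (tx$strand == "+") "-" else "+"
    mtx$exon_starts <- paste(rev(L - ex$end + 1L), collapse = ",")
    mtx$exon_ends <- paste(rev(L - ex$start + 1L), collapse = ",")
    mtx$cds_start <- L - tx$cds_end + 1L
    mtx$cds_end <- L - tx$cds_start + 1L

    cds_pos <- denovotrio:::.cds_positions(tx)
    for (codon in c(5L, 20L)) {
      pos <- cds_pos[3 * (codon - 1) + 2]
      ref <- denovotrio:::.genome_base(res$genome, tx$chrom, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      a1 <- call_consequence(tx$chrom, pos, ref, alt, tx, res$genome)
      a2 <- call_consequence(tx$chrom, L - pos + 1L, unname(comp[ref]),
                             unname(comp[alt]), mtx, mirror_genome)
      expect_identical(a1$consequence, a2$consequence)
      expect_identical(a1$protein_change, a2$protein_change)
    }
  }
})

test_that("a variant hitting several transcripts takes the most severe
          consequence deterministically", {
  res <- shared_resources()
  tx <- res$transcripts[res$transcripts$gene == "DHRS3", ]
  # duplicate the transcript under a higher tx_id: tie broken by lowest id
  tx2 <- data.table::copy(data.table::as.data.table(tx))
  tx2$tx_id <- "TX_ZZZ"
  both <- rbind(data.table::as.data.table(tx), tx2)
  cds_pos <- denovotrio:::.cds_positions(tx)
  ann <- call_consequence(tx$chrom, cds_pos[3 * 36 + 2], "C", "T", both,
                          res$genome)
  expect_identical(ann$tx_id, "TX_DHRS3")
})
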