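#' @importFrom VariantAnnotation readVcf geno alt ref
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom IRanges start
NULL

.processed_chroms <- function() c(.autosomes(), "chrX")

# ---- PED ------------------------------------------------------------------

#' Read a pedigree (PED) file into case-parent trios
#'
#' Standard 6+ column PED (FID IID PAT MAT SEX PHENO), with optional columns
#' 7 (country) and 8 (cleft status) on the child line. Only complete
#' father + mother + child trios are returned; incomplete families (e.g.
#' mother-child dyads) are dropped with a warning.
#'
#' @param path PED file path
#' @return a [trio_pedigree()] table
#' @export
read_pedigree <- function(path) {
  ped <- fread(path, header = FALSE, fill = TRUE, colClasses = "character")
  if (ncol(ped) < 6L) stop("PED file needs at least 6 columns")
  names(ped)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  if (!all(ped$sex %in% c("1", "2", "0")))
    stop("unknown sex code in PED (expected 1/2/0)")
  children <- ped[ped$pat != "0" | ped$mat != "0", ]
  if (anyDuplicated(children$iid)) stop("duplicated child id in PED")
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(children))) {
    ch <- children[i, ]
    fam <- ped[ped$fid == ch$fid, ]
    if (ch$pat == "0" || ch$mat == "0" ||
        !(ch$pat %in% fam$iid) || !(ch$mat %in% fam$iid)) {
      dropped <- dropped + 1L   # dyad or incomplete family
      next
    }
    rows[[length(rows) + 1L]] <- data.table(
      trio_id = ch$fid, father_id = ch$pat, mother_id = ch$mat,
      child_id = ch$iid,
      child_sex = if (ch$sex == "1") "male" else "female",
      cleft_status = if (ncol(ped) >= 8L && nzchar(ch[[8L]])) ch[[8L]] else "CLP",
      country = if (ncol(ped) >= 7L && nzchar(ch[[7L]])) ch[[7L]] else "NA")
  }
  # families with no child row at all are also incomplete (e.g. dyads where
  # the listed parent ids never resolve)
  if (dropped > 0L)
    warning(dropped, " incomplete famil",
            if (dropped == 1L) "y" else "ies",
            " (dyads) dropped; only case-parent trios are included")
  if (length(rows) == 0L) {
    out <- data.table(trio_id = character(0), father_id = character(0),
                      mother_id = character(0), child_id = character(0),
                      child_sex = character(0), cleft_status = character(0),
                      country = character(0))
    class(out) <- c("trio_pedigree", class(out))
    return(out)
  }
  out <- rbindlist(rows)
  validate_pedigree(out)
  class(out) <- c("trio_pedigree", class(out))
  out
}

#' Write a trio pedigree as a PED file
#'
#' @param pedigree a [trio_pedigree()] table
#' @param path output path
#' @export
write_pedigree <- function(pedigree, path) {
  lines <- character(0)
  for (i in seq_len(nrow(pedigree))) {
    p <- pedigree[i, ]
    sex_code <- if (p$child_sex == "male") "1" else "2"
    lines <- c(lines,
      paste(p$trio_id, p$father_id, "0", "0", "1", "1", p$country, ".", sep = "\t"),
      paste(p$trio_id, p$mother_id, "0", "0", "2", "1", p$country, ".", sep = "\t"),
      paste(p$trio_id, p$child_id, p$father_id, p$mother_id, sex_code, "2",
            p$country, p$cleft_status, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

.parse_gt <- function(gt, record) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  if (!grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt))
    stop("malformed GT string '", gt, "' at record ", record)
  parts <- strsplit(gt, "[/|]")[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)  # hemizygous call
  if (any(parts == ".")) return(c(NA_integer_, NA_integer_))
  as.integer(parts)
}

#' Read one trio's VCF into a calls table
#'
#' Reads a VCF 4.x file with GT, GQ and DP FORMAT fields via
#' `VariantAnnotation::readVcf`, decomposes multi-allelic rows into
#' biallelic records (other-alt alleles recoded as reference), normalizes
#' phased and unphased genotypes to unordered allele pairs, and restricts to
#' chr1-chr22 and chrX (other contigs counted and skipped). Missing
#' genotypes are retained, not dropped.
#'
#' @param path VCF path
#' @param pedigree one-row [trio_pedigree()] naming the three sample ids
#' @return a [trio_calls()] table; attribute `skipped_contigs` counts
#'   records dropped for being outside the processed chromosomes
#' @export
read_trio_vcf <- function(path, pedigree) {
  stopifnot(nrow(pedigree) == 1L)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  samples <- colnames(vcf)
  ids <- c(f = pedigree$father_id, m = pedigree$mother_id,
           c = pedigree$child_id)
  if (!all(ids %in% samples))
    stop("sample id(s) missing from VCF header: ",
         paste(setdiff(ids, samples), collapse = ", "))
  rr <- rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- IRanges::start(rr)
  refs <- as.character(ref(vcf))
  alts <- alt(vcf)   # DNAStringSetList, one entry per ALT allele
  gt <- geno(vcf)$GT
  gq <- if ("GQ" %in% names(geno(vcf))) geno(vcf)$GQ else
    matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dp <- if ("DP" %in% names(geno(vcf))) geno(vcf)$DP else
    matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))

  keep_chrom <- chrom %in% .processed_chroms()
  skipped <- sum(!keep_chrom)

  out <- vector("list", sum(lengths(alts)[keep_chrom]))
  k <- 0L
  for (i in which(keep_chrom)) {
    row_alts <- as.character(alts[[i]])
    parsed <- lapply(ids, function(s) .parse_gt(gt[i, s], i))
    for (j in seq_along(row_alts)) {
      # recode: this alt allele -> 1, reference and other alts -> 0
      rec <- lapply(parsed, function(a)
        if (anyNA(a)) c(NA_integer_, NA_integer_) else as.integer(a == j))
      k <- k + 1L
      out[[k]] <- data.table(
        chrom = chrom[i], pos = pos[i],
        id = if (is.na(names(rr)[i])) "." else names(rr)[i],
        ref = refs[i], alt = row_alts[j],
        f_a1 = rec$f[1], f_a2 = rec$f[2],
        m_a1 = rec$m[1], m_a2 = rec$m[2],
        c_a1 = rec$c[1], c_a2 = rec$c[2],
        f_gq = as.integer(gq[i, ids["f"]]), m_gq = as.integer(gq[i, ids["m"]]),
        c_gq = as.integer(gq[i, ids["c"]]),
        f_dp = as.integer(dp[i, ids["f"]]), m_dp = as.integer(dp[i, ids["m"]]),
        c_dp = as.integer(dp[i, ids["c"]]))
    }
  }
  res <- if (k > 0L) rbindlist(out[seq_len(k)]) else
    trio_calls(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0))
  class(res) <- unique(c("trio_calls", class(res)))
  attr(res, "skipped_contigs") <- skipped
  res
}

#' Write one trio's calls table as a VCF 4.2 file
#'
#' Emits GT:GQ:DP genotypes for the father, mother and child samples.
#'
#' @param calls a [trio_calls()] table
#' @param pedigree one-row [trio_pedigree()] supplying the sample ids
#' @param path output path
#' @export
write_trio_vcf <- function(calls, pedigree, path) {
  stopifnot(nrow(pedigree) == 1L)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", .processed_chroms(), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", pedigree$father_id, pedigree$mother_id,
                 pedigree$child_id, sep = "\t"))
  fmt_gt <- function(a1, a2, gq, dp) {
    g <- ifelse(is.na(a1), "./.", paste0(a1, "/", a2))
    paste(g, ifelse(is.na(gq), ".", gq), ifelse(is.na(dp), ".", dp), sep = ":")
  }
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, calls$id, calls$ref, calls$alt, ".",
          "PASS", ".", "GT:GQ:DP",
          fmt_gt(calls$f_a1, calls$f_a2, calls$f_gq, calls$f_dp),
          fmt_gt(calls$m_a1, calls$m_a2, calls$m_gq, calls$m_dp),
          fmt_gt(calls$c_a1, calls$c_a2, calls$c_gq, calls$c_dp),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- annotation resources -------------------------------------------------

.read_tsv <- function(path, ...) {
  # tolerate '#'-prefixed provenance header lines
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "# ")))
  fread(path, skip = skip, ...)
}

#' Read a transcript-model table
#'
#' TSV with columns gene, tx_id, chrom, strand, exon_starts, exon_ends
#' (comma-joined 1-based inclusive), cds_start, cds_end, n_codons. Validates
#' that exons are sorted and non-overlapping, the CDS length is divisible by
#' three, and the first coding codon is ATG (when a genome is supplied).
#'
#' @param path TSV path
#' @param genome optional `DNAStringSet` for start-codon validation
#' @return transcript `data.table`
#' @export
read_transcripts <- function(path, genome = NULL) {
  tx <- .read_tsv(path, colClasses = list(character = c("exon_starts",
                                                        "exon_ends")))
  for (i in seq_len(nrow(tx))) {
    ex <- .tx_exons(tx[i, ])
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("transcript ", tx$tx_id[i], ": exons must be sorted, non-overlapping")
    cds_len <- sum(pmin(ex$end, tx$cds_end[i]) - pmax(ex$start, tx$cds_start[i]) + 1L)
    if (cds_len %% 3L != 0L)
      stop("transcript ", tx$tx_id[i], ": CDS length not divisible by 3")
    if (!is.null(genome)) {
      cds <- transcript_cds(tx[i, ], genome)
      if (substr(cds, 1, 3) != "ATG")
        stop("transcript ", tx$tx_id[i], ": first CDS codon is not ATG")
    }
  }
  tx
}

.read_panel <- function(path) {
  p <- .read_tsv(path)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(p)))
  if (any(p$af < 0 | p$af > 1))
    stop("allele frequency outside [0, 1] in panel ", basename(path))
  p
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, tab-separated gene symbols)
#' @return named list of uppercase gene-symbol vectors; term descriptions in
#'   attribute `descriptions`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("GMT line with no genes: ", parts[1])
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("empty gene set: ", parts[1])
    sets[[parts[1]]] <- sort(genes)
    desc[parts[1]] <- parts[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Read the full annotation resource bundle from disk
#'
#' @param paths named list/vector: `genome` (FASTA), `transcripts` (TSV),
#'   `panels` (character vector of panel TSVs, named), `scores` (TSV),
#'   `evidence` (TSV), `gene_sets` (GMT), `expression` (TSV)
#' @return `dnm_resources` list as produced by [generate_resources()]
#' @export
read_resources <- function(paths) {
  genome <- readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  transcripts <- read_transcripts(paths$transcripts, genome)
  panels <- lapply(paths$panels, .read_panel)
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- tools::file_path_sans_ext(basename(unlist(paths$panels)))
  scores <- .read_tsv(paths$scores)
  if (any(stats::na.omit(scores$sift) < 0 | stats::na.omit(scores$sift) > 1) ||
      any(stats::na.omit(scores$polyphen) < 0 | stats::na.omit(scores$polyphen) > 1))
    stop("SIFT/PolyPhen scores must lie in [0, 1]")
  evidence <- .read_tsv(paths$evidence)
  stopifnot(all(c("gene", "mouse_ko", "cnv_report", "snv_report") %in%
                  names(evidence)))
  gene_sets <- read_gmt(paths$gene_sets)
  expr_dt <- .read_tsv(paths$expression)
  expr <- as.matrix(expr_dt[, -1])
  rownames(expr) <- expr_dt[[1]]
  if (anyDuplicated(rownames(expr))) stop("duplicate gene rows in expression matrix")
  if (any(expr < 0)) stop("expression intensities must be non-negative")
  structure(list(genome = genome, transcripts = transcripts,
                 peptides = NULL, panels = panels, scores = scores,
                 evidence = evidence, gene_sets = gene_sets,
                 expression = expr, seed = NA_integer_),
            class = "dnm_resources")
}

#' Write an annotation resource bundle to a directory
#'
#' Inverse of [read_resources()]; returns the `paths` list it accepts.
#'
#' @param resources a `dnm_resources` bundle
#' @param dir output directory (created if needed)
#' @return named list of written paths
#' @export
write_resources <- function(resources, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  writeXStringSet(resources$genome, fp("genome.fa"))
  fwrite(resources$transcripts, fp("transcripts.tsv"), sep = "\t")
  panel_paths <- setNames(
    vapply(names(resources$panels), function(nm) {
      fwrite(resources$panels[[nm]], fp(paste0("panel_", nm, ".tsv")),
             sep = "\t")
      fp(paste0("panel_", nm, ".tsv"))
    }, character(1)), names(resources$panels))
  fwrite(resources$scores, fp("scores.tsv"), sep = "\t")
  fwrite(resources$evidence, fp("evidence.tsv"), sep = "\t")
  desc <- attr(resources$gene_sets, "descriptions") %||%
    setNames(names(resources$gene_sets), names(resources$gene_sets))
  writeLines(vapply(names(resources$gene_sets), function(nm)
    paste(c(nm, desc[[nm]], resources$gene_sets[[nm]]), collapse = "\t"),
    character(1)), fp("gene_sets.gmt"))
  expr_dt <- data.table(gene = rownames(resources$expression))
  for (cn in colnames(resources$expression))
    expr_dt[[cn]] <- resources$expression[, cn]
  fwrite(expr_dt, fp("expression.tsv"), sep = "\t")
  list(genome = fp("genome.fa"), transcripts = fp("transcripts.tsv"),
       panels = panel_paths, scores = fp("scores.tsv"),
       evidence = fp("evidence.tsv"), gene_sets = fp("gene_sets.gmt"),
       expression = fp("expression.tsv"))
}

# ---- result tables --------------------------------------------------------

.write_tsv_seeded <- function(dt, path, seed) {
  con <- file(path, "w")
  writeLines(paste0("# seed: ", seed), con)
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Emits, under `out_dir`: `dnms.tsv` (one row per high-confidence DNM),
#' `funnel.tsv` (per-stage retained counts), `qc_exclusions.tsv` (per-trio
#' reason codes), and `enrichment.tsv`. Outputs are byte-stable given fixed
#' inputs; every file carries a `# seed:` header line.
#'
#' @param results list with elements `dnm` ([discover_dnms()] output), `qc`
#'   ([apply_qc()] output), and optionally `enrichment`
#' @param out_dir output directory (created if needed)
#' @param seed seed recorded in the output headers
#' @return invisible vector of written paths
#' @export
write_outputs <- function(results, out_dir, seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(results$dnm)) {
    p <- file.path(out_dir, "dnms.tsv")
    .write_tsv_seeded(results$dnm$dnms, p, seed)
    f <- results$dnm$funnel
    .write_tsv_seeded(data.table(stage = f$stage, n_retained = f$retained),
                      file.path(out_dir, "funnel.tsv"), seed)
    paths <- c(paths, p, file.path(out_dir, "funnel.tsv"))
  }
  if (!is.null(results$qc)) {
    p <- file.path(out_dir, "qc_exclusions.tsv")
    .write_tsv_seeded(results$qc$results, p, seed)
    paths <- c(paths, p)
  }
  if (!is.null(results$enrichment)) {
    p <- file.path(out_dir, "enrichment.tsv")
    .write_tsv_seeded(results$enrichment, p, seed)
    paths <- c(paths, p)
  }
  invisible(paths)
}
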