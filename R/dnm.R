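#' Genotype-quality filter for a trio call
#'
#' TRUE iff all three members are genotyped (non-missing) with GQ >= `min_gq`
#' and DP >= `min_dp` (both bounds inclusive: GQ 20 and DP 10 pass at the
#' defaults). Vectorized over sites.
#'
#' @param calls a [trio_calls()] table
#' @param min_gq,min_dp inclusive thresholds
#' @return logical vector
#' @export
passes_quality <- function(calls, min_gq = 20L, min_dp = 10L) {
  with(calls,
       !is.na(f_a1) & !is.na(m_a1) & !is.na(c_a1) &
       !is.na(f_gq) & !is.na(m_gq) & !is.na(c_gq) &
       !is.na(f_dp) & !is.na(m_dp) & !is.na(c_dp) &
       f_gq >= min_gq & m_gq >= min_gq & c_gq >= min_gq &
       f_dp >= min_dp & m_dp >= min_dp & c_dp >= min_dp)
}

#' De novo genotype configuration
#'
#' TRUE iff both parents are homozygous reference and the child is
#' heterozygous (autosomes), i.e. the mutation is present in the case but
#' absent in both parents. On chrX a hemizygous male child (emitted as a
#' homozygous-alternate diploid call) also qualifies. Autosomal
#' homozygous-alternate children are rejected (a double-hit de novo is
#' implausible) but counted separately for review.
#'
#' @param calls a [trio_calls()] table
#' @param child_sex "male" or "female"
#' @return list with logical `denovo` and logical `flagged_homalt`
#'   (autosomal child 1/1 with hom-ref parents, diagnostics channel)
#' @export
is_denovo <- function(calls, child_sex = "female") {
  with(calls, {
    parents_ref <- !is.na(f_a1) & !is.na(m_a1) &
      f_a1 + f_a2 == 0L & m_a1 + m_a2 == 0L
    child_het <- !is.na(calls$c_a1) & c_a1 + c_a2 == 1L
    child_homalt <- !is.na(calls$c_a1) & c_a1 + c_a2 == 2L
    x_hemi <- chrom == "chrX" & child_sex == "male"
    list(denovo = parents_ref & (child_het | (child_homalt & x_hemi)),
         flagged_homalt = parents_ref & child_homalt & !x_hemi)
  })
}

#' Maximum allele frequency across population panels
#'
#' Looks the (normalized) variant up in every loaded panel and returns the
#' maximum reported frequency; a variant absent from all panels is rare by
#' convention (frequency 0).
#'
#' @param chrom,pos,ref,alt variant (vectors accepted)
#' @param panels named list of panel `data.table`s with columns
#'   chrom, pos, ref, alt, af
#' @return numeric vector of maximum frequencies
#' @export
max_panel_maf <- function(chrom, pos, ref, alt, panels) {
  if (length(panels) == 0L) stop("at least one frequency panel is required")
  norm <- mapply(function(c, p, r, a) {
    v <- normalize_variant(c, p, r, a)
    .site_key(v$chrom, v$pos, v$ref, v$alt)
  }, chrom, pos, ref, alt)
  out <- rep(0, length(norm))
  for (panel in panels) {
    key <- .site_key(panel$chrom, panel$pos, panel$ref, panel$alt)
    hit <- match(norm, key)
    af <- ifelse(is.na(hit), 0, panel$af[hit])
    out <- pmax(out, af)
  }
  unname(out)
}

.funnel_stages <- c("raw", "quality_pass", "denovo_config",
                    "protein_altering", "rare")

#' Construct a filtration funnel
#'
#' @param counts named integer vector over the stage vocabulary
#'   raw, quality_pass, denovo_config, protein_altering, rare
#' @return object of class `filter_funnel`
#' @export
filter_funnel <- function(counts) {
  stopifnot(identical(names(counts), .funnel_stages))
  if (any(diff(counts) > 0))
    stop("funnel counts must be monotonically non-increasing")
  structure(list(stage = .funnel_stages, retained = as.integer(counts)),
            class = "filter_funnel")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("variant filtration funnel:\n")
  for (i in seq_along(x$stage))
    cat(sprintf("  %-16s %d\n", x$stage[i], x$retained[i]))
  invisible(x)
}

#' Run the DNM filtration funnel over a QC-retained cohort
#'
#' Stages, in order: raw records -> quality (GQ/DP in all members) ->
#' de novo configuration -> protein-altering consequence (protein-truncating
#' or missense) -> rare (maximum panel MAF <= `max_maf`). Consequences are
#' called only for variants reaching the consequence stage. Returns one row
#' per high-confidence DNM with its annotations plus the per-stage funnel.
#'
#' @param cohort a QC-retained [trio_cohort()]
#' @param resources resource bundle (see [read_resources()] /
#'   [generate_resources()]): transcripts, genome, panels, scores
#' @param min_gq,min_dp,max_maf filter thresholds (all inclusive)
#' @param maf_inclusive if FALSE, use strict MAF < `max_maf`
#' @return list of class `dnm_result`: `dnms` (annotated candidate table),
#'   `funnel` ([filter_funnel()]), `per_trio` counts, `flagged_homalt`
#'   diagnostics count, and `stage_of` (per-record terminal stage table)
#' @export
discover_dnms <- function(cohort, resources, min_gq = 20L, min_dp = 10L,
                          max_maf = 0.01, maf_inclusive = TRUE) {
  ped <- cohort$pedigree
  if (nrow(ped) == 0L) {
    funnel <- filter_funnel(setNames(integer(5), .funnel_stages))
    return(structure(list(dnms = .empty_dnm_table(), funnel = funnel,
                          per_trio = data.table(trio_id = character(0),
                                                n_dnm = integer(0)),
                          flagged_homalt = 0L,
                          stage_of = data.table()),
                     class = "dnm_result"))
  }
  stacked <- .stack_cohort(cohort)
  stacked <- merge(stacked, ped[, c("trio_id", "child_sex")], by = "trio_id",
                   sort = FALSE)

  n_raw <- nrow(stacked)
  q <- passes_quality(stacked, min_gq, min_dp)
  s1 <- stacked[q]
  dn <- is_denovo(s1, child_sex = s1$child_sex)
  flagged_homalt <- sum(dn$flagged_homalt)
  s2 <- s1[dn$denovo]

  if (nrow(s2)) {
    ann <- rbindlist(lapply(seq_len(nrow(s2)), function(i)
      call_consequence(s2$chrom[i], s2$pos[i], s2$ref[i], s2$alt[i],
                       resources$transcripts, resources$genome)))
    s2 <- cbind(s2, ann)
    s2[, impact := impact_class(consequence)]
  } else {
    s2 <- cbind(s2, .empty_dnm_table()[, c("gene", "tx_id", "consequence",
                                           "protein_change", "impact")])
  }
  s3 <- s2[s2$impact %in% c("protein_truncating", "missense"), ]

  if (nrow(s3)) {
    s3[, max_maf := max_panel_maf(chrom, pos, ref, alt, resources$panels)]
  } else {
    s3[, max_maf := numeric(0)]
  }
  keep <- if (maf_inclusive) s3$max_maf <= max_maf else s3$max_maf < max_maf
  s4 <- s3[keep]

  # attach pathogenicity scores
  if (nrow(s4)) {
    key <- mapply(function(c, p, r, a) {
      v <- normalize_variant(c, p, r, a)
      .site_key(v$chrom, v$pos, v$ref, v$alt)
    }, s4$chrom, s4$pos, s4$ref, s4$alt)
    sc <- resources$scores
    hit <- match(key, .site_key(sc$chrom, sc$pos, sc$ref, sc$alt))
    s4[, `:=`(cadd_phred = sc$cadd_phred[hit],
              sift = sc$sift[hit], polyphen = sc$polyphen[hit])]
  } else {
    s4[, `:=`(cadd_phred = numeric(0), sift = numeric(0),
              polyphen = numeric(0))]
  }

  funnel <- filter_funnel(c(raw = n_raw, quality_pass = nrow(s1),
                            denovo_config = nrow(s2),
                            protein_altering = nrow(s3), rare = nrow(s4)))
  per_trio <- merge(ped[, "trio_id"],
                    if (nrow(s4)) s4[, .(n_dnm = .N), by = trio_id]
                    else data.table(trio_id = character(0), n_dnm = integer(0)),
                    by = "trio_id", all.x = TRUE, sort = TRUE)
  per_trio$n_dnm[is.na(per_trio$n_dnm)] <- 0L

  cols <- c("trio_id", "chrom", "pos", "id", "ref", "alt", "gene", "tx_id",
            "consequence", "protein_change", "impact", "max_maf",
            "cadd_phred", "sift", "polyphen")
  structure(list(dnms = s4[order(chrom, pos, trio_id), ..cols],
                 funnel = funnel, per_trio = per_trio,
                 flagged_homalt = flagged_homalt),
            class = "dnm_result")
}

.empty_dnm_table <- function() {
  data.table(trio_id = character(0), chrom = character(0), pos = integer(0),
             id = character(0), ref = character(0), alt = character(0),
             gene = character(0), tx_id = character(0),
             consequence = character(0), protein_change = character(0),
             impact = character(0), max_maf = numeric(0),
             cadd_phred = numeric(0), sift = numeric(0),
             polyphen = numeric(0))
}

#' @export
print.dnm_result <- function(x, ...) {
  cat("DNM discovery:", nrow(x$dnms), "high-confidence protein-altering DNMs",
      sprintf("(mean %.2f per case)\n", mean(x$per_trio$n_dnm)))
  print(x$funnel)
  invisible(x)
}
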