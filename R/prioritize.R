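# --- Table-1-style prioritization: CADD bins, in-silico classes, evidence --

#' CADD phred percentile bin
#'
#' The phred scale defines score C = -10*log10(rank fraction among all
#' possible substitutions), so C >= 30 is the top 0.1% most deleterious,
#' C >= 20 the top 1%, C >= 10 the top 10%.
#'
#' @param score CADD phred score(s), >= 0
#' @return factor-like character: "top0.1%", "top1%", "top10%" or "lower"
#' @export
cadd_bin <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("CADD phred scores must be >= 0")
  ifelse(is.na(score), NA_character_,
  ifelse(score >= 30, "top0.1%",
  ifelse(score >= 20, "top1%",
  ifelse(score >= 10, "top10%", "lower"))))
}

#' SIFT / PolyPhen-2 class labels
#'
#' SIFT < 0.05 is deleterious, otherwise tolerated. PolyPhen-2 (HumDiv
#' convention) >= 0.85 probably damaging, >= 0.446 possibly damaging,
#' otherwise benign. `damaging_any` is TRUE iff at least one tool calls the
#' variant deleterious/damaging; for protein-truncating variants the scores
#' are not defined and all labels are NA.
#'
#' @param sift,polyphen scores in \[0, 1\] (NA for protein-truncating
#'   variants)
#' @param sift_cut,pp_possibly,pp_probably configurable cutoffs
#' @return `data.table` with columns sift_class, polyphen_class,
#'   damaging_any
#' @export
insilico_classes <- function(sift, polyphen, sift_cut = 0.05,
                             pp_possibly = 0.446, pp_probably = 0.85) {
  if (any(sift < 0 | sift > 1, na.rm = TRUE) ||
      any(polyphen < 0 | polyphen > 1, na.rm = TRUE))
    stop("SIFT/PolyPhen scores must lie in [0, 1]")
  n <- max(length(sift), length(polyphen))
  sift <- rep_len(sift, n); polyphen <- rep_len(polyphen, n)
  sift_class <- ifelse(is.na(sift), NA_character_,
                       ifelse(sift < sift_cut, "deleterious", "tolerated"))
  pp_class <- ifelse(is.na(polyphen), NA_character_,
              ifelse(polyphen >= pp_probably, "probably_damaging",
              ifelse(polyphen >= pp_possibly, "possibly_damaging", "benign")))
  damaging_any <- ifelse(is.na(sift_class) & is.na(pp_class), NA,
    (!is.na(sift_class) & sift_class == "deleterious") |
    (!is.na(pp_class) & pp_class %in% c("probably_damaging",
                                        "possibly_damaging")))
  data.table(sift_class = sift_class, polyphen_class = pp_class,
             damaging_any = damaging_any)
}

#' Look a gene up in the craniofacial evidence table
#'
#' A gene absent from the table gets an all-none record, never an error.
#'
#' @param genes gene symbol(s)
#' @param evidence evidence `data.table` (gene, mouse_ko, cnv_report,
#'   snv_report) with mouse_ko in cleft / craniofacial / lethal / none
#' @return `data.table`, one row per queried gene
#' @export
evidence_join <- function(genes, evidence) {
  stopifnot(all(evidence$mouse_ko %in% c("cleft", "craniofacial", "lethal",
                                         "none")))
  hit <- match(genes, evidence$gene)
  data.table(
    gene = genes,
    mouse_ko = ifelse(is.na(hit), "none", evidence$mouse_ko[hit]),
    cnv_report = !is.na(hit) & evidence$cnv_report[hit],
    snv_report = !is.na(hit) & evidence$snv_report[hit])
}

#' Build the prioritized DNM table
#'
#' A DNM is prioritized iff its gene carries any craniofacial evidence: a
#' mouse-knockout phenotype (cleft, other craniofacial, or embryonic
#' lethal), or a CNV report, or an SNV report. Prioritization is a pure
#' filter over the input rows; output is sorted deterministically by
#' (impact class, CADD bin, gene).
#'
#' @param dnms DNM candidate table ([discover_dnms()] `$dnms`)
#' @param evidence evidence `data.table`
#' @return prioritized `data.table` with evidence, CADD bin and in-silico
#'   class columns appended
#' @export
build_prioritized_table <- function(dnms, evidence) {
  dnms <- as.data.table(dnms)
  if (nrow(dnms) == 0L) return(dnms)
  ev <- evidence_join(dnms$gene, evidence)
  ann <- cbind(dnms,
               ev[, c("mouse_ko", "cnv_report", "snv_report")],
               insilico_classes(dnms$sift, dnms$polyphen))
  ann$cadd_bin <- cadd_bin(ann$cadd_phred)
  keep <- ann$mouse_ko != "none" | ann$cnv_report | ann$snv_report
  out <- ann[keep, ]
  bin_rank <- match(out$cadd_bin, c("top0.1%", "top1%", "top10%", "lower"))
  impact_rank <- match(out$impact, c("protein_truncating", "missense", "other"))
  out[order(impact_rank, bin_rank, out$gene), ]
}
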