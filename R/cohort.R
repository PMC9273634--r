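#' Construct a trio pedigree table
#'
#' One row per case-parent trio: an affected proband with two unaffected
#' biological parents. Cleft status uses the three standard codes: CL (cleft
#' lip only), CLP (cleft lip and palate), CP (cleft palate only).
#'
#' @param trio_id,father_id,mother_id,child_id character vectors
#' @param child_sex "male" or "female" (as reported at recruitment)
#' @param cleft_status "CL", "CLP" or "CP"
#' @param country recruitment-site label
#' @return `data.table` of class `trio_pedigree`
#' @export
trio_pedigree <- function(trio_id, father_id, mother_id, child_id,
                          child_sex, cleft_status = "CLP", country = "NA") {
  ped <- data.table(trio_id = as.character(trio_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    child_id = as.character(child_id),
                    child_sex = as.character(child_sex),
                    cleft_status = as.character(cleft_status),
                    country = as.character(country))
  validate_pedigree(ped)
  class(ped) <- c("trio_pedigree", class(ped))
  ped
}

validate_pedigree <- function(ped) {
  needed <- c("trio_id", "father_id", "mother_id", "child_id", "child_sex",
              "cleft_status", "country")
  if (!all(needed %in% names(ped)))
    stop("pedigree is missing columns: ",
         paste(setdiff(needed, names(ped)), collapse = ", "))
  for (i in seq_len(nrow(ped))) {
    ids <- unlist(ped[i, c("father_id", "mother_id", "child_id")])
    if (anyDuplicated(ids))
      stop("trio ", ped$trio_id[i], ": father/mother/child ids must be distinct")
  }
  if (anyDuplicated(ped$child_id)) stop("duplicated child id in pedigree")
  if (anyDuplicated(ped$trio_id)) stop("duplicated trio id in pedigree")
  all_parents <- c(ped$father_id, ped$mother_id)
  if (anyDuplicated(all_parents))
    stop("a parent id is shared between trios")
  if (!all(ped$child_sex %in% c("male", "female")))
    stop("child_sex must be 'male' or 'female'")
  if (!all(ped$cleft_status %in% c("CL", "CLP", "CP")))
    stop("cleft_status must be one of CL, CLP, CP")
  invisible(ped)
}

#' Construct a per-trio genotype call table
#'
#' The internal unit the QC and DNM filters act on: one row per decomposed
#' biallelic site with the three members' unordered allele pairs (0 =
#' reference, 1 = alternate, NA = missing) and their GQ/DP quality fields.
#'
#' @param chrom,pos,id,ref,alt site fields (VCF convention, 1-based)
#' @param f_a1,f_a2,m_a1,m_a2,c_a1,c_a2 father/mother/child allele indices
#' @param f_gq,m_gq,c_gq phred genotype qualities
#' @param f_dp,m_dp,c_dp read depths
#' @return `data.table` of class `trio_calls`
#' @export
trio_calls <- function(chrom, pos, ref, alt, id = ".",
                       f_a1 = 0L, f_a2 = 0L, m_a1 = 0L, m_a2 = 0L,
                       c_a1 = 0L, c_a2 = 0L,
                       f_gq = 99L, m_gq = 99L, c_gq = 99L,
                       f_dp = 30L, m_dp = 30L, c_dp = 30L) {
  .validate_site(chrom, pos, ref, alt)
  x <- data.table(chrom = chrom, pos = as.integer(pos), id = id,
                  ref = ref, alt = alt,
                  f_a1 = as.integer(f_a1), f_a2 = as.integer(f_a2),
                  m_a1 = as.integer(m_a1), m_a2 = as.integer(m_a2),
                  c_a1 = as.integer(c_a1), c_a2 = as.integer(c_a2),
                  f_gq = as.integer(f_gq), m_gq = as.integer(m_gq),
                  c_gq = as.integer(c_gq),
                  f_dp = as.integer(f_dp), m_dp = as.integer(m_dp),
                  c_dp = as.integer(c_dp))
  # missing genotype => both alleles missing, for each member
  for (m in c("f", "m", "c")) {
    a1 <- x[[paste0(m, "_a1")]]; a2 <- x[[paste0(m, "_a2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half)) stop("half-missing genotype for member ", m)
  }
  class(x) <- c("trio_calls", class(x))
  x
}

#' Bundle a pedigree with per-trio call tables
#'
#' @param pedigree a [trio_pedigree()] table
#' @param calls named list of [trio_calls()] tables keyed by trio id
#' @return object of class `trio_cohort`
#' @export
trio_cohort <- function(pedigree, calls) {
  if (!all(pedigree$trio_id %in% names(calls)))
    stop("every pedigree trio needs a calls table")
  structure(list(pedigree = pedigree, calls = calls[pedigree$trio_id]),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", nrow(x$pedigree), "case-parent trios,",
      if (length(x$calls)) nrow(x$calls[[1]]) else 0L,
      "sites in first trio\n")
  invisible(x)
}

#' Cross-tabulate a cohort by country and cleft status
#'
#' Mirrors the standard recruitment summary: trios per country of origin and
#' cleft subtype, with marginal totals.
#'
#' @param pedigree a [trio_pedigree()] table
#' @return list with `table` (country x cleft-status counts incl. totals) and
#'   `total` trio count
#' @export
summarize_cohort <- function(pedigree) {
  statuses <- c("CL", "CLP", "CP")
  countries <- sort(unique(pedigree$country))
  tab <- matrix(0L, nrow = length(countries) + 1L, ncol = length(statuses) + 1L,
                dimnames = list(c(countries, "Total"), c(statuses, "Total")))
  if (nrow(pedigree) > 0L) {
    xt <- table(factor(pedigree$country, levels = countries),
                factor(pedigree$cleft_status, levels = statuses))
    tab[seq_along(countries), seq_along(statuses)] <- as.integer(xt)
  }
  tab[, "Total"] <- rowSums(tab[, statuses, drop = FALSE])
  tab["Total", ] <- colSums(tab[c(countries), , drop = FALSE])
  if (length(countries) == 0L) tab["Total", ] <- 0L
  stopifnot(tab["Total", "Total"] == nrow(pedigree))
  list(table = tab, total = nrow(pedigree))
}
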