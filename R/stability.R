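# --- folding free-energy (ddG) arithmetic and disease classification ------

#' Folding free-energy change of a single replicate
#'
#' ddG = dG_folded - dG_unfolded (kcal/mol). A positive change destabilizes
#' the protein.
#'
#' @param dg_folded,dg_unfolded replicate free energies (kcal/mol)
#' @return ddG (kcal/mol), vectorized
#' @export
ddg <- function(dg_folded, dg_unfolded) {
  if (any(!is.finite(dg_folded)) || any(!is.finite(dg_unfolded)))
    stop("free energies must be finite")
  dg_folded - dg_unfolded
}

#' Summarize ddG replicates into a stability classification
#'
#' Mean and sample SD (n-1 denominator; SD = 0 for a single replicate) over
#' replicate ddG values. The mutation is destabilizing iff mean ddG > 0;
#' changes strictly greater than 1 kcal/mol are flagged as likely disease
#' causing.
#'
#' @param dg_folded,dg_unfolded replicate free energies (kcal/mol)
#' @return list of class `stability_result`: `ddg_mean`, `ddg_sd`,
#'   `n_replicates`, `destabilizing`, `disease_likely`
#' @export
summarize_stability <- function(dg_folded, dg_unfolded) {
  if (length(dg_folded) == 0L) stop("at least one replicate is required")
  stopifnot(length(dg_folded) == length(dg_unfolded))
  d <- ddg(dg_folded, dg_unfolded)
  m <- mean(d)
  s <- if (length(d) == 1L) 0 else sd(d)
  structure(list(ddg_mean = m, ddg_sd = s, n_replicates = length(d),
                 destabilizing = m > 0, disease_likely = m > 1.0),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("ddG = %.3f +/- %.3f kcal/mol (n = %d): %s%s\n",
              x$ddg_mean, x$ddg_sd, x$n_replicates,
              if (x$destabilizing) "destabilizing" else "not destabilizing",
              if (x$disease_likely) ", likely disease causing" else ""))
  invisible(x)
}

#' Read a ddG replicate table and classify each variant
#'
#' @param path TSV with columns variant, replicate, dg_folded, dg_unfolded
#' @return `data.table` with one row per variant: ddg_mean, ddg_sd,
#'   n_replicates, destabilizing, disease_likely
#' @export
stability_from_table <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("variant", "dg_folded", "dg_unfolded") %in% names(d)))
  d[, {
    s <- summarize_stability(dg_folded, dg_unfolded)
    list(ddg_mean = s$ddg_mean, ddg_sd = s$ddg_sd,
         n_replicates = s$n_replicates, destabilizing = s$destabilizing,
         disease_likely = s$disease_likely)
  }, by = "variant"]
}
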