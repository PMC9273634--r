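#' @importFrom data.table data.table as.data.table setDT setkey rbindlist fwrite fread :=
#' @importFrom stats rbinom rpois runif rnorm setNames phyper dhyper sd
#' @importFrom utils head tail
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "ref", "alt", "trio_id", "gene",
  "tx_id", "class", "consequence", "impact", "max_maf", "cadd_phred",
  "stage", "n_retained", "panel_af", "p_hwe", "site_key", "reason"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

.autosomes <- function() paste0("chr", 1:22)

.chrom_is_autosomal <- function(chrom) chrom %in% .autosomes()

.site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' Normalize an indel/SNV allele pair by trimming shared sequence
#'
#' Trims the shared suffix, then the shared prefix (advancing `pos`), always
#' leaving at least one base in each allele. Panels and score tables are keyed
#' on normalized alleles so that equivalent representations of the same indel
#' hit the same record.
#'
#' @param chrom chromosome name
#' @param pos 1-based position
#' @param ref,alt allele strings (uppercase A/C/G/T)
#' @return list with elements `chrom`, `pos`, `ref`, `alt`
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  stopifnot(nchar(ref) >= 1L, nchar(alt) >= 1L)
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # shared suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # shared prefix
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos),
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

.validate_site <- function(chrom, pos, ref, alt) {
  ok_base <- function(x) grepl("^[ACGT]+$", x)
  if (any(pos < 1L)) stop("variant position must be >= 1")
  if (!all(ok_base(ref)) || !all(ok_base(alt)))
    stop("ref/alt must be non-empty uppercase A/C/G/T strings")
  if (any(ref == alt)) stop("ref and alt must differ")
  invisible(TRUE)
}

# three-letter amino acid codes keyed by one-letter code ("*" = Ter)
.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

.seed_stream <- function(seed, offset) {
  # derived seeds stay below 2^31
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483629L
}
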