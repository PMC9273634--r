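# --- gene-set enrichment (Fisher/EASE) and expression summarization -------

#' Upper-tail hypergeometric p-value (Fisher / EASE)
#'
#' P(X >= k) for X ~ Hypergeometric(set size K in background N, draws n).
#' With `ease = TRUE` the tail is evaluated at k - 1 (floored at 0), the
#' conservative modified Fisher statistic used by DAVID, so the EASE p-value
#' is always >= the Fisher p-value.
#'
#' @param k observed overlap between query and set
#' @param n query size
#' @param K set size
#' @param N background size
#' @param ease use the one-member-removed EASE penalty
#' @return p-value in (0, 1]
#' @export
hypergeom_upper_p <- function(k, n, K, N, ease = FALSE) {
  if (k < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(n, K) <= N)")
  if (ease) k <- max(0L, k - 1L)
  if (k == 0L) return(1.0)
  # P(X >= k) = 1 - P(X <= k-1), lower.tail = FALSE gives P(X > k-1)
  min(1.0, phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
}

#' Gene-set enrichment of a query gene list
#'
#' One-sided hypergeometric enrichment of the (deduplicated, uppercased)
#' query against every term in the collection, with the nominal p < 0.05
#' significance flag and no multiple-testing correction by default (a
#' Benjamini-Hochberg column is available behind `bh`).
#'
#' @param query character vector of gene symbols (e.g. DNM genes)
#' @param gene_sets named list of gene-symbol vectors (see [read_gmt()])
#' @param background background size N; default: number of distinct genes
#'   carrying any annotation in the collection
#' @param ease use the EASE penalty instead of plain Fisher
#' @param bh add Benjamini-Hochberg adjusted p-values
#' @return `data.table` sorted by ascending p: term, k, n, K, N, p,
#'   significant (and p_bh if requested)
#' @export
enrich <- function(query, gene_sets, background = NULL, ease = FALSE,
                   bh = FALSE) {
  if (length(query) == 0L) stop("query gene list is empty")
  query <- unique(toupper(query))
  universe <- unique(toupper(unlist(gene_sets)))
  N <- background %||% length(universe)
  if (any(lengths(gene_sets) > N))
    stop("a gene set is larger than the background")
  n <- length(query)
  if (n > N) stop("query is larger than the background")
  out <- rbindlist(lapply(names(gene_sets), function(term) {
    set <- unique(toupper(gene_sets[[term]]))
    k <- length(intersect(query, set))
    data.table(term = term, k = k, n = n, K = length(set), N = N,
               p = hypergeom_upper_p(k, n, length(set), N, ease = ease))
  }))
  out <- out[order(out$p, out$term), ]
  out$significant <- out$p < 0.05
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Tissue-vs-tissue expression contrast
#'
#' Per-gene intensity ratio between two tissue columns with a pseudo-count
#' of `eps` fluorescence units guarding zero denominators; a gene is
#' elevated iff ratio > `threshold` (strict). Genes absent from the matrix
#' are reported as missing, not an error.
#'
#' @param expression genes x tissues intensity matrix
#' @param genes gene symbols to contrast
#' @param tissue_a,tissue_b column names (e.g. "maxillary_E10.5" vs
#'   "mandibular_E10.5")
#' @param threshold elevation ratio threshold (default 1.0)
#' @param eps intensity pseudo-count (default 1.0 unit)
#' @return `data.table`: gene, intensity_a, intensity_b, ratio, elevated,
#'   missing
#' @export
tissue_contrast <- function(expression, genes, tissue_a, tissue_b,
                            threshold = 1.0, eps = 1.0) {
  stopifnot(threshold > 0)
  if (!all(c(tissue_a, tissue_b) %in% colnames(expression)))
    stop("tissue column(s) not found in expression matrix")
  hit <- match(genes, rownames(expression))
  a <- ifelse(is.na(hit), NA_real_, expression[hit, tissue_a])
  b <- ifelse(is.na(hit), NA_real_, expression[hit, tissue_b])
  ratio <- (a + eps) / (b + eps)
  data.table(gene = genes, intensity_a = a, intensity_b = b, ratio = ratio,
             elevated = !is.na(ratio) & ratio > threshold,
             missing = is.na(hit))
}

#' Row-wise min-max scaled heat values
#'
#' Each gene row is scaled to \[0, 1\] for heat-map display; constant rows
#' map to 0.5 by convention. Original intensities are preserved in the
#' `intensity` attribute.
#'
#' @param expression genes x tissues intensity matrix
#' @param genes gene symbols (must be present)
#' @return scaled matrix with attribute `intensity` (the original rows)
#' @export
heat_values <- function(expression, genes) {
  if (!all(genes %in% rownames(expression)))
    stop("gene(s) absent from expression matrix: ",
         paste(setdiff(genes, rownames(expression)), collapse = ", "))
  raw <- expression[genes, , drop = FALSE]
  scaled <- t(apply(raw, 1L, function(r) {
    rng <- range(r)
    if (rng[1] == rng[2]) rep(0.5, length(r))
    else (r - rng[1]) / (rng[2] - rng[1])
  }))
  dimnames(scaled) <- dimnames(raw)
  attr(scaled, "intensity") <- raw
  scaled
}
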