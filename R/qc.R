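#' Quality-control thresholds
#'
#' Defaults are the published screen: sample missingness > 10% excluded,
#' per-site Hardy-Weinberg exact p < 1e-6 excluded (sites, computed on
#' founders), trio Mendelian-error counts outside 3 SD of the cohort mean
#' excluded, samples beyond 4 SD of the mean het/hom ratio excluded, and a
#' sex check comparing reported sex against X-chromosome homozygosity
#' (inbreeding F > 0.8 called male, F < 0.2 called female). All rules are
#' strict inequalities. Kinship between each parent and the child must fall
#' in the parent-offspring window.
#'
#' @param max_missingness exclusive upper bound on per-sample missingness
#' @param hwe_alpha site-level HWE exact-test significance cutoff
#' @param mendelian_sd number of SDs defining a Mendelian-error outlier trio
#' @param hethom_sd number of SDs defining a het/hom ratio outlier sample
#' @param sex_f_female,sex_f_male X inbreeding-F cutoffs for sex inference
#' @param kinship_window parent-offspring kinship acceptance interval
#' @param hwe_on whether HWE failures remove `"sites"` (default) or
#'   `"samples"`; the screen is ambiguous in the source protocol
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(max_missingness = 0.10, hwe_alpha = 1e-6,
                          mendelian_sd = 3, hethom_sd = 4,
                          sex_f_female = 0.2, sex_f_male = 0.8,
                          kinship_window = c(0.15, 0.35),
                          hwe_on = c("sites", "samples")) {
  stopifnot(max_missingness > 0, hwe_alpha > 0, mendelian_sd > 0,
            hethom_sd > 0, sex_f_female < sex_f_male)
  structure(list(max_missingness = max_missingness, hwe_alpha = hwe_alpha,
                 mendelian_sd = mendelian_sd, hethom_sd = hethom_sd,
                 sex_f_female = sex_f_female, sex_f_male = sex_f_male,
                 kinship_window = kinship_window,
                 hwe_on = match.arg(hwe_on)),
            class = "qc_thresholds")
}

#' Fraction of missing genotypes in a sample
#'
#' @param a1,a2 allele-index vectors (NA = missing; a genotype is missing iff
#'   both alleles are)
#' @return fraction in \[0, 1\]
#' @export
missingness <- function(a1, a2 = a1) {
  if (length(a1) == 0L) stop("missingness needs at least one site")
  mean(is.na(a1) & is.na(a2))
}

#' X-chromosome inbreeding coefficient and sex inference
#'
#' F = (O_hom - E_hom) / (N - E_hom) with E_hom = sum over sites of
#' 1 - 2p(1-p). Hemizygous males, emitted as homozygous diploid X calls in
#' the common VCF dialect, drive F toward 1; diploid females toward 0.
#'
#' @param a1,a2 X-chromosome allele indices for one sample
#' @param freq per-site alternate-allele frequencies (same length)
#' @return F statistic (scalar)
#' @export
x_inbreeding_f <- function(a1, a2, freq) {
  keep <- !is.na(a1) & !is.na(a2) & !is.na(freq) & freq > 0 & freq < 1
  if (!any(keep)) stop("no informative (polymorphic, non-missing) X sites")
  a1 <- a1[keep]; a2 <- a2[keep]; p <- freq[keep]
  n <- length(a1)
  o_hom <- sum(a1 == a2)
  e_hom <- sum(1 - 2 * p * (1 - p))
  (o_hom - e_hom) / (n - e_hom)
}

#' Infer sex from the X inbreeding coefficient
#'
#' @param f X inbreeding coefficient from [x_inbreeding_f()]
#' @param thresholds a [qc_thresholds()] object
#' @return "male", "female" or "ambiguous"
#' @export
infer_sex <- function(f, thresholds = qc_thresholds()) {
  if (f > thresholds$sex_f_male) "male"
  else if (f < thresholds$sex_f_female) "female"
  else "ambiguous"
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: conditioning on the observed allele counts, sums
#' the probabilities of all heterozygote counts whose probability does not
#' exceed that of the observed configuration.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt)
#' @return exact p-value in (0, 1]
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype")
  n_a <- 2L * n_aa + n_ab          # copies of the A allele
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0L) return(1.0)      # monomorphic: single attainable config
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(h hets | n, n_a) up to the common normalizer
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - n_a - hets) / 2 + 1) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  if (is.na(obs)) stop("observed heterozygote count has wrong parity")
  min(1.0, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Mendelian consistency of a trio genotype configuration
#'
#' TRUE iff the child's unordered allele pair can be formed by one allele
#' transmitted from each parent. Vectorized over sites.
#'
#' @param f_a1,f_a2,m_a1,m_a2,c_a1,c_a2 biallelic allele indices (0/1),
#'   non-missing
#' @return logical vector
#' @export
mendelian_consistent <- function(f_a1, f_a2, m_a1, m_a2, c_a1, c_a2) {
  if (anyNA(c(f_a1, f_a2, m_a1, m_a2, c_a1, c_a2)))
    stop("mendelian_consistent requires non-missing genotypes")
  sc <- c_a1 + c_a2
  ok <- rep(FALSE, length(sc))
  for (x in 0:1) for (y in 0:1) {
    ok <- ok | (((f_a1 == x) | (f_a2 == x)) &
                ((m_a1 == y) | (m_a2 == y)) &
                (x + y == sc))
  }
  ok
}

#' Heterozygote / non-reference-homozygote ratio
#'
#' @param a1,a2 allele indices for one sample (NA pairs skipped)
#' @return ratio; `Inf` when the sample has het calls but no non-ref
#'   homozygotes (flagged extreme by the SD rule, never an error)
#' @export
het_hom_ratio <- function(a1, a2) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  n_het <- sum(a1 != a2)
  n_hom_alt <- sum(a1 == a2 & a1 == 1L)
  if (n_hom_alt == 0L) {
    if (n_het == 0L) return(0)
    return(Inf)
  }
  n_het / n_hom_alt
}

#' Method-of-moments kinship coefficient
#'
#' KING-robust within-pair estimator:
#' phi = (N_both_het - 2 * N_opposite_hom) / (N_het_i + N_het_j).
#' Expected values: duplicates ~0.5, parent-offspring ~0.25, unrelated ~0.
#'
#' @param i_a1,i_a2,j_a1,j_a2 allele indices for the two samples at shared
#'   sites
#' @param min_overlap minimum number of jointly non-missing sites
#' @return kinship estimate
#' @export
kinship <- function(i_a1, i_a2, j_a1, j_a2, min_overlap = 50L) {
  keep <- !is.na(i_a1) & !is.na(i_a2) & !is.na(j_a1) & !is.na(j_a2)
  if (sum(keep) < min_overlap)
    stop("kinship needs >= ", min_overlap, " overlapping non-missing sites")
  gi <- (i_a1 + i_a2)[keep]
  gj <- (j_a1 + j_a2)[keep]
  het_i <- gi == 1L
  het_j <- gj == 1L
  n_both_het <- sum(het_i & het_j)
  n_opp_hom <- sum(abs(gi - gj) == 2L)
  denom <- sum(het_i) + sum(het_j)
  if (denom == 0L) stop("no heterozygous sites in either sample")
  (n_both_het - 2 * n_opp_hom) / denom
}

# stack per-trio calls into one long table keyed by trio_id
.stack_cohort <- function(cohort) {
  rbindlist(lapply(names(cohort$calls), function(tid) {
    x <- as.data.table(cohort$calls[[tid]])
    x[, trio_id := tid]
    x
  }))
}

# X alternate-allele frequencies estimated from mothers (pedigree females)
.x_freqs <- function(stacked) {
  xs <- stacked[chrom == "chrX"]
  if (nrow(xs) == 0L) return(NULL)
  xs[, .(freq = {
    a <- c(m_a1, m_a2)
    a <- a[!is.na(a)]
    if (length(a)) mean(a) else NA_real_
  }), by = .(chrom, pos, ref, alt)]
}

#' Apply the full trio QC screen
#'
#' Computes per-sample metrics (missingness, het/hom ratio, X inbreeding F
#' and inferred sex), per-trio metrics (Mendelian-error counts, kinship with
#' each parent), screens sites for Hardy-Weinberg violations on founders,
#' then applies the exclusion rules in [qc_thresholds()]. A trio is retained
#' only when all three members pass every sample rule and the trio passes
#' every trio rule. SD-based rules use cohort statistics computed once on
#' the full pre-exclusion cohort (pass `cohort_stats` from a previous run to
#' re-screen a subset against the original statistics).
#'
#' @param cohort a [trio_cohort()]
#' @param thresholds a [qc_thresholds()] object
#' @param cohort_stats optional statistics from a previous [apply_qc()] run
#' @return list of class `trio_qc`: `retained` (pedigree subset), `results`
#'   (per-trio table with metrics and reason codes), `sample_metrics`,
#'   `hwe_failed_sites` (site keys removed cohort-wide), `cohort_stats`,
#'   `retained_cohort` (the cohort restricted to retained trios and
#'   HWE-passing sites)
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds(),
                     cohort_stats = NULL) {
  ped <- cohort$pedigree
  if (nrow(ped) < 2L && is.null(cohort_stats))
    stop("SD-based QC rules need a cohort of at least 2 trios")
  stacked <- .stack_cohort(cohort)
  auto <- stacked[.chrom_is_autosomal(chrom)]

  ## --- site screen: HWE exact test on founders (parents), autosomes ---
  founder_counts <- auto[, .(
    n_aa = sum(f_a1 + f_a2 == 0L, na.rm = TRUE) + sum(m_a1 + m_a2 == 0L, na.rm = TRUE),
    n_ab = sum(f_a1 + f_a2 == 1L, na.rm = TRUE) + sum(m_a1 + m_a2 == 1L, na.rm = TRUE),
    n_bb = sum(f_a1 + f_a2 == 2L, na.rm = TRUE) + sum(m_a1 + m_a2 == 2L, na.rm = TRUE)
  ), by = .(chrom, pos, ref, alt)]
  founder_counts[, p_hwe := mapply(hwe_exact_p, n_aa, n_ab, n_bb)]
  hwe_fail <- founder_counts[p_hwe < thresholds$hwe_alpha]
  hwe_failed_sites <- .site_key(hwe_fail$chrom, hwe_fail$pos,
                                hwe_fail$ref, hwe_fail$alt)
  auto <- auto[!.site_key(chrom, pos, ref, alt) %in% hwe_failed_sites]

  ## --- per-sample metrics ---
  xfreq <- .x_freqs(stacked)
  xsites <- stacked[chrom == "chrX"]
  if (!is.null(xfreq)) {
    xsites <- merge(xsites, xfreq, by = c("chrom", "pos", "ref", "alt"),
                    sort = FALSE)
  }
  sample_metrics <- rbindlist(lapply(seq_len(nrow(ped)), function(i) {
    tid <- ped$trio_id[i]
    all_t <- stacked[trio_id == tid]
    auto_t <- auto[trio_id == tid]
    x_t <- if (nrow(xsites)) xsites[trio_id == tid] else xsites
    one <- function(member, sample_id, reported) {
      a1 <- all_t[[paste0(member, "_a1")]]
      a2 <- all_t[[paste0(member, "_a2")]]
      f <- if (nrow(x_t)) {
        tryCatch(x_inbreeding_f(x_t[[paste0(member, "_a1")]],
                                x_t[[paste0(member, "_a2")]], x_t$freq),
                 error = function(e) NA_real_)
      } else NA_real_
      data.table(trio_id = tid, sample_id = sample_id, role = member,
                 reported_sex = reported,
                 missingness = missingness(a1, a2),
                 het_hom = het_hom_ratio(auto_t[[paste0(member, "_a1")]],
                                         auto_t[[paste0(member, "_a2")]]),
                 x_f = f,
                 inferred_sex = if (is.na(f)) "ambiguous"
                                else infer_sex(f, thresholds))
    }
    rbind(one("f", ped$father_id[i], "male"),
          one("m", ped$mother_id[i], "female"),
          one("c", ped$child_id[i], ped$child_sex[i]))
  }))

  ## --- per-trio metrics: Mendelian errors + kinship (autosomes) ---
  trio_metrics <- rbindlist(lapply(ped$trio_id, function(tid) {
    d <- auto[trio_id == tid]
    full <- d[!is.na(f_a1) & !is.na(m_a1) & !is.na(c_a1) &
                f_gq >= 20L & m_gq >= 20L & c_gq >= 20L]
    n_err <- if (nrow(full)) {
      sum(!mendelian_consistent(full$f_a1, full$f_a2, full$m_a1, full$m_a2,
                                full$c_a1, full$c_a2))
    } else 0L
    kin <- function(p1, p2) tryCatch(
      kinship(d[[paste0(p1, "_a1")]], d[[paste0(p1, "_a2")]],
              d[[paste0(p2, "_a1")]], d[[paste0(p2, "_a2")]]),
      error = function(e) NA_real_)
    data.table(trio_id = tid, mendel_errors = n_err,
               mendel_sites = nrow(full),
               kin_fc = kin("f", "c"), kin_mc = kin("m", "c"),
               kin_fm = kin("f", "m"))
  }))

  ## --- cohort statistics (single pass on the full pre-exclusion cohort) ---
  if (is.null(cohort_stats)) {
    finite_hh <- sample_metrics$het_hom[is.finite(sample_metrics$het_hom)]
    cohort_stats <- list(
      hethom_mean = mean(finite_hh), hethom_sd = sd(finite_hh),
      mendel_mean = mean(trio_metrics$mendel_errors),
      mendel_sd = sd(trio_metrics$mendel_errors))
  }

  ## --- exclusion rules, ordered reason codes ---
  kw <- thresholds$kinship_window
  results <- rbindlist(lapply(seq_len(nrow(ped)), function(i) {
    tid <- ped$trio_id[i]
    sm <- sample_metrics[trio_id == tid]
    tm <- trio_metrics[trio_id == tid]
    reasons <- character(0)
    if (any(sm$missingness > thresholds$max_missingness))
      reasons <- c(reasons, "missingness")
    if (any(sm$inferred_sex != sm$reported_sex))
      reasons <- c(reasons, "sex_mismatch")
    po_bad <- function(k) !is.na(k) && (k < kw[1] || k > kw[2])
    if (po_bad(tm$kin_fc) || po_bad(tm$kin_mc))
      reasons <- c(reasons, "relatedness")
    if (!is.na(cohort_stats$mendel_sd) && cohort_stats$mendel_sd >= 0 &&
        abs(tm$mendel_errors - cohort_stats$mendel_mean) >
          thresholds$mendelian_sd * cohort_stats$mendel_sd)
      reasons <- c(reasons, "mendelian")
    hh_bad <- !is.finite(sm$het_hom) |
      abs(sm$het_hom - cohort_stats$hethom_mean) >
        thresholds$hethom_sd * cohort_stats$hethom_sd
    if (any(hh_bad)) reasons <- c(reasons, "hethom")
    data.table(trio_id = tid, pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               mendel_errors = tm$mendel_errors,
               kin_fc = tm$kin_fc, kin_mc = tm$kin_mc, kin_fm = tm$kin_fm)
  }))

  retained <- ped[ped$trio_id %in% results$trio_id[results$pass], ]
  retained_calls <- lapply(cohort$calls[retained$trio_id], function(x) {
    x[!(.chrom_is_autosomal(chrom) &
          .site_key(chrom, pos, ref, alt) %in% hwe_failed_sites)]
  })
  structure(list(retained = retained, results = results,
                 sample_metrics = sample_metrics,
                 hwe_failed_sites = hwe_failed_sites,
                 cohort_stats = cohort_stats,
                 retained_cohort = if (nrow(retained))
                   trio_cohort(retained, retained_calls)
                 else structure(list(pedigree = retained, calls = list()),
                                class = "trio_cohort")),
            class = "trio_qc")
}

#' @export
print.trio_qc <- function(x, ...) {
  cat("trio QC:", nrow(x$results), "trios screened,",
      nrow(x$retained), "retained,",
      length(x$hwe_failed_sites), "sites removed by HWE\n")
  invisible(x)
}
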