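# --- synthetic trio cohort with planted DNMs, decoys and QC failures -----

#' Cohort simulation specification
#'
#' Defaults emulate the published study design: 150 case-parent trios of
#' which 20 are constructed to violate exactly one QC rule each (8
#' missingness, 4 sex mismatch, 4 relatedness, 4 Mendelian-error excess),
#' and clean trios carry Poisson(1.2) planted protein-altering DNMs with a
#' 94% missense / 6% protein-truncating consequence mix.
#'
#' @param n_trios number of case-parent trios
#' @param n_qc_fail named counts of planted QC failures over
#'   missingness / sex_mismatch / relatedness / mendelian_outlier
#' @param dnm_mean Poisson mean of planted coding protein-altering DNMs per
#'   clean case
#' @param decoys_per_class planted decoy variants per class (each violates
#'   exactly one funnel filter): low_gq, low_dp, inherited, common_maf,
#'   noncoding, parent_missing
#' @param n_background_sites shared autosomal variant sites drawn in HWE
#'   with allele frequencies ~ Uniform(0.05, 0.5)
#' @param n_x_sites shared chrX sites used by the sex check
#' @param seed integer seed
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_trios = 150L,
                        n_qc_fail = c(missingness = 8L, sex_mismatch = 4L,
                                      relatedness = 4L,
                                      mendelian_outlier = 4L),
                        dnm_mean = 1.2,
                        decoys_per_class = c(low_gq = 6L, low_dp = 6L,
                                             inherited = 6L, common_maf = 6L,
                                             noncoding = 6L,
                                             parent_missing = 6L),
                        n_background_sites = 3000L, n_x_sites = 800L,
                        seed = 1L) {
  if (any(n_qc_fail < 0L) || any(decoys_per_class < 0L) || n_trios < 0L)
    stop("all counts must be >= 0")
  if (sum(n_qc_fail) > n_trios)
    stop("infeasible spec: more planted QC failures than trios")
  structure(list(n_trios = as.integer(n_trios), n_qc_fail = n_qc_fail,
                 dnm_mean = dnm_mean, decoys_per_class = decoys_per_class,
                 n_background_sites = as.integer(n_background_sites),
                 n_x_sites = as.integer(n_x_sites), seed = as.integer(seed)),
            class = "cohort_spec")
}

# planted consequence mix: 94% missense, 6% protein-truncating
.dnm_mix <- c(missense = 0.94, stop_gained = 0.02, splice_donor = 0.015,
              start_lost = 0.01, frameshift = 0.015)

.genome_base <- function(genome, chrom, pos, len = 1L)
  as.character(subseq(genome[[chrom]], pos, pos + len - 1L))

.other_base <- function(b) {
  alt <- setdiff(c("A", "C", "G", "T"), b)
  sample(alt, 1L)
}

# ---- variant planting helpers (all return chrom/pos/ref/alt/consequence) --

.plant_missense <- function(res) {
  tx_tab <- res$transcripts
  repeat {
    tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
    cds_pos <- .cds_positions(tx)
    codon <- sample(2:(tx$n_codons - 2L), 1L)
    within <- sample(1:3, 1L)
    cpos <- cds_pos[(3L * (codon - 1L) + 1L):(3L * codon)]
    ref_codon <- .coding_base(res$genome, tx, cpos)
    ref_aa <- GENETIC_CODE[paste(ref_codon, collapse = "")]
    for (b in sample(setdiff(c("A", "C", "G", "T"), ref_codon[within]))) {
      alt_codon <- ref_codon; alt_codon[within] <- b
      alt_aa <- GENETIC_CODE[paste(alt_codon, collapse = "")]
      if (alt_aa != ref_aa && alt_aa != "*") {
        gpos <- cpos[within]
        gref <- .genome_base(res$genome, tx$chrom, gpos)
        galt <- if (tx$strand == "-") unname(.comp[b]) else b
        return(list(chrom = tx$chrom, pos = gpos, ref = gref, alt = galt,
                    consequence = "missense_variant", gene = tx$gene))
      }
    }
  }
}

.plant_stop_gained <- function(res) {
  tx_tab <- res$transcripts
  repeat {
    tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
    cds_pos <- .cds_positions(tx)
    codon <- sample(2:(tx$n_codons - 2L), 1L)
    cpos <- cds_pos[(3L * (codon - 1L) + 1L):(3L * codon)]
    ref_codon <- .coding_base(res$genome, tx, cpos)
    for (stp in sample(.stop_codons)) {
      sc <- strsplit(stp, "")[[1]]
      mis <- which(sc != ref_codon)
      if (length(mis) == 1L) {
        gpos <- cpos[mis]
        gref <- .genome_base(res$genome, tx$chrom, gpos)
        galt <- if (tx$strand == "-") unname(.comp[sc[mis]]) else sc[mis]
        return(list(chrom = tx$chrom, pos = gpos, ref = gref, alt = galt,
                    consequence = "stop_gained", gene = tx$gene))
      }
    }
  }
}

.plant_start_lost <- function(res) {
  tx_tab <- res$transcripts
  tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
  cds_pos <- .cds_positions(tx)
  within <- sample(1:3, 1L)
  gpos <- cds_pos[within]
  gref <- .genome_base(res$genome, tx$chrom, gpos)
  list(chrom = tx$chrom, pos = gpos, ref = gref, alt = .other_base(gref),
       consequence = "start_lost", gene = tx$gene)
}

.plant_splice_donor <- function(res) {
  tx_tab <- res$transcripts[vapply(res$transcripts$exon_starts,
                                   function(s) grepl(",", s), TRUE), ]
  tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
  ex <- .tx_exons(tx)
  i <- sample(nrow(ex) - 1L, 1L)
  off <- sample(1:2, 1L)
  gpos <- if (tx$strand == "+") ex$end[i] + off else ex$start[i + 1L] - off
  gref <- .genome_base(res$genome, tx$chrom, gpos)
  list(chrom = tx$chrom, pos = gpos, ref = gref, alt = .other_base(gref),
       consequence = "splice_donor_variant", gene = tx$gene)
}

.plant_frameshift <- function(res) {
  # 1-bp left-anchored deletion inside a plus-strand exon
  tx_tab <- res$transcripts[res$transcripts$strand == "+", ]
  repeat {
    tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
    ex <- .tx_exons(tx)
    wide <- which(ex$end - ex$start >= 12L)
    if (!length(wide)) next
    i <- sample(rep(wide, 2L), 1L)
    anchor <- sample((ex$start[i] + 3L):(ex$end[i] - 4L), 1L)
    gref <- .genome_base(res$genome, tx$chrom, anchor, len = 2L)
    return(list(chrom = tx$chrom, pos = anchor, ref = gref,
                alt = substr(gref, 1L, 1L),
                consequence = "frameshift_variant", gene = tx$gene))
  }
}

.plant_deep_intron <- function(res) {
  tx_tab <- res$transcripts[vapply(res$transcripts$exon_starts,
                                   function(s) grepl(",", s), TRUE), ]
  repeat {
    tx <- tx_tab[sample(nrow(tx_tab), 1L), ]
    ex <- .tx_exons(tx)
    i <- sample(nrow(ex) - 1L, 1L)
    lo <- ex$end[i] + 10L; hi <- ex$start[i + 1L] - 10L
    if (hi <= lo) next
    gpos <- sample(lo:hi, 1L)
    gref <- .genome_base(res$genome, tx$chrom, gpos)
    return(list(chrom = tx$chrom, pos = gpos, ref = gref,
                alt = .other_base(gref),
                consequence = "intron_variant", gene = tx$gene))
  }
}

.plant_by_class <- function(res, class) {
  switch(class,
         missense = .plant_missense(res),
         stop_gained = .plant_stop_gained(res),
         start_lost = .plant_start_lost(res),
         splice_donor = .plant_splice_donor(res),
         frameshift = .plant_frameshift(res),
         deep_intron = .plant_deep_intron(res),
         stop("unknown planting class: ", class))
}

#' Corrupt one trio's calls to fail a single QC rule
#'
#' Each failure class violates exactly its targeted rule with margin under
#' default thresholds: `missingness` sets 15% of the child's genotypes
#' missing (vs the 10% cutoff); `sex_mismatch` regenerates the child's chrX
#' genotypes with the opposite-sex pattern; `relatedness` replaces the
#' father's autosomal genotypes with a copy of the child's (a
#' duplicate-sample anomaly: kinship ~0.5, provably introducing no new
#' Mendelian errors); `mendelian_outlier` plants `n_errors` impossible child
#' genotypes at sites where both parents are homozygous reference.
#'
#' @param calls a [trio_calls()] table for one trio
#' @param class one of "missingness", "sex_mismatch", "relatedness",
#'   "mendelian_outlier"
#' @param child_sex reported sex of the child ("male"/"female"), used by the
#'   sex-mismatch corruption
#' @param x_freq named numeric vector of chrX alternate-allele frequencies
#'   (names = positions), used by the sex-mismatch corruption
#' @param n_errors planted Mendelian-error count for mendelian_outlier
#' @param miss_frac planted child missingness for missingness
#' @return the corrupted calls table (a copy)
#' @export
corrupt_for_qc <- function(calls, class, child_sex = "female",
                           x_freq = NULL, n_errors = 40L, miss_frac = 0.15) {
  x <- data.table::copy(as.data.table(calls))
  if (class == "missingness") {
    idx <- sample(nrow(x), round(miss_frac * nrow(x)))
    x[idx, `:=`(c_a1 = NA_integer_, c_a2 = NA_integer_,
                c_gq = NA_integer_, c_dp = NA_integer_)]
  } else if (class == "sex_mismatch") {
    xi <- which(x$chrom == "chrX")
    if (!length(xi)) stop("sex_mismatch corruption needs chrX sites")
    p <- if (!is.null(x_freq)) unname(x_freq[as.character(x$pos[xi])])
         else rep(0.3, length(xi))
    if (child_sex == "male") {
      # reported male, planted female X pattern: diploid HWE genotypes
      x[xi, `:=`(c_a1 = rbinom(length(xi), 1L, p),
                 c_a2 = rbinom(length(xi), 1L, p))]
    } else {
      # reported female, planted male (hemizygous) X pattern
      a <- rbinom(length(xi), 1L, p)
      x[xi, `:=`(c_a1 = a, c_a2 = a)]
    }
  } else if (class == "relatedness") {
    ai <- which(.chrom_is_autosomal(x$chrom))
    x[ai, `:=`(f_a1 = c_a1, f_a2 = c_a2)]
  } else if (class == "mendelian_outlier") {
    cand <- which(.chrom_is_autosomal(x$chrom) &
                    !is.na(x$f_a1) & !is.na(x$m_a1) & !is.na(x$c_a1) &
                    x$f_a1 + x$f_a2 == 0L & x$m_a1 + x$m_a2 == 0L)
    if (length(cand) < n_errors)
      stop("not enough hom-ref parent sites to plant Mendelian errors")
    idx <- sample(cand, n_errors)
    x[idx, `:=`(c_a1 = 0L, c_a2 = 1L)]
  } else {
    stop("unknown QC failure class: ", class)
  }
  x
}

#' Generate a synthetic trio cohort with planted truth
#'
#' Emits a full case-parent cohort: shared background variant sites drawn in
#' Hardy-Weinberg equilibrium with child genotypes formed by biparental
#' transmission, chrX sites encoding sex through hemizygosity, planted QC
#' failures ([corrupt_for_qc()]), planted true DNMs (child het / parents
#' hom-ref, GQ >= 20 and DP >= 10 in all members, panel MAF <= 0.01) in
#' QC-clean trios, decoy variants each violating exactly one funnel filter,
#' and two planted HWE-violating sites. Frequency panels and the score
#' table in the returned resources are populated consistently with the
#' planted classes.
#'
#' @param spec a [cohort_spec()]
#' @param resources optional bundle from [generate_resources()]; defaults to
#'   `generate_resources(spec$seed)`
#' @return list of class `synthetic_cohort`: `cohort` ([trio_cohort()]),
#'   `truth` (planted-truth ledger: `trios`, `variants`, `hwe_bad_sites`),
#'   and `resources` (with panels/scores filled in)
#' @export
generate_cohort <- function(spec = cohort_spec(), resources = NULL) {
  resources <- resources %||% generate_resources(spec$seed)
  res <- resources
  n <- spec$n_trios
  set.seed(.seed_stream(spec$seed, 307L))

  ## pedigree (country x cleft-status mix follows the recruitment profile)
  ped <- trio_pedigree(
    trio_id = sprintf("TRIO%03d", seq_len(n)),
    father_id = sprintf("F%03d", seq_len(n)),
    mother_id = sprintf("M%03d", seq_len(n)),
    child_id = sprintf("C%03d", seq_len(n)),
    child_sex = sample(c("male", "female"), n, replace = TRUE),
    cleft_status = sample(c("CL", "CLP"), n, replace = TRUE,
                          prob = c(51, 79)),
    country = sample(c("Ghana", "Nigeria"), n, replace = TRUE,
                     prob = c(104, 26)))

  ## planted QC failure assignment
  fail_classes <- rep(names(spec$n_qc_fail), times = spec$n_qc_fail)
  fail_trios <- if (length(fail_classes))
    sample(ped$trio_id, length(fail_classes)) else character(0)
  qc_class <- setNames(rep("clean", n), ped$trio_id)
  qc_class[fail_trios] <- fail_classes
  clean_trios <- ped$trio_id[qc_class == "clean"]

  ## shared background autosomal sites (HWE, freq ~ U(0.05, 0.5));
  ## positions 60-99 kb, disjoint from all transcript CDS by construction
  n_bg <- spec$n_background_sites
  bg_chrom <- sample(.autosomes(), n_bg, replace = TRUE)
  bg_pos <- integer(n_bg)
  for (ch in unique(bg_chrom)) {
    i <- which(bg_chrom == ch)
    bg_pos[i] <- sample(60000:99000, length(i))
  }
  bg_ref <- mapply(function(c, p) .genome_base(res$genome, c, p),
                   bg_chrom, bg_pos)
  bg_alt <- vapply(bg_ref, .other_base, character(1))
  bg_p <- runif(n_bg, 0.05, 0.5)

  ## two HWE-violating sites: every founder heterozygous
  hwe_chrom <- sample(.autosomes(), 2L)
  hwe_pos <- sapply(hwe_chrom, function(ch) sample(59000:59900, 1L))
  hwe_ref <- mapply(function(c, p) .genome_base(res$genome, c, p),
                    hwe_chrom, hwe_pos)
  hwe_alt <- vapply(hwe_ref, .other_base, character(1))

  ## chrX sites for the sex check
  n_x <- spec$n_x_sites
  x_pos <- sample(1000:99000, n_x)
  x_ref <- vapply(x_pos, function(p) .genome_base(res$genome, "chrX", p),
                  character(1))
  x_alt <- vapply(x_ref, .other_base, character(1))
  # common variants only, as in PLINK-style sex checks: keeps the
  # X-heterozygosity F estimator's sampling noise (~0.04 SD at 800 sites)
  # far from the fixed 0.2/0.8 inference cutoffs
  x_p <- runif(n_x, 0.2, 0.5)

  ## vectorized genotype draws: sites x trios
  draw <- function(p, n) matrix(rbinom(length(p) * n, 1L, p), nrow = length(p))
  f1 <- draw(bg_p, n); f2 <- draw(bg_p, n)
  m1 <- draw(bg_p, n); m2 <- draw(bg_p, n)
  pick <- function(a, b) ifelse(matrix(runif(length(a)), nrow = nrow(a)) < 0.5,
                                a, b)
  c_f <- pick(f1, f2)   # allele transmitted by the father
  c_m <- pick(m1, m2)
  # X: fathers hemizygous (one allele, emitted as a homozygous diploid call),
  # mothers diploid; male child inherits mother's transmitted allele only
  xf <- draw(x_p, n)
  xm1 <- draw(x_p, n); xm2 <- draw(x_p, n)
  xc_m <- pick(xm1, xm2)
  male_child <- matrix(rep(ped$child_sex == "male", each = n_x), nrow = n_x)
  xc1 <- ifelse(male_child, xc_m, xf)
  xc2 <- xc_m

  gq <- function(nr) matrix(sample(40:99, nr * n, replace = TRUE), nrow = nr)
  dp <- function(nr) matrix(rpois(nr * n, 35L), nrow = nr)

  f_gq <- gq(n_bg); m_gq <- gq(n_bg); c_gq <- gq(n_bg)
  f_dp <- dp(n_bg); m_dp <- dp(n_bg); c_dp <- dp(n_bg)
  xf_gq <- gq(n_x); xm_gq <- gq(n_x); xc_gq <- gq(n_x)
  xf_dp <- dp(n_x); xm_dp <- dp(n_x); xc_dp <- dp(n_x)

  used <- new.env(parent = emptyenv())
  mark_used <- function(ch, p) assign(.site_key(ch, p, "x", "x"), TRUE,
                                      envir = used)
  is_used <- function(ch, p) exists(.site_key(ch, p, "x", "x"), envir = used)

  calls <- vector("list", n); names(calls) <- ped$trio_id
  for (t in seq_len(n)) {
    base <- data.table(
      chrom = c(bg_chrom, hwe_chrom, rep("chrX", n_x)),
      pos = c(bg_pos, hwe_pos, x_pos), id = ".",
      ref = c(bg_ref, hwe_ref, x_ref), alt = c(bg_alt, hwe_alt, x_alt),
      f_a1 = c(f1[, t], 0L, 0L, xf[, t]),
      f_a2 = c(f2[, t], 1L, 1L, xf[, t]),
      m_a1 = c(m1[, t], 0L, 0L, xm1[, t]),
      m_a2 = c(m2[, t], 1L, 1L, xm2[, t]),
      c_a1 = c(c_f[, t], 0L, 0L, xc1[, t]),
      c_a2 = c(c_m[, t], 1L, 1L, xc2[, t]),
      f_gq = c(f_gq[, t], 80L, 80L, xf_gq[, t]),
      m_gq = c(m_gq[, t], 80L, 80L, xm_gq[, t]),
      c_gq = c(c_gq[, t], 80L, 80L, xc_gq[, t]),
      f_dp = c(f_dp[, t], 30L, 30L, xf_dp[, t]),
      m_dp = c(m_dp[, t], 30L, 30L, xm_dp[, t]),
      c_dp = c(c_dp[, t], 30L, 30L, xc_dp[, t]))
    calls[[t]] <- base
  }
  for (i in seq_len(n_bg)) mark_used(bg_chrom[i], bg_pos[i])
  for (i in 1:2) mark_used(hwe_chrom[i], hwe_pos[i])

  ## QC corruptions
  x_freq <- setNames(x_p, as.character(x_pos))
  for (tid in fail_trios) {
    sex <- ped$child_sex[ped$trio_id == tid]
    calls[[tid]] <- corrupt_for_qc(calls[[tid]], qc_class[tid],
                                   child_sex = sex, x_freq = x_freq)
  }

  ## planted true DNMs in clean trios
  plant_unique <- function(class) {
    repeat {
      v <- .plant_by_class(res, class)
      if (!is_used(v$chrom, v$pos)) {
        mark_used(v$chrom, v$pos)
        return(v)
      }
    }
  }
  truth_vars <- list()
  new_row <- function(v, trio, f_gt = c(0L, 0L), m_gt = c(0L, 0L),
                      c_gt = c(0L, 1L), gq3 = NULL, dp3 = NULL,
                      missing_member = NULL) {
    gq3 <- gq3 %||% sample(50:99, 3L, replace = TRUE)
    dp3 <- dp3 %||% sample(20:50, 3L, replace = TRUE)
    row <- data.table(chrom = v$chrom, pos = as.integer(v$pos), id = ".",
                      ref = v$ref, alt = v$alt,
                      f_a1 = f_gt[1], f_a2 = f_gt[2],
                      m_a1 = m_gt[1], m_a2 = m_gt[2],
                      c_a1 = c_gt[1], c_a2 = c_gt[2],
                      f_gq = gq3[1], m_gq = gq3[2], c_gq = gq3[3],
                      f_dp = dp3[1], m_dp = dp3[2], c_dp = dp3[3])
    if (!is.null(missing_member)) {
      for (col in paste0(missing_member, c("_a1", "_a2", "_gq", "_dp")))
        row[[col]] <- NA_integer_
    }
    calls[[trio]] <<- rbind(calls[[trio]], row)
    row
  }

  n_dnm <- rpois(length(clean_trios), spec$dnm_mean)
  for (i in seq_along(clean_trios)) {
    tid <- clean_trios[i]
    if (n_dnm[i] == 0L) next
    for (k in seq_len(n_dnm[i])) {
      cls <- sample(names(.dnm_mix), 1L, prob = .dnm_mix)
      v <- plant_unique(cls)
      new_row(v, tid)
      truth_vars[[length(truth_vars) + 1L]] <- data.table(
        trio_id = tid, chrom = v$chrom, pos = as.integer(v$pos),
        ref = v$ref, alt = v$alt, class = "true_dnm",
        consequence = v$consequence, gene = v$gene, planted_maf = 0,
        expected_drop_stage = NA_character_)
    }
  }

  ## decoys: each violates exactly one funnel filter
  decoy_stage <- c(low_gq = "quality_pass", low_dp = "quality_pass",
                   parent_missing = "quality_pass",
                   inherited = "denovo_config",
                   noncoding = "protein_altering", common_maf = "rare")
  for (cls in names(spec$decoys_per_class)) {
    for (k in seq_len(spec$decoys_per_class[[cls]])) {
      tid <- sample(clean_trios, 1L)
      v <- plant_unique(if (cls == "noncoding") "deep_intron" else "missense")
      maf <- 0
      if (cls == "low_gq") {
        new_row(v, tid, gq3 = c(80L, 80L, 15L))
      } else if (cls == "low_dp") {
        new_row(v, tid, dp3 = c(5L, 30L, 30L))
      } else if (cls == "parent_missing") {
        new_row(v, tid, missing_member = "m")
      } else if (cls == "inherited") {
        new_row(v, tid, f_gt = c(0L, 1L))
      } else if (cls == "common_maf") {
        new_row(v, tid)
        maf <- 0.05
      } else {
        new_row(v, tid)   # noncoding: clean de novo config, intronic site
      }
      truth_vars[[length(truth_vars) + 1L]] <- data.table(
        trio_id = tid, chrom = v$chrom, pos = as.integer(v$pos),
        ref = v$ref, alt = v$alt, class = paste0("decoy_", cls),
        consequence = v$consequence, gene = v$gene, planted_maf = maf,
        expected_drop_stage = decoy_stage[[cls]])
    }
  }
  truth_vars <- if (length(truth_vars)) rbindlist(truth_vars)
    else data.table(trio_id = character(0), chrom = character(0),
                    pos = integer(0), ref = character(0), alt = character(0),
                    class = character(0), consequence = character(0),
                    gene = character(0), planted_maf = numeric(0),
                    expected_drop_stage = character(0))

  ## populate frequency panels and score table
  jitter_af <- function(p) pmin(0.99, pmax(1e-4, p + rnorm(length(p), 0, 0.01)))
  bg_panel <- data.table(chrom = bg_chrom, pos = bg_pos, ref = bg_ref,
                         alt = bg_alt, af = bg_p)
  for (nm in names(res$panels)) {
    keep <- runif(n_bg) < 0.9
    res$panels[[nm]] <- rbind(
      res$panels[[nm]],
      bg_panel[keep][, af := jitter_af(af)])
  }
  common <- truth_vars[class == "decoy_common_maf"]
  if (nrow(common)) {
    res$panels$gnomad_afr <- rbind(
      res$panels$gnomad_afr,
      common[, .(chrom, pos, ref, alt, af = 0.05)])
    res$panels$thousand_genomes <- rbind(
      res$panels$thousand_genomes,
      common[, .(chrom, pos, ref, alt, af = 0.02)])
  }

  coding <- truth_vars[consequence != "intron_variant"]
  if (nrow(coding)) {
    trunc <- impact_class(coding$consequence) == "protein_truncating"
    n_c <- nrow(coding)
    cadd <- numeric(n_c)
    cadd[trunc] <- round(runif(sum(trunc), 33, 48), 1)
    bin_draw <- sample(c("top01", "top1", "top10", "lower"), sum(!trunc),
                       replace = TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
    cadd[!trunc] <- round(
      ifelse(bin_draw == "top01", runif(sum(!trunc), 30, 45),
      ifelse(bin_draw == "top1", runif(sum(!trunc), 20, 29.9),
      ifelse(bin_draw == "top10", runif(sum(!trunc), 10, 19.9),
             runif(sum(!trunc), 1, 9.9)))), 1)
    sift <- ifelse(trunc, NA_real_, round(runif(n_c, 0, 0.3), 3))
    polyphen <- ifelse(trunc, NA_real_, round(runif(n_c, 0, 1), 3))
    res$scores <- rbind(res$scores, data.table(
      chrom = coding$chrom, pos = coding$pos, ref = coding$ref,
      alt = coding$alt, cadd_phred = cadd, sift = sift, polyphen = polyphen))
  }

  ## finalize: sort each trio's calls in genome order
  chrom_order <- c(.autosomes(), "chrX")
  calls <- lapply(calls, function(x) {
    x[order(match(chrom, chrom_order), pos)]
  })

  truth <- list(
    trios = data.table(trio_id = ped$trio_id,
                       qc_class = unname(qc_class[ped$trio_id])),
    variants = truth_vars,
    hwe_bad_sites = .site_key(hwe_chrom, hwe_pos, hwe_ref, hwe_alt),
    seed = spec$seed)

  structure(list(cohort = trio_cohort(ped, calls), truth = truth,
                 resources = res, spec = spec),
            class = "synthetic_cohort")
}
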