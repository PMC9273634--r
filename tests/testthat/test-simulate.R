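test_that("resource generation is deterministic and meets the transcript
          contract", {
  res <- shared_resources()
  res2 <- generate_resources(seed = 1L)
  expect_equal(as.character(res$genome), as.character(res2$genome))
  expect_equal(as.data.frame(res$transcripts), as.data.frame(res2$transcripts))
  expect_equal(res$expression, res2$expression)

  tx <- res$transcripts
  expect_gte(nrow(tx), 20L)
  expect_setequal(unique(tx$strand), c("+", "-"))
  n_exons <- vapply(strsplit(tx$exon_starts, ","), length, integer(1))
  expect_gte(max(n_exons), 40L)
  expect_true(all(vapply(res$genome, length, integer(1)) <= 100000L))
  # gene sets include the two craniofacial terms; expression has the E10.5
  # maxillary/mandibular columns; TULP4 has no mouse ortholog row
  expect_true(all(c("GO:palate_development", "GO:neural_crest_migration")
                  %in% names(res$gene_sets)))
  expect_true(all(c("maxillary_E10.5", "mandibular_E10.5")
                  %in% colnames(res$expression)))
  expect_false("TULP4" %in% rownames(res$expression))
})

test_that("cohort generation is reproducible from (spec, seed)", {
  sim1 <- generate_cohort(small_spec(), resources = shared_resources())
  sim2 <- generate_cohort(small_spec(), resources = shared_resources())
  expect_equal(as.data.frame(sim1$cohort$pedigree),
               as.data.frame(sim2$cohort$pedigree))
  for (tid in sim1$cohort$pedigree$trio_id)
    expect_equal(as.data.frame(sim1$cohort$calls[[tid]]),
                 as.data.frame(sim2$cohort$calls[[tid]]), info = tid)
  expect_equal(as.data.frame(sim1$truth$variants),
               as.data.frame(sim2$truth$variants))
})

test_that("infeasible cohort specs and unknown corruption classes error", {
  expect_error(cohort_spec(n_trios = 10L,
                           n_qc_fail = c(missingness = 6L, sex_mismatch = 6L,
                                         relatedness = 0L,
                                         mendelian_outlier = 0L)),
               "infeasible")
  expect_error(cohort_spec(n_trios = -1L), ">= 0")
  sim <- small_sim()
  expect_error(corrupt_for_qc(sim$cohort$calls[[1]], "volcano"),
               "unknown QC failure class")
})

test_that("every planted true DNM lies in a CDS or at a canonical donor
          site", {
  sim <- default_sim()
  tx <- sim$resources$transcripts
  truth <- sim$truth$variants[sim$truth$variants$class == "true_dnm", ]
  in_cds_or_donor <- function(chrom, pos) {
    for (i in which(tx$chrom == chrom)) {
      t1 <- tx[i, ]
      ex <- denovotrio:::.tx_exons(t1)
      if (pos >= t1$cds_start && pos <= t1$cds_end &&
          any(pos >= ex$start & pos <= ex$end)) return(TRUE)
      for (j in seq_len(nrow(ex) - 1L)) {
        don <- if (t1$strand == "+") ex$end[j] + 1:2 else ex$start[j + 1L] - 1:2
        if (pos %in% don) return(TRUE)
      }
    }
    FALSE
  }
  ok <- mapply(in_cds_or_donor, truth$chrom, truth$pos)
  expect_true(all(ok))
})

test_that("planted DNM totals follow the Poisson(1.2) design", {
  sim <- default_sim()
  n_clean <- sum(sim$truth$trios$qc_class == "clean")
  expect_equal(n_clean, 130L)
  n_true <- sum(sim$truth$variants$class == "true_dnm")
  # sum of 130 Poisson(1.2) draws: within 3 * sqrt(156) of 156
  expect_lt(abs(n_true - 156), 3 * sqrt(130 * 1.2))
})

test_that("corrupt_for_qc violates exactly the targeted rule with margin", {
  sim <- small_sim()
  calls <- sim$cohort$calls[[1]]
  set.seed(99)

  m <- corrupt_for_qc(calls, "missingness")
  expect_equal(missingness(m$c_a1, m$c_a2),
               round(0.15 * nrow(calls)) / nrow(calls))
  expect_gt(missingness(m$c_a1, m$c_a2), 0.10)   # clears the cutoff
  expect_equal(missingness(m$f_a1, m$f_a2), 0)

  s <- corrupt_for_qc(calls, "sex_mismatch", child_sex = "male",
                      x_freq = setNames(rep(0.3, sum(calls$chrom == "chrX")),
                                        calls$pos[calls$chrom == "chrX"]))
  xs <- s[s$chrom == "chrX", ]
  f <- x_inbreeding_f(xs$c_a1, xs$c_a2, rep(0.3, nrow(xs)))
  expect_identical(infer_sex(f), "female")    # opposite of reported male

  r <- corrupt_for_qc(calls, "relatedness")
  auto <- r[denovotrio:::.chrom_is_autosomal(r$chrom), ]
  k <- kinship(auto$f_a1, auto$f_a2, auto$c_a1, auto$c_a2)
  expect_gt(k, 0.45)                          # duplicate-sample anomaly
  # ...which introduces no new Mendelian errors
  n_errors <- function(x) {
    x <- x[!is.na(x$f_a1) & !is.na(x$m_a1) & !is.na(x$c_a1), ]
    sum(!mendelian_consistent(x$f_a1, x$f_a2, x$m_a1, x$m_a2,
                              x$c_a1, x$c_a2))
  }
  expect_lte(n_errors(auto),
             n_errors(calls[denovotrio:::.chrom_is_autosomal(calls$chrom), ]))

  md <- corrupt_for_qc(calls, "mendelian_outlier", n_errors = 40L)
  expect_gte(n_errors(md[denovotrio:::.chrom_is_autosomal(md$chrom), ]), 40L)
})
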