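test_that("missingness is the fraction of missing genotypes", {
  expect_equal(missingness(rep(0L, 10)), 0.0)
  a <- c(rep(0L, 9), NA)
  expect_equal(missingness(a, a), 0.1)
  # 0.1 is NOT above the strict > 0.10 exclusion threshold
  expect_false(missingness(a, a) > qc_thresholds()$max_missingness)
  b <- c(rep(1L, 17), NA, NA, NA)
  expect_equal(missingness(b, b), 0.15)
  expect_true(missingness(b, b) > qc_thresholds()$max_missingness)
  expect_error(missingness(integer(0)), "at least one site")
})

test_that("X inbreeding F matches the direct formula and drives sex calls", {
  # 10 sites at p = 0.5, all homozygous: F = (10 - 5)/(10 - 5) = 1 -> male
  expect_equal(x_inbreeding_f(rep(0L, 10), rep(0L, 10), rep(0.5, 10)), 1.0)
  expect_identical(infer_sex(1.0), "male")
  # 5 het of 10 at p = 0.5: O_hom = E_hom -> F = 0 -> female
  a1 <- c(rep(0L, 5), rep(0L, 5)); a2 <- c(rep(1L, 5), rep(0L, 5))
  expect_equal(x_inbreeding_f(a1, a2, rep(0.5, 10)), 0.0)
  expect_identical(infer_sex(0.0), "female")
  # 10 sites p = 0.2, 7 hom: E_hom = 10 * 0.68 = 6.8, F = 0.2/3.2 = 0.0625
  a1 <- c(rep(0L, 7), rep(0L, 3)); a2 <- c(rep(0L, 7), rep(1L, 3))
  expect_equal(x_inbreeding_f(a1, a2, rep(0.2, 10)), (7 - 6.8) / (10 - 6.8))
  expect_identical(infer_sex(0.0625), "female")
  expect_identical(infer_sex(0.5), "ambiguous")
  expect_error(x_inbreeding_f(c(0L, 0L), c(0L, 0L), c(0, 1)),
               "no informative")
})

test_that("HWE exact p matches hand-enumerated worked examples", {
  # (2,0,2): h in {0,2,4} with multiplicities 6/48/16 -> p = 6/70
  expect_equal(hwe_exact_p(2, 0, 2), 6 / 70, tolerance = 1e-12)
  # (0,4,0): p = P(4) + P(0) = (16 + 6)/70 (P(2) = 48/70 exceeds observed)
  expect_equal(hwe_exact_p(0, 4, 0), 22 / 70, tolerance = 1e-12)
  expect_equal(hwe_exact_p(5, 0, 0), 1.0)   # monomorphic
  expect_error(hwe_exact_p(-1, 2, 0), ">= 0")
})

test_that("HWE exact p equals the enumeration oracle for n <= 50 and is
          allele-relabeling symmetric", {
  set.seed(11)
  # exhaustive sweep at small n, random configurations up to n = 50
  configs <- expand.grid(aa = 0:6, ab = 0:6, bb = 0:6)
  configs <- configs[rowSums(configs) >= 1, ]
  extra <- data.frame(aa = sample(0:20, 60, TRUE), ab = sample(0:20, 60, TRUE),
                      bb = sample(0:10, 60, TRUE))
  configs <- rbind(configs, extra[rowSums(extra) <= 50, ])
  for (i in seq_len(nrow(configs))) {
    cc <- configs[i, ]
    p <- hwe_exact_p(cc$aa, cc$ab, cc$bb)
    expect_equal(p, hwe_oracle(cc$aa, cc$ab, cc$bb), tolerance = 1e-12)
    expect_equal(p, hwe_exact_p(cc$bb, cc$ab, cc$aa), tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("mendelian_consistent agrees with the transmission oracle on all
          27 trio configurations", {
  gts <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  for (f in gts) for (m in gts) for (c in gts) {
    got <- mendelian_consistent(f[1], f[2], m[1], m[2], c[1], c[2])
    expect_identical(got, mendel_oracle(f, m, c),
                     info = sprintf("f=%s m=%s c=%s", paste(f, collapse = "/"),
                                    paste(m, collapse = "/"),
                                    paste(c, collapse = "/")))
  }
  # spec worked examples
  expect_false(mendelian_consistent(0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(mendelian_consistent(0L, 0L, 1L, 1L, 0L, 1L))
  expect_error(mendelian_consistent(NA, 0L, 0L, 0L, 0L, 1L), "non-missing")
})

test_that("het/hom ratio handles the degenerate zero-homozygote case", {
  expect_equal(het_hom_ratio(c(0L, 0L, 1L), c(1L, 1L, 1L)), 2.0)
  expect_equal(het_hom_ratio(c(1L, 1L), c(1L, 1L)), 0.0)
  expect_identical(het_hom_ratio(c(0L, 0L), c(1L, 1L)), Inf)  # flagged, no crash
})

test_that("kinship estimator hits duplicate / parent-offspring / unrelated
          targets", {
  set.seed(21)
  p <- runif(1000, 0.1, 0.5)
  f1 <- rbinom(1000, 1, p); f2 <- rbinom(1000, 1, p)
  m1 <- rbinom(1000, 1, p); m2 <- rbinom(1000, 1, p)
  pick <- function(a, b) ifelse(runif(1000) < 0.5, a, b)
  c1 <- pick(f1, f2); c2 <- pick(m1, m2)
  expect_equal(kinship(c1, c2, c1, c2), 0.5)                 # duplicate
  k_po <- kinship(f1, f2, c1, c2)
  expect_gt(k_po, 0.15); expect_lt(k_po, 0.35)               # parent-offspring
  u1 <- rbinom(1000, 1, p); u2 <- rbinom(1000, 1, p)
  k_un <- kinship(f1, f2, u1, u2)
  expect_gt(k_un, -0.1); expect_lt(k_un, 0.1)                # unrelated
  expect_error(kinship(f1[1:10], f2[1:10], c1[1:10], c2[1:10]), "overlapping")
})

test_that("apply_qc retains an all-clean cohort and excludes whole trios", {
  sim <- small_sim()
  qc <- apply_qc(sim$cohort)
  expect_equal(nrow(qc$retained), nrow(sim$cohort$pedigree))
  expect_true(all(qc$results$pass))
  expect_true(all(qc$results$reasons == ""))

  # failing father only -> entire trio excluded
  cohort2 <- sim$cohort
  tid <- cohort2$pedigree$trio_id[1]
  bad <- data.table::copy(cohort2$calls[[tid]])
  idx <- seq_len(round(0.15 * nrow(bad)))
  bad[idx, c("f_a1", "f_a2", "f_gq", "f_dp")] <- NA_integer_
  cohort2$calls[[tid]] <- bad
  qc2 <- apply_qc(cohort2)
  expect_false(tid %in% qc2$retained$trio_id)
  expect_match(qc2$results$reasons[qc2$results$trio_id == tid], "missingness")
  expect_equal(nrow(qc2$retained), nrow(sim$cohort$pedigree) - 1L)
})

test_that("apply_qc is idempotent when reusing original cohort statistics", {
  qc <- default_qc()
  qc2 <- apply_qc(qc$retained_cohort, cohort_stats = qc$cohort_stats)
  expect_equal(nrow(qc2$retained), nrow(qc$retained))
  expect_true(all(qc2$results$pass))
})

test_that("tightening thresholds never retains more trios", {
  sim <- small_sim()
  base <- apply_qc(sim$cohort)
  tighter <- list(
    qc_thresholds(max_missingness = 0.05),
    qc_thresholds(hethom_sd = 2),
    qc_thresholds(mendelian_sd = 1),
    qc_thresholds(kinship_window = c(0.2, 0.3)))
  for (th in tighter) {
    qc <- apply_qc(sim$cohort, th)
    expect_lte(nrow(qc$retained), nrow(base$retained))
  }
})

test_that("HWE screen removes planted violating sites cohort-wide", {
  # needs the full cohort: the all-heterozygote exact test only crosses
  # p < 1e-6 with a founder set of realistic size (300 here)
  sim <- default_sim()
  qc <- default_qc()
  expect_setequal(qc$hwe_failed_sites, sim$truth$hwe_bad_sites)
  remaining <- denovotrio:::.stack_cohort(qc$retained_cohort)
  keys <- denovotrio:::.site_key(remaining$chrom, remaining$pos,
                                 remaining$ref, remaining$alt)
  expect_false(any(sim$truth$hwe_bad_sites %in% keys))
})
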