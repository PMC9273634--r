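test_that("quality filter applies GQ >= 20 and DP >= 10 to all members", {
  expect_true(passes_quality(one_call(gq = c(99L, 99L, 99L),
                                      dp = c(30L, 30L, 30L))))
  expect_false(passes_quality(one_call(gq = c(99L, 99L, 19L))))  # child GQ 19
  expect_true(passes_quality(one_call(dp = c(10L, 30L, 30L))))   # inclusive
  expect_true(passes_quality(one_call(gq = c(20L, 20L, 20L))))
  expect_false(passes_quality(one_call(dp = c(9L, 30L, 30L))))
  miss <- one_call(ch = c(NA_integer_, NA_integer_))
  expect_false(passes_quality(miss))
})

test_that("de novo configuration requires hom-ref parents and an alt child", {
  expect_true(is_denovo(one_call())$denovo)                       # 0/0 0/0 0/1
  expect_false(is_denovo(one_call(f = c(0L, 1L)))$denovo)         # inherited
  homalt <- one_call(ch = c(1L, 1L))
  r <- is_denovo(homalt)
  expect_false(r$denovo)                  # autosomal double hit rejected
  expect_true(r$flagged_homalt)           # ...but surfaced for review
  # male hemizygous alt on chrX qualifies
  xcall <- one_call(chrom = "chrX", ch = c(1L, 1L))
  expect_true(is_denovo(xcall, child_sex = "male")$denovo)
  expect_false(is_denovo(xcall, child_sex = "female")$denovo)
})

test_that("max panel MAF is the maximum across panels, 0 when absent", {
  panels <- list(
    a = data.table::data.table(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "T", af = 0.005),
    b = data.table::data.table(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "T", af = 0.02))
  expect_equal(max_panel_maf("chr1", 100L, "A", "T", panels), 0.02)
  expect_equal(max_panel_maf("chr1", 999L, "A", "T", panels), 0.0)
  expect_error(max_panel_maf("chr1", 100L, "A", "T", list()), "panel")
})

test_that("indel representations are normalized before panel lookup", {
  expect_equal(normalize_variant("chr1", 100L, "AT", "AAT"),
               list(chrom = "chr1", pos = 100L, ref = "A", alt = "AA"))
  expect_equal(normalize_variant("chr1", 100L, "CAG", "CG"),
               list(chrom = "chr1", pos = 100L, ref = "CA", alt = "C"))
  expect_equal(normalize_variant("chr1", 100L, "TCC", "TCT"),
               list(chrom = "chr1", pos = 102L, ref = "C", alt = "T"))
  # a panel keyed post-normalization is hit by an unnormalized query
  panels <- list(p = data.table::data.table(chrom = "chr1", pos = 100L,
                                            ref = "CA", alt = "C", af = 0.3))
  expect_equal(max_panel_maf("chr1", 100L, "CAG", "CG", panels), 0.3)
})

test_that("MAF threshold is inclusive by default, strict behind the flag", {
  sim <- small_sim()
  qc <- apply_qc(sim$cohort)
  res <- sim$resources
  # craft a panel that pins one true DNM at exactly 0.01
  truth <- sim$truth$variants[sim$truth$variants$class == "true_dnm" &
                                sim$truth$variants$trio_id %in%
                                  qc$retained$trio_id, ][1, ]
  res$panels$evs <- rbind(res$panels$evs,
                          data.table::data.table(chrom = truth$chrom,
                                                 pos = truth$pos,
                                                 ref = truth$ref,
                                                 alt = truth$alt, af = 0.01))
  key <- paste(truth$chrom, truth$pos)
  incl <- discover_dnms(qc$retained_cohort, res)
  expect_true(key %in% paste(incl$dnms$chrom, incl$dnms$pos))
  strict <- discover_dnms(qc$retained_cohort, res, maf_inclusive = FALSE)
  expect_false(key %in% paste(strict$dnms$chrom, strict$dnms$pos))
})

test_that("noise-free recovery is exact and decoys drop at their intended
          stage", {
  sim <- small_sim()
  qc <- apply_qc(sim$cohort)
  dnm <- discover_dnms(qc$retained_cohort, sim$resources)
  truth <- sim$truth$variants
  tkey <- function(d) paste(d$trio_id, d$chrom, d$pos, d$ref, d$alt)
  true_keys <- tkey(truth[truth$class == "true_dnm", ])
  got_keys <- tkey(dnm$dnms)
  expect_setequal(got_keys, true_keys)     # precision = recall = 1

  # stage attribution: reconstruct each decoy's terminal stage from the
  # filter primitives
  stacked <- denovotrio:::.stack_cohort(qc$retained_cohort)
  decoys <- truth[grepl("^decoy_", truth$class), ]
  for (i in seq_len(nrow(decoys))) {
    d <- decoys[i, ]
    row <- stacked[stacked$trio_id == d$trio_id & stacked$chrom == d$chrom &
                     stacked$pos == d$pos, ]
    expect_equal(nrow(row), 1L, info = d$class)
    sex <- sim$cohort$pedigree$child_sex[
      sim$cohort$pedigree$trio_id == d$trio_id]
    q <- passes_quality(row)
    dn <- if (q) is_denovo(row, sex)$denovo else FALSE
    imp <- if (dn) impact_class(call_consequence(
      d$chrom, d$pos, d$ref, d$alt, sim$resources$transcripts,
      sim$resources$genome)$consequence) else NA
    pa <- isTRUE(imp %in% c("protein_truncating", "missense"))
    rare <- if (pa) max_panel_maf(d$chrom, d$pos, d$ref, d$alt,
                                  sim$resources$panels) <= 0.01 else FALSE
    dropped_at <- if (!q) "quality_pass" else if (!dn) "denovo_config"
      else if (!pa) "protein_altering" else if (!rare) "rare" else "none"
    expect_identical(dropped_at, unname(d$expected_drop_stage),
                     info = d$class)
  }
})

test_that("funnel counts are monotone and stages commute", {
  dnm <- default_dnm()
  expect_true(all(diff(dnm$funnel$retained) <= 0))
  expect_identical(dnm$funnel$stage,
                   c("raw", "quality_pass", "denovo_config",
                     "protein_altering", "rare"))
  expect_error(filter_funnel(c(raw = 1L, quality_pass = 5L,
                               denovo_config = 0L, protein_altering = 0L,
                               rare = 0L)), "non-increasing")

  # protein-altering and rare filters commute on the de novo set
  sim <- small_sim()
  qc <- apply_qc(sim$cohort)
  stacked <- denovotrio:::.stack_cohort(qc$retained_cohort)
  stacked <- merge(stacked,
                   qc$retained[, c("trio_id", "child_sex")], by = "trio_id")
  s <- stacked[passes_quality(stacked)]
  s <- s[is_denovo(s, s$child_sex)$denovo]
  pa <- vapply(seq_len(nrow(s)), function(i)
    impact_class(call_consequence(s$chrom[i], s$pos[i], s$ref[i], s$alt[i],
                                  sim$resources$transcripts,
                                  sim$resources$genome)$consequence) %in%
      c("protein_truncating", "missense"), logical(1))
  rare <- max_panel_maf(s$chrom, s$pos, s$ref, s$alt,
                        sim$resources$panels) <= 0.01
  key <- paste(s$trio_id, s$chrom, s$pos)
  expect_setequal(key[pa][rare[pa]], key[rare][pa[rare]])
})

test_that("no DNM is emitted for a QC-excluded trio", {
  sim <- default_sim()
  qc <- default_qc()
  dnm <- default_dnm()
  excluded <- qc$results$trio_id[!qc$results$pass]
  expect_false(any(dnm$dnms$trio_id %in% excluded))
})

test_that("empty cohort and zero-planting specs yield empty tables", {
  empty <- structure(list(pedigree = small_sim()$cohort$pedigree[0, ],
                          calls = list()), class = "trio_cohort")
  r <- discover_dnms(empty, shared_resources())
  expect_equal(nrow(r$dnms), 0L)
  expect_true(all(r$funnel$retained == 0L))

  spec0 <- small_spec(seed = 9L)
  spec0$dnm_mean <- 0
  spec0$decoys_per_class[] <- 0L
  sim0 <- generate_cohort(spec0, resources = shared_resources())
  qc0 <- apply_qc(sim0$cohort)
  r0 <- discover_dnms(qc0$retained_cohort, sim0$resources)
  expect_equal(nrow(r0$dnms), 0L)
  expect_equal(r0$funnel$retained[5], 0L)
})
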