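# Build a consensus table directly: `alleles` is one consensus allele (or NA)
# per molecule at the panel locus.
consensus_fixture <- function(alleles, pos = 100L, ref = "A") {
  n <- length(alleles)
  tibble::tibble(
    group_id = sprintf("g%03d", seq_len(n)),
    fragment_key = sprintf("chr_t:%d-%d", 50L + seq_len(n), 250L + seq_len(n)),
    contig = "chr_t", start = 50L + seq_len(n), end = 250L + seq_len(n),
    n_reads_top = 2L, n_reads_bottom = 2L,
    pos = pos, ref = ref, allele = alleles, is_panel = TRUE
  )
}

test_that("pileup counts molecules and excludes no-calls from both sides", {
  panel <- snv_panel()
  cons <- consensus_fixture(c(rep("A", 8), "T", "T"))
  pl <- pileup(cons, panel)
  alt <- pl[pl$allele == "T", ]
  expect_identical(alt$n_molecules, 2L)
  expect_identical(alt$total_molecules, 10L)
  # a no-call contributes to neither numerator nor denominator
  cons_nc <- consensus_fixture(c(rep("A", 8), "T", NA))
  pl_nc <- pileup(cons_nc, panel)
  expect_identical(unique(pl_nc$total_molecules), 9L)
  expect_identical(pl_nc$n_molecules[pl_nc$allele == "T"], 1L)
})

test_that("pileup alt fraction recovers the simulated vaf", {
  panel <- sim_panel()
  cfg <- test_config(panel, input_ng = 7, vaf = 0.2, seed = 61,
                     seq_error_rate = 0, lesion_rate = 0, umi_error_rate = 0)
  pl <- simulate_reads(cfg) |>
    group_reads("with_umis") |>
    collapse_groups(panel) |>
    pileup(panel)
  alt <- dplyr::semi_join(pl[pl$is_alt, ], panel, by = c("pos", "allele" = "alt"))
  n_alt <- sum(alt$n_molecules)
  n_tot <- sum(pl[!duplicated(pl$pos) & pl$is_panel, "total_molecules"])
  se <- sqrt(0.2 * 0.8 / n_tot)
  expect_lt(abs(n_alt / n_tot - 0.2), 3 * se)
})

test_that("threshold calling emits exactly the supported variants", {
  panel <- snv_panel()
  pl <- pileup(consensus_fixture(c(rep("A", 8), "T", "T")), panel)
  expect_identical(nrow(call_variants(pl, 2)), 1L)
  expect_identical(nrow(call_variants(pl, 3)), 0L)
  pl1 <- pileup(consensus_fixture(c(rep("A", 9), "T")), panel)
  expect_identical(nrow(call_variants(pl1, 2)), 0L)
  expect_identical(nrow(call_variants(pl1, 1)), 1L)
})

test_that("ungrouped pileup sees duplicated single-strand noise", {
  panel <- snv_panel()
  # 95 clean reads + 5 PCR duplicates of one lesion-bearing strand
  clean <- lapply(1:95, function(i) stats::setNames("A", 100L))
  noisy <- lapply(1:5, function(i) stats::setNames("G", 100L))
  reads <- make_reads(
    n = 100, start = 50L, end = 250L,
    strand = rep(c("top", "bottom", "top"), c(48, 47, 5)),
    umi1 = c(sprintf("A%03d", 1:95), rep("GGGG", 5)),
    umi2 = "CCCC",
    calls = c(clean, noisy),
    molecule_id = rep(c(sprintf("m%02d", 1:95), "mLES"), c(rep(1, 95), 5))
  )
  raw <- raw_pileup_call(reads, panel, vaf_threshold = 0.01)
  expect_identical(raw$alt, "G")
  expect_equal(raw$fraction, 0.05)
  # duplex calling suppresses it: within the single position group the five
  # duplicated lesion reads are outvoted by the clean majority
  called <- reads |>
    group_reads("position_only") |>
    collapse_groups(panel) |>
    pileup(panel) |>
    call_variants(1)
  expect_false("G" %in% called$alt)
  # error-free reads at a 50% molecule VAF give a ~50% raw fraction
  cfg <- test_config(snv_panel(), input_ng = 4, vaf = 0.5, seed = 67,
                     seq_error_rate = 0, lesion_rate = 0)
  sim_reads <- simulate_reads(cfg)
  raw2 <- raw_pileup_call(sim_reads, snv_panel(), vaf_threshold = 0.05)
  expect_lt(abs(raw2$fraction[raw2$pos == 100 & raw2$alt == "T"] - 0.5), 0.1)
  expect_identical(nrow(raw_pileup_call(sim_reads[0, ], panel)), 0L)
})

test_that("sensitivity is the called fraction of truth loci", {
  truth <- tibble::tibble(pos = 1:110, alt = "T")
  all_called <- tibble::tibble(pos = 1:110, alt = "T")
  expect_equal(sensitivity(all_called, truth), 1.0)
  expect_equal(sensitivity(all_called[0, ], truth), 0.0)
  expect_equal(sensitivity(all_called[1:55, ], truth), 0.5)
  # allele must match, not just position
  wrong <- tibble::tibble(pos = 1:110, alt = "G")
  expect_equal(sensitivity(wrong, truth), 0.0)
  expect_error(sensitivity(all_called, truth[0, ]), "non-empty")
})

test_that("specificity counts five theoretical false calls per position", {
  truth <- tibble::tibble(pos = 1:110, alt = "T")
  none <- tibble::tibble(pos = integer(), alt = character())
  s <- specificity_fp_per_kb(none, 46000, truth)
  expect_equal(s$specificity, 1.0)
  expect_equal(s$fp_per_kb, 0)
  expect_identical(s$theoretical_false_calls, (46000L - 110L) * 5)
  # 1000 interrogated, no expected variants -> 5000 theoretical false calls
  s2 <- specificity_fp_per_kb(none, 1000 + 110, truth)
  expect_identical(s2$theoretical_false_calls, 5000)
  # 46 false calls over 46 kb -> 1 FP/kb
  fp <- tibble::tibble(pos = 200:245, alt = "G")
  s3 <- specificity_fp_per_kb(fp, 46000, truth)
  expect_equal(s3$fp_per_kb, 1.0)
})

test_that("ROC is monotone in the threshold and AUC handles separability", {
  panel <- snv_panel()
  truth <- tibble::tibble(pos = 100L, alt = "T")
  # perfect separation: truth at 5 molecules, no noise
  pl <- pileup(consensus_fixture(c(rep("A", 5), rep("T", 5))), panel)
  perf <- roc_auc(pl, truth, 400, min_molecules = 2)
  expect_equal(perf$auc, 1.0)
  expect_equal(perf$sensitivity, 1.0)
  by_thr <- dplyr::arrange(perf$roc, threshold)
  expect_true(all(diff(by_thr$sensitivity) <= 0))
  expect_true(all(diff(by_thr$n_false_calls) <= 0))
  expect_gte(perf$auc, 0)
  expect_lte(perf$auc, 1)
  expect_identical(tidy(perf), perf$roc)
  expect_identical(glance(perf)$auc, perf$auc)
  p <- autoplot(perf)
  expect_s3_class(p, "ggplot")
})

test_that("Fisher utility builds the called-vs-missed table", {
  ht <- compare_sensitivity_fisher(60, 60, 110)
  expect_equal(ht$p.value, 1)
  ht2 <- compare_sensitivity_fisher(93, 40, 110)
  expect_lt(ht2$p.value, 1e-7)
})
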