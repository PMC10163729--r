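test_that("panel generator produces the requested composition", {
  panel <- simulate_panel(seed = 5)
  expect_identical(nrow(panel), 110L)
  expect_identical(sum(panel$class == "SNV"), 70L)
  expect_identical(sum(panel$class == "deletion"), 20L)
  expect_identical(sum(panel$class == "insertion"), 20L)
  expect_identical(panel_span(panel), 46000L)
  expect_false(anyDuplicated(panel$pos) > 0)
  # allele lengths consistent with class
  expect_true(all(nchar(panel$ref[panel$class == "deletion"]) >
                    nchar(panel$alt[panel$class == "deletion"])))
  expect_true(all(nchar(panel$ref[panel$class == "insertion"]) <
                    nchar(panel$alt[panel$class == "insertion"])))
  # reference alleles match the contig sequence
  seq <- attr(panel, "contig_seq")
  expect_identical(substring(seq, panel$pos, panel$pos),
                   substr(panel$ref, 1, 1))
})

test_that("molecule count is Poisson around the input model", {
  panel <- sim_panel()
  cfg <- test_config(panel, input_ng = 20, lcr = 0.5, vaf = 0, seed = 7)
  mol <- simulate_molecules(cfg)
  expect_lt(abs(nrow(mol) - 3000), 4 * sqrt(3000))
})

test_that("vaf = 0 molecules carry no alternative allele", {
  panel <- sim_panel()
  cfg <- test_config(panel, vaf = 0, seed = 3)
  mol <- simulate_molecules(cfg)
  alleles <- unlist(mol$genotype)
  key <- as.integer(names(alleles))
  expect_identical(unname(alleles), panel$ref[match(key, panel$pos)])
})

test_that("molecule-level alt fraction is binomially consistent with vaf", {
  panel <- snv_panel()
  # ~10^4 molecules covering the single locus
  cfg <- simulation_config(panel, input_ng = 100, lcr = 1 / 3, vaf = 0.01,
                           seed = 9)
  mol <- simulate_molecules(cfg)
  alt <- vapply(mol$genotype, function(g) any(g == "T"), logical(1))
  se <- sqrt(0.01 * 0.99 / length(alt))
  expect_lt(abs(mean(alt) - 0.01), 3 * se)
})

test_that("random-shear fragment lengths match the model", {
  model <- fragmentation_model("random_shear", mean_fragment_len = 170,
                               fragment_len_sd = 30)
  set.seed(21)
  frag <- fragment_endpoints(model, rep(5000L, 10000L), span_bp = 10000L)
  len <- frag$end - frag$start
  expect_true(all(frag$start < 5000 & frag$end >= 5000))
  expect_lt(abs(mean(len) - 170), 3 * 30 / sqrt(10000))
})

test_that("jitter-free nucleosomal cutting yields grid-period lengths", {
  model <- fragmentation_model("nucleosomal", cut_jitter_sd = 0,
                               core_cut_rate = 0)
  period <- model$core_len + model$linker_len_mean
  set.seed(22)
  frag <- fragment_endpoints(model, rep(5000L, 2000L), span_bp = 20000L)
  len <- frag$end - frag$start
  expect_true(all(len %% period == 0))
  expect_true(all(frag$start < 5000 & frag$end >= 5000))
  # finite endpoint support
  expect_lt(dplyr::n_distinct(paste(frag$start, frag$end)), 20)
})

test_that("nucleosomal cutting concentrates fragment ends", {
  nuc <- fragmentation_model("nucleosomal")
  period <- nuc$core_len + nuc$linker_len_mean
  shear <- fragmentation_model("random_shear",
                               mean_fragment_len = period * 1.14,
                               fragment_len_sd = 30)
  set.seed(23)
  f_nuc <- fragment_endpoints(nuc, rep(5000L, 10000L), span_bp = 20000L)
  f_shr <- fragment_endpoints(shear, rep(5000L, 10000L), span_bp = 20000L)
  distinct <- function(f) dplyr::n_distinct(paste(f$start, f$end))
  expect_lt(distinct(f_nuc), distinct(f_shr))
})

test_that("error-free reads reproduce their molecule's genotype", {
  panel <- sim_panel()
  cfg <- test_config(panel, vaf = 0.2, seed = 13,
                     seq_error_rate = 0, lesion_rate = 0, umi_error_rate = 0)
  mol <- simulate_molecules(cfg)
  reads <- generate_reads(mol, cfg)
  geno <- mol$genotype[match(reads$molecule_id, mol$molecule_id)]
  expect_true(all(mapply(identical, reads$calls, geno)))
  # UMI orientation: top reads report (umi_top, umi_bottom), bottom swapped
  top <- reads$strand == "top"
  umi_top <- mol$umi_top[match(reads$molecule_id, mol$molecule_id)]
  umi_bot <- mol$umi_bottom[match(reads$molecule_id, mol$molecule_id)]
  expect_identical(reads$umi1[top], umi_top[top])
  expect_identical(reads$umi2[top], umi_bot[top])
  expect_identical(reads$umi1[!top], umi_bot[!top])
  expect_identical(reads$umi2[!top], umi_top[!top])
  # reads of one molecule share the fragment key
  frag_by_mol <- tapply(paste(reads$start, reads$end), reads$molecule_id,
                        dplyr::n_distinct)
  expect_true(all(frag_by_mol == 1))
})

test_that("duplicate counts are Poisson at the configured mean", {
  panel <- snv_panel()
  cfg <- simulation_config(panel, input_ng = 100, lcr = 1 / 3, vaf = 0,
                           reads_per_molecule_mean = 5, seed = 17)
  mol <- simulate_molecules(cfg)
  reads <- generate_reads(mol, cfg)
  mean_reads <- nrow(reads) / nrow(mol)
  se <- sqrt(5 / nrow(mol))
  expect_lt(abs(mean_reads - 5), 3 * se)
})

test_that("lesions are strand-specific in molecules and reads", {
  panel <- sim_panel()
  cfg <- test_config(panel, input_ng = 4, vaf = 0, seed = 19,
                     lesion_rate = 5e-3, seq_error_rate = 0)
  mol <- simulate_molecules(cfg)
  overlap <- mapply(function(t, b) length(intersect(names(t), names(b))),
                    mol$lesions_top, mol$lesions_bottom)
  expect_true(all(overlap == 0))
  reads <- generate_reads(mol, cfg)
  # a top-strand lesion never shows in bottom-strand reads of that molecule
  with_lesion <- which(lengths(mol$lesions_top) > 0)
  for (i in with_lesion[seq_len(min(20, length(with_lesion)))]) {
    bot <- reads[reads$molecule_id == mol$molecule_id[i] &
                   reads$strand == "bottom", ]
    les_pos <- names(mol$lesions_top[[i]])
    for (v in bot$calls) expect_false(any(les_pos %in% names(v) &
                                            v[les_pos] == mol$lesions_top[[i]]))
  }
})

test_that("simulation is reproducible by seed and decorrelated across seeds", {
  panel <- sim_panel()
  cfg <- test_config(panel, seed = 31)
  r1 <- simulate_reads(cfg)
  r2 <- simulate_reads(cfg)
  expect_identical(r1, r2)
  cfg2 <- test_config(panel, seed = 32)
  r3 <- simulate_reads(cfg2)
  expect_false(identical(r1, r3))
})

test_that("configs reject inconsistent parameters", {
  panel <- snv_panel()
  expect_error(simulation_config(panel, 1, 0.5, vaf = 0.6), "0.5")
  expect_error(simulation_config(panel, 1, 1.5, vaf = 0.1), "lcr|\\[0, 1\\]")
})
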