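# Shared fixtures, all built in code.

# A small single-SNV panel with a known reference sequence.
snv_panel <- function(pos = 100L, ref = "A", alt = "T", span_bp = 400L) {
  seq <- paste(rep("A", span_bp), collapse = "")
  variant_panel("chr_t", pos, ref, alt, "SNV", span_bp = span_bp,
                contig_seq = seq)
}

# Construct a read tibble row by row.
make_reads <- function(n, start, end, strand, umi1, umi2, calls,
                       molecule_id = NULL, contig = "chr_t") {
  tibble::tibble(
    read_id = sprintf("t%03d", seq_len(n)),
    molecule_id = if (is.null(molecule_id)) sprintf("mol%03d", seq_len(n))
                  else molecule_id,
    contig = contig,
    start = as.integer(start), end = as.integer(end),
    strand = strand, umi1 = umi1, umi2 = umi2,
    calls = calls
  )
}

# The worked duplex-UMI example: 8 reads, one fragment key, two duplex UMI
# families of four reads each (two top + two bottom per family).
fig1c_reads <- function(call_allele = c(rep("A", 4), rep("A", 4)),
                        pos = 100L) {
  calls <- lapply(call_allele, function(a) stats::setNames(a, pos))
  make_reads(
    n = 8, start = 50L, end = 250L,
    strand = rep(c("top", "top", "bottom", "bottom"), 2),
    umi1 = c("AAAA", "AAAA", "CCCC", "CCCC", "GGGG", "GGGG", "TTTT", "TTTT"),
    umi2 = c("CCCC", "CCCC", "AAAA", "AAAA", "TTTT", "TTTT", "GGGG", "GGGG"),
    calls = calls,
    molecule_id = rep(c("molA", "molB"), each = 4)
  )
}

# A duplex read group over the single-SNV panel: `top` and `bottom` give the
# allele observed at the locus by each read of that strand.
duplex_group <- function(top, bottom, pos = 100L, molecule_id = "molX") {
  n <- length(top) + length(bottom)
  calls <- lapply(c(top, bottom), function(a) stats::setNames(a, pos))
  make_reads(
    n = n, start = 50L, end = 250L,
    strand = rep(c("top", "bottom"), c(length(top), length(bottom))),
    umi1 = rep("ACGT", n), umi2 = rep("TTAA", n),
    calls = calls,
    molecule_id = rep(molecule_id, n)
  )
}

# Small simulation config used across tests.
test_config <- function(panel, input_ng = 2, lcr = 0.5, vaf = 0.1,
                        seed = 42L, ...) {
  simulation_config(panel, input_ng = input_ng, lcr = lcr, vaf = vaf, seed = seed,
                    ...)
}

# Mid-size panel shared by simulation-based tests (kept small for speed).
sim_panel <- function(seed = 11L) {
  simulate_panel(n_snv = 12, n_deletion = 4, n_insertion = 4,
                 span_bp = 9000, seed = seed)
}
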