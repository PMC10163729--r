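BASES <- c("A", "C", "G", "T")

#' Describe a fragmentation regime
#'
#' Two regimes are supported. `random_shear` models sonication or enzymatic
#' fragmentation: fragment lengths are Gaussian (truncated at 50 bp) and
#' start positions uniform around the covered locus. `nucleosomal` models
#' cell-free DNA: cuts fall near linker midpoints of a fixed, phased
#' nucleosome grid (period `core_len + linker_len_mean`) with Gaussian
#' jitter, and rarely inside a core. Nucleosomal fragment lengths are set by
#' the grid, so `mean_fragment_len`/`fragment_len_sd` are informational
#' there.
#'
#' @param regime `"random_shear"` or `"nucleosomal"`.
#' @param mean_fragment_len,fragment_len_sd Fragment length distribution in
#'   bp (random shear).
#' @param core_len Nucleosome core length in bp (default 147).
#' @param linker_len_mean Mean linker length in bp (default 38).
#' @param cut_jitter_sd Gaussian jitter of cut positions around linker
#'   midpoints, bp.
#' @param core_cut_rate Probability that a cut falls inside a core instead
#'   of a linker; must be small.
#' @param multi_nucleosome_prob Probability that a fragment extends past one
#'   nucleosome unit (geometric tail on the number of units).
#' @param phase Fixed grid phase of the nucleosome array on the contig, bp.
#' @return A list of class `fragmentation_model`.
#' @export
fragmentation_model <- function(regime = c("random_shear", "nucleosomal"),
                                mean_fragment_len = 250, fragment_len_sd = 50,
                                core_len = 147L, linker_len_mean = 38L,
                                cut_jitter_sd = 5, core_cut_rate = 0.01,
                                multi_nucleosome_prob = 0.12, phase = 50L) {
  regime <- match.arg(regime)
  stopifnot(mean_fragment_len > 0, fragment_len_sd >= 0, core_len > 0,
            linker_len_mean >= 0, cut_jitter_sd >= 0,
            core_cut_rate >= 0, core_cut_rate < 0.5,
            multi_nucleosome_prob >= 0, multi_nucleosome_prob < 1)
  structure(
    list(regime = regime, mean_fragment_len = mean_fragment_len,
         fragment_len_sd = fragment_len_sd, core_len = as.integer(core_len),
         linker_len_mean = as.integer(linker_len_mean),
         cut_jitter_sd = cut_jitter_sd, core_cut_rate = core_cut_rate,
         multi_nucleosome_prob = multi_nucleosome_prob,
         phase = as.integer(phase)),
    class = "fragmentation_model"
  )
}

#' Simulation configuration
#'
#' Bundles a panel, library parameters and error model into one validated
#' configuration object. Coordinates are 0-based half-open internally and
#' 1-based in exported tabular formats.
#'
#' @param panel A panel tibble from [simulate_panel()].
#' @param input_ng Input DNA in nanograms.
#' @param lcr Library conversion rate in `[0, 1]`.
#' @param vaf Variant allele fraction of the mixture, in `[0, 0.5]`.
#' @param fragmentation A [fragmentation_model()].
#' @param umi_len Length of each strand's exogenous UMI in bases
#'   (0 disables UMIs; the study's duplex barcodes are 4-5 bp).
#' @param reads_per_molecule_mean Mean sequenced duplicates per molecule
#'   (split evenly across strands; Poisson per strand).
#' @param seq_error_rate Per-base substitution error rate at sequencing.
#' @param lesion_rate Per-base, per-strand pre-amplification damage rate
#'   (single-strand lesions, e.g. FFPE-like deamination).
#' @param umi_error_rate Per-base substitution rate inside the UMI.
#' @param seed Optional integer seed making the simulation reproducible.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(panel, input_ng, lcr, vaf,
                              fragmentation = fragmentation_model(),
                              umi_len = 4L, reads_per_molecule_mean = 5,
                              seq_error_rate = 1e-3, lesion_rate = 2e-5,
                              umi_error_rate = 1e-3, seed = NULL) {
  stopifnot(inherits(fragmentation, "fragmentation_model"))
  if (vaf < 0 || vaf > 0.5) {
    stop("`vaf` must lie in [0, 0.5]: mixture semantics break above 0.5",
         call. = FALSE)
  }
  rates <- c(seq_error_rate, lesion_rate, umi_error_rate, lcr)
  if (any(rates < 0 | rates > 1)) {
    stop("rates and `lcr` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(input_ng >= 0, umi_len >= 0, reads_per_molecule_mean >= 0)
  structure(
    list(panel = panel, input_ng = input_ng, lcr = lcr, vaf = vaf,
         fragmentation = fragmentation, umi_len = as.integer(umi_len),
         reads_per_molecule_mean = reads_per_molecule_mean,
         seq_error_rate = seq_error_rate, lesion_rate = lesion_rate,
         umi_error_rate = umi_error_rate, seed = seed),
    class = "sim_config"
  )
}

#' Draw fragment endpoints covering given loci
#'
#' Draws one fragment per entry of `locus_pos` under the given fragmentation
#' model, such that the fragment covers the locus anchor.
#'
#' @param model A [fragmentation_model()].
#' @param locus_pos Integer vector of 1-based locus anchor positions.
#' @param span_bp Contig length, used to clip fragments to the contig.
#' @param locus_width Width of the reference allele to cover (default 1).
#' @return A tibble with 0-based half-open `start`, `end` columns.
#' @export
fragment_endpoints <- function(model, locus_pos, span_bp, locus_width = 1L) {
  n <- length(locus_pos)
  if (n == 0L) return(tibble::tibble(start = integer(), end = integer()))
  if (model$regime == "random_shear") {
    len <- pmax(50L, as.integer(round(stats::rnorm(
      n, model$mean_fragment_len, model$fragment_len_sd))))
    len <- pmax(len, locus_width + 1L)
    lo <- pmax(0L, locus_pos + locus_width - 1L - len)
    hi <- locus_pos - 1L
    start <- lo + floor(stats::runif(n) * (hi - lo + 1L))
    end <- start + len
  } else {
    period <- model$core_len + model$linker_len_mean
    m <- 1L + stats::rgeom(n, 1 - model$multi_nucleosome_prob)
    k0 <- floor((locus_pos - 1L - model$phase) / period)
    k_start <- k0 - floor(stats::runif(n) * m)
    b_start <- model$phase + k_start * period
    b_end <- model$phase + (k_start + m) * period
    start <- b_start + as.integer(round(stats::rnorm(n, 0, model$cut_jitter_sd)))
    end <- b_end + as.integer(round(stats::rnorm(n, 0, model$cut_jitter_sd)))
    if (model$core_cut_rate > 0) {
      # rare cuts inside the core: uniform within the adjacent grid cell
      hit_s <- stats::runif(n) < model$core_cut_rate
      hit_e <- stats::runif(n) < model$core_cut_rate
      start[hit_s] <- b_start[hit_s] + floor(stats::runif(sum(hit_s)) * period)
      end[hit_e] <- b_end[hit_e] - floor(stats::runif(sum(hit_e)) * period)
    }
    # jitter must not uncover the anchored locus
    start <- pmin(start, locus_pos - 1L)
    end <- pmax(end, locus_pos + locus_width - 1L)
  }
  start <- pmax(start, 0L)
  end <- pmin(end, as.integer(span_bp))
  tibble::tibble(start = as.integer(start), end = as.integer(end))
}

#' Simulate double-stranded input molecules
#'
#' Draws the molecule count from a Poisson with mean
#' `molecular_count(input_ng, lcr)`, anchors each molecule at a uniformly
#' chosen panel locus, draws fragment endpoints from the fragmentation
#' model, assigns the alternative allele independently at each covered locus
#' with probability `vaf`, ligates a double-stranded UMI pair, and places
#' strand-specific pre-amplification lesions at `lesion_rate` per base.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the RNG is
#'   seeded (scoped to this call).
#' @return A tibble with one row per molecule: `molecule_id`, `contig`,
#'   `start`, `end` (0-based half-open), `umi_top`, `umi_bottom`, and
#'   list-columns `genotype`, `lesions_top`, `lesions_bottom` (named
#'   character vectors keyed by 1-based position).
#' @export
simulate_molecules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(config$seed)
  }
  sim_molecules_core(config)
}

sim_molecules_core <- function(config) {
  panel <- config$panel
  span <- panel_span(panel)
  n <- stats::rpois(1L, molecular_count(config$input_ng, config$lcr))
  if (n == 0L) return(empty_molecules())

  anchor <- sample.int(nrow(panel), n, replace = TRUE)
  width <- nchar(panel$ref[anchor])
  frag <- fragment_endpoints(config$fragmentation, panel$pos[anchor], span,
                             locus_width = width)
  mol <- tibble::tibble(
    molecule_id = sprintf("m%06d", seq_len(n)),
    contig = panel$contig[1],
    start = frag$start, end = frag$end
  )

  # covered panel loci per molecule (panel$pos is ascending)
  lo <- findInterval(mol$start, panel$pos) + 1L
  hi <- findInterval(mol$end, panel$pos)
  n_cov <- pmax(hi - lo + 1L, 0L)
  mol_idx <- rep.int(seq_len(n), n_cov)
  loc_idx <- unlist(lapply(seq_len(n)[n_cov > 0L],
                           function(i) seq.int(lo[i], hi[i])), use.names = FALSE)
  is_alt <- stats::runif(length(mol_idx)) < config$vaf
  allele <- ifelse(is_alt, panel$alt[loc_idx], panel$ref[loc_idx])
  geno_pos <- panel$pos[loc_idx]
  mol$genotype <- split_named(allele, geno_pos, mol_idx, n)

  # UMIs
  if (config$umi_len > 0L) {
    mol$umi_top <- random_umis(n, config$umi_len)
    mol$umi_bottom <- random_umis(n, config$umi_len)
  } else {
    mol$umi_top <- ""
    mol$umi_bottom <- ""
  }

  # strand-specific lesions
  len <- mol$end - mol$start
  for (strand in c("top", "bottom")) {
    k <- stats::rbinom(n, size = pmax(len, 0L), prob = config$lesion_rate)
    idx <- rep.int(seq_len(n), k)
    if (length(idx)) {
      pos <- mol$start[idx] + 1L +
        floor(stats::runif(length(idx)) * (len[idx]))
      cur <- current_allele(mol$genotype[idx], pos, panel)
      les <- mutate_base(cur)
      keep <- !duplicated(paste(idx, pos))
      col <- split_named(les[keep], pos[keep], idx[keep], n)
    } else {
      col <- rep(list(character()), n)
    }
    mol[[paste0("lesions_", strand)]] <- col
  }
  # single-strand damage only: drop bottom lesions colliding with a top one
  both <- which(lengths(mol$lesions_top) > 0L & lengths(mol$lesions_bottom) > 0L)
  for (i in both) {
    keep <- !(names(mol$lesions_bottom[[i]]) %in% names(mol$lesions_top[[i]]))
    mol$lesions_bottom[[i]] <- mol$lesions_bottom[[i]][keep]
  }
  mol
}

empty_molecules <- function() {
  tibble::tibble(
    molecule_id = character(), contig = character(),
    start = integer(), end = integer(),
    genotype = list(), umi_top = character(), umi_bottom = character(),
    lesions_top = list(), lesions_bottom = list()
  )
}

# named-character list-column: one named vector per molecule
split_named <- function(values, pos, mol_idx, n) {
  names(values) <- pos
  out <- rep(list(character()), n)
  if (length(values)) {
    sp <- split(values, factor(mol_idx, levels = seq_len(n)))
    out[as.integer(names(sp))] <- sp
  }
  out
}

random_umis <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# allele currently carried at `pos` given per-molecule genotype vectors
current_allele <- function(genotype_list, pos, panel) {
  out <- ref_base_at(panel, pos)
  key <- as.character(pos)
  for (i in seq_along(pos)) {
    g <- genotype_list[[i]]
    if (length(g) && key[i] %in% names(g)) out[i] <- g[[key[i]]]
  }
  out
}

# substitute with a uniformly chosen different base (first base of indel alleles)
mutate_base <- function(cur) {
  first <- substr(cur, 1L, 1L)
  idx <- match(first, BASES)
  idx[is.na(idx)] <- sample.int(4L, sum(is.na(idx)), replace = TRUE)
  shift <- sample.int(3L, length(cur), replace = TRUE)
  BASES[(idx - 1L + shift) %% 4L + 1L]
}

#' Generate duplicated, strand-tracked sequencing reads
#'
#' For each molecule the duplicate count per strand is Poisson with mean
#' `reads_per_molecule_mean / 2` (zero is allowed and produces simplex or
#' dropped molecules). Each read copies the molecule's alleles, applies its
#' strand's lesions, then independent per-base substitution errors at
#' `seq_error_rate`. Top-strand reads report the UMI pair as
#' `(umi_top, umi_bottom)`, bottom-strand reads as `(umi_bottom, umi_top)`;
#' observed UMIs carry per-base errors at `umi_error_rate`.
#'
#' Runs on the current RNG state; use [simulate_reads()] for a seeded
#' molecules-plus-reads pipeline.
#'
#' @param molecules Output of [simulate_molecules()].
#' @param config The same [simulation_config()].
#' @return A tibble with one row per read: `read_id`, `molecule_id`,
#'   `contig`, `start`, `end`, `strand`, `umi1`, `umi2`, and a `calls`
#'   list-column of named character vectors (1-based position -> observed
#'   allele; positions not listed are implicitly reference).
#' @export
generate_reads <- function(molecules, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(molecules)
  if (n == 0L) return(empty_reads())
  half <- config$reads_per_molecule_mean / 2
  n_top <- stats::rpois(n, half)
  n_bot <- stats::rpois(n, half)

  # per-molecule per-strand base call sets (genotype overridden by lesions)
  calls_strand <- function(geno, lesions) {
    mapply(function(g, l) { g[names(l)] <- l; g },
           geno, lesions, SIMPLIFY = FALSE)
  }
  calls_top <- calls_strand(molecules$genotype, molecules$lesions_top)
  calls_bot <- calls_strand(molecules$genotype, molecules$lesions_bottom)

  idx <- c(rep.int(seq_len(n), n_top), rep.int(seq_len(n), n_bot))
  strand <- rep(c("top", "bottom"), c(sum(n_top), sum(n_bot)))
  if (length(idx) == 0L) return(empty_reads())
  reads <- tibble::tibble(
    read_id = sprintf("r%07d", seq_along(idx)),
    molecule_id = molecules$molecule_id[idx],
    contig = molecules$contig[idx],
    start = molecules$start[idx], end = molecules$end[idx],
    strand = strand
  )
  calls <- c(calls_top[idx[strand == "top"]], calls_bot[idx[strand == "bottom"]])

  # sequencing errors
  if (config$seq_error_rate > 0) {
    len <- reads$end - reads$start
    k <- stats::rbinom(nrow(reads), size = pmax(len, 0L),
                       prob = config$seq_error_rate)
    for (i in which(k > 0L)) {
      pos <- reads$start[i] + 1L + floor(stats::runif(k[i]) * len[i])
      pos <- unique(pos)
      key <- as.character(pos)
      cur <- calls[[i]][key]
      miss <- is.na(cur)
      cur[miss] <- ref_base_at(config$panel, pos[miss])
      err <- mutate_base(cur)
      v <- calls[[i]]
      v[key] <- err
      calls[[i]] <- v
    }
  }
  reads$calls <- calls

  # observed UMIs in read orientation, with barcode errors
  u1 <- ifelse(reads$strand == "top",
               molecules$umi_top[idx], molecules$umi_bottom[idx])
  u2 <- ifelse(reads$strand == "top",
               molecules$umi_bottom[idx], molecules$umi_top[idx])
  if (config$umi_len > 0L && config$umi_error_rate > 0) {
    u1 <- garble_umis(u1, config$umi_error_rate)
    u2 <- garble_umis(u2, config$umi_error_rate)
  }
  reads$umi1 <- u1
  reads$umi2 <- u2
  reads[c("read_id", "molecule_id", "contig", "start", "end",
          "strand", "umi1", "umi2", "calls")]
}

garble_umis <- function(umis, rate) {
  len <- nchar(umis[1])
  k <- stats::rbinom(length(umis), size = len, prob = rate)
  for (i in which(k > 0L)) {
    p <- unique(1L + floor(stats::runif(k[i]) * len))
    ch <- strsplit(umis[i], "", fixed = TRUE)[[1]]
    ch[p] <- mutate_base(ch[p])
    umis[i] <- paste(ch, collapse = "")
  }
  umis
}

empty_reads <- function() {
  tibble::tibble(
    read_id = character(), molecule_id = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    umi1 = character(), umi2 = character(), calls = list()
  )
}

#' Simulate molecules and reads in one seeded call
#'
#' @param config A [simulation_config()]; `config$seed` (when set) makes the
#'   full molecules-plus-reads simulation reproducible.
#' @return A read tibble as from [generate_reads()].
#' @examples
#' panel <- simulate_panel(n_snv = 5, n_deletion = 0, n_insertion = 0,
#'                         span_bp = 5000, seed = 1)
#' cfg <- simulation_config(panel, input_ng = 0.5, lcr = 0.5, vaf = 0.1,
#'                          seed = 7)
#' reads <- simulate_reads(cfg)
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(config$seed)
  }
  molecules <- sim_molecules_core(config)
  generate_reads(molecules, config)
}

#' Flatten read base calls to a long tibble
#'
#' @param reads A read tibble with a `calls` list-column.
#' @return A tibble with one row per recorded (read, position) call:
#'   `read_id`, `pos` (1-based), `allele`.
#' @export
calls_long <- function(reads) {
  k <- lengths(reads$calls)
  flat <- unlist(reads$calls, use.names = TRUE)
  tibble::tibble(
    read_id = rep.int(reads$read_id, k),
    pos = as.integer(names(flat)),
    allele = unname(flat)
  )
}
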