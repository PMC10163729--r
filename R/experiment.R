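#' Preset simulation configurations for FF, FFPE and cfDNA
#'
#' Ships the three study conditions as ready-made configurations:
#' fresh-frozen tissue DNA (`"FF"`, 100 ng, random shear, low damage), FFPE
#' DNA (`"FFPE"`, 25 ng, random shear, elevated single-strand lesion rate)
#' and cell-free DNA (`"cfDNA"`, 12.5 ng, nucleosome-guided fragmentation,
#' ~170 bp fragments). Library conversion rates are calibrated so the
#' expected molecule counts land near the average molecular yields of the
#' three conditions (roughly 1200, 1050 and 2250 molecules). Every field can
#' be overridden through `...` (passed to [simulation_config()]).
#'
#' @param type `"FF"`, `"FFPE"` or `"cfDNA"`.
#' @param panel A panel tibble; defaults to `simulate_panel(seed = panel_seed)`.
#' @param vaf Variant allele fraction of the mixture (the study mixed at
#'   0.05%-2%).
#' @param seed Simulation seed.
#' @param panel_seed Seed for the default panel.
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A [simulation_config()].
#' @export
preset_config <- function(type = c("FF", "FFPE", "cfDNA"), panel = NULL,
                          vaf = 0.005, seed = NULL, panel_seed = 1L, ...) {
  type <- match.arg(type)
  if (is.null(panel)) panel <- simulate_panel(seed = panel_seed)
  preset <- switch(type,
    FF = list(input_ng = 100, lcr = 0.04, lesion_rate = 2e-5,
              fragmentation = fragmentation_model("random_shear",
                                                  mean_fragment_len = 250,
                                                  fragment_len_sd = 50)),
    FFPE = list(input_ng = 25, lcr = 0.14, lesion_rate = 5e-4,
                fragmentation = fragmentation_model("random_shear",
                                                    mean_fragment_len = 220,
                                                    fragment_len_sd = 50)),
    cfDNA = list(input_ng = 12.5, lcr = 0.6, lesion_rate = 2e-5,
                 fragmentation = fragmentation_model("nucleosomal"))
  )
  args <- utils::modifyList(
    c(list(panel = panel, vaf = vaf, seed = seed), preset),
    list(...)
  )
  do.call(simulation_config, args)
}

#' Run the end-to-end grouping-mode comparison on synthetic data
#'
#' Simulates reads from `config`, groups them under both modes
#' (position-only and position+UMI), collapses each to duplex consensus
#' molecules, piles up, computes performance (sensitivity, FP/kb, ROC, AUC)
#' per mode, and measures the collision rate against simulator truth. Fully
#' reproducible given `config$seed`.
#'
#' @param config A [simulation_config()] (see [preset_config()]).
#' @param min_reads,min_consistency Consensus parameters.
#' @param min_molecules Operating calling threshold (default 2 molecules).
#' @param max_umi_mismatch UMI clustering tolerance.
#' @param modes Grouping modes to compare.
#' @return An object of class `duplex_experiment`: a list with `reads`,
#'   per-mode `pileups` and `performance` (`duplex_performance` objects),
#'   `collision` (one-row tibble), `comparison` (side-by-side metric table)
#'   and `counts` (molecule/read/group diagnostics).
#' @examples
#' \donttest{
#' panel <- simulate_panel(seed = 1)
#' exp <- run_experiment(preset_config("cfDNA", panel = panel, vaf = 0.02,
#'                                     seed = 3))
#' exp$comparison
#' }
#' @export
run_experiment <- function(config, min_reads = 3L, min_consistency = 0.70,
                           min_molecules = 2L, max_umi_mismatch = 1L,
                           modes = c("with_umis", "position_only")) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) {
    stop("`config$seed` must be set: experiments are reproducible by contract",
         call. = FALSE)
  }
  panel <- config$panel
  span <- panel_span(panel)
  truth <- panel[c("pos", "alt")]
  reads <- simulate_reads(config)

  pileups <- list()
  performance <- list()
  counts <- list()
  for (mode in modes) {
    grouped <- group_reads(reads, mode, max_umi_mismatch)
    groups <- summarize_groups(grouped)
    cons <- collapse_groups(grouped, panel, min_reads, min_consistency)
    pl <- pileup(cons, panel)
    pileups[[mode]] <- pl
    performance[[mode]] <- roc_auc(pl, truth, span, min_molecules)
    counts[[mode]] <- tibble::tibble(
      mode = mode,
      n_reads = nrow(reads),
      n_groups = nrow(groups),
      n_duplex = sum(groups$duplexity == "duplex"),
      n_consensus = dplyr::n_distinct(cons$group_id)
    )
  }
  comparison <- purrr::imap(performance, function(p, mode) {
    dplyr::bind_cols(tibble::tibble(mode = mode), glance(p))
  }) |>
    dplyr::bind_rows()

  structure(
    list(config = config, reads = reads, pileups = pileups,
         performance = performance,
         collision = collision_rate(reads),
         comparison = comparison,
         counts = dplyr::bind_rows(counts)),
    class = "duplex_experiment"
  )
}

#' @export
print.duplex_experiment <- function(x, ...) {
  cat("<duplex_experiment>\n")
  cat(sprintf("  %d reads; collision rate %.3f\n",
              nrow(x$reads), x$collision$collision_rate))
  print(x$comparison)
  invisible(x)
}

#' One-row-per-mode summary of an experiment
#'
#' @param x A `duplex_experiment` object.
#' @param ... Unused.
#' @return The comparison tibble (mode, auc, sensitivity, specificity,
#'   fp_per_kb) with the collision rate attached.
#' @method glance duplex_experiment
#' @export
glance.duplex_experiment <- function(x, ...) {
  dplyr::mutate(x$comparison, collision_rate = x$collision$collision_rate)
}
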