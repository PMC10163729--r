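#' Pileup of duplex consensus molecules
#'
#' Counts, per position and allele, the consensus molecules supporting that
#' allele. No-call positions contribute to neither the numerator nor the
#' denominator; the per-position molecule total is the number of covering
#' consensus molecules minus its no-calls.
#'
#' @param consensus Output of [collapse_groups()].
#' @param panel The panel tibble.
#' @return A tibble with one row per observed (position, allele):
#'   `contig`, `pos`, `ref`, `allele`, `n_molecules`, `total_molecules`,
#'   `is_alt`, `is_panel`.
#' @export
pileup <- function(consensus, panel) {
  if (nrow(consensus) == 0L) {
    return(tibble::tibble(
      contig = character(), pos = integer(), ref = character(),
      allele = character(), n_molecules = integer(),
      total_molecules = integer(), is_alt = logical(), is_panel = logical()
    ))
  }
  groups <- dplyr::distinct(consensus, .data$group_id, .data$start, .data$end)
  starts <- sort(groups$start)
  ends <- sort(groups$end)

  by_pos <- consensus |>
    dplyr::group_by(.data$contig, .data$pos, .data$ref, .data$is_panel) |>
    dplyr::summarise(n_nocall = sum(is.na(.data$allele)), .groups = "drop") |>
    dplyr::mutate(
      coverage = findInterval(.data$pos - 1L, starts) -
        findInterval(.data$pos - 1L, ends),
      total_molecules = .data$coverage - .data$n_nocall
    )

  consensus |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$contig, .data$pos, .data$ref, .data$is_panel,
                 .data$allele, name = "n_molecules") |>
    dplyr::left_join(
      by_pos[c("contig", "pos", "total_molecules")],
      by = c("contig", "pos")) |>
    dplyr::mutate(is_alt = .data$allele != .data$ref) |>
    dplyr::arrange(.data$pos, .data$allele)
}

#' Call variants from a molecule-count pileup
#'
#' Emits a call for every (position, alternative allele) supported by at
#' least `min_molecules` consensus molecules.
#'
#' @param pileup_tbl Output of [pileup()].
#' @param min_molecules Minimum supporting molecules (default 2).
#' @return A tibble of calls: `contig`, `pos`, `ref`, `alt`, `n_support`,
#'   `total_molecules`.
#' @export
call_variants <- function(pileup_tbl, min_molecules = 2L) {
  stopifnot(min_molecules >= 1)
  pileup_tbl |>
    dplyr::filter(.data$is_alt, .data$n_molecules >= min_molecules) |>
    dplyr::transmute(.data$contig, .data$pos, .data$ref, alt = .data$allele,
                     n_support = .data$n_molecules, .data$total_molecules)
}

#' Variant calling without read grouping
#'
#' The no-grouping baseline: per-position allele fractions are computed
#' directly over the raw reads (no deduplication, no consensus) and a call
#' is made when the fraction of reads supporting a non-reference allele
#' reaches `vaf_threshold`. PCR-duplicated errors and single-strand lesions
#' remain visible to this caller.
#'
#' @param reads A read tibble.
#' @param panel The panel tibble.
#' @param vaf_threshold Minimum read fraction to call (default 0.01).
#' @return A tibble of calls: `contig`, `pos`, `ref`, `alt`, `n_reads`,
#'   `coverage`, `fraction`.
#' @export
raw_pileup_call <- function(reads, panel, vaf_threshold = 0.01) {
  if (nrow(reads) == 0L) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          n_reads = integer(), coverage = integer(),
                          fraction = double()))
  }
  starts <- sort(reads$start)
  ends <- sort(reads$end)
  long <- calls_long(reads)
  refs <- tibble::tibble(pos = sort(unique(long$pos))) |>
    dplyr::left_join(panel[c("pos", "ref")], by = "pos") |>
    dplyr::mutate(ref = ifelse(is.na(.data$ref), ref_base_at(panel, .data$pos),
                               .data$ref))
  long |>
    dplyr::left_join(refs, by = "pos") |>
    dplyr::filter(.data$allele != .data$ref) |>
    dplyr::count(.data$pos, .data$ref, .data$allele, name = "n_reads") |>
    dplyr::mutate(
      contig = reads$contig[1],
      coverage = findInterval(.data$pos - 1L, starts) -
        findInterval(.data$pos - 1L, ends),
      fraction = .data$n_reads / .data$coverage
    ) |>
    dplyr::filter(.data$fraction >= vaf_threshold) |>
    dplyr::transmute(.data$contig, .data$pos, .data$ref, alt = .data$allele,
                     .data$n_reads, .data$coverage, .data$fraction)
}

#' Sensitivity of a call set against truth loci
#'
#' Fraction of confirmed (truth) variants that were called, matching on
#' position and alternative allele.
#'
#' @param calls A call tibble with `pos` and `alt` columns.
#' @param truth_loci Truth tibble with `pos` and `alt` columns (a panel
#'   tibble works).
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(calls, truth_loci) {
  if (nrow(truth_loci) == 0L) stop("`truth_loci` must be non-empty", call. = FALSE)
  hit <- dplyr::semi_join(truth_loci, calls, by = c("pos", "alt"))
  nrow(hit) / nrow(truth_loci)
}

#' Specificity and false positives per kilobase
#'
#' False calls are calls absent from the truth set. The number of
#' theoretically possible false calls is the number of interrogated
#' positions without an expected variant multiplied by 5 (three alternative
#' bases, an insertion and a deletion per position). Specificity is one
#' minus the ratio of false calls to that theoretical maximum; for
#' interpretability the same false-call count is also expressed per 1 kb of
#' interrogated territory.
#'
#' @param calls A call tibble with `pos` and `alt` columns.
#' @param interrogated_positions Number of interrogated positions (panel
#'   span in bp).
#' @param truth_loci Truth tibble with `pos` and `alt` columns.
#' @return A one-row tibble: `n_false_calls`, `theoretical_false_calls`,
#'   `specificity`, `fp_per_kb`.
#' @export
specificity_fp_per_kb <- function(calls, interrogated_positions, truth_loci) {
  stopifnot(interrogated_positions > 0)
  false_calls <- calls |>
    dplyr::anti_join(truth_loci, by = c("pos", "alt")) |>
    dplyr::distinct(.data$pos, .data$alt)
  n_false <- nrow(false_calls)
  theoretical <- (interrogated_positions - dplyr::n_distinct(truth_loci$pos)) * 5
  tibble::tibble(
    n_false_calls = n_false,
    theoretical_false_calls = theoretical,
    specificity = 1 - n_false / theoretical,
    fp_per_kb = n_false / (interrogated_positions / 1000)
  )
}

#' ROC curve and AUC over the molecule-support threshold
#'
#' Sweeps the required number of supporting molecules from 1 to one past the
#' maximum observed count. For each threshold, sensitivity is the fraction
#' of truth loci whose true alternative allele reaches the threshold, and
#' the false-call rate is the number of non-truth alternative alleles
#' reaching it divided by the theoretical number of possible false calls
#' (the specificity complement). `(0, 0)` and `(1, 1)` anchor the curve and
#' the AUC is obtained by trapezoidal integration.
#'
#' @param pileup_tbl Output of [pileup()].
#' @param truth_loci Truth tibble with `pos` and `alt` columns.
#' @param interrogated_positions Number of interrogated positions.
#' @param min_molecules Operating threshold at which point metrics
#'   (sensitivity, specificity, FP/kb) are reported (default 2).
#' @return An object of class `duplex_performance`: a list with `roc`
#'   (tibble of `threshold`, `n_false_calls`, `false_call_rate`,
#'   `sensitivity`), `auc`, and the operating-point metrics.
#' @export
roc_auc <- function(pileup_tbl, truth_loci, interrogated_positions,
                    min_molecules = 2L) {
  stopifnot(nrow(pileup_tbl) > 0, nrow(truth_loci) > 0)
  alt <- dplyr::filter(pileup_tbl, .data$is_alt)
  truth_n <- truth_loci |>
    dplyr::left_join(alt[c("pos", "allele", "n_molecules")],
                     by = c("pos", "alt" = "allele")) |>
    dplyr::mutate(n_molecules = dplyr::coalesce(.data$n_molecules, 0L)) |>
    dplyr::pull("n_molecules")
  noise_n <- alt |>
    dplyr::anti_join(truth_loci, by = c("pos", "allele" = "alt")) |>
    dplyr::pull("n_molecules")
  theoretical <- (interrogated_positions - dplyr::n_distinct(truth_loci$pos)) * 5

  max_n <- max(c(truth_n, noise_n, 1L))
  thresholds <- seq_len(max_n + 1L)
  roc <- tibble::tibble(
    threshold = thresholds,
    n_false_calls = vapply(thresholds, function(t) sum(noise_n >= t), double(1)),
    false_call_rate = .data$n_false_calls / theoretical,
    sensitivity = vapply(thresholds, function(t) mean(truth_n >= t), double(1))
  ) |>
    dplyr::arrange(.data$false_call_rate, .data$sensitivity)

  x <- c(0, roc$false_call_rate, 1)
  y <- c(0, roc$sensitivity, 1)
  ord <- order(x, y)
  auc <- sum(diff(x[ord]) * (utils::head(y[ord], -1) + utils::tail(y[ord], -1)) / 2)

  op_calls <- call_variants(pileup_tbl, min_molecules)
  op_spec <- specificity_fp_per_kb(op_calls, interrogated_positions, truth_loci)
  structure(
    list(roc = roc, auc = auc,
         min_molecules = as.integer(min_molecules),
         sensitivity = sensitivity(op_calls, truth_loci),
         specificity = op_spec$specificity,
         fp_per_kb = op_spec$fp_per_kb,
         n_truth = nrow(truth_loci),
         interrogated_positions = interrogated_positions),
    class = "duplex_performance"
  )
}

#' @export
print.duplex_performance <- function(x, ...) {
  cat("<duplex_performance>\n")
  cat(sprintf("  AUC: %.4f\n", x$auc))
  cat(sprintf("  at threshold >= %d molecules: sensitivity %s, FP/kb %.3f\n",
              x$min_molecules, percent_label(x$sensitivity), x$fp_per_kb))
  invisible(x)
}

#' Tidy the ROC points of a performance report
#'
#' @param x A `duplex_performance` object.
#' @param ... Unused.
#' @return The ROC tibble (`threshold`, `n_false_calls`, `false_call_rate`,
#'   `sensitivity`).
#' @method tidy duplex_performance
#' @export
tidy.duplex_performance <- function(x, ...) {
  x$roc
}

#' One-row summary of a performance report
#'
#' @param x A `duplex_performance` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `min_molecules`, `sensitivity`,
#'   `specificity`, `fp_per_kb`.
#' @method glance duplex_performance
#' @export
glance.duplex_performance <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, min_molecules = x$min_molecules,
    sensitivity = x$sensitivity, specificity = x$specificity,
    fp_per_kb = x$fp_per_kb
  )
}

#' Plot the ROC curve of a performance report
#'
#' @param object A `duplex_performance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot duplex_performance
#' @export
autoplot.duplex_performance <- function(object, ...) {
  df <- tibble::tibble(
    false_call_rate = c(0, object$roc$false_call_rate, 1),
    sensitivity = c(0, object$roc$sensitivity, 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$false_call_rate, .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "False-call rate (fraction of theoretical false calls)",
      y = "Sensitivity",
      title = sprintf("ROC over molecule-support threshold (AUC = %.3f)",
                      object$auc)
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1))
}

#' Fisher test comparing the sensitivity of two calling configurations
#'
#' Builds the 2x2 contingency table (called vs missed truth loci, by mode)
#' and applies Fisher's exact test.
#'
#' @param n_called_a,n_called_b Truth loci called under each mode.
#' @param n_truth Total number of truth loci (same panel for both modes).
#' @return The `htest` object from [stats::fisher.test()].
#' @export
compare_sensitivity_fisher <- function(n_called_a, n_called_b, n_truth) {
  stopifnot(n_called_a <= n_truth, n_called_b <= n_truth)
  tab <- matrix(c(n_called_a, n_truth - n_called_a,
                  n_called_b, n_truth - n_called_b), nrow = 2)
  stats::fisher.test(tab)
}
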