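#' Measure the mapping-position collision rate
#'
#' A collision is two or more distinct input molecules sharing the same
#' fragment mapping coordinates, indistinguishable by position-only
#' grouping. Reads are grouped by position alone; a position group
#' "collides" when it contains at least two distinct molecules, resolved
#' from simulator truth (`molecule_id`) when available and from UMI
#' clustering otherwise. The collision rate is the fraction of position
#' groups that display at least one collision.
#'
#' @param reads A read tibble.
#' @param identity `"auto"` (truth `molecule_id` when present, else UMIs),
#'   `"molecule_id"`, or `"umi"`.
#' @param max_umi_mismatch Mismatch tolerance when identity comes from UMI
#'   clustering.
#' @return A one-row tibble: `n_position_groups`, `n_molecules`
#'   (position+identity groups), `n_colliding_groups`, `collision_rate`,
#'   `count_discrepancy` = (n_molecules - n_position_groups) /
#'   n_position_groups.
#' @export
collision_rate <- function(reads, identity = c("auto", "molecule_id", "umi"),
                           max_umi_mismatch = 1L) {
  identity <- match.arg(identity)
  if (identity == "auto") {
    identity <- if ("molecule_id" %in% names(reads)) "molecule_id" else "umi"
  }
  key <- paste0(reads$contig, ":", reads$start, "-", reads$end)
  if (identity == "molecule_id") {
    if (!"molecule_id" %in% names(reads)) {
      stop("no `molecule_id` column; use UMI-based identity", call. = FALSE)
    }
    mol <- reads$molecule_id
  } else {
    grouped <- group_reads(reads, "with_umis", max_umi_mismatch)
    mol <- grouped$group_id
  }
  per_key <- tibble::tibble(key = key, mol = mol) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_mol = dplyr::n_distinct(.data$mol), .groups = "drop")
  n_pos <- nrow(per_key)
  n_mol <- sum(per_key$n_mol)
  tibble::tibble(
    n_position_groups = n_pos,
    n_molecules = n_mol,
    n_colliding_groups = sum(per_key$n_mol >= 2L),
    collision_rate = if (n_pos > 0) sum(per_key$n_mol >= 2L) / n_pos else NA_real_,
    count_discrepancy = if (n_pos > 0) (n_mol - n_pos) / n_pos else NA_real_
  )
}

#' Merge read sets as an in-silico sample mix
#'
#' Multiset union mirroring FASTQ concatenation: reads keep their records,
#' read and molecule identifiers are prefixed per source sample so that
#' molecules from different samples never alias, and no cross-sample
#' deduplication is performed before grouping.
#'
#' @param read_sets A list of read tibbles.
#' @return One read tibble.
#' @export
merge_read_sets <- function(read_sets) {
  stopifnot(length(read_sets) >= 1)
  tagged <- purrr::imap(read_sets, function(rs, i) {
    rs$read_id <- paste0("s", i, "_", rs$read_id)
    if ("molecule_id" %in% names(rs)) {
      rs$molecule_id <- paste0("s", i, "_", rs$molecule_id)
    }
    rs
  })
  dplyr::bind_rows(tagged)
}

#' Enumerate an in-silico dilution series
#'
#' Merges a variant-bearing sample with subsets of variant-free background
#' samples, emulating FASTQ concatenation. Backgrounds are sorted by input
#' amount (descending) and subsets enumerated in binary-counter order; only
#' the first combination per total input amount is kept, and successive
#' totals must differ by at least `min_step_ng` (the study used 20 ng for
#' FF, 10 ng for FFPE and 5 ng for cfDNA).
#'
#' @param variant_reads Read tibble of the variant-bearing sample.
#' @param variant_input_ng Its input amount in ng.
#' @param backgrounds A tibble with list-column `reads` and column
#'   `input_ng`, one row per background sample. May have zero rows.
#' @param min_step_ng Minimum difference between successive total inputs.
#' @return A tibble with one row per retained combination: `combo_id`,
#'   `total_input_ng`, `n_backgrounds`, `background_idx` (list-column of
#'   indices into `backgrounds`), `reads` (list-column of merged read
#'   tibbles). The first row is always the undiluted sample.
#' @export
enumerate_dilutions <- function(variant_reads, variant_input_ng,
                                backgrounds, min_step_ng) {
  if (is.null(backgrounds) || nrow(backgrounds) == 0L) {
    return(tibble::tibble(
      combo_id = 1L, total_input_ng = variant_input_ng, n_backgrounds = 0L,
      background_idx = list(integer()), reads = list(variant_reads)
    ))
  }
  ord <- order(backgrounds$input_ng, decreasing = TRUE)
  bg <- backgrounds[ord, ]
  b <- nrow(bg)
  subsets <- lapply(seq_len(2^b) - 1L, function(i) {
    which((i %/% 2^(seq_len(b) - 1L)) %% 2L == 1L)
  })
  totals <- variant_input_ng +
    vapply(subsets, function(s) sum(bg$input_ng[s]), double(1))
  keep <- !duplicated(totals)
  subsets <- subsets[keep]
  totals <- totals[keep]
  o <- order(totals)
  subsets <- subsets[o]
  totals <- totals[o]
  sel <- logical(length(totals))
  sel[1] <- TRUE # the undiluted sample is always retained
  last <- totals[1]
  for (i in seq_along(totals)[-1]) {
    if (totals[i] - last >= min_step_ng) {
      sel[i] <- TRUE
      last <- totals[i]
    }
  }
  subsets <- subsets[sel]
  totals <- totals[sel]
  reads <- purrr::map(subsets, function(s) {
    merge_read_sets(c(list(variant_reads), bg$reads[s]))
  })
  tibble::tibble(
    combo_id = seq_along(totals),
    total_input_ng = totals,
    n_backgrounds = lengths(subsets),
    background_idx = purrr::map(subsets, function(s) ord[s]),
    reads = reads
  )
}

#' Variant signal loss along a dilution series
#'
#' For each dilution point, the merged reads are grouped under both modes,
#' collapsed to duplex consensus molecules and piled up; the number of
#' variant-supporting molecules summed over the truth loci is reported for
#' each mode, together with the fraction of that signal lost by
#' position-only grouping:
#' `1 - sum(n_alt_position_only) / sum(n_alt_with_umi)`.
#'
#' @param dilutions Output of [enumerate_dilutions()].
#' @param panel The panel tibble (also the truth loci).
#' @param min_reads,min_consistency Consensus parameters (see
#'   [collapse_groups()]).
#' @param max_umi_mismatch UMI clustering tolerance.
#' @return A tibble with one row per dilution point: `combo_id`,
#'   `total_input_ng`, `n_alt_with_umi`, `n_alt_position_only`,
#'   `fraction_lost`.
#' @export
alt_signal_loss <- function(dilutions, panel, min_reads = 3L,
                            min_consistency = 0.70, max_umi_mismatch = 1L) {
  truth <- panel[c("pos", "alt")]
  alt_total <- function(reads, mode) {
    pl <- reads |>
      group_reads(mode, max_umi_mismatch) |>
      collapse_groups(panel, min_reads, min_consistency) |>
      pileup(panel)
    if (nrow(pl) == 0L) return(0L)
    hits <- dplyr::semi_join(
      dplyr::filter(pl, .data$is_alt),
      truth, by = c("pos", "allele" = "alt"))
    sum(hits$n_molecules)
  }
  res <- purrr::map(dilutions$reads, function(rs) {
    tibble::tibble(
      n_alt_with_umi = alt_total(rs, "with_umis"),
      n_alt_position_only = alt_total(rs, "position_only")
    )
  })
  dplyr::bind_cols(
    dilutions[c("combo_id", "total_input_ng")],
    dplyr::bind_rows(res)
  ) |>
    dplyr::mutate(fraction_lost = ifelse(
      .data$n_alt_with_umi > 0,
      1 - .data$n_alt_position_only / .data$n_alt_with_umi,
      NA_real_))
}

#' Plot variant signal loss against total input amount
#'
#' @param loss_tbl Output of [alt_signal_loss()], optionally with extra
#'   grouping columns (e.g. `vaf`).
#' @param colour Optional name of a column to colour lines by.
#' @return A ggplot object.
#' @export
plot_signal_loss <- function(loss_tbl, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(.data$total_input_ng, .data$fraction_lost)
  } else {
    ggplot2::aes(.data$total_input_ng, .data$fraction_lost,
                 colour = factor(.data[[colour]]), group = .data[[colour]])
  }
  ggplot2::ggplot(loss_tbl, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Total input (ng)",
                  y = "Fraction of ALT molecules lost",
                  colour = colour) +
    ggplot2::ylim(0, 1)
}

#' Plot collision rate against molecule count
#'
#' @param collision_tbl A tibble with columns `n_molecules`,
#'   `collision_rate` and a grouping column (default `regime`).
#' @param colour Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_collision_rates <- function(collision_tbl, colour = "regime") {
  ggplot2::ggplot(collision_tbl,
                  ggplot2::aes(.data$n_molecules, .data$collision_rate,
                               colour = .data[[colour]],
                               group = .data[[colour]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sequenced molecules", y = "Collision rate") +
    ggplot2::ylim(0, 1)
}
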