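#' Majority consensus of one strand's base calls at a locus
#'
#' Returns the majority allele when its fraction among the covering reads of
#' that strand reaches `min_consistency`, otherwise `NA` (no-call).
#'
#' @param alleles Character vector of observed alleles (one per read of one
#'   strand covering the locus).
#' @param min_consistency Required base-call consistency within the strand
#'   (default 0.70).
#' @return The consensus allele, or `NA_character_` for a no-call.
#' @examples
#' strand_consensus(c("A", "A", "T")) # 66.7% < 70% -> NA
#' strand_consensus(c("A", "A", "A", "A", "T")) # 80% -> "A"
#' @export
strand_consensus <- function(alleles, min_consistency = 0.70) {
  stopifnot(length(alleles) >= 1)
  tab <- table(alleles)
  top <- which.max(tab)
  if (tab[top] / length(alleles) >= min_consistency) names(tab)[top] else NA_character_
}

#' Collapse read groups into duplex consensus molecules
#'
#' Simplex groups and groups with fewer than `min_reads` total reads are
#' discarded. For each surviving group and each candidate position (covered
#' panel loci plus any position with a recorded non-reference call), a
#' per-strand majority consensus is formed (at `min_consistency`); the
#' double-strand consensus is the common allele when both strand consensuses
#' agree, and a no-call (`NA`) when either strand is inconsistent or the
#' strands disagree. An alternative allele therefore survives only when it
#' is present in both strand consensuses, which suppresses single-strand
#' lesions. Reads not carrying an explicit call at a covered position count
#' as reference.
#'
#' @param grouped_reads Output of [group_reads()].
#' @param panel The panel tibble (supplies loci and reference bases).
#' @param min_reads Minimum total reads per group (default 3).
#' @param min_consistency Per-strand consistency threshold (default 0.70).
#' @return A tibble with one row per (consensus molecule, candidate
#'   position): `group_id`, `fragment_key`, `contig`, `start`, `end`,
#'   `n_reads_top`, `n_reads_bottom`, `pos`, `ref`, `allele` (`NA` =
#'   no-call), `is_panel`.
#' @export
collapse_groups <- function(grouped_reads, panel, min_reads = 3L,
                            min_consistency = 0.70) {
  groups <- summarize_groups(grouped_reads) |>
    dplyr::filter(.data$duplexity == "duplex", .data$n_reads >= min_reads)
  if (nrow(groups) == 0L) return(empty_consensus())

  kept <- dplyr::semi_join(grouped_reads, groups, by = "group_id")

  # candidate positions: covered panel loci ...
  lo <- findInterval(groups$start, panel$pos) + 1L
  hi <- findInterval(groups$end, panel$pos)
  n_cov <- pmax(hi - lo + 1L, 0L)
  cand_panel <- tibble::tibble(
    group_id = rep.int(groups$group_id, n_cov),
    pos = panel$pos[unlist(
      lapply(which(n_cov > 0L), function(i) seq.int(lo[i], hi[i])),
      use.names = FALSE)]
  )
  # ... plus recorded call positions (sequencing errors, lesions)
  long <- calls_long(kept) |>
    dplyr::left_join(kept[c("read_id", "group_id", "strand")], by = "read_id")
  cand <- dplyr::bind_rows(cand_panel, dplyr::distinct(long, .data$group_id, .data$pos)) |>
    dplyr::distinct()

  refs <- tibble::tibble(pos = sort(unique(cand$pos))) |>
    dplyr::left_join(panel[c("pos", "ref")], by = "pos") |>
    dplyr::mutate(is_panel = !is.na(.data$ref),
                  ref = ifelse(.data$is_panel, .data$ref,
                               ref_base_at(panel, .data$pos)))
  cand <- dplyr::left_join(cand, refs, by = "pos")

  # every read in a group shares the fragment key, so each strand's covering
  # read count at any candidate position is the strand's read count
  strand_n <- tidyr::pivot_longer(
    groups[c("group_id", "n_reads_top", "n_reads_bottom")],
    cols = c("n_reads_top", "n_reads_bottom"),
    names_to = "strand", names_prefix = "n_reads_", values_to = "n_strand"
  )

  cand_strand <- tidyr::crossing(cand, strand = c("top", "bottom")) |>
    dplyr::left_join(strand_n, by = c("group_id", "strand"))

  counts <- dplyr::count(long, .data$group_id, .data$strand, .data$pos,
                         .data$allele, name = "n")
  recorded_total <- counts |>
    dplyr::group_by(.data$group_id, .data$strand, .data$pos) |>
    dplyr::summarise(n_recorded = sum(.data$n), .groups = "drop")

  # reads without a recorded call at a candidate position count as reference
  implicit_ref <- cand_strand |>
    dplyr::left_join(recorded_total, by = c("group_id", "strand", "pos")) |>
    dplyr::mutate(n = .data$n_strand - dplyr::coalesce(.data$n_recorded, 0L),
                  allele = .data$ref) |>
    dplyr::filter(.data$n > 0L) |>
    dplyr::select("group_id", "strand", "pos", "allele", "n")

  tally <- dplyr::bind_rows(
    dplyr::semi_join(counts, cand, by = c("group_id", "pos")),
    implicit_ref
  ) |>
    dplyr::group_by(.data$group_id, .data$strand, .data$pos, .data$allele) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")

  strand_cons <- tally |>
    dplyr::left_join(strand_n, by = c("group_id", "strand")) |>
    dplyr::group_by(.data$group_id, .data$strand, .data$pos) |>
    dplyr::summarise(
      cons = {
        frac <- .data$n / .data$n_strand[1]
        if (max(frac) >= min_consistency) .data$allele[which.max(frac)]
        else NA_character_
      },
      .groups = "drop"
    ) |>
    dplyr::right_join(tidyr::crossing(cand[c("group_id", "pos", "ref", "is_panel")],
                                      strand = c("top", "bottom")),
                      by = c("group_id", "strand", "pos"))

  duplex <- strand_cons |>
    dplyr::select("group_id", "pos", "ref", "is_panel", "strand", "cons") |>
    tidyr::pivot_wider(names_from = "strand", values_from = "cons") |>
    dplyr::mutate(allele = ifelse(!is.na(.data$top) & !is.na(.data$bottom) &
                                    .data$top == .data$bottom,
                                  .data$top, NA_character_))

  groups[c("group_id", "fragment_key", "contig", "start", "end",
           "n_reads_top", "n_reads_bottom")] |>
    dplyr::inner_join(
      duplex[c("group_id", "pos", "ref", "allele", "is_panel")],
      by = "group_id") |>
    dplyr::arrange(.data$group_id, .data$pos)
}

empty_consensus <- function() {
  tibble::tibble(
    group_id = character(), fragment_key = character(), contig = character(),
    start = integer(), end = integer(),
    n_reads_top = integer(), n_reads_bottom = integer(),
    pos = integer(), ref = character(), allele = character(),
    is_panel = logical()
  )
}

#' Collapse a single read group
#'
#' Convenience wrapper around [collapse_groups()] for one group of reads;
#' returns `NULL` when the group is rejected (simplex, or fewer than
#' `min_reads` reads).
#'
#' @param group A tibble of reads forming one group.
#' @param panel The panel tibble.
#' @inheritParams collapse_groups
#' @return A consensus tibble for the group, or `NULL` if rejected.
#' @export
duplex_collapse <- function(group, panel, min_reads = 3L,
                            min_consistency = 0.70) {
  stopifnot(nrow(group) > 0)
  if (!"group_id" %in% names(group)) {
    group$fragment_key <- paste0(group$contig, ":", group$start, "-", group$end)
    group$umi_canonical <- NA_character_
    group$group_id <- group$fragment_key[1]
  }
  out <- collapse_groups(group, panel, min_reads = min_reads,
                         min_consistency = min_consistency)
  if (nrow(out) == 0L) NULL else out
}
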