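#' Group reads into inferred source molecules
#'
#' Reads are grouped either by mapping position alone (`position_only`: one
#' group per distinct fragment key `contig:start-end`) or by mapping
#' position plus UMI (`with_umis`): within each fragment key, canonicalized
#' duplex UMI pairs are single-linkage clustered at Hamming distance
#' `<= max_umi_mismatch` on the concatenated canonical pair, tolerating UMI
#' sequencing errors. The canonical pair is the lexicographic minimum of
#' `u1 + u2` and `u2 + u1`, so top- and bottom-strand reads of one molecule
#' co-cluster. Grouping is a partition of the reads and is independent of
#' input row order (cluster labels are the lexicographically smallest member
#' UMI).
#'
#' @param reads A read tibble (see [simulate_reads()] or
#'   [read_reads_tsv()]); `with_umis` mode requires non-empty `umi1`/`umi2`.
#' @param mode `"with_umis"` or `"position_only"`.
#' @param max_umi_mismatch Mismatch tolerance for UMI clustering (default 1).
#' @return The input tibble with added columns `fragment_key`,
#'   `umi_canonical` (`NA` in position-only mode) and `group_id`.
#' @examples
#' panel <- simulate_panel(n_snv = 4, n_deletion = 0, n_insertion = 0,
#'                         span_bp = 4000, seed = 1)
#' cfg <- simulation_config(panel, 0.2, 0.5, 0.1, seed = 2)
#' reads <- simulate_reads(cfg)
#' grouped <- group_reads(reads, "with_umis")
#' count_molecules(grouped)
#' @export
group_reads <- function(reads, mode = c("with_umis", "position_only"),
                        max_umi_mismatch = 1L) {
  mode <- match.arg(mode)
  reads <- tibble::as_tibble(reads)
  key <- paste0(reads$contig, ":", reads$start, "-", reads$end)
  reads$fragment_key <- key
  if (mode == "position_only") {
    reads$umi_canonical <- NA_character_
    reads$group_id <- key
    return(reads)
  }
  if (nrow(reads) > 0 &&
      (anyNA(reads$umi1) || anyNA(reads$umi2) ||
       any(!nzchar(reads$umi1)) || any(!nzchar(reads$umi2)))) {
    stop("`with_umis` grouping requires UMIs on every read", call. = FALSE)
  }
  canon <- pmin(paste0(reads$umi1, reads$umi2), paste0(reads$umi2, reads$umi1))
  reads$umi_canonical <- canon
  cluster <- character(nrow(reads))
  for (rows in split(seq_len(nrow(reads)), key)) {
    cluster[rows] <- cluster_umis(canon[rows], max_umi_mismatch)
  }
  reads$group_id <- paste0(key, "|", cluster)
  reads
}

# Single-linkage clustering of UMI strings at Hamming distance <= max_mismatch.
# Returns, for each element, the lexicographically smallest UMI of its cluster.
cluster_umis <- function(umis, max_mismatch = 1L) {
  uniq <- sort(unique(umis))
  m <- length(uniq)
  if (m == 1L) return(rep(uniq, length(umis)))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chars <- strsplit(uniq, "", fixed = TRUE)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      a <- chars[[i]]; b <- chars[[j]]
      if (length(a) == length(b) && sum(a != b) <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(m), find, integer(1))
  labels <- uniq[root] # root is the smallest index, i.e. lexicographic min
  labels[match(umis, uniq)]
}

#' Summarize read groups and classify simplex/duplex
#'
#' A group is `duplex` when reads from both source strands are present and
#' `simplex` otherwise.
#'
#' @param grouped_reads Output of [group_reads()].
#' @return A tibble with one row per group: `group_id`, `fragment_key`,
#'   `umi_cluster_id`, `contig`, `start`, `end`, `n_reads_top`,
#'   `n_reads_bottom`, `n_reads`, `duplexity`.
#' @export
summarize_groups <- function(grouped_reads) {
  stopifnot("group_id" %in% names(grouped_reads))
  grouped_reads |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      fragment_key = .data$fragment_key[1],
      umi_cluster_id = .data$umi_canonical[1],
      contig = .data$contig[1],
      start = .data$start[1],
      end = .data$end[1],
      n_reads_top = sum(.data$strand == "top"),
      n_reads_bottom = sum(.data$strand == "bottom"),
      n_reads = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(duplexity = ifelse(.data$n_reads_top > 0 & .data$n_reads_bottom > 0,
                                     "duplex", "simplex")) |>
    dplyr::arrange(.data$group_id)
}

#' Classify one read group as simplex or duplex
#'
#' @param group A tibble of reads belonging to one group (needs a `strand`
#'   column with values `"top"`/`"bottom"`).
#' @return `"duplex"` or `"simplex"`.
#' @export
classify_group <- function(group) {
  stopifnot(nrow(group) > 0)
  if (any(group$strand == "top") && any(group$strand == "bottom")) {
    "duplex"
  } else {
    "simplex"
  }
}

#' Count inferred molecules
#'
#' Both simplex and duplex groups are counted.
#'
#' @param grouped_reads Output of [group_reads()] (or a
#'   [summarize_groups()] table).
#' @return Integer number of molecule groups.
#' @export
count_molecules <- function(grouped_reads) {
  stopifnot("group_id" %in% names(grouped_reads))
  dplyr::n_distinct(grouped_reads$group_id)
}
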