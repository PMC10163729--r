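#' Generate a synthetic hybridization-capture variant panel
#'
#' Builds a panel of variant loci on a single synthetic contig, together
#' with the contig's reference sequence. The default emulates a capture
#' panel spanning 46 kbp with 110 variant loci: 70 SNVs, 20 deletions and
#' 20 insertions. Insertions and deletions are represented as atomic alleles
#' anchored at a single position (no realignment semantics).
#'
#' @param n_snv,n_deletion,n_insertion Number of loci of each variant class.
#' @param span_bp Interrogated span of the panel in bp.
#' @param contig Contig name for the synthetic reference.
#' @param min_gap Minimum distance between consecutive loci in bp.
#' @param seed Optional integer seed; the panel (positions, alleles and
#'   reference sequence) is fully reproducible given the seed.
#' @return A tibble of class `umi_panel` with columns `locus_id`, `contig`,
#'   `pos` (1-based anchor), `ref`, `alt`, `class`, and attributes
#'   `span_bp` and `contig_seq` (the reference sequence as a single string).
#' @examples
#' panel <- simulate_panel(seed = 1)
#' dplyr::count(panel, class)
#' @export
simulate_panel <- function(n_snv = 70L, n_deletion = 20L, n_insertion = 20L,
                           span_bp = 46000L, contig = "panel1",
                           min_gap = 250L, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n <- n_snv + n_deletion + n_insertion
  if (n * min_gap >= span_bp - 400L) {
    stop("panel span too small for the requested loci and `min_gap`", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  contig_seq <- paste(sample(bases, span_bp, replace = TRUE), collapse = "")

  # loci spaced >= min_gap apart, away from the contig edges
  usable <- span_bp - 400L - n * min_gap
  slack <- sort(sample.int(usable, n))
  pos <- as.integer(200L + slack + min_gap * seq_len(n))

  class <- sample(rep(c("SNV", "deletion", "insertion"),
                      times = c(n_snv, n_deletion, n_insertion)))
  ref_base <- substring(contig_seq, pos, pos)
  next_base <- substring(contig_seq, pos + 1L, pos + 1L)
  ref <- ifelse(class == "deletion", paste0(ref_base, next_base), ref_base)
  alt <- character(n)
  for (i in seq_len(n)) {
    alt[i] <- switch(class[i],
      SNV       = sample(setdiff(bases, ref_base[i]), 1L),
      deletion  = ref_base[i],
      insertion = paste0(ref_base[i], sample(bases, 1L))
    )
  }
  panel <- tibble::tibble(
    locus_id = seq_len(n), contig = contig, pos = pos,
    ref = ref, alt = alt, class = class
  )
  new_umi_panel(panel, span_bp = span_bp, contig_seq = contig_seq)
}

#' Build a variant panel from explicit loci
#'
#' For user-defined panels (or test fixtures): positions must be unique per
#' contig and the variant class consistent with the allele lengths.
#'
#' @param contig Contig name (scalar or per-locus vector).
#' @param pos 1-based anchor positions.
#' @param ref,alt Reference and alternative alleles (atomic strings;
#'   insertions/deletions are anchored at `pos`).
#' @param class Variant classes (`"SNV"`, `"deletion"`, `"insertion"`);
#'   inferred from allele lengths when omitted.
#' @param span_bp Interrogated span of the panel in bp.
#' @param contig_seq Optional reference sequence of the contig.
#' @return A panel tibble as from [simulate_panel()].
#' @export
variant_panel <- function(contig, pos, ref, alt, class = NULL, span_bp,
                          contig_seq = NULL) {
  contig <- rep_len(contig, length(pos))
  if (anyDuplicated(paste(contig, pos))) {
    stop("panel positions must be unique per contig", call. = FALSE)
  }
  if (is.null(class)) {
    class <- dplyr::case_when(
      nchar(ref) > nchar(alt) ~ "deletion",
      nchar(ref) < nchar(alt) ~ "insertion",
      TRUE ~ "SNV"
    )
  }
  ok <- (class == "SNV" & nchar(ref) == nchar(alt)) |
    (class == "deletion" & nchar(ref) > nchar(alt)) |
    (class == "insertion" & nchar(ref) < nchar(alt))
  if (!all(ok)) {
    stop("variant class inconsistent with allele lengths", call. = FALSE)
  }
  o <- order(contig, pos)
  df <- tibble::tibble(
    locus_id = seq_along(pos), contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt, class = class
  )[o, ]
  df$locus_id <- seq_along(pos)
  new_umi_panel(df, span_bp = span_bp, contig_seq = contig_seq)
}

new_umi_panel <- function(df, span_bp, contig_seq = NULL) {
  structure(
    tibble::as_tibble(df),
    span_bp = as.integer(span_bp),
    contig_seq = contig_seq,
    class = c("umi_panel", class(tibble::tibble()))
  )
}

#' @export
print.umi_panel <- function(x, ...) {
  cat(sprintf("<umi_panel> %d loci over %d bp\n", nrow(x), panel_span(x)))
  NextMethod()
}

#' Interrogated span of a panel in bp
#'
#' @param panel A panel tibble from [simulate_panel()] or [read_panel_tsv()].
#' @return Integer span in bp.
#' @export
panel_span <- function(panel) {
  span <- attr(panel, "span_bp")
  if (is.null(span)) stop("panel has no `span_bp` attribute", call. = FALSE)
  span
}

# Reference base at arbitrary 1-based positions; falls back to "N" when the
# panel carries no contig sequence (e.g. a panel read back from TSV).
ref_base_at <- function(panel, pos) {
  if (length(pos) == 0L) return(character())
  seq <- attr(panel, "contig_seq")
  if (is.null(seq)) return(rep("N", length(pos)))
  substring(seq, pos, pos)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
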