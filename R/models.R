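#' Probability of sequencing at least `min_alt` variant-carrying molecules
#'
#' The number of variant-supporting molecules among `n_molecules` sequenced
#' molecules follows a binomial distribution `Binomial(n_molecules, vaf)`
#' when every converted molecule is sequenced at least once. This returns
#' the exact upper-tail probability `P(N_alt >= min_alt)`, evaluated through
#' the binomial survival function so it is stable for large molecule counts.
#'
#' @param n_molecules Non-negative integer vector: number of sequenced
#'   molecules overlapping the position of interest.
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param min_alt Positive integer: minimum number of variant-supporting
#'   molecules required to count as detected.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' detection_probability(1900, 0.002, min_alt = 2)
#' @export
detection_probability <- function(n_molecules, vaf, min_alt = 1L) {
  if (any(n_molecules < 0) || any(n_molecules != floor(n_molecules))) {
    stop("`n_molecules` must be a non-negative integer", call. = FALSE)
  }
  if (any(vaf < 0 | vaf > 1)) {
    stop("`vaf` must lie in [0, 1]", call. = FALSE)
  }
  if (any(min_alt < 1) || any(min_alt != floor(min_alt))) {
    stop("`min_alt` must be an integer >= 1", call. = FALSE)
  }
  stats::pbinom(min_alt - 1, size = n_molecules, prob = vaf, lower.tail = FALSE)
}

#' Smallest molecule count achieving a target detection probability
#'
#' Finds the minimal number of sequenced molecules `N` such that
#' `detection_probability(N, vaf, min_alt) >= target_prob`. Detection
#' probability is monotone non-decreasing in `N`, so a doubling bracket
#' followed by binary search is exact.
#'
#' @param vaf Variant allele fraction, strictly between 0 and 1.
#' @param target_prob Required detection probability, strictly between 0 and 1.
#' @param min_alt Minimum number of variant-supporting molecules (default 1).
#' @return Integer molecule count.
#' @examples
#' required_molecules(0.001, 0.95) # MRD-style bound, ~3000 molecules
#' @export
required_molecules <- function(vaf, target_prob, min_alt = 1L) {
  stopifnot(length(vaf) == 1, length(target_prob) == 1)
  if (vaf <= 0 || vaf >= 1) stop("`vaf` must be in (0, 1)", call. = FALSE)
  if (target_prob <= 0 || target_prob >= 1) {
    stop("`target_prob` must be in (0, 1)", call. = FALSE)
  }
  hi <- max(min_alt, 1L)
  while (detection_probability(hi, vaf, min_alt) < target_prob) hi <- hi * 2L
  lo <- max(min_alt - 1L, 0L) # probability at lo is < target (0 below min_alt)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (detection_probability(mid, vaf, min_alt) >= target_prob) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Expected molecular count from input amount and library conversion rate
#'
#' Average number of sequenced molecules given an input amount in nanograms
#' and a library conversion rate (LCR): `N = G * input_ng * lcr`, with
#' `G = 300` genome equivalents per nanogram of human double-stranded DNA.
#'
#' @param input_ng Input DNA amount in nanograms (non-negative).
#' @param lcr Library conversion rate, fraction of input molecules converted
#'   to sequencing-ready library, in `[0, 1]`.
#' @param genome_equivalents_per_ng Genome equivalents per nanogram
#'   (default 300).
#' @return Expected molecule count (numeric).
#' @examples
#' molecular_count(20, 0.5) # 3000 molecules
#' @export
molecular_count <- function(input_ng, lcr, genome_equivalents_per_ng = 300) {
  if (any(input_ng < 0)) stop("`input_ng` must be non-negative", call. = FALSE)
  if (any(lcr < 0 | lcr > 1)) stop("`lcr` must lie in [0, 1]", call. = FALSE)
  if (any(genome_equivalents_per_ng <= 0)) {
    stop("`genome_equivalents_per_ng` must be positive", call. = FALSE)
  }
  genome_equivalents_per_ng * input_ng * lcr
}

#' Fraction of a sequencing read consumed by the UMI
#'
#' @param umi_len UMI length in bases, `0 <= umi_len < read_len`.
#' @param read_len Read length in bases.
#' @return Fraction of the read spent on the barcode.
#' @examples
#' umi_read_overhead(16, 150)
#' @export
umi_read_overhead <- function(umi_len, read_len) {
  if (any(umi_len < 0)) stop("`umi_len` must be non-negative", call. = FALSE)
  if (any(umi_len >= read_len)) {
    stop("`umi_len` must be shorter than `read_len`", call. = FALSE)
  }
  umi_len / read_len
}

#' Format a probability as the nearest integer percentage
#'
#' Raw fractions are kept internally; user-facing reports round to the
#' nearest whole percent.
#'
#' @param p Numeric vector of fractions.
#' @return Character vector like `"59%"`.
#' @export
percent_label <- function(p) {
  sprintf("%d%%", as.integer(round(100 * p)))
}
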