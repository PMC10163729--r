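#' Write reads as a SAM-like TSV
#'
#' One row per read with 1-based inclusive coordinates (`pos` =
#' internal `start + 1`, `end` unchanged), the observed UMI pair in a single
#' `umi` tag field (`u1-u2`, `"."` when absent) and recorded base calls
#' serialized as `pos:allele` pairs separated by `;` (`"."` when the read
#' carries only reference calls).
#'
#' @param reads A read tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  ser <- vapply(reads$calls, function(v) {
    if (length(v) == 0L) "." else paste(names(v), v, sep = ":", collapse = ";")
  }, character(1))
  out <- tibble::tibble(
    read_id = reads$read_id,
    molecule_id = if ("molecule_id" %in% names(reads)) reads$molecule_id else ".",
    contig = reads$contig,
    pos = reads$start + 1L,
    end = reads$end,
    strand = reads$strand,
    umi = ifelse(nzchar(reads$umi1), paste0(reads$umi1, "-", reads$umi2), "."),
    calls = ser
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read reads from a SAM-like TSV
#'
#' Inverse of [write_reads_tsv()]; restores 0-based half-open internal
#' coordinates and the `calls` list-column.
#'
#' @param path File written by [write_reads_tsv()].
#' @return A read tibble.
#' @export
read_reads_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", molecule_id = "c", contig = "c", pos = "i", end = "i",
    strand = "c", umi = "c", calls = "c"
  ))
  umis <- strsplit(ifelse(raw$umi == ".", "-", raw$umi), "-", fixed = TRUE)
  calls <- lapply(raw$calls, function(s) {
    if (s == ".") return(stats::setNames(character(), character()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, character(1), 2),
                    vapply(parts, `[`, character(1), 1))
  })
  tibble::tibble(
    read_id = raw$read_id,
    molecule_id = raw$molecule_id,
    contig = raw$contig,
    start = raw$pos - 1L,
    end = raw$end,
    strand = raw$strand,
    umi1 = vapply(umis, function(u) if (length(u) >= 1) u[1] else "", character(1)),
    umi2 = vapply(umis, function(u) if (length(u) >= 2) u[2] else "", character(1)),
    calls = calls
  )
}

#' Write a variant panel as a BED-like TSV
#'
#' Coordinates are exported 0-based half-open over the reference allele span
#' (BED convention); the anchor `pos` column stays 1-based. The interrogated
#' span is stored on a `#span_bp=` header line. The contig reference
#' sequence is not serialized (regenerate the panel from its seed when base
#' level context is needed).
#'
#' @param panel A panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  header <- sprintf("#span_bp=%d", panel_span(panel))
  body <- tibble::tibble(
    contig = panel$contig,
    start = panel$pos - 1L,
    end = panel$pos - 1L + nchar(panel$ref),
    locus_id = panel$locus_id,
    pos = panel$pos,
    ref = panel$ref,
    alt = panel$alt,
    class = panel$class
  )
  writeLines(header, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a variant panel from a BED-like TSV
#'
#' @param path File written by [write_panel_tsv()].
#' @return A panel tibble (without a reference sequence attribute).
#' @export
read_panel_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  span <- as.integer(sub("^#span_bp=", "", header))
  raw <- readr::read_tsv(path, skip = 1L, col_types = readr::cols(
    contig = "c", start = "i", end = "i", locus_id = "i", pos = "i",
    ref = "c", alt = "c", class = "c"
  ))
  new_umi_panel(
    raw[c("locus_id", "contig", "pos", "ref", "alt", "class")],
    span_bp = span
  )
}

#' Write variant calls as a VCF-like TSV
#'
#' @param calls A call tibble from [call_variants()] or [raw_pileup_call()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- tibble::tibble(
    contig = calls$contig, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    support = if ("n_support" %in% names(calls)) calls$n_support else calls$n_reads,
    filter = "PASS"
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read variant calls from a VCF-like TSV
#'
#' @param path File written by [write_calls_tsv()].
#' @return A call tibble.
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = "c", pos = "i", ref = "c", alt = "c", support = "i", filter = "c"
  ))
}

#' Write a simulation configuration as YAML
#'
#' Serializes every scalar field and the fragmentation model; the panel
#' itself is written separately (see [write_panel_tsv()]) and re-attached on
#' read.
#'
#' @param config A [simulation_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  fields <- config[setdiff(names(config), "panel")]
  fields$fragmentation <- unclass(fields$fragmentation)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path File written by [write_sim_config_yaml()].
#' @param panel The panel tibble to attach.
#' @return A [simulation_config()].
#' @export
read_sim_config_yaml <- function(path, panel) {
  fields <- yaml::read_yaml(path)
  frag <- do.call(fragmentation_model, fields$fragmentation)
  simulation_config(
    panel = panel, input_ng = fields$input_ng, lcr = fields$lcr,
    vaf = fields$vaf, fragmentation = frag, umi_len = fields$umi_len,
    reads_per_molecule_mean = fields$reads_per_molecule_mean,
    seq_error_rate = fields$seq_error_rate, lesion_rate = fields$lesion_rate,
    umi_error_rate = fields$umi_error_rate, seed = fields$seed
  )
}

#' Write a performance report as JSON
#'
#' @param performance A `duplex_performance` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_performance_json <- function(performance, path) {
  stopifnot(inherits(performance, "duplex_performance"))
  jsonlite::write_json(
    list(
      auc = performance$auc,
      min_molecules = performance$min_molecules,
      sensitivity = performance$sensitivity,
      specificity = performance$specificity,
      fp_per_kb = performance$fp_per_kb,
      roc = performance$roc
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
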