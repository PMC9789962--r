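# Readers and writers for the standard formats the tool touches:
# eventalign-style TSV, call tables, haplotags, FASTA (Biostrings),
# BED (rtracklayer).

#' Read an eventalign-style event table
#'
#' Expects a TSV with at least `contig`, `position`, `reference_kmer`,
#' `read_id` (or `read_name`), `event_index` and `event_level_mean`;
#' extra columns are kept.
#'
#' @param path File path.
#' @return A tibble ordered by read and event index.
#' @export
read_eventalign <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("read_name" %in% names(ev) && !"read_id" %in% names(ev)) {
    ev <- dplyr::rename(ev, read_id = "read_name")
  }
  need <- c("contig", "position", "reference_kmer", "read_id",
            "event_index", "event_level_mean")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("eventalign table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(ev, .data$read_id, .data$event_index)
}

#' @rdname read_eventalign
#' @param events Event tibble.
#' @export
write_eventalign <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Read a haplotag table
#'
#' @param path TSV with columns `read_id` and `haplotype` (1, 2 or
#'   `unphased`).
#' @return A tibble.
#' @export
read_haplotags <- function(path) {
  ht <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("read_id", "haplotype")
  missing <- setdiff(need, names(ht))
  if (length(missing)) {
    stop("haplotag table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ht
}

#' Read or write per-window call tables
#'
#' @param path File path.
#' @return A tibble of calls / the path, invisibly.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_calls
#' @param calls Call tibble.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_reference_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_reference_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED region file into a tibble
#'
#' @param path BED path.
#' @return A tibble with `contig`, `start` (0-based), `end`, `name`.
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_
  )
}

#' Write intervals to BED6
#'
#' @param x Tibble with `contig`, `start` (0-based half-open), `end`,
#'   and optionally `name` and `score`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$contig,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  gr$name <- if ("name" %in% names(x)) x$name else "."
  gr$score <- if ("score" %in% names(x)) x$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write per-site methylation frequencies as bedMethyl-style TSV
#'
#' Nine-column bedMethyl layout: chrom, start, end, name, score
#' (coverage capped at 1000), strand, thickStart, thickEnd, and the
#' methylated percentage.
#'
#' @param freqs Output of [site_frequencies()].
#' @param path Output path.
#' @export
write_bedmethyl <- function(freqs, path) {
  out <- data.frame(
    chrom = freqs$contig, start = freqs$start, end = freqs$end,
    name = ".", score = pmin(freqs$coverage, 1000L), strand = "+",
    thickStart = freqs$start, thickEnd = freqs$end,
    pct = round(100 * freqs$frequency, 2)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a binned count track as bedGraph
#'
#' @param bins Output of [window_counts()].
#' @param path Output path.
#' @param value Column to write as the track value (default `"count"`).
#' @export
write_bedgraph <- function(bins, path, value = "count") {
  out <- data.frame(chrom = bins$contig, start = bins$bin_start,
                    end = bins$bin_end, value = bins[[value]])
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
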