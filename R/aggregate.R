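# Aggregation of per-read calls to genomic summaries.

#' Expand joint CpG-substring calls to per-CpG-site rows
#'
#' A CpG substring is called jointly for all CpGs it contains; for
#' per-site frequency summaries the call is propagated to each CpG site
#' within the substring.
#'
#' @param calls Per-read call tibble (from [call_read()]), rows of kind
#'   `cpg_substring`.
#' @param reference Named character vector of reference sequences, or a
#'   single unnamed sequence.
#' @return A tibble with one row per (read, CpG site): `read_id`,
#'   `contig`, `start` (0-based C position), `end`, `llr`, `call`.
#' @export
expand_cpg_calls <- function(calls, reference) {
  calls <- calls[calls$kind == "cpg_substring", ]
  if (nrow(calls) == 0L) {
    return(tibble::tibble(read_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          llr = numeric(), call = character()))
  }
  get_ref <- function(contig) {
    if (length(reference) == 1L && is.null(names(reference))) reference
    else reference[[contig]]
  }
  out <- purrr::pmap(
    calls[c("read_id", "contig", "start", "end", "llr", "call")],
    function(read_id, contig, start, end, llr, call) {
      ref <- get_ref(contig)
      seg <- substr(ref, start + 1L, end)
      rel <- gregexpr("CG", seg, fixed = TRUE)[[1]]
      if (rel[1] == -1L) return(NULL)
      pos <- start + rel - 1L
      tibble::tibble(read_id = read_id, contig = contig,
                     start = as.integer(pos), end = as.integer(pos + 2L),
                     llr = llr, call = call)
    })
  dplyr::bind_rows(out)
}

#' Per-CpG-site methylation frequencies
#'
#' Groups per-site calls by genomic CpG site and computes the methylated
#' fraction; `no_call` rows are excluded from both counts, and sites with
#' only no-calls are omitted.
#'
#' @param site_calls Per-site call tibble (see [expand_cpg_calls()]).
#' @return A tibble ordered by coordinate: `contig`, `start`, `end`,
#'   `n_methylated`, `n_unmethylated`, `coverage`, `frequency`,
#'   `category` (high >= 0.7, intermediate 0.3-0.7, low < 0.3).
#' @export
site_frequencies <- function(site_calls) {
  site_calls |>
    dplyr::filter(.data$call %in% c("methylated", "unmethylated")) |>
    dplyr::group_by(.data$contig, .data$start, .data$end) |>
    dplyr::summarise(
      n_methylated = sum(.data$call == "methylated"),
      n_unmethylated = sum(.data$call == "unmethylated"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      coverage = .data$n_methylated + .data$n_unmethylated,
      frequency = .data$n_methylated / .data$coverage,
      category = methylation_category(.data$frequency)
    ) |>
    dplyr::arrange(.data$contig, .data$start)
}

#' Methylation-level category bins
#'
#' @param frequency Methylated fraction in `[0, 1]`.
#' @return `"high"` (>= 70%), `"intermediate"` (30-70%) or `"low"`
#'   (< 30%).
#' @export
methylation_category <- function(frequency) {
  dplyr::case_when(
    frequency >= 0.7 ~ "high",
    frequency >= 0.3 ~ "intermediate",
    TRUE ~ "low"
  )
}

#' IgG background correction of 6mA window counts
#'
#' For a region, scales the IgG (background) count of 6mA-containing
#' windows by the coverage ratio of the target and IgG experiments and
#' subtracts: `sf = C_s / C_i`, `R_f = R_s - sf * R_b`, with `R_f`
#' floored at 0 (negative corrected counts are meaningless).
#'
#' @param r_s 6mA-containing window count in the target data.
#' @param r_b Same count in the IgG data.
#' @param c_s,c_i Coverage depths of the region in target and IgG data.
#' @param region Optional region labels used in error messages.
#' @return A tibble with columns `sf` and `r_f` (vectorised).
#' @export
background_correct <- function(r_s, r_b, c_s, c_i, region = NULL) {
  n <- max(length(r_s), length(r_b), length(c_s), length(c_i))
  r_s <- rep_len(r_s, n); r_b <- rep_len(r_b, n)
  c_s <- rep_len(c_s, n); c_i <- rep_len(c_i, n)
  if (any(c_i == 0)) {
    lab <- if (!is.null(region)) rep_len(region, n)[c_i == 0][1] else
      which(c_i == 0)[1]
    stop("IgG coverage is zero for region ", lab, call. = FALSE)
  }
  sf <- c_s / c_i
  tibble::tibble(sf = sf, r_f = pmax(r_s - sf * r_b, 0))
}

#' Binned genome track of 6mA-containing windows
#'
#' Counts `contains_6mA` calls in fixed-size bins tiled 0-based from the
#' chromosome start (a window is assigned to the bin containing its
#' start). Optionally adds counts-per-million normalisation.
#'
#' @param calls Per-window call tibble.
#' @param bin_size Bin width in bp (default 2500).
#' @param total_reads Total read count for CPM normalisation (optional).
#' @return A tibble: `contig`, `bin_start`, `bin_end`, `count` (and
#'   `cpm` when `total_reads` is given).
#' @export
window_counts <- function(calls, bin_size = 2500L, total_reads = NULL) {
  stopifnot(bin_size > 0)
  out <- calls |>
    dplyr::filter(.data$call == "contains_6mA") |>
    dplyr::mutate(bin_start = (.data$start %/% bin_size) * bin_size) |>
    dplyr::count(.data$contig, .data$bin_start, name = "count") |>
    dplyr::mutate(bin_end = .data$bin_start + bin_size,
                  .after = "bin_start")
  if (!is.null(total_reads)) {
    out$cpm <- out$count * 1e6 / total_reads
  }
  out
}

#' Distances between adjacent 6mA-containing windows within reads
#'
#' Measures midpoint-to-midpoint distances between consecutive
#' `contains_6mA` windows on the same read; reads with fewer than two
#' positive windows contribute nothing. In nucleosome-footprinting data
#' the distribution parallels linker lengths and nucleosome-multiple
#' spacings.
#'
#' @param calls Per-window call tibble.
#' @return A tibble with columns `read_id` and `distance` (bp).
#' @export
linker_lengths <- function(calls) {
  calls |>
    dplyr::filter(.data$call == "contains_6mA") |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2) |>
    dplyr::arrange(.data$read_id, .data$start) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::reframe(distance = diff(.data$mid)) |>
    dplyr::ungroup()
}
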