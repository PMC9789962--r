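# Haplotype-resolved statistics: allele-specific CpG methylation by
# Fisher's exact test and allele-specific 6mA enrichment by window
# bootstrap, both gated at combined coverage >= 20 and corrected by
# Benjamini-Hochberg (significant: p < 0.01 at 10% FDR).

#' Allele-specific CpG methylation test for one region
#'
#' Builds the 2x2 table of methylated/unmethylated call counts by
#' haplotype from a region's per-site calls and applies a two-sided
#' Fisher exact test.
#'
#' @param calls Per-site CpG call tibble for the region with columns
#'   `call` and `haplotype` (values 1/2).
#' @param region Region label carried into the result.
#' @param min_coverage Minimum combined informative calls (default 20).
#' @return One-row tibble: `region`, `test`, `n_h1`, `n_h2`,
#'   `statistic` (odds ratio), `p_value`, `skipped`, `reason`.
#' @export
fisher_cpg <- function(calls, region = NA_character_, min_coverage = 20L) {
  skip <- function(reason) tibble::tibble(
    region = region, test = "cpg_fisher", n_h1 = NA_integer_,
    n_h2 = NA_integer_, statistic = NA_real_, p_value = NA_real_,
    skipped = TRUE, reason = reason)

  calls <- calls[calls$call %in% c("methylated", "unmethylated"), ]
  if (nrow(calls) < min_coverage) return(skip("coverage below threshold"))
  h1 <- calls[calls$haplotype == 1, ]
  h2 <- calls[calls$haplotype == 2, ]
  if (nrow(h1) == 0L || nrow(h2) == 0L) return(skip("empty haplotype"))

  tab <- matrix(c(sum(h1$call == "methylated"), sum(h1$call == "unmethylated"),
                  sum(h2$call == "methylated"), sum(h2$call == "unmethylated")),
                nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(region = region, test = "cpg_fisher",
                 n_h1 = nrow(h1), n_h2 = nrow(h2),
                 statistic = unname(ft$estimate), p_value = ft$p.value,
                 skipped = FALSE, reason = NA_character_)
}

#' Segment per-read calls into 250-bp windows flagged for 6mA
#'
#' For allele-specific 6mA analysis, each read's span is tiled into
#' non-overlapping windows (default 250 bp) and a window is flagged
#' positive when it contains at least one `contains_6mA` call.
#'
#' @param calls Per-window call tibble (50-bp adenine windows) with
#'   columns `read_id`, `start`, `end`, `call` and optionally
#'   `haplotype`.
#' @param size Window width in bp (default 250).
#' @return A tibble: `read_id`, (`haplotype`,) `start`, `end`,
#'   `positive`.
#' @export
read_windows_250 <- function(calls, size = 250L) {
  per_read <- function(d) {
    s0 <- min(d$start)
    n <- (max(d$end) - s0) %/% size
    if (n < 1L) return(NULL)
    ws <- s0 + size * (seq_len(n) - 1L)
    pos <- d$start[d$call == "contains_6mA"]
    out <- tibble::tibble(
      read_id = d$read_id[1],
      start = as.integer(ws), end = as.integer(ws + size),
      positive = vapply(ws, function(w)
        any(pos >= w & pos < w + size), logical(1))
    )
    if ("haplotype" %in% names(d)) out$haplotype <- d$haplotype[1]
    out
  }
  dplyr::bind_rows(lapply(split(calls, calls$read_id), per_read))
}

#' Allele-specific 6mA enrichment test by window bootstrap
#'
#' For each bootstrap replication, samples `n_windows` windows with
#' replacement from each allele and records the number of 6mA-positive
#' windows; the replication counts are pooled into one 2x2 table
#' (positive/negative x allele) tested by a two-sided Fisher exact test.
#' Deterministic given `seed`.
#'
#' @param windows Window tibble with columns `haplotype` (1/2) and
#'   `positive` (logical), e.g. from [read_windows_250()].
#' @param region Region label carried into the result.
#' @param n_windows Windows sampled per allele per replication (default
#'   30).
#' @param n_reps Bootstrap replications (default 100).
#' @param seed Integer seed (required).
#' @return One-row tibble: `region`, `test`, `n_h1`, `n_h2`,
#'   `statistic` (odds ratio), `p_value`, `skipped`, `reason`, and a
#'   list-column `bootstrap` holding the per-replication positive counts
#'   for each allele.
#' @export
bootstrap_6ma <- function(windows, region = NA_character_, n_windows = 30L,
                          n_reps = 100L, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  skip <- function(reason) tibble::tibble(
    region = region, test = "ada_bootstrap", n_h1 = NA_integer_,
    n_h2 = NA_integer_, statistic = NA_real_, p_value = NA_real_,
    skipped = TRUE, reason = reason,
    bootstrap = list(NULL))

  h1 <- windows$positive[windows$haplotype == 1]
  h2 <- windows$positive[windows$haplotype == 2]
  if (length(h1) < n_windows || length(h2) < n_windows) {
    return(skip("fewer windows than the bootstrap sample size"))
  }

  withr::local_seed(seed)
  draw <- function(x) vapply(seq_len(n_reps), function(i)
    sum(sample(x, n_windows, replace = TRUE)), integer(1))
  k1 <- draw(h1)
  k2 <- draw(h2)
  tot <- n_reps * n_windows
  tab <- matrix(c(sum(k1), tot - sum(k1), sum(k2), tot - sum(k2)), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(region = region, test = "ada_bootstrap",
                 n_h1 = length(h1), n_h2 = length(h2),
                 statistic = unname(ft$estimate), p_value = ft$p.value,
                 skipped = FALSE, reason = NA_character_,
                 bootstrap = list(tibble::tibble(rep = seq_len(n_reps),
                                                 h1 = k1, h2 = k2)))
}

#' Benjamini-Hochberg correction and significance selection
#'
#' Adds step-up BH q-values over the non-skipped tests and flags results
#' significant when `p < p_threshold` and `q <= fdr`.
#'
#' @param results Tibble of test results with a `p_value` column.
#' @param p_threshold Raw p-value gate (default 0.01).
#' @param fdr Target false discovery rate (default 0.10).
#' @return `results` with `q_value` and `significant` columns.
#' @export
correct_and_select <- function(results, p_threshold = 0.01, fdr = 0.10) {
  if (nrow(results) < 1L) stop("no results to correct", call. = FALSE)
  ok <- !is.na(results$p_value)
  results$q_value <- NA_real_
  results$q_value[ok] <- stats::p.adjust(results$p_value[ok], method = "BH")
  results$significant <- !is.na(results$p_value) &
    results$p_value < p_threshold & results$q_value <= fdr
  results
}
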