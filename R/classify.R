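# Per-read LLR classification of CpG substrings and 50-bp adenine windows
# under the four modification hypotheses ref1 (none), ref2 (all CpGs
# methylated), ref3 (6mA-containing), ref4 (both).

#' Classification thresholds
#'
#' CpG substrings are called methylated at LLR >= 1.5 and unmethylated at
#' LLR <= -1.5 (inclusive boundaries); adenine windows are called
#' 6mA-containing at LLR >= 8 (low stringency) or >= 32 (high
#' stringency). LLRs are natural-log values.
#'
#' @param cpg_meth,cpg_unmeth CpG call boundaries (default +1.5 / -1.5).
#' @param ada_low,ada_high Adenine-window thresholds (default 8 / 32).
#' @return A list of class `nj_thresholds`.
#' @export
thresholds <- function(cpg_meth = 1.5, cpg_unmeth = -1.5,
                       ada_low = 8, ada_high = 32) {
  if (cpg_meth <= cpg_unmeth) stop("cpg_meth must exceed cpg_unmeth",
                                   call. = FALSE)
  if (ada_high < ada_low) stop("ada_high must be >= ada_low", call. = FALSE)
  structure(list(cpg_meth = cpg_meth, cpg_unmeth = cpg_unmeth,
                 ada_low = ada_low, ada_high = ada_high),
            class = "nj_thresholds")
}

# log max-likelihood of each hypothesis for one window's events
hypothesis_logliks <- function(hyps, events, model, scaling, cfg, k) {
  vapply(hyps, function(s)
    forward_loglik(events, s, model, scaling, cfg, k), numeric(1))
}

# Eq-8-style sum of log max-likelihoods over the modified-side hypotheses
# minus the unmodified side, using only the distinct hypotheses present.
llr_from_logliks <- function(ll, target = c("cpg", "6ma")) {
  target <- match.arg(target)
  pos <- if (target == "cpg") c("ref2", "ref4") else c("ref3", "ref4")
  neg <- if (target == "cpg") c("ref1", "ref3") else c("ref1", "ref2")
  sum(ll[intersect(pos, names(ll))]) - sum(ll[intersect(neg, names(ll))])
}

#' Per-read log-likelihood ratio for one classification window
#'
#' Builds the modification-hypothesis variants of the window's sequence
#' context, evaluates the forward log-likelihood of each under the pore
#' model (multi-component entries contribute through their
#' maximum-density component), and returns the LLR: the sum of
#' log-likelihoods of the hypotheses carrying the target modification
#' minus the sum for those without it. For `target = "cpg"` the
#' methylated side is ref2 + ref4; for `target = "6ma"` it is ref3 +
#' ref4. When the window lacks adenines (or CpGs) the duplicate
#' hypotheses are omitted and the LLR degenerates to a two-hypothesis
#' difference.
#'
#' @param context Unmodified sequence context covering every k-mer
#'   overlapping the window.
#' @param events Events anchored within the context, ordered by signal
#'   time (numeric vector or tibble with `event_level_mean`).
#' @param target `"cpg"` or `"6ma"`.
#' @param interval_start,interval_end Window interval relative to the
#'   context (0-based half-open); modifications are hypothesised only
#'   inside it.
#' @param model,scaling,cfg,k As in [forward_loglik()].
#' @return A list with `llr` and `n_hypotheses`.
#' @export
llr_window <- function(context, events, target = c("cpg", "6ma"),
                       interval_start = 0L, interval_end = nchar(context),
                       model = NULL, scaling = read_scaling(),
                       cfg = hmm_config(), k = 6L) {
  target <- match.arg(target)
  hyps <- reference_variants(context, interval_start, interval_end)
  ll <- hypothesis_logliks(hyps, events, model, scaling, cfg, k)
  list(llr = llr_from_logliks(ll, target), n_hypotheses = length(hyps))
}

#' Convert LLR values to categorical methylation calls
#'
#' CpG: `llr >= cpg_meth` is `methylated`, `llr <= cpg_unmeth` is
#' `unmethylated`, anything between is `no_call`. Adenine windows:
#' `llr >= tau` is `contains_6mA` and otherwise `non_6mA`, where `tau` is
#' the low- (8) or high- (32) stringency threshold.
#'
#' @param llr Numeric vector of finite LLRs.
#' @param kind `"cpg_substring"` or `"adenine_window"` (recycled).
#' @param th A [thresholds()] object.
#' @param stringency `"low"` or `"high"` adenine threshold.
#' @return Character vector of calls.
#' @export
call_llr <- function(llr, kind, th = thresholds(),
                     stringency = c("low", "high")) {
  stringency <- match.arg(stringency)
  if (any(is.nan(llr))) stop("NaN llr", call. = FALSE)
  kind <- rep_len(kind, length(llr))
  tau <- if (stringency == "low") th$ada_low else th$ada_high
  dplyr::case_when(
    kind == "cpg_substring" & llr >= th$cpg_meth ~ "methylated",
    kind == "cpg_substring" & llr <= th$cpg_unmeth ~ "unmethylated",
    kind == "cpg_substring" ~ "no_call",
    kind == "adenine_window" & llr >= tau ~ "contains_6mA",
    kind == "adenine_window" ~ "non_6mA",
    TRUE ~ NA_character_
  )
}

#' Call methylation on every window of one read
#'
#' Segments the read's reference span into CpG substrings and tiled
#' adenine windows, computes the per-window LLR from the events anchored
#' to each window's context (all k-mers overlapping the window plus k-1
#' flanking bases), and attaches categorical calls. Windows without
#' overlapping events are reported as `no_call` with an `NA` LLR; one bad
#' window never aborts the read.
#'
#' @param events One read's eventalign-style tibble: columns `read_id`,
#'   `contig`, `position` (0-based k-mer start), `event_index`,
#'   `event_level_mean`, `reference_kmer`.
#' @param reference Reference sequence string for the read's contig.
#' @param model Pore-model tibble or prebuilt index.
#' @param scaling A [read_scaling()]; fitted from the read when `NULL`.
#' @param cfg,k As in [forward_loglik()].
#' @param th A [thresholds()].
#' @param stringency Adenine-window stringency.
#' @param window_size,flank Segmentation parameters (see
#'   [segment_read()]).
#' @param kinds Which window kinds to call: any of `"cpg_substring"`,
#'   `"adenine_window"` (default both).
#' @return A tibble of per-window calls: `read_id`, `contig`, `start`,
#'   `end`, `kind`, `n_cpg`, `n_adenine`, `llr`, `n_hypotheses`, `call`.
#' @export
call_read <- function(events, reference, model, scaling = NULL,
                      cfg = hmm_config(), th = thresholds(),
                      stringency = "low", window_size = 50L, flank = 10L,
                      k = 6L, kinds = c("cpg_substring", "adenine_window")) {
  events <- dplyr::arrange(events, .data$event_index)
  idx <- if (is.list(model) && !is.data.frame(model)) model else model_index(model)
  if (is.null(scaling)) scaling <- fit_read_scaling(events, idx, cfg)

  span_start <- min(events$position)
  span_end <- max(events$position) + k
  ref_chars <- strsplit(reference, "")[[1]]
  span_seq <- substr(reference, span_start + 1L, span_end)

  cpg_sites <- span_start - 1L +
    which(ref_chars[(span_start + 1L):(span_end - 1L)] == "C" &
          ref_chars[(span_start + 2L):span_end] == "G")
  aden <- span_start - 1L +
    which(ref_chars[(span_start + 1L):span_end] == "A")

  wins <- segment_read(span_start, span_end, cpg_sites, aden,
                       window_size, flank)
  if (nrow(wins) == 0L) {
    return(tibble::tibble(read_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          kind = character(), n_cpg = integer(),
                          n_adenine = integer(), llr = numeric(),
                          n_hypotheses = integer(), call = character()))
  }
  # adenine windows with nothing to test are dropped
  wins <- wins[!(wins$kind == "adenine_window" &
                 wins$n_cpg == 0L & wins$n_adenine == 0L), ]
  wins <- wins[wins$kind %in% kinds, ]
  if (nrow(wins) == 0L) {
    return(tibble::tibble(read_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          kind = character(), n_cpg = integer(),
                          n_adenine = integer(), llr = numeric(),
                          n_hypotheses = integer(), call = character()))
  }

  read_id <- events$read_id[1]
  contig <- if ("contig" %in% names(events)) events$contig[1] else NA_character_

  res <- purrr::pmap(wins, function(kind, start, end, n_cpg, n_adenine) {
    ctx_start <- max(span_start, start - (k - 1L))
    ctx_end <- min(span_end, end + (k - 1L))
    ctx <- substr(reference, ctx_start + 1L, ctx_end)
    ev <- events[events$position >= ctx_start &
                 events$position <= ctx_end - k, ]
    target <- if (kind == "cpg_substring") "cpg" else "6ma"
    if (nrow(ev) == 0L || nchar(ctx) < k) {
      return(tibble::tibble(llr = NA_real_, n_hypotheses = NA_integer_,
                            call = "no_call"))
    }
    out <- tryCatch(
      llr_window(ctx, ev, target, start - ctx_start, end - ctx_start,
                 idx, scaling, cfg, k),
      error = function(e) NULL)
    if (is.null(out)) {
      return(tibble::tibble(llr = NA_real_, n_hypotheses = NA_integer_,
                            call = "no_call"))
    }
    tibble::tibble(llr = out$llr, n_hypotheses = out$n_hypotheses,
                   call = call_llr(out$llr, kind, th, stringency))
  })

  dplyr::bind_cols(
    tibble::tibble(read_id = read_id, contig = contig),
    wins,
    dplyr::bind_rows(res)
  )
}

#' Call methylation on a set of reads
#'
#' Applies [call_read()] to every read in an eventalign-style table.
#' Reads whose scaling fit fails (too few labelled events) are skipped
#' with a warning.
#'
#' @param events Eventalign-style tibble covering one or more reads.
#' @param reference Named character vector of reference sequences (names
#'   matching the `contig` column), or a single unnamed sequence.
#' @inheritParams call_read
#' @return A tibble of per-window calls across reads.
#' @export
call_reads <- function(events, reference, model, cfg = hmm_config(),
                       th = thresholds(), stringency = "low",
                       window_size = 50L, flank = 10L, k = 6L,
                       kinds = c("cpg_substring", "adenine_window")) {
  idx <- if (is.list(model) && !is.data.frame(model)) model else model_index(model)
  skipped <- 0L
  out <- lapply(split(events, events$read_id), function(grp) {
    ref <- if (length(reference) == 1L && is.null(names(reference))) {
      reference
    } else {
      reference[[grp$contig[1]]]
    }
    tryCatch(
      call_read(grp, ref, idx, NULL, cfg, th, stringency, window_size,
                flank, k, kinds),
      error = function(e) { skipped <<- skipped + 1L; NULL })
  })
  if (skipped > 0L) {
    warning(skipped, " read(s) skipped (no valid scaling fit)",
            call. = FALSE)
  }
  dplyr::bind_rows(out)
}
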