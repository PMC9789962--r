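# Expanded six-letter alphabet: A,C,G,T plus M (5-methylcytosine, CpG context
# only) and Z (N6-methyladenine).

NJ_ALPHABET <- c("A", "C", "G", "T", "M", "Z")

#' Enumerate all k-mers over the six-letter modification alphabet
#'
#' Generates every length-`k` string over `{A,C,G,T,M,Z}` (or a restricted
#' alphabet) and flags each as a valid or invalid methylation context.
#' Because cytosine methylation is restricted to CpG dinucleotides, any
#' k-mer in which an `M` is followed by a letter other than `G` is invalid;
#' an `M` at the final position is valid (its `G` lies in the next k-mer).
#'
#' @param k K-mer length, an integer between 1 and 8.
#' @param alphabet Character vector of single letters to enumerate over.
#'   Defaults to the full six-letter alphabet.
#' @return A tibble with columns `kmer` and `valid` (logical), containing
#'   exactly `length(alphabet)^k` rows.
#' @examples
#' nrow(enumerate_kmers(2))                              # 36
#' sum(enumerate_kmers(2, c("A", "C", "G", "T"))$valid)  # 16, all valid
#' @export
enumerate_kmers <- function(k, alphabet = NJ_ALPHABET) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 1 || k > 8) {
    stop("`k` must be a single integer between 1 and 8", call. = FALSE)
  }
  if (!all(alphabet %in% NJ_ALPHABET)) {
    stop("`alphabet` may only contain letters A, C, G, T, M, Z",
         call. = FALSE)
  }
  k <- as.integer(k)
  # expand.grid with the first factor varying slowest gives lexicographic order
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  kmers <- sort(kmers)
  tibble::tibble(kmer = kmers, valid = valid_kmer(kmers))
}

#' Test whether k-mers are valid methylation contexts
#'
#' A k-mer is invalid iff it contains an `M` immediately followed by any
#' letter other than `G` (`MA`, `MC`, `MT`, `MM`, `MZ`). A terminal `M` is
#' valid: the CpG's guanine is completed by the next k-mer downstream.
#'
#' @param kmer Character vector of k-mers over `{A,C,G,T,M,Z}`.
#' @return Logical vector, one element per k-mer.
#' @examples
#' valid_kmer(c("TAMGGG", "TAMAGG", "TTTTTM"))  # TRUE FALSE -> TRUE
#' @export
valid_kmer <- function(kmer) {
  if (!is.character(kmer)) stop("`kmer` must be character", call. = FALSE)
  if (any(grepl("[^ACGTMZ]", kmer))) {
    bad <- kmer[grepl("[^ACGTMZ]", kmer)][1L]
    stop("illegal character in k-mer '", bad, "'", call. = FALSE)
  }
  !grepl("M[^G]", kmer)
}

#' Collapse k-mers to their k-bar equivalence class
#'
#' Partial adenine labelling makes it impossible to assign trained
#' parameters to individual `Z` positions, so all k-mers sharing base
#' composition and order up to A/Z substitution are pooled into one class
#' (the k-bar class). The class label is the A-collapsed k-mer with a
#' trailing `+` when the original k-mer carried at least one `Z`
#' (e.g. `TZCACG`, `TACZCG` and `TZCZCG` all map to `TACACG+`).
#'
#' @param kmer Character vector of valid k-mers.
#' @return A tibble with columns `kmer`, `base_kmer` (Z replaced by A),
#'   `has_6ma` (logical) and `label` (the class key used by the pore model).
#' @examples
#' collapse_kmer(c("TZCACG", "TACZCG", "TACACG"))
#' @export
collapse_kmer <- function(kmer) {
  ok <- valid_kmer(kmer)
  if (any(!ok)) {
    stop("invalid k-mer(s): ", paste(utils::head(kmer[!ok], 3), collapse = ", "),
         call. = FALSE)
  }
  base <- gsub("Z", "A", kmer, fixed = TRUE)
  has_6ma <- grepl("Z", kmer, fixed = TRUE)
  tibble::tibble(
    kmer = kmer,
    base_kmer = base,
    has_6ma = has_6ma,
    label = paste0(base, ifelse(has_6ma, "+", ""))
  )
}

# Map every k-mer of a six-letter sequence to its pore-model label.
# Errors on invalid k-mers or sequences shorter than k.
seq_kmer_labels <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k", call. = FALSE)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  collapse_kmer(kmers)$label
}

#' Build the modification-hypothesis variants of a window context
#'
#' For a window being classified, constructs up to four sequence
#' hypotheses: `ref1` (unmodified), `ref2` (every CpG cytosine inside the
#' window interval replaced by `M`, jointly), `ref3` (every adenine inside
#' the interval replaced by `Z`, so that all overlapping k-mers are
#' evaluated under their 6mA-containing class) and `ref4` (both). When the
#' interval contains no CpG, `ref2`/`ref4` duplicate `ref1`/`ref3` and are
#' omitted; symmetrically when it contains no adenine.
#'
#' @param context Character scalar: the sequence context covering all
#'   k-mers overlapping the interval (plain `{A,C,G,T}` letters).
#' @param interval_start,interval_end 0-based half-open interval of the
#'   window *relative to the start of `context`*. Defaults to the whole
#'   context.
#' @return Named character vector of distinct hypothesis sequences, names
#'   among `ref1`..`ref4`.
#' @examples
#' reference_variants("TTACGTT")  # ref1 "TTACGTT", ref2 "TTAMGTT", ...
#' @export
reference_variants <- function(context,
                               interval_start = 0L,
                               interval_end = nchar(context)) {
  stopifnot(is.character(context), length(context) == 1L)
  if (grepl("[^ACGT]", context)) {
    stop("`context` must be an unmodified {A,C,G,T} sequence", call. = FALSE)
  }
  n <- nchar(context)
  chars <- strsplit(context, "")[[1]]
  idx <- seq_len(n) - 1L  # 0-based

  in_win <- idx >= interval_start & idx < interval_end
  # CpG cytosines whose C falls inside the interval
  cpg_c <- which(chars == "C" & c(chars[-1], "") == "G" & in_win)
  aden <- which(chars == "A" & in_win)

  if (length(cpg_c) == 0L && length(aden) == 0L) {
    stop("window contains neither CpG nor adenine; nothing to test",
         call. = FALSE)
  }

  make <- function(m, z) {
    v <- chars
    if (m) v[cpg_c] <- "M"
    if (z) v[aden] <- "Z"
    paste(v, collapse = "")
  }
  out <- c(ref1 = make(FALSE, FALSE))
  if (length(cpg_c) > 0L) out["ref2"] <- make(TRUE, FALSE)
  if (length(aden) > 0L) out["ref3"] <- make(FALSE, TRUE)
  if (length(cpg_c) > 0L && length(aden) > 0L) out["ref4"] <- make(TRUE, TRUE)
  out
}

#' Segment a read's reference span into classification windows
#'
#' Produces the per-read units of joint methylation calling:
#' * `cpg_substring` rows: maximal clusters of CpGs padded so that each
#'   cluster has at least `flank` CpG-free bases on both sides. Consecutive
#'   CpGs separated by fewer than `flank` CpG-free bases are merged into
#'   one substring. Clusters whose flanks would extend beyond the read
#'   span are dropped.
#' * `adenine_window` rows: a non-overlapping `window_size`-bp tiling of
#'   the span anchored at the read's reference start; a terminal remainder
#'   shorter than `window_size` is dropped.
#'
#' @param span_start,span_end 0-based half-open reference interval covered
#'   by the read.
#' @param cpg_sites Integer vector of 0-based positions of the `C` of each
#'   CpG within the span.
#' @param adenine_sites Integer vector of 0-based adenine positions within
#'   the span.
#' @param window_size Adenine window width in bp (default 50).
#' @param flank Required CpG-free flank in bp (default 10).
#' @return A tibble with columns `kind`, `start`, `end`, `n_cpg`,
#'   `n_adenine`; empty when there is nothing to segment.
#' @export
segment_read <- function(span_start, span_end, cpg_sites, adenine_sites,
                         window_size = 50L, flank = 10L) {
  stopifnot(span_end >= span_start, window_size > 0, flank >= 0)
  cpg_sites <- sort(as.integer(cpg_sites))
  adenine_sites <- sort(as.integer(adenine_sites))
  if (length(cpg_sites) &&
      (min(cpg_sites) < span_start || max(cpg_sites) + 2L > span_end)) {
    stop("CpG sites outside the read span", call. = FALSE)
  }

  rows <- list()

  if (length(cpg_sites)) {
    # merge CpGs with < `flank` CpG-free bases between them; a gap of at
    # least `flank` opens a new cluster
    new_cluster <- c(TRUE,
                     cpg_sites[-1] - (cpg_sites[-length(cpg_sites)] + 2L) >= flank)
    cluster <- cumsum(new_cluster)
    for (cl in split(cpg_sites, cluster)) {
      s <- min(cl) - flank
      e <- max(cl) + 2L + flank
      if (s >= span_start && e <= span_end) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "cpg_substring", start = s, end = e,
          n_cpg = length(cl),
          n_adenine = sum(adenine_sites >= s & adenine_sites < e)
        )
      }
    }
  }

  n_win <- (span_end - span_start) %/% window_size
  if (n_win > 0L) {
    ws <- span_start + window_size * (seq_len(n_win) - 1L)
    we <- ws + window_size
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "adenine_window", start = as.integer(ws), end = as.integer(we),
      n_cpg = vapply(seq_len(n_win), function(i)
        sum(cpg_sites >= ws[i] & cpg_sites + 2L <= we[i]), integer(1)),
      n_adenine = vapply(seq_len(n_win), function(i)
        sum(adenine_sites >= ws[i] & adenine_sites < we[i]), integer(1))
    )
  }

  if (length(rows) == 0L) {
    return(tibble::tibble(kind = character(), start = integer(),
                          end = integer(), n_cpg = integer(),
                          n_adenine = integer()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$start, .data$kind)
}
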