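# Seeded simulator for event-aligned nanopore reads with known
# methylation truth. Event generation follows the calling model's own
# assumptions: per-read shift/scale/variance distortion (a, b, d),
# Gaussian events around (possibly methylation-shifted) k-mer levels,
# geometric stays and Bernoulli skips.

# per-position shift weights: CpG methylation perturbs the signal most at
# the fifth k-mer position, adenine methylation in the middle positions
shift_profile <- function(k, type = c("M", "Z")) {
  type <- match.arg(type)
  if (type == "M") {
    w <- c(0.3, 0.5, 0.7, 0.85, 1.0, 0.6)
  } else {
    w <- c(0.5, 0.8, 1.0, 1.0, 0.8, 0.5)
  }
  if (k == 6L) w else stats::approx(seq(0, 1, length.out = 6), w,
                                    seq(0, 1, length.out = k))$y
}

# mean shift (pA) of a modified k-mer relative to its unmodified parent.
# Each modified position contributes a signed, position-weighted offset;
# the sign is a deterministic hash of the parent k-mer, the position and
# the modification type, so shifts go in both directions and 5mC / 6mA
# perturb the same k-mer independently (as real shift tables do).
kmer_shift <- function(kmer, base_sd, shift_sd_units, k = nchar(kmer)) {
  chars <- strsplit(kmer, "")[[1]]
  wM <- shift_profile(k, "M")
  wZ <- shift_profile(k, "Z")
  pM <- which(chars == "M")
  pZ <- which(chars == "Z")
  # the strongest-placed modification sets the magnitude
  w <- max(c(wM[pM], wZ[pZ]))
  parent <- gsub("Z", "A", gsub("M", "C", kmer))
  h <- sum(utf8ToInt(parent)) + sum(7L * pM) + sum(11L * pZ + 13L)
  sgn <- if (h %% 2L == 0L) 1 else -1
  sgn * shift_sd_units * base_sd * w
}

#' Simulate a reference sequence with controlled CpG density
#'
#' Draws a random sequence in which G is suppressed after C (so the
#' background CpG rate is zero) and then injects CpG dinucleotides at
#' uniformly sampled, well-separated positions until the requested
#' density is reached. Reproducible given `seed`.
#'
#' @param length Reference length in bp.
#' @param cpg_density Target CpGs per bp (default 0.02).
#' @param gc GC content of the background sequence (default 0.5).
#' @param seed Integer seed (required).
#' @return A list with `sequence` (string), `cpg_sites` (0-based C
#'   positions) and `length`.
#' @export
simulate_reference <- function(length, cpg_density = 0.02, gc = 0.5,
                               seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(length >= 100, cpg_density >= 0, cpg_density < 0.2)
  withr::local_seed(seed)

  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- character(length)
  prev <- ""
  bases <- names(p)
  # no-CpG background: after a C, G is excluded
  draws <- sample(bases, length, replace = TRUE, prob = p)
  redraw <- sample(c("A", "C", "T"), length, replace = TRUE,
                   prob = p[c("A", "C", "T")])
  for (i in seq_len(length)) {
    chars[i] <- if (prev == "C" && draws[i] == "G") redraw[i] else draws[i]
    prev <- chars[i]
  }

  n_cpg <- round(length * cpg_density)
  cpg_sites <- integer(0)
  if (n_cpg > 0) {
    # candidate C positions spaced >= 4 bp apart, away from the ends
    cand <- sample(seq(5L, length - 6L), min(5L * n_cpg, length %/% 8))
    keep <- integer(0)
    for (pos in cand) {
      if (!any(abs(keep - pos) < 4L)) keep <- c(keep, pos)
      if (base::length(keep) >= n_cpg) break
    }
    cpg_sites <- sort(keep)
    chars[cpg_sites + 1L] <- "C"
    chars[cpg_sites + 2L] <- "G"
  }
  seqc <- paste(chars, collapse = "")
  # injected CpGs may abut pre-existing Cs; recompute realized sites
  real <- gregexpr("CG", seqc, fixed = TRUE)[[1]]
  cpg_sites <- if (real[1] == -1L) integer(0) else as.integer(real) - 1L
  list(sequence = seqc, cpg_sites = cpg_sites, length = length)
}

#' Accessible (linker) regions of a nucleosome-array footprint
#'
#' Alternating protected/accessible segments: `nucleosome` bp wrapped
#' (inaccessible to the adenine methyltransferase) followed by `linker`
#' bp accessible, tiled across the interval.
#'
#' @param length Interval length in bp.
#' @param nucleosome Protected segment width (default 147).
#' @param linker Accessible segment width (default 30).
#' @param offset Phase offset of the first nucleosome (default 0).
#' @return A tibble of 0-based half-open accessible intervals.
#' @export
footprint_regions <- function(length, nucleosome = 147L, linker = 30L,
                              offset = 0L) {
  period <- nucleosome + linker
  starts <- seq(offset + nucleosome, length - 1L, by = period)
  starts <- starts[starts < length]
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(pmin(starts + linker, length)))
}

#' Simulate event-aligned reads with known methylation truth
#'
#' Each read receives a haplotype, per-read scaling distortions
#' (`a ~ Normal(0, sd_a)`, `b ~ Normal(1, sd_b)`, `d ~ Normal(1, sd_d)`,
#' the latter two truncated positive), a per-read methylation state
#' (every CpG methylated independently with `cpg_meth_prob`; every
#' adenine inside `accessible` labelled with `ada_label_prob`), and a
#' stream of events: per k-mer, a Bernoulli(`p_skip`) skip or
#' `1 + Geometric(p_stay)` events drawn from
#' `Normal(a + b * (mu_k + shift), (d * sigma_k * signal_noise)^2)`,
#' where the shift applies the position-weighted methylation offset
#' (peaking mid-k-mer for 6mA, at the fifth position for 5mC; default
#' magnitude `shift_sd_units` = 3 standard deviations).
#'
#' @param reference A list from [simulate_reference()] (or a list with
#'   `sequence` and `cpg_sites`).
#' @param model Base pore-model tibble.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp.
#' @param cpg_meth_prob Per-CpG methylation probability (default 0).
#' @param ada_label_prob Per-adenine labelling probability inside
#'   accessible regions (default 0).
#' @param accessible Tibble of accessible intervals (`start`, `end`),
#'   `NULL` for labelling everywhere (naked DNA).
#' @param sd_a,sd_b,sd_d Scaling distortion spreads (defaults 2 pA,
#'   0.02, 0.05).
#' @param p_stay,p_skip Stay and skip probabilities (defaults 0.1, 0.01).
#' @param shift_sd_units Methylation shift magnitude in units of the
#'   k-mer sd (default 3).
#' @param signal_noise Multiplier on the emission sd; 0 gives noiseless
#'   events exactly at the scaled levels.
#' @param contig Contig name written to the events (default "sim").
#' @param seed Integer seed (required).
#' @param k K-mer length.
#' @return A list with `events` (eventalign-style tibble), `cpg_truth`
#'   (`read_id`, `pos`, `methylated`), `ada_truth` (`read_id`, `pos`,
#'   `labeled`) and `reads` (`read_id`, `start`, `end`, `haplotype`,
#'   `a`, `b`, `d`).
#' @export
simulate_reads <- function(reference, model, n_reads, read_length,
                           cpg_meth_prob = 0, ada_label_prob = 0,
                           accessible = NULL, sd_a = 2, sd_b = 0.02,
                           sd_d = 0.05, p_stay = 0.1, p_skip = 0.01,
                           shift_sd_units = 3, signal_noise = 1,
                           contig = "sim", seed, k = 6L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::local_seed(seed)

  refseq <- reference$sequence
  ref_len <- nchar(refseq)
  cpg_sites <- reference$cpg_sites
  ref_chars <- strsplit(refseq, "")[[1]]
  idx <- model_index(model)

  acc_mask <- rep(is.null(accessible), ref_len)
  if (!is.null(accessible)) {
    for (i in seq_len(nrow(accessible))) {
      acc_mask[(accessible$start[i] + 1L):accessible$end[i]] <- TRUE
    }
  }
  aden_all <- which(ref_chars == "A") - 1L  # 0-based

  events_l <- list(); cpg_l <- list(); ada_l <- list(); reads_l <- list()
  for (r in seq_len(n_reads)) {
    read_id <- sprintf("read_%04d", r)
    L <- min(read_length, ref_len)
    s <- sample.int(ref_len - L + 1L, 1L) - 1L  # 0-based start
    e <- s + L
    a <- stats::rnorm(1, 0, sd_a)
    b <- max(stats::rnorm(1, 1, sd_b), 0.5)
    d <- max(stats::rnorm(1, 1, sd_d), 0.5)
    hap <- sample(1:2, 1L)

    cpg_in <- cpg_sites[cpg_sites >= s & cpg_sites + 2L <= e]
    meth <- stats::runif(length(cpg_in)) < cpg_meth_prob
    aden_in <- aden_all[aden_all >= s & aden_all < e]
    eligible <- acc_mask[aden_in + 1L]
    labeled <- eligible & stats::runif(length(aden_in)) < ada_label_prob

    mod <- ref_chars[(s + 1L):e]
    mod[cpg_in[meth] - s + 1L] <- "M"
    mod[aden_in[labeled] - s + 1L] <- "Z"
    mod_seq <- paste(mod, collapse = "")

    n_k <- L - k + 1L
    starts <- seq_len(n_k)
    mod_kmers <- substring(mod_seq, starts, starts + k - 1L)
    plain_kmers <- substring(refseq, s + starts, s + starts + k - 1L)

    ev_mean <- list(); ev_pos <- list(); ev_kmer <- list()
    skip <- stats::runif(n_k) < p_skip
    n_extra <- stats::rgeom(n_k, 1 - p_stay)
    for (j in seq_len(n_k)) {
      if (skip[j]) next
      base <- idx[[plain_kmers[j]]]
      mu <- base$mean[1]
      sig <- base$sd[1]
      if (grepl("[MZ]", mod_kmers[j])) {
        mu <- mu + kmer_shift(mod_kmers[j], sig, shift_sd_units, k)
      }
      n_ev <- 1L + n_extra[j]
      means <- stats::rnorm(n_ev, a + b * mu, d * sig * signal_noise)
      ev_mean[[j]] <- means
      ev_pos[[j]] <- rep(s + j - 1L, n_ev)
      ev_kmer[[j]] <- rep(plain_kmers[j], n_ev)
    }
    mm <- unlist(ev_mean)
    if (is.null(mm) || length(mm) == 0L) next
    n_ev_tot <- length(mm)
    events_l[[r]] <- tibble::tibble(
      contig = contig, position = unlist(ev_pos),
      reference_kmer = unlist(ev_kmer), read_id = read_id, strand = "+",
      event_index = seq_len(n_ev_tot), event_level_mean = mm,
      event_stdv = abs(stats::rnorm(n_ev_tot, 1, 0.2)),
      event_length = stats::rexp(n_ev_tot, 500)
    )
    if (length(cpg_in)) {
      cpg_l[[r]] <- tibble::tibble(read_id = read_id, pos = cpg_in,
                                   methylated = meth)
    }
    if (length(aden_in)) {
      ada_l[[r]] <- tibble::tibble(read_id = read_id, pos = aden_in,
                                   labeled = labeled)
    }
    reads_l[[r]] <- tibble::tibble(read_id = read_id, start = s, end = e,
                                   haplotype = hap, a = a, b = b, d = d)
  }

  list(events = dplyr::bind_rows(events_l),
       cpg_truth = dplyr::bind_rows(cpg_l),
       ada_truth = dplyr::bind_rows(ada_l),
       reads = dplyr::bind_rows(reads_l))
}

#' Simulate the four model-training conditions
#'
#' Emulates the training design on PCR-amplified (methylation-free) DNA:
#' untreated (`pcr`), near-complete CpG methylation (`msssi`, per-CpG
#' probability 0.962), partial adenine methylation on naked DNA
#' (`hia5`, labelling everywhere at `ada_label_prob`), and both
#' (`both`). Partial adenine labelling is what forces k-bar class
#' mixtures during training.
#'
#' @param reference A list from [simulate_reference()].
#' @param model Base pore-model tibble.
#' @param n_reads Reads per condition.
#' @param read_length Read length in bp.
#' @param cpg_meth_prob M.SssI completeness (default 0.962).
#' @param ada_label_prob Per-adenine labelling probability (default 0.4).
#' @param seed Integer seed; condition seeds are derived from it.
#' @param ... Passed on to [simulate_reads()].
#' @return Named list (`pcr`, `msssi`, `hia5`, `both`) of
#'   [simulate_reads()] results.
#' @export
simulate_training_conditions <- function(reference, model, n_reads,
                                         read_length,
                                         cpg_meth_prob = 0.962,
                                         ada_label_prob = 0.4, seed, ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  probs <- list(pcr = c(0, 0), msssi = c(cpg_meth_prob, 0),
                hia5 = c(0, ada_label_prob),
                both = c(cpg_meth_prob, ada_label_prob))
  out <- list()
  for (i in seq_along(probs)) {
    tag <- names(probs)[i]
    out[[tag]] <- simulate_reads(
      reference, model, n_reads, read_length,
      cpg_meth_prob = probs[[tag]][1], ada_label_prob = probs[[tag]][2],
      accessible = NULL, seed = seed + i, ...)
  }
  out
}
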