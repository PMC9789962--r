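# Emission-model training: 5-round Viterbi realignment + grid EM fitting
# + consistency-based parameter assignment, from the four labelled
# training conditions (untreated PCR, near-complete CpG methylation,
# partial adenine methylation, both).

TRAIN_CONDITIONS <- c("pcr", "msssi", "hia5", "both")

#' Build the training hypothesis sequence for a condition
#'
#' `pcr` leaves the reference unmodified; `msssi` replaces the cytosine of
#' every CpG by `M` (near-complete CpG methylation); `hia5` replaces every
#' adenine by `Z`, so that each adenine-containing k-mer is pooled into
#' its k-bar class (partial labelling makes per-position assignment
#' impossible); `both` applies both substitutions.
#'
#' @param reference Reference sequence (plain `{A,C,G,T}` string).
#' @param condition One of `"pcr"`, `"msssi"`, `"hia5"`, `"both"`.
#' @return The condition sequence over the six-letter alphabet.
#' @export
condition_sequence <- function(reference, condition) {
  condition <- match.arg(condition, TRAIN_CONDITIONS)
  out <- reference
  if (condition %in% c("msssi", "both")) {
    out <- gsub("CG", "MG", out, fixed = TRUE)
  }
  if (condition %in% c("hia5", "both")) {
    out <- gsub("A", "Z", out, fixed = TRUE)
  }
  out
}

#' Collect shift/scale-transformed events per k-mer class for one read
#'
#' Viterbi-aligns a read's events to a (condition-substituted) sequence
#' and returns the match-state events transformed to the model scale:
#' `x = (e - a) / b` with variance factor `v = d / b`, keyed by the
#' aligned k-mer's class label.
#'
#' @param events Tibble of one read's events, ordered by signal time, with
#'   an `event_level_mean` column.
#' @param seq Hypothesis sequence over the six-letter alphabet.
#' @param model Pore-model tibble or prebuilt index.
#' @param scaling A [read_scaling()] fitted for this read.
#' @param cfg An [hmm_config()].
#' @param k K-mer length.
#' @return A tibble with columns `label`, `x`, `v`.
#' @export
collect_transformed_events <- function(events, seq, model, scaling,
                                       cfg = hmm_config(), k = 6L) {
  if (is.null(scaling)) stop("missing read scaling", call. = FALSE)
  va <- viterbi_align(events, seq, model, scaling, cfg, k)
  labels <- seq_kmer_labels(seq, k)
  e <- if (is.data.frame(events)) events$event_level_mean else as.numeric(events)
  keep <- va$path$state == "match"
  tibble::tibble(
    label = labels[va$path$kmer_index[keep]],
    x = (e[keep] - scaling$a) / scaling$b,
    v = scaling$d / scaling$b
  )
}

# component count for a target label: 2 for a single-modification (M-only)
# k-mer; for k-bar classes, one component per pooled A/Z pattern plus the
# unmodified one, i.e. 2^nA, capped
target_n_components <- function(label, max_components = 4L) {
  if (!grepl("+", label, fixed = TRUE)) return(2L)
  base <- sub("+", "", label, fixed = TRUE)
  n_a <- stringr::str_count(base, "A")
  min(2^n_a, max_components)
}

target_kind <- function(label) {
  if (grepl("+", label, fixed = TRUE)) "multi_component" else "two_component"
}

#' Train per-k-mer emission parameters from labelled condition datasets
#'
#' Runs the outer training loop: in each of `cfg$outer_rounds` rounds,
#' every read is Viterbi-realigned to its condition sequence under the
#' current model, transformed events are pooled per k-mer class across
#' conditions, mixtures are fitted over the full initialisation grid, and
#' parameters are assigned by the consistency rule. Methylated / k-bar
#' entries without a consensus keep their sd+2 initialisation and are
#' flagged untrained. Unmodified k-mers are refit by a closed-form
#' single-Gaussian weighted fit from their pooled unmodified events.
#'
#' @param conditions Named list of eventalign-style tibbles; names must be
#'   among `"pcr"`, `"msssi"`, `"hia5"`, `"both"`. Each tibble needs
#'   columns `read_id`, `position` (0-based k-mer start),
#'   `reference_kmer`, `event_index`, `event_level_mean`.
#' @param reference Reference sequence string (plain letters).
#' @param base_model Base pore-model tibble with unmodified entries.
#' @param cfg A [training_config()].
#' @param hmm_cfg An [hmm_config()].
#' @param k K-mer length.
#' @return The trained pore-model tibble, with a `training_summary`
#'   attribute (tibble: `label`, `kind`, `n_events`, `trained`).
#' @export
train_model <- function(conditions, reference, base_model,
                        cfg = training_config(), hmm_cfg = hmm_config(),
                        k = 6L) {
  if (length(conditions) < 1L || is.null(names(conditions)) ||
      !all(names(conditions) %in% TRAIN_CONDITIONS)) {
    stop("`conditions` must be a named list with names among: ",
         paste(TRAIN_CONDITIONS, collapse = ", "), call. = FALSE)
  }
  cond_seqs <- lapply(stats::setNames(names(conditions), names(conditions)),
                      function(tag) condition_sequence(reference, tag))

  # target labels: every methylated k-mer / k-bar class occurring in a
  # condition sequence
  targets <- unique(unlist(lapply(cond_seqs, function(s) {
    labs <- unique(seq_kmer_labels(s, k))
    labs[grepl("[MZ+]", labs)]
  })))
  for (tag in setdiff(names(conditions), "pcr")) {
    labs <- unique(seq_kmer_labels(cond_seqs[[tag]], k))
    if (!any(grepl("[MZ+]", labs))) {
      stop("condition '", tag, "' yields no modified k-mer classes for ",
           "this reference", call. = FALSE)
    }
  }

  model <- init_methylated_entries(base_model, targets)
  base_idx <- model_index(base_model)

  # per-read event groups and scalings, fixed across rounds. The scaling
  # is fit on events anchored at positions whose condition-sequence k-mer
  # is unmodified: modified k-mers are signal-shifted and would bias the
  # least-squares fit. Falls back to all events when too few remain.
  plain_pos <- lapply(cond_seqs, function(s) {
    labs <- seq_kmer_labels(s, k)
    which(!grepl("[MZ+]", labs)) - 1L  # 0-based k-mer start positions
  })
  read_groups <- list()
  for (tag in names(conditions)) {
    ev <- dplyr::arrange(conditions[[tag]], .data$read_id, .data$event_index)
    for (grp in split(ev, ev$read_id)) {
      unmod <- grp[grp$position %in% plain_pos[[tag]], ]
      scl <- tryCatch(fit_read_scaling(unmod, base_idx, hmm_cfg),
                      error = function(e)
                        tryCatch(fit_read_scaling(grp, base_idx, hmm_cfg),
                                 error = function(e2) NULL))
      if (is.null(scl)) next
      rs <- min(grp$position)
      re <- max(grp$position) + k
      read_groups[[length(read_groups) + 1L]] <- list(
        tag = tag, events = grp,
        seq = substr(cond_seqs[[tag]], rs + 1L, re), scaling = scl)
    }
  }
  if (length(read_groups) == 0L) {
    stop("no reads with a valid scaling fit", call. = FALSE)
  }

  summary_tbl <- NULL
  for (round in seq_len(cfg$outer_rounds)) {
    idx <- model_index(model)
    pooled <- dplyr::bind_rows(lapply(read_groups, function(rg)
      collect_read_chunked(rg$events, cond_seqs[[rg$tag]], idx,
                           rg$scaling, hmm_cfg, k)))
    by_label <- split(pooled, pooled$label)

    rows <- list()
    updates <- list()
    for (label in names(by_label)) {
      d <- by_label[[label]]
      if (grepl("[MZ+]", label)) {
        ncomp <- target_n_components(label, cfg$max_components)
        # with few pooled events, fall back to a coarser component-count
        # guess (the modified patterns blend into one broad component)
        while (ncomp > 2L && nrow(d) < cfg$min_events_per_component * ncomp) {
          ncomp <- ncomp - 1L
        }
        if (nrow(d) < cfg$min_events_per_component * ncomp) {
          rows[[label]] <- tibble::tibble(label = label,
                                          kind = target_kind(label),
                                          n_events = nrow(d), trained = FALSE)
          next
        }
        parent <- parent_label(label)
        ref <- base_idx[[parent]]
        fits <- fit_gmm_grid(d$x, d$v, ref$mean[1], ref$sd[1], ncomp, cfg)
        asg <- assign_parameters(fits, ref$mean[1], ref$sd[1],
                                 target_kind(label), cfg$consistency_tol)
        if (asg$trained) {
          updates[[label]] <- entry_rows(label, asg$components, "trained")
        }
        rows[[label]] <- tibble::tibble(label = label,
                                        kind = target_kind(label),
                                        n_events = nrow(d),
                                        trained = asg$trained)
      } else {
        if (nrow(d) < cfg$min_events_per_component) next
        comp <- fit_single_gaussian(d$x, d$v)
        updates[[label]] <- entry_rows(label, comp, "trained")
      }
    }
    if (length(updates)) {
      add <- dplyr::bind_rows(updates)
      out <- dplyr::bind_rows(model[!model$kmer %in% add$kmer, ], add)
      model <- new_pore_model(dplyr::arrange(out, .data$kmer,
                                             .data$component_index))
    }
    summary_tbl <- dplyr::bind_rows(rows)
  }

  attr(model, "training_summary") <- summary_tbl
  model
}

# Realign one read in chunks of `chunk` k-mers (cutting the quadratic
# alignment cost): events are grouped by their reference anchors, each
# chunk is Viterbi-realigned against its local stretch of the condition
# sequence, and the transformed match events are pooled. Chunk
# boundaries follow the anchor positions, so every event is realigned
# exactly once.
collect_read_chunked <- function(events, cond_seq, idx, scaling, hmm_cfg,
                                 k, chunk = 120L) {
  pos <- events$position
  lo <- min(pos)
  hi <- max(pos)
  if (hi - lo + 1L <= chunk + chunk %/% 2L) {
    seq_sub <- substr(cond_seq, lo + 1L, hi + k)
    return(collect_transformed_events(events, seq_sub, idx, scaling,
                                      hmm_cfg, k))
  }
  starts <- seq(lo, hi, by = chunk)
  out <- lapply(starts, function(c0) {
    c1 <- min(c0 + chunk, hi + 1L)
    sel <- pos >= c0 & pos < c1
    if (!any(sel)) return(NULL)
    seq_sub <- substr(cond_seq, c0 + 1L, min(c1 + k - 1L, nchar(cond_seq)))
    if (nchar(seq_sub) < k) return(NULL)
    collect_transformed_events(events[sel, ], seq_sub, idx, scaling,
                               hmm_cfg, k)
  })
  dplyr::bind_rows(out)
}

# model rows for one entry's components
entry_rows <- function(label, components, provenance) {
  tibble::tibble(
    kmer = label,
    component_index = seq_len(nrow(components)),
    level_mean = components$mean,
    level_stdv = components$sd,
    weight = components$weight,
    provenance = provenance
  )
}

# replace a model entry's components
set_entry <- function(model, label, components, provenance) {
  add <- entry_rows(label, components, provenance)
  out <- dplyr::bind_rows(model[model$kmer != label, ], add)
  new_pore_model(dplyr::arrange(out, .data$kmer, .data$component_index))
}
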