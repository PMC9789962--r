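# Pore model: per-k-mer Gaussian emission components. Stored as a tibble
# with one row per component; k-bar classes are keyed by their collapsed
# label (see collapse_kmer).

new_pore_model <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("nj_pore_model", class(x))
  x
}

validate_pore_model <- function(model) {
  need <- c("kmer", "component_index", "level_mean", "level_stdv",
            "weight", "provenance")
  missing <- setdiff(need, names(model))
  if (length(missing)) {
    stop("pore model is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(model[c("kmer", "component_index")])) {
    stop("duplicate (kmer, component_index) rows in pore model",
         call. = FALSE)
  }
  if (any(model$level_stdv <= 0)) {
    stop("non-positive level_stdv in pore model", call. = FALSE)
  }
  wsum <- tapply(model$weight, model$kmer, sum)
  off <- abs(wsum - 1) > 1e-8
  if (any(off)) {
    stop("component weights do not sum to 1 for k-mer(s): ",
         paste(utils::head(names(wsum)[off], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(model)
}

#' Generate a synthetic reference pore model
#'
#' Builds a deterministic table of single-Gaussian current distributions
#' for all `4^k` unmodified k-mers. Means are a weighted sum of per-base,
#' per-position contributions (spanning roughly 70-130 pA, as for real
#' 6-mer tables) and standard deviations vary smoothly between about 1 and
#' 2.5 pA. This is a synthetic stand-in for an instrument-provided model,
#' suitable for simulation and testing; it reproduces the format and scale
#' of real pore models, not their values.
#'
#' @param k K-mer length (default 6).
#' @return A pore-model tibble with `4^k` single-component entries, all
#'   with weight 1 and provenance `"synthetic"`.
#' @export
synthetic_pore_model <- function(k = 6L) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  kmers <- sort(do.call(paste0, rev(grid)))
  mat <- do.call(rbind, strsplit(kmers, ""))
  # per-base values, position-weighted: central positions dominate the level
  base_val <- c(A = -1.6, C = 0.4, G = 1.1, T = -0.2)
  pos_w <- seq(2, 9, length.out = k)
  pos_w <- pos_w[order(abs(seq_len(k) - (k + 1) / 2))]  # peak mid-kmer
  contrib <- matrix(base_val[mat], nrow = length(kmers))
  mean_pa <- 100 + as.numeric(contrib %*% pos_w)
  # smooth deterministic spread in [1, 2.5] pA
  sd_pa <- 1.75 + 0.75 * sin(mean_pa * 2.399)
  new_pore_model(tibble::tibble(
    kmer = kmers,
    component_index = 1L,
    level_mean = round(mean_pa, 3),
    level_stdv = round(sd_pa, 3),
    weight = 1,
    provenance = "synthetic"
  ))
}

#' Read or write a pore model TSV
#'
#' The on-disk dialect mirrors instrument-style model tables but carries
#' one row per mixture component: columns `kmer` (or k-bar class label),
#' `component_index`, `level_mean`, `level_stdv`, `weight`, `provenance`.
#' `read_pore_model()` validates uniqueness of (kmer, component_index),
#' positive standard deviations, and per-entry weights summing to 1.
#'
#' @param path File path.
#' @return `read_pore_model()` returns a pore-model tibble;
#'   `write_pore_model()` returns `path` invisibly.
#' @export
read_pore_model <- function(path) {
  model <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_pore_model(model)
  model <- dplyr::arrange(model, .data$kmer, .data$component_index)
  new_pore_model(model)
}

#' @rdname read_pore_model
#' @param model A pore-model tibble.
#' @export
write_pore_model <- function(model, path) {
  validate_pore_model(model)
  readr::write_tsv(model, path, progress = FALSE)
  invisible(path)
}

parent_label <- function(label) {
  gsub("M", "C", gsub("+", "", label, fixed = TRUE), fixed = TRUE)
}

#' Initialise emission entries for methylated k-mers and k-bar classes
#'
#' Before training, every methylated target entry is seeded from its
#' unmodified parent (`+` stripped, `M` mapped back to `C`): the mean is
#' kept and the standard deviation is increased by 2 pA. Existing base
#' entries are never altered.
#'
#' @param model Base pore-model tibble containing the unmodified parents.
#' @param targets Character vector of methylated k-mer / k-bar class
#'   labels (e.g. `"TAMGGG"`, `"TACACG+"`).
#' @return The model with one `"initialized"` single-component row added
#'   per target (any pre-existing rows for a target are replaced).
#' @export
init_methylated_entries <- function(model, targets) {
  validate_pore_model(model)
  targets <- unique(targets)
  parents <- parent_label(targets)
  base <- model[model$component_index == 1L, ]
  hit <- match(parents, base$kmer)
  if (anyNA(hit)) {
    stop("base model lacks parent entries for: ",
         paste(utils::head(targets[is.na(hit)], 3), collapse = ", "),
         call. = FALSE)
  }
  add <- tibble::tibble(
    kmer = targets,
    component_index = 1L,
    level_mean = base$level_mean[hit],
    level_stdv = base$level_stdv[hit] + 2,
    weight = 1,
    provenance = "initialized"
  )
  out <- dplyr::bind_rows(model[!model$kmer %in% targets, ], add)
  new_pore_model(dplyr::arrange(out, .data$kmer, .data$component_index))
}

# Fast lookup structure: named list label -> list(mean, sd) vectors ordered
# by component_index. Build once, pass around internally.
model_index <- function(model) {
  validate_pore_model(model)
  model <- model[order(model$kmer, model$component_index), ]
  split_idx <- split(seq_len(nrow(model)), model$kmer)
  lapply(split_idx, function(i) {
    list(mean = model$level_mean[i], sd = model$level_stdv[i],
         weight = model$weight[i])
  })
}

# Look up a label; if a methylated/k-bar entry is absent, derive it from
# its unmodified parent (mean kept, sd + 2) so every valid class queried
# by the HMM has at least one component.
lookup_entry <- function(idx, label) {
  e <- idx[[label]]
  if (!is.null(e)) return(e)
  parent <- parent_label(label)
  if (parent != label) {
    p <- idx[[parent]]
    if (!is.null(p)) {
      return(list(mean = p$mean[1], sd = p$sd[1] + 2, weight = 1))
    }
  }
  stop("pore model has no entry (or parent entry) for k-mer '", label, "'",
       call. = FALSE)
}

#' Select the maximum-density component of a model entry
#'
#' During classification, multi-component entries (trained k-bar classes)
#' contribute through the single component maximising the Gaussian density
#' of the event under the read's scaling, i.e. a hard parameter selection
#' rather than a mixture marginal. Ties break deterministically to the
#' lowest component index.
#'
#' @param entry A list with numeric `mean` and `sd` vectors (one element
#'   per component), as stored in the pore model.
#' @param event Observed event mean current in pA.
#' @param scaling A read scaling object (see [fit_read_scaling()]).
#' @return Integer index of the selected component.
#' @export
best_component <- function(entry, event, scaling = read_scaling(0, 1, 1)) {
  stopifnot(length(entry$mean) >= 1L)
  dens <- stats::dnorm(event, scaling$a + scaling$b * entry$mean,
                       scaling$d * entry$sd, log = TRUE)
  which.max(dens)  # which.max returns the first (lowest-index) maximum
}
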