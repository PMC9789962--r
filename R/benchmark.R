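# Self-contained simulation benchmark: train emission models on the four
# labelled conditions, call fresh reads with known truth, and score the
# per-read classification.

#' Run the simulated joint-calling benchmark
#'
#' Generates a reference, simulates the four training conditions
#' (untreated, near-complete CpG methylation, partial adenine
#' methylation, both), trains the emission model with the full
#' 5-round grid-EM procedure, then calls fresh evaluation reads.
#' Reported scores:
#'
#' * per-read CpG classification AUC over singleton CpG substrings
#'   (sites containing exactly one CpG) of footprinted reads — adenines
#'   labelled only inside nucleosome-linker regions, as in real
#'   footprinting data — with truth taken from the per-read simulation
#'   record;
#' * per-read 6mA window classification AUC for each requested window
#'   size, from a treated/untreated pair of read sets: positives are
#'   windows of the everywhere-labelled set that truly contain at least
#'   one methylated adenine, negatives are windows of the unlabelled
#'   set.
#'
#' Everything is deterministic given `seed`.
#'
#' @param seed Integer seed (required).
#' @param ref_length Reference length in bp (default 900).
#' @param cpg_density Reference CpG density (default 0.02).
#' @param n_train_reads Reads per training condition (default 32).
#' @param n_eval_reads Reads per treated/untreated evaluation set
#'   (default 28).
#' @param n_footprint_reads Footprinted reads for the CpG evaluation
#'   (default 55).
#' @param read_length Read length (default `ref_length`).
#' @param ada_label_prob Per-adenine labelling probability in the
#'   Hia5-style conditions and the labelled evaluation set (default
#'   0.4).
#' @param eval_cpg_prob Per-CpG methylation probability in the
#'   evaluation sets (default 0.5).
#' @param shift_sd_units Methylation shift magnitude in sd units
#'   (default 3).
#' @param window_sizes Adenine window sizes to sweep (default
#'   `c(12, 24, 50, 100)`).
#' @param train_cfg A [training_config()].
#' @return A list with `auc` (tibble: `measure`, `window_size`, `auc`,
#'   `n_pos`, `n_neg`), `model` (the trained pore model), and
#'   `training_summary`.
#' @export
run_benchmark <- function(seed, ref_length = 900L, cpg_density = 0.02,
                          n_train_reads = 32L, n_eval_reads = 28L,
                          n_footprint_reads = 55L,
                          read_length = ref_length, ada_label_prob = 0.4,
                          eval_cpg_prob = 0.5, shift_sd_units = 3,
                          window_sizes = c(12L, 24L, 50L, 100L),
                          train_cfg = training_config()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  base_model <- synthetic_pore_model(6L)
  ref <- simulate_reference(ref_length, cpg_density, seed = seed)

  sims <- simulate_training_conditions(
    ref, base_model, n_reads = n_train_reads, read_length = read_length,
    ada_label_prob = ada_label_prob, shift_sd_units = shift_sd_units,
    seed = seed + 100L)
  trained <- train_model(lapply(sims, `[[`, "events"), ref$sequence,
                         base_model, train_cfg)

  idx <- model_index(trained)
  rows <- list()

  # CpG evaluation on footprinted reads (labelling restricted to
  # nucleosome linkers, as in footprinting data)
  acc <- footprint_regions(ref_length)
  sim_fp <- simulate_reads(
    ref, base_model, n_footprint_reads, read_length,
    cpg_meth_prob = eval_cpg_prob, ada_label_prob = ada_label_prob,
    accessible = acc, shift_sd_units = shift_sd_units,
    seed = seed + 400L)
  calls_fp <- call_reads(sim_fp$events, ref$sequence, idx,
                         kinds = "cpg_substring")
  cpg <- calls_fp[calls_fp$n_cpg == 1L & is.finite(calls_fp$llr), ]
  cpg$site <- cpg$start + 10L
  cpg <- dplyr::inner_join(cpg, sim_fp$cpg_truth,
                           by = c("read_id", site = "pos"))
  roc_c <- compute_roc(cpg$llr, cpg$methylated)
  rows[[1L]] <- tibble::tibble(
    measure = "cpg_site_auc", window_size = NA_integer_,
    auc = attr(roc_c, "auc"),
    n_pos = sum(cpg$methylated), n_neg = sum(!cpg$methylated))

  # 6mA window evaluation from a treated/untreated read-set pair
  sim_lab <- simulate_reads(
    ref, base_model, n_eval_reads, read_length,
    cpg_meth_prob = eval_cpg_prob, ada_label_prob = ada_label_prob,
    shift_sd_units = shift_sd_units, seed = seed + 200L)
  sim_un <- simulate_reads(
    ref, base_model, n_eval_reads, read_length,
    cpg_meth_prob = eval_cpg_prob, ada_label_prob = 0,
    shift_sd_units = shift_sd_units, seed = seed + 300L)
  sim_un$events$read_id <- paste0(sim_un$events$read_id, "_u")

  for (wsz in window_sizes) {
    calls_lab <- call_reads(sim_lab$events, ref$sequence, idx,
                            window_size = wsz, kinds = "adenine_window")
    calls_un <- call_reads(sim_un$events, ref$sequence, idx,
                           window_size = wsz, kinds = "adenine_window")

    ada_pos <- sim_lab$ada_truth[sim_lab$ada_truth$labeled, ]
    win_lab <- calls_lab[is.finite(calls_lab$llr), ]
    has_z <- mapply(function(rid, s, e)
      any(ada_pos$read_id == rid & ada_pos$pos >= s & ada_pos$pos < e),
      win_lab$read_id, win_lab$start, win_lab$end)
    win_lab <- win_lab[has_z, ]
    win_un <- calls_un[is.finite(calls_un$llr), ]
    roc <- compute_roc(c(win_lab$llr, win_un$llr),
                       c(rep(TRUE, nrow(win_lab)),
                         rep(FALSE, nrow(win_un))))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      measure = "ada_window_auc", window_size = wsz,
      auc = attr(roc, "auc"),
      n_pos = nrow(win_lab), n_neg = nrow(win_un))
  }

  list(auc = dplyr::bind_rows(rows), model = trained,
       training_summary = attr(trained, "training_summary"))
}
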