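# small synthetic setup shared across classifier tests: k = 3 model with
# an explicit methylated entry shifted by `shift` pA
classify_fixture <- function(shift = 8) {
  model <- synthetic_pore_model(3)
  labels <- unique(c(seq_kmer_labels(condition_sequence("TACGTT", "msssi"), 3),
                     seq_kmer_labels(condition_sequence("TACGTT", "both"), 3),
                     seq_kmer_labels(condition_sequence("TACGTT", "hia5"), 3)))
  targets <- labels[grepl("[MZ+]", labels)]
  model <- init_methylated_entries(model, targets)
  # give M-containing entries a real shift (init keeps the parent mean)
  for (lab in targets[grepl("M", targets)]) {
    parent <- nanojoint:::parent_label(lab)
    base <- model[model$kmer == parent, ]
    model <- nanojoint:::set_entry(
      model, lab,
      tibble::tibble(weight = 1, mean = base$level_mean + shift,
                     sd = base$level_stdv),
      "trained")
  }
  model
}

test_that("LLR is zero when hypotheses share identical emissions", {
  model <- synthetic_pore_model(3)
  # M entries identical to their parents: the hypotheses cannot differ
  ctx <- "TTCGTT"  # no adenine: hypotheses are ref1/ref2 only
  targets <- unique(seq_kmer_labels(gsub("CG", "MG", ctx), 3))
  targets <- targets[grepl("M", targets)]
  for (lab in targets) {
    parent <- nanojoint:::parent_label(lab)
    base <- model[model$kmer == parent, ]
    model <- nanojoint:::set_entry(
      model, lab,
      tibble::tibble(weight = 1, mean = base$level_mean,
                     sd = base$level_stdv), "trained")
  }
  withr::local_seed(21)
  e <- rnorm(4, 95, 5)
  out <- llr_window(ctx, e, "cpg", model = model, k = 3)
  expect_equal(out$llr, 0)
  expect_equal(out$n_hypotheses, 2)
})

test_that("the CpG LLR is antisymmetric in the hypothesis roles", {
  ll <- c(ref1 = -10.2, ref2 = -8.1, ref3 = -11.0, ref4 = -7.7)
  llr_meth <- nanojoint:::llr_from_logliks(ll, "cpg")
  swapped <- c(ref1 = ll[["ref2"]], ref2 = ll[["ref1"]],
               ref3 = ll[["ref4"]], ref4 = ll[["ref3"]])
  expect_equal(nanojoint:::llr_from_logliks(swapped, "cpg"), -llr_meth)
  # and the same for the 6mA contrast
  llr_ada <- nanojoint:::llr_from_logliks(ll, "6ma")
  swap6 <- c(ref1 = ll[["ref3"]], ref3 = ll[["ref1"]],
             ref2 = ll[["ref4"]], ref4 = ll[["ref2"]])
  expect_equal(nanojoint:::llr_from_logliks(swap6, "6ma"), -llr_ada)
})

test_that("simulated methylated reads push the CpG LLR across the threshold", {
  model <- classify_fixture(shift = 8)
  ctx <- "TACGTT"
  base_mu <- function(km) model$level_mean[model$kmer == km][1]
  kms <- substring(ctx, 1:4, 3:6)
  kms_meth <- substring("TAMGTT", 1:4, 3:6)
  mu_un <- vapply(kms, base_mu, numeric(1))
  mu_me <- vapply(kms_meth, base_mu, numeric(1))
  sig <- vapply(kms, function(km) model$level_stdv[model$kmer == km][1],
                numeric(1))
  withr::local_seed(22)
  up <- 0L; dn <- 0L
  for (rep in 1:200) {
    e_meth <- rnorm(4, mu_me, sig)
    e_un <- rnorm(4, mu_un, sig)
    up <- up + (llr_window(ctx, e_meth, "cpg", model = model,
                           k = 3)$llr > 1.5)
    dn <- dn + (llr_window(ctx, e_un, "cpg", model = model,
                           k = 3)$llr < -1.5)
  }
  expect_gte(up / 200, 0.9)
  expect_gte(dn / 200, 0.9)
})

test_that("LLR grows with the methylation shift", {
  ctx <- "TACGTT"
  withr::local_seed(23)
  med <- vapply(c(2, 4, 6, 8), function(s) {
    model <- classify_fixture(shift = s)
    kms_meth <- substring("TAMGTT", 1:4, 3:6)
    mu_me <- vapply(kms_meth, function(km)
      model$level_mean[model$kmer == km][1], numeric(1))
    sig <- vapply(substring(ctx, 1:4, 3:6), function(km)
      model$level_stdv[model$kmer == km][1], numeric(1))
    stats::median(vapply(1:20, function(i)
      llr_window(ctx, rnorm(4, mu_me, sig), "cpg", model = model,
                 k = 3)$llr, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("threshold rules are applied exactly at the boundaries", {
  th <- thresholds()
  expect_equal(call_llr(1.5, "cpg_substring", th), "methylated")
  expect_equal(call_llr(1.2, "cpg_substring", th), "no_call")
  expect_equal(call_llr(-1.5, "cpg_substring", th), "unmethylated")
  expect_equal(call_llr(-1.2, "cpg_substring", th), "no_call")
  expect_equal(call_llr(8, "adenine_window", th, "low"), "contains_6mA")
  expect_equal(call_llr(7.9, "adenine_window", th, "low"), "non_6mA")
  expect_equal(call_llr(33, "adenine_window", th, "high"), "contains_6mA")
  expect_equal(call_llr(31.9, "adenine_window", th, "high"), "non_6mA")
  expect_error(call_llr(NaN, "cpg_substring", th), "NaN")
})

test_that("per-read calling segments, calls, and survives empty windows", {
  model <- synthetic_pore_model(6)
  ref <- simulate_reference(400, cpg_density = 0, seed = 31)
  sim <- simulate_reads(ref, model, n_reads = 2, read_length = 400,
                        seed = 32, sd_a = 1, sd_b = 0.01, sd_d = 0.02)
  calls <- call_reads(sim$events, ref$sequence, model)
  # no CpGs in the reference: only adenine windows are emitted
  expect_true(all(calls$kind == "adenine_window"))
  expect_true(all(calls$read_id %in% sim$events$read_id))
  expect_true(all(calls$call %in% c("contains_6mA", "non_6mA", "no_call")))

  # dropping one window's events (including its k-1 bp context flanks)
  # turns that window into a no_call only
  ev1 <- sim$events[sim$events$read_id == sim$events$read_id[1], ]
  s0 <- min(ev1$position)
  gap <- ev1$position < s0 + 44 | ev1$position >= s0 + 106
  calls_gap <- call_read(ev1[gap, ], ref$sequence, model)
  hit <- calls_gap[calls_gap$start == s0 + 50, ]
  # the emptied window is either dropped from the span or no_call
  if (nrow(hit)) expect_equal(hit$call, "no_call")
  expect_gt(sum(calls_gap$call != "no_call"), 0)
})

test_that("a window's LLR ignores events outside its k-mer support", {
  model <- synthetic_pore_model(6)
  ref <- simulate_reference(400, cpg_density = 0, seed = 33)
  sim <- simulate_reads(ref, model, n_reads = 1, read_length = 400,
                        seed = 34, sd_a = 1, sd_b = 0.01, sd_d = 0.02)
  ev <- sim$events
  sc <- fit_read_scaling(ev, model)
  s0 <- min(ev$position)
  full <- call_read(ev, ref$sequence, model, scaling = sc)
  # remove all events of the second 50-bp window and recall with the same
  # scaling: every other window's LLR is unchanged
  gap <- ev$position < s0 + 50 | ev$position >= s0 + 100
  part <- call_read(ev[gap, ], ref$sequence, model, scaling = sc)
  # windows sharing context flanks with the removed stretch may change;
  # all windows at least k bp away must be identical
  touched <- c(s0 + 50, s0 + 100)
  shared <- dplyr::inner_join(
    full[!full$start %in% touched, c("start", "llr")],
    part[!part$start %in% touched, c("start", "llr")],
    by = "start")
  expect_gt(nrow(shared), 2)
  expect_equal(shared$llr.x, shared$llr.y)
})
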