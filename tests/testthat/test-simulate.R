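test_that("the simulator is fully deterministic under a fixed seed", {
  m <- synthetic_pore_model(6)
  r1 <- simulate_reference(2000, 0.02, seed = 81)
  r2 <- simulate_reference(2000, 0.02, seed = 81)
  expect_identical(r1, r2)

  s1 <- simulate_reads(r1, m, 4, 800, cpg_meth_prob = 0.5,
                       ada_label_prob = 0.3, seed = 82)
  s2 <- simulate_reads(r1, m, 4, 800, cpg_meth_prob = 0.5,
                       ada_label_prob = 0.3, seed = 82)
  expect_identical(s1, s2)

  # a different seed changes the events
  s3 <- simulate_reads(r1, m, 4, 800, cpg_meth_prob = 0.5,
                       ada_label_prob = 0.3, seed = 83)
  expect_false(identical(s1$events$event_level_mean,
                         s3$events$event_level_mean))
})

test_that("realized CpG density is close to the request", {
  ref <- simulate_reference(50000, 0.02, seed = 84)
  dens <- length(ref$cpg_sites) / ref$length
  expect_gte(dens, 0.016)
  expect_lte(dens, 0.024)
  # and the recorded sites are real CpGs
  chars <- strsplit(ref$sequence, "")[[1]]
  expect_true(all(chars[ref$cpg_sites + 1] == "C"))
  expect_true(all(chars[ref$cpg_sites + 2] == "G"))
})

test_that("zero labelling probability leaves the truth tracks empty", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(1500, 0.02, seed = 85)
  sim <- simulate_reads(ref, m, 5, 700, cpg_meth_prob = 0,
                        ada_label_prob = 0, seed = 86)
  expect_false(any(sim$cpg_truth$methylated))
  expect_false(any(sim$ada_truth$labeled))
})

test_that("noiseless undistorted events sit exactly at the model levels", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(600, 0.01, seed = 87)
  sim <- simulate_reads(ref, m, 2, 300, sd_a = 0, sd_b = 0, sd_d = 0,
                        p_stay = 0, p_skip = 0, signal_noise = 0,
                        seed = 88)
  mu <- vapply(sim$events$reference_kmer, function(km)
    m$level_mean[m$kmer == km][1], numeric(1))
  expect_equal(sim$events$event_level_mean, unname(mu))
  # one event per k-mer, none skipped
  expect_equal(nrow(sim$events), 2 * (300 - 6 + 1))
})

test_that("stay and methylation completeness rates match their settings", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(3000, 0.08, seed = 89)
  sim <- simulate_reads(ref, m, 45, 3000, cpg_meth_prob = 0.962,
                        p_stay = 0.1, p_skip = 0, seed = 90)
  # stay fraction: extra events per emitted event
  n_events <- nrow(sim$events)
  n_kmers <- nrow(dplyr::distinct(sim$events, read_id,
                                  position))
  stay_frac <- (n_events - n_kmers) / n_events
  expect_lt(abs(stay_frac - 0.1), 0.02)

  # M.SssI-style completeness over >= 1e4 CpG draws
  expect_gt(nrow(sim$cpg_truth), 1e4)
  expect_lt(abs(mean(sim$cpg_truth$methylated) - 0.962), 0.01)
})

test_that("training conditions carry the intended modification design", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(1200, 0.02, seed = 91)
  sims <- simulate_training_conditions(ref, m, n_reads = 3,
                                       read_length = 600, seed = 92)
  expect_named(sims, c("pcr", "msssi", "hia5", "both"))
  expect_false(any(sims$pcr$cpg_truth$methylated))
  expect_false(any(sims$pcr$ada_truth$labeled))
  expect_gt(mean(sims$msssi$cpg_truth$methylated), 0.9)
  expect_false(any(sims$msssi$ada_truth$labeled))
  p_ada <- mean(sims$hia5$ada_truth$labeled)
  expect_gt(p_ada, 0.25)
  expect_lt(p_ada, 0.55)
  expect_gt(mean(sims$both$cpg_truth$methylated), 0.9)
  expect_gt(mean(sims$both$ada_truth$labeled), 0.25)
})

test_that("Hia5-style partial labelling produces bimodal k-bar event pools", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(800, 0, seed = 93)
  sim <- simulate_reads(ref, m, 40, 800, ada_label_prob = 0.4,
                        shift_sd_units = 3, sd_a = 0, sd_b = 0, sd_d = 0,
                        seed = 94)
  # pick a frequent single-A k-mer position set and pool its events
  ev <- dplyr::count(sim$events, reference_kmer, sort = TRUE)
  km <- ev$reference_kmer[stringr::str_count(ev$reference_kmer, "A") == 1][1]
  pool <- sim$events$event_level_mean[sim$events$reference_kmer == km]
  base <- m[m$kmer == km, ]
  # two-component fit separates the unmodified and shifted modes
  fit <- fit_gmm(pool, 1, mu = c(base$level_mean, base$level_mean + 5),
                 sigma = rep(base$level_stdv, 2))
  comp <- fit$components[order(fit$components$mean), ]
  expect_equal(nrow(comp), 2)
  expect_gt(comp$mean[2] - comp$mean[1], 2 * base$level_stdv)
  expect_gt(min(comp$weight), 0.2)
})

test_that("simulated events round-trip through the eventalign reader", {
  m <- synthetic_pore_model(6)
  ref <- simulate_reference(600, 0.02, seed = 95)
  sim <- simulate_reads(ref, m, 2, 300, seed = 96)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eventalign(sim$events, path)
  back <- read_eventalign(path)
  expect_equal(as.data.frame(back), as.data.frame(
    dplyr::arrange(sim$events, read_id, event_index)))
})

test_that("footprint regions alternate protected and accessible segments", {
  acc <- footprint_regions(1000, 147, 30)
  expect_true(all(acc$end - acc$start <= 30))
  expect_equal(acc$start[1], 147)
  expect_true(all(diff(acc$start) == 177))
  expect_true(all(acc$end <= 1000))
})
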