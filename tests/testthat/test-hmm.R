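# helpers shared by the HMM tests
tiny_model <- function() synthetic_pore_model(3)

model_mu <- function(model, kmers) {
  vapply(kmers, function(km) model$level_mean[model$kmer == km][1], numeric(1))
}

test_that("read scaling is recovered by least squares", {
  m <- synthetic_pore_model(6)
  withr::local_seed(11)
  kmers <- sample(m$kmer, 500, replace = TRUE)
  mu <- model_mu(m, kmers)
  sig <- vapply(kmers, function(km) m$level_stdv[m$kmer == km][1], numeric(1))
  a <- 10; b <- 1.05; d <- 1.2
  ev <- tibble::tibble(
    reference_kmer = kmers,
    event_level_mean = rnorm(500, a + b * mu, d * sig)
  )
  sc <- fit_read_scaling(ev, m)
  expect_lt(abs(sc$a - a), 0.5)
  expect_lt(abs(sc$b - b), 0.01)
  expect_lt(abs(sc$d - d), 0.1)

  # perfect fit: a = 0, b = 1, d floored at d_min
  ev0 <- tibble::tibble(reference_kmer = kmers, event_level_mean = mu)
  sc0 <- fit_read_scaling(ev0, m)
  expect_equal(sc0$a, 0, tolerance = 1e-8)
  expect_equal(sc0$b, 1, tolerance = 1e-10)
  expect_equal(sc0$d, hmm_config()$d_min)

  expect_error(fit_read_scaling(ev[1:10, ], m), "insufficient")
  same <- tibble::tibble(reference_kmer = rep(kmers[1], 40),
                         event_level_mean = rnorm(40, 100, 1))
  expect_error(fit_read_scaling(same, m), "degenerate")
})

test_that("emission log-density matches the closed form and is shift-equivariant", {
  m <- tibble::tibble(kmer = c("AAA", "CCC"), component_index = 1L,
                      level_mean = c(100, 90), level_stdv = c(2, 2),
                      weight = 1, provenance = "synthetic")
  expect_equal(emission_logpdf(100, "AAA", m), log(1 / (2 * sqrt(2 * pi))))
  # shifting the model mean and the scaling offset by the same amount
  expect_equal(emission_logpdf(100, "CCC", m, read_scaling(a = 10)),
               emission_logpdf(100, "AAA", m))
  # monotone decay away from the center
  devs <- sapply(c(0, 1, 2, 4), function(dx)
    emission_logpdf(100 + dx, "AAA", m))
  expect_true(all(diff(devs) < 0))
})

test_that("forward reduces to the bare emission for a single path", {
  m <- tiny_model()
  cfg0 <- hmm_config(p_stay = 0, p_skip = 0, p_bad = 0, p_clip = 0)
  e <- m$level_mean[m$kmer == "ACG"] + 0.7
  expect_equal(forward_loglik(e, "ACG", m, read_scaling(), cfg0, k = 3),
               emission_logpdf(e, "ACG", m))
})

test_that("forward and Viterbi match exhaustive path enumeration", {
  m <- tiny_model()
  cfg <- hmm_config(max_skip = 2L)
  sc <- read_scaling(2, 1.01, 1.1)
  withr::local_seed(97)
  for (rep in 1:25) {
    K <- sample(1:4, 1)
    N <- sample(1:6, 1)
    seqS <- paste(sample(c("A", "C", "G", "T"), K + 2, replace = TRUE),
                  collapse = "")
    mu <- model_mu(m, substring(seqS, 1:K, 3:(K + 2)))
    e <- rnorm(N, sample(mu, N, replace = TRUE), 3)
    oracle <- oracle_path_sums(e, seqS, m, sc, cfg, k = 3)
    expect_equal(forward_loglik(e, seqS, m, sc, cfg, k = 3),
                 oracle$forward, tolerance = 1e-9)
    va <- viterbi_align(e, seqS, m, sc, cfg, k = 3)
    expect_equal(va$logprob, oracle$viterbi, tolerance = 1e-9)
    # max over paths can never exceed the sum over paths
    expect_lte(va$logprob, oracle$forward + 1e-12)
  }
})

test_that("Viterbi recovers the generating alignment on clean events", {
  # equal-sd model so exact-mean matches always dominate
  m <- tibble::tibble(
    kmer = c("ACG", "CGT", "GTG", "TGA"), component_index = 1L,
    level_mean = c(80, 95, 110, 125), level_stdv = 2, weight = 1,
    provenance = "synthetic")
  seqS <- "ACGTGA"
  mu <- m$level_mean
  va <- viterbi_align(mu, seqS, m, read_scaling(), hmm_config(), k = 3)
  expect_equal(va$path$kmer_index, 1:4)
  expect_true(all(va$path$state == "match"))

  # duplicated event for k-mer 2 is absorbed by the match self-transition
  va2 <- viterbi_align(mu[c(1, 2, 2, 3, 4)], seqS, m, read_scaling(),
                       hmm_config(), k = 3)
  expect_equal(va2$path$kmer_index, c(1, 2, 2, 3, 4))
})

test_that("the true sequence is preferred over a strongly shifted one", {
  m <- tiny_model()
  cfg <- hmm_config()
  truth <- "ACGTGAC"  # 5 k-mers
  K <- 5
  kms <- substring(truth, 1:K, 3:(K + 2))
  mu <- model_mu(m, kms)
  sig <- vapply(kms, function(km) m$level_stdv[m$kmer == km][1], numeric(1))
  # competitor sequence whose k-mer means differ by >= 3 sd at >= 2 k-mers
  other <- NULL
  for (cand in c("TTTTGAC", "ACGAAAC", "GGGGGAC", "TTTATAC")) {
    mu2 <- model_mu(m, substring(cand, 1:K, 3:(K + 2)))
    if (sum(abs(mu2 - mu) >= 3 * sig) >= 2) { other <- cand; break }
  }
  expect_false(is.null(other))
  withr::local_seed(5)
  wins <- 0L
  for (rep in 1:200) {
    e <- rnorm(K, mu, sig)
    ll_true <- forward_loglik(e, truth, m, read_scaling(), cfg, k = 3)
    ll_other <- forward_loglik(e, other, m, read_scaling(), cfg, k = 3)
    wins <- wins + (ll_true > ll_other)
  }
  expect_gte(wins / 200, 0.95)
})

test_that("forward is invariant to jointly relabelling scaling and model means", {
  m <- tiny_model()
  seqS <- "ACGTG"
  withr::local_seed(13)
  e <- rnorm(5, 100, 5)
  base <- forward_loglik(e, seqS, m, read_scaling(0, 1, 1), hmm_config(), k = 3)
  # transform model means mu -> (mu - 10) / 1.05 and invert via (a, b)
  m2 <- m
  m2$level_mean <- (m2$level_mean - 10) / 1.05
  m2$level_stdv <- m2$level_stdv / 1.05
  shifted <- forward_loglik(e, seqS, m2, read_scaling(10, 1.05, 1.05),
                            hmm_config(), k = 3)
  expect_equal(base, shifted, tolerance = 1e-9)
})
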