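# Brute-force path-enumeration oracle for the event HMM, written from the
# model definition (not from the package's DP): states are start-clip,
# match_j / bad_j per k-mer block, end-clip; transitions and emissions as
# documented in hmm_config(). Enumerates every state path over N events
# and returns both the log-sum (forward) and log-max (Viterbi)
# probability. Feasible for K <= 4 blocks and N <= 6 events.

oracle_path_sums <- function(e, seq, model, scaling, cfg, k) {
  n <- nchar(seq)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  # collapse Z -> A class labels the same way the model keys entries
  labels <- paste0(gsub("Z", "A", kmers),
                   ifelse(grepl("Z", kmers), "+", ""))
  K <- length(labels)
  N <- length(e)

  # emission density of event under a label: max over components
  comp_dens <- function(ev, label, sd_mult) {
    rows <- model[model$kmer == label, ]
    if (nrow(rows) == 0L) {
      parent <- gsub("M", "C", gsub("+", "", label, fixed = TRUE))
      rows <- model[model$kmer == parent, ][1, ]
      rows$level_stdv <- rows$level_stdv + 2
    }
    max(dnorm(ev, scaling$a + scaling$b * rows$level_mean,
              scaling$d * rows$level_stdv * sd_mult))
  }

  # state ids: 1 = cs, 1 + j = match_j, 1 + K + j = bad_j, 2K + 2 = ce
  S <- 2L * K + 2L
  cs <- 1L; ce <- S
  match_id <- 1L + seq_len(K)
  bad_id <- 1L + K + seq_len(K)
  block_of <- function(s) ifelse(s %in% match_id, s - 1L,
                                 ifelse(s %in% bad_id, s - 1L - K, NA))

  geom <- function(m) if (m == 1L) (1 - cfg$p_skip) else
    cfg$p_skip^(m - 1L) * (1 - cfg$p_skip)

  # start probabilities
  start <- numeric(S)
  start[cs] <- cfg$p_clip
  for (j in seq_len(K)) {
    p <- (1 - cfg$p_clip) * geom(j)
    start[match_id[j]] <- p * (1 - cfg$p_bad)
    start[bad_id[j]] <- p * cfg$p_bad
  }

  # transition matrix
  Tm <- matrix(0, S, S)
  Tm[cs, cs] <- cfg$p_stay
  for (j in seq_len(K)) {
    p <- (1 - cfg$p_stay) * geom(j)
    Tm[cs, match_id[j]] <- p * (1 - cfg$p_bad)
    Tm[cs, bad_id[j]] <- p * cfg$p_bad
  }
  for (j in seq_len(K)) {
    for (from in c(match_id[j], bad_id[j])) {
      Tm[from, match_id[j]] <- cfg$p_stay * (1 - cfg$p_bad)
      Tm[from, bad_id[j]] <- cfg$p_stay * cfg$p_bad
      for (m in seq_len(min(cfg$max_skip, K - j))) {
        p <- (1 - cfg$p_stay - cfg$p_clip) * geom(m)
        Tm[from, match_id[j + m]] <- p * (1 - cfg$p_bad)
        Tm[from, bad_id[j + m]] <- p * cfg$p_bad
      }
      Tm[from, ce] <- cfg$p_clip
    }
  }
  Tm[ce, ce] <- 1

  # emission matrix
  Em <- matrix(0, S, N)
  Em[cs, ] <- cfg$softclip_emission
  Em[ce, ] <- cfg$softclip_emission
  for (j in seq_len(K)) {
    for (i in seq_len(N)) {
      Em[match_id[j], i] <- comp_dens(e[i], labels[j], 1)
      Em[bad_id[j], i] <- comp_dens(e[i], labels[j], cfg$bad_sd_mult)
    }
  }

  # enumerate all S^N paths
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), N)))
  prob <- start[paths[, 1]] * Em[cbind(paths[, 1], 1L)]
  if (N > 1L) {
    for (t in 2:N) {
      prob <- prob * Tm[cbind(paths[, t - 1L], paths[, t])] *
        Em[cbind(paths[, t], t)]
    }
  }
  # terminal state must not be the start clip
  prob[paths[, N] == cs] <- 0
  list(forward = log(sum(prob)), viterbi = log(max(prob)))
}
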