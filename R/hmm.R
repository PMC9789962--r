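# Event-to-k-mer hidden Markov model with Gaussian emissions.
#
# One state block per k-mer of the hypothesis sequence. Within a block an
# event is emitted by the match state (best-component Gaussian under the
# read scaling) or, with probability p_bad, by a bad state whose sd is
# broadened by bad_sd_mult. Block-to-block transitions: self (p_stay),
# advance by m k-mers with mass (1 - p_stay - p_clip) * p_skip^(m-1) *
# (1 - p_skip) for m = 1..max_skip (skips are silent), or exit to an
# absorbing end softclip with p_clip. Leading/trailing softclip states emit
# a uniform density constant. The same definition is enumerated by the
# brute-force oracle used in the tests.

#' HMM configuration
#'
#' Transition constants and numeric guards for the event-alignment HMM.
#' The probabilities follow squiggle-HMM convention; all of them are
#' exposed because the classification properties hold for any fixed
#' choice.
#'
#' @param p_stay Match self-transition probability (multiple events per
#'   k-mer), default 0.1.
#' @param p_skip Probability mass decay per additionally skipped k-mer,
#'   default 0.01.
#' @param p_bad Probability that an event is emitted by the broadened bad
#'   state, default 0.001.
#' @param p_clip Probability of starting in / exiting to a softclip state,
#'   default 0.001.
#' @param softclip_emission Uniform softclip emission density per pA,
#'   default 1e-3.
#' @param bad_sd_mult Bad-state sd multiplier, default 10.
#' @param d_min Floor for the per-read variance scale, default 0.01.
#' @param max_skip Largest skip handled in one transition, default 3.
#' @return A list of class `nj_hmm_config`.
#' @export
hmm_config <- function(p_stay = 0.1, p_skip = 0.01, p_bad = 0.001,
                       p_clip = 0.001, softclip_emission = 1e-3,
                       bad_sd_mult = 10, d_min = 0.01, max_skip = 3L) {
  probs <- c(p_stay = p_stay, p_skip = p_skip, p_bad = p_bad, p_clip = p_clip)
  if (any(probs < 0) || any(probs >= 1)) {
    stop("HMM probabilities must lie in [0, 1)", call. = FALSE)
  }
  if (p_stay + p_skip + p_bad >= 1 || p_stay + p_clip >= 1) {
    stop("transition probabilities must leave mass for the advance move",
         call. = FALSE)
  }
  stopifnot(softclip_emission > 0, bad_sd_mult >= 1, d_min > 0, max_skip >= 1)
  structure(list(p_stay = p_stay, p_skip = p_skip, p_bad = p_bad,
                 p_clip = p_clip, softclip_emission = softclip_emission,
                 bad_sd_mult = bad_sd_mult, d_min = d_min,
                 max_skip = as.integer(max_skip)),
            class = "nj_hmm_config")
}

#' Per-read scaling parameters
#'
#' Shift `a` (pA), scale `b` and variance scale `d` relating a read's
#' events to the reference pore model: an event for k-mer k is modelled as
#' Normal(a + b * mu_k, (d * sigma_k)^2).
#'
#' @param a Shift in pA.
#' @param b Scale (dimensionless, > 0).
#' @param d Variance scale (dimensionless, > 0).
#' @return A list of class `nj_read_scaling`.
#' @export
read_scaling <- function(a = 0, b = 1, d = 1) {
  stopifnot(is.finite(a), b > 0, d > 0)
  structure(list(a = a, b = b, d = d), class = "nj_read_scaling")
}

#' Fit per-read shift/scale/variance parameters by least squares
#'
#' Ordinary least squares of the observed event means on the model means
#' of their labelled reference k-mers gives (a, b); the variance scale d
#' is the root mean square of the standardised residuals, floored at
#' `cfg$d_min` to avoid degenerate zero-variance fits.
#'
#' @param events A tibble with columns `event_level_mean` and
#'   `reference_kmer` (plain reference k-mer labels present in the model).
#' @param model A pore-model tibble (base entries are used).
#' @param cfg An [hmm_config()].
#' @param min_events Minimum number of labelled events required (default
#'   30).
#' @param trim_sd Events whose standardised residual exceeds this many
#'   sds are dropped and the fit repeated (`trim_iter` times); this keeps
#'   methylation-shifted events from inflating the variance scale. The
#'   final `d` is corrected for the truncation so it stays unbiased on
#'   clean reads. Set to `Inf` for the plain untrimmed fit.
#' @param trim_iter Number of trim/refit passes (default 2).
#' @return An [read_scaling()] object with extra fields `n` (events used)
#'   and `rss`.
#' @export
fit_read_scaling <- function(events, model, cfg = hmm_config(),
                             min_events = 30L, trim_sd = 2.5,
                             trim_iter = 2L) {
  idx <- if (is.list(model) && !is.data.frame(model)) model else model_index(model)
  labs <- events$reference_kmer
  e <- events$event_level_mean
  hit <- labs %in% names(idx)
  e <- e[hit]
  labs <- labs[hit]
  if (length(e) < min_events) {
    stop("insufficient labelled events for scaling fit (", length(e),
         " < ", min_events, ")", call. = FALSE)
  }
  mu <- vapply(idx[labs], function(x) x$mean[1], numeric(1))
  sig <- vapply(idx[labs], function(x) x$sd[1], numeric(1))
  if (stats::var(mu) == 0) {
    stop("degenerate design: all model means identical", call. = FALSE)
  }

  ols <- function(keep) {
    fit <- stats::lm.fit(cbind(1, mu[keep]), e[keep])
    list(a = fit$coefficients[[1]], b = fit$coefficients[[2]])
  }
  keep <- rep(TRUE, length(e))
  cf <- ols(keep)
  if (is.finite(trim_sd)) {
    for (it in seq_len(trim_iter)) {
      z <- (e - cf$a - cf$b * mu) / sig
      scale_hat <- max(sqrt(stats::median(z[keep]^2)) / 0.6745, cfg$d_min)
      keep_new <- abs(z) <= trim_sd * scale_hat
      if (sum(keep_new) < min_events) break
      keep <- keep_new
      cf <- ols(keep)
    }
  }
  if (cf$b <= 0) stop("non-positive fitted scale b", call. = FALSE)
  resid <- e[keep] - cf$a - cf$b * mu[keep]
  d2 <- mean((resid / sig[keep])^2)
  if (is.finite(trim_sd)) {
    # debias the truncated second moment of a standard normal
    t <- trim_sd
    corr <- 1 - 2 * t * stats::dnorm(t) / (2 * stats::pnorm(t) - 1)
    d2 <- d2 / corr
  }
  d <- max(sqrt(d2), cfg$d_min)
  out <- read_scaling(cf$a, cf$b, d)
  out$n <- sum(keep)
  out$rss <- sum(resid^2)
  out
}

#' Gaussian emission log-density of one event under a k-mer entry
#'
#' Evaluates log Normal(e; a + b * mu, (d * sigma)^2) using the
#' maximum-density component for multi-component entries.
#'
#' @param event Event mean current (pA), may be a vector.
#' @param kmer K-mer or k-bar class label.
#' @param model Pore-model tibble (or prebuilt index).
#' @param scaling A [read_scaling()].
#' @return Log-density, same length as `event`.
#' @export
emission_logpdf <- function(event, kmer, model, scaling = read_scaling()) {
  idx <- if (is.list(model) && !is.data.frame(model)) model else model_index(model)
  entry <- idx[[kmer]]
  if (is.null(entry)) stop("no model entry for k-mer '", kmer, "'", call. = FALSE)
  entry_logpdf(event, entry, scaling, 1)
}

# best-component log-density of events under an entry; sd_mult broadens
# for the bad state
entry_logpdf <- function(e, entry, scaling, sd_mult) {
  J <- length(entry$mean)
  mu <- scaling$a + scaling$b * entry$mean
  sig <- scaling$d * entry$sd * sd_mult
  out <- stats::dnorm(e, mu[1], sig[1], log = TRUE)
  if (J > 1L) {
    for (j in 2:J) {
      out <- pmax(out, stats::dnorm(e, mu[j], sig[j], log = TRUE))
    }
  }
  out
}

# N x K match and bad log-emission matrices for events against the k-mer
# labels of a hypothesis sequence. Auto-derives missing methylated entries
# from their unmodified parent (lookup_entry).
emission_matrices <- function(e, labels, idx, scaling, cfg) {
  uniq <- unique(labels)
  pos <- match(labels, uniq)
  lm_u <- matrix(0, length(e), length(uniq))
  lb_u <- matrix(0, length(e), length(uniq))
  for (u in seq_along(uniq)) {
    entry <- lookup_entry(idx, uniq[u])
    lm_u[, u] <- entry_logpdf(e, entry, scaling, 1)
    lb_u[, u] <- entry_logpdf(e, entry, scaling, cfg$bad_sd_mult)
  }
  list(lm = lm_u[, pos, drop = FALSE], lb = lb_u[, pos, drop = FALSE])
}

# elementwise log(exp(x) + exp(y)) robust to -Inf
lse2 <- function(x, y) {
  m <- pmax(x, y)
  r <- m + log1p(exp(-abs(x - y)))
  r[m == -Inf] <- -Inf
  r
}

lse_vec <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# geometric skip log-mass: (m-1) * log(p), defined as 0 for m = 1 even
# when p = 0
geom_log <- function(m, p) ifelse(m == 1, 0, (m - 1) * log(p))

hmm_log_constants <- function(cfg, K) {
  list(
    stay = log(cfg$p_stay),
    clip = log(cfg$p_clip),
    u = log(cfg$softclip_emission),
    adv = log(1 - cfg$p_stay - cfg$p_clip) +
      geom_log(seq_len(cfg$max_skip), cfg$p_skip) + log(1 - cfg$p_skip),
    entry = log(1 - cfg$p_clip) + geom_log(seq_len(K), cfg$p_skip) +
      log(1 - cfg$p_skip),
    from_cs = log(1 - cfg$p_stay) + geom_log(seq_len(K), cfg$p_skip) +
      log(1 - cfg$p_skip),
    bad = log(cfg$p_bad),
    match = log(1 - cfg$p_bad)
  )
}

shift_down <- function(x, m) {
  K <- length(x)
  if (m >= K) return(rep(-Inf, K))
  c(rep(-Inf, m), x[seq_len(K - m)])
}

prepare_hmm_inputs <- function(events, seq, model, scaling, cfg, k) {
  e <- if (is.data.frame(events)) events$event_level_mean else as.numeric(events)
  if (length(e) == 0L) stop("no events supplied", call. = FALSE)
  labels <- seq_kmer_labels(seq, k)
  idx <- if (is.list(model) && !is.data.frame(model)) model else model_index(model)
  em <- emission_matrices(e, labels, idx, scaling, cfg)
  list(e = e, labels = labels, em = em)
}

#' Forward log-likelihood of a hypothesis sequence given observed events
#'
#' Computes log P(e_1..e_n | S, Theta): the log of the sum over all legal
#' state paths of the path transition probability times the Gaussian
#' emission densities, in log space. The match self-transition permits
#' multiple events per k-mer; silent skips, a broadened bad state and
#' uniform softclip states absorb alignment noise.
#'
#' @param events Numeric vector of event mean currents, or a tibble with
#'   an `event_level_mean` column, ordered by signal time.
#' @param seq Hypothesis sequence over `{A,C,G,T,M,Z}`; must yield at
#'   least one valid k-mer.
#' @param model Pore-model tibble (or prebuilt index).
#' @param scaling A [read_scaling()].
#' @param cfg An [hmm_config()].
#' @param k K-mer length (default 6).
#' @return The forward log-likelihood (natural log).
#' @export
forward_loglik <- function(events, seq, model, scaling = read_scaling(),
                           cfg = hmm_config(), k = 6L) {
  inp <- prepare_hmm_inputs(events, seq, model, scaling, cfg, k)
  K <- length(inp$labels)
  N <- length(inp$e)
  cst <- hmm_log_constants(cfg, K)
  emis <- lse2(cst$match + inp$em$lm, cst$bad + inp$em$lb)  # N x K

  a_blocks <- cst$entry + emis[1, ]
  a_cs <- cst$clip + cst$u
  a_ce <- -Inf
  if (N > 1L) {
    for (i in 2:N) {
      acc <- a_blocks + cst$stay
      for (m in seq_len(min(cfg$max_skip, K))) {
        acc <- lse2(acc, shift_down(a_blocks, m) + cst$adv[m])
      }
      acc <- lse2(acc, a_cs + cst$from_cs)
      new_ce <- lse2(a_ce, lse_vec(a_blocks) + cst$clip) + cst$u
      a_cs <- a_cs + cst$stay + cst$u
      a_ce <- new_ce
      a_blocks <- acc + emis[i, ]
    }
  }
  lse2(lse_vec(a_blocks), a_ce)
}

#' Viterbi alignment of events to the k-mers of a hypothesis sequence
#'
#' Finds the single maximum-probability state path of the same model as
#' [forward_loglik()]. Assignments are monotonically non-decreasing in
#' k-mer index, and the path log-probability never exceeds the forward
#' log-likelihood.
#'
#' @inheritParams forward_loglik
#' @return A list of class `nj_alignment` with elements `path` (a tibble
#'   with `event_index`, `state` in match/bad/softclip_start/softclip_end,
#'   and `kmer_index`, NA for softclips) and `logprob`.
#' @export
viterbi_align <- function(events, seq, model, scaling = read_scaling(),
                          cfg = hmm_config(), k = 6L) {
  inp <- prepare_hmm_inputs(events, seq, model, scaling, cfg, k)
  K <- length(inp$labels)
  N <- length(inp$e)
  cst <- hmm_log_constants(cfg, K)
  emis <- pmax(cst$match + inp$em$lm, cst$bad + inp$em$lb)
  n_shift <- min(cfg$max_skip, K)

  # backpointers: 0 stay, 1..max_skip advance-by-m, -1 from start clip
  bp <- matrix(0L, N, K)
  ce_from <- integer(N)  # 0: stayed in ce; j > 0: entered ce from block j

  v_blocks <- cst$entry + emis[1, ]
  v_cs <- cst$clip + cst$u
  v_ce <- -Inf
  bp[1, ] <- -2L  # entry
  if (N > 1L) {
    for (i in 2:N) {
      best <- v_blocks + cst$stay
      choice <- rep(0L, K)
      for (m in seq_len(n_shift)) {
        cand <- shift_down(v_blocks, m) + cst$adv[m]
        upd <- cand > best
        best[upd] <- cand[upd]
        choice[upd] <- m
      }
      cand <- v_cs + cst$from_cs
      upd <- cand > best
      best[upd] <- cand[upd]
      choice[upd] <- -1L

      jbest <- which.max(v_blocks)
      enter_ce <- v_blocks[jbest] + cst$clip
      if (enter_ce > v_ce) {
        v_ce_new <- enter_ce + cst$u
        ce_from[i] <- jbest
      } else {
        v_ce_new <- v_ce + cst$u
        ce_from[i] <- 0L
      }
      v_cs <- v_cs + cst$stay + cst$u
      v_ce <- v_ce_new
      v_blocks <- best + emis[i, ]
      bp[i, ] <- choice
    }
  }

  # backtrace
  state <- character(N)
  kmer_index <- rep(NA_integer_, N)
  jK <- which.max(v_blocks)
  if (v_ce > v_blocks[jK]) {
    logprob <- v_ce
    # walk back through end-clip events to the block the path exited from
    i <- N
    j <- 0L
    while (i >= 2L) {
      state[i] <- "softclip_end"
      if (ce_from[i] > 0L) { j <- ce_from[i]; i <- i - 1L; break }
      i <- i - 1L
    }
    if (j == 0L) stop("internal error: end-clip path without entry")
  } else {
    logprob <- v_blocks[jK]
    i <- N
    j <- jK
  }
  while (i >= 1L) {
    ch <- bp[i, j]
    state[i] <- if ((cst$match + inp$em$lm[i, j]) >=
                    (cst$bad + inp$em$lb[i, j])) "match" else "bad"
    kmer_index[i] <- j
    if (ch == -2L) {  # entry at event 1
      i <- i - 1L
      break
    } else if (ch == -1L) {  # came from start clip
      i <- i - 1L
      while (i >= 1L) {
        state[i] <- "softclip_start"
        i <- i - 1L
      }
      break
    } else if (ch == 0L) {
      i <- i - 1L
    } else {
      j <- j - ch
      i <- i - 1L
    }
  }

  structure(
    list(path = tibble::tibble(event_index = seq_len(N), state = state,
                               kmer_index = kmer_index),
         logprob = logprob),
    class = "nj_alignment"
  )
}
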