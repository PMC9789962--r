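test_that("EM recovers a well-separated two-component mixture", {
  withr::local_seed(301)
  truth_mu <- c(80, 86); truth_sd <- c(2, 2); truth_w <- c(0.5, 0.5)
  z <- sample(1:2, 5000, replace = TRUE, prob = truth_w)
  x <- rnorm(5000, truth_mu[z], truth_sd[z])
  fit <- fit_gmm(x, v = 1, mu = c(80, 85), sigma = c(2, 2))
  comp <- fit$components[order(fit$components$mean), ]
  expect_equal(comp$mean, truth_mu, tolerance = 0.3 / 80)
  expect_true(all(abs(comp$mean - truth_mu) < 0.3))
  expect_true(all(abs(comp$weight - truth_w) < 0.03))

  # observed-data log-likelihood is non-decreasing at every iteration
  expect_true(all(diff(fit$loglik) > -1e-8))

  # responsibilities are a proper soft assignment
  expect_equal(rowSums(fit$responsibilities), rep(1, 5000))
})

test_that("partial methylation yields the right mixture weight", {
  withr::local_seed(302)
  z <- runif(4000) < 0.5
  x <- rnorm(4000, ifelse(z, 106, 100), 2)
  fit <- fit_gmm(x, v = 1, mu = c(100, 105), sigma = c(2, 2))
  comp <- fit$components
  w_meth <- comp$weight[which.max(comp$mean)]
  expect_lt(abs(w_meth - 0.5), 0.1)
})

test_that("single-Gaussian data collapses or merges a 2-component init", {
  withr::local_seed(303)
  x <- rnorm(3000, 100, 2)
  fit <- fit_gmm(x, v = 1, mu = c(100, 105), sigma = c(2, 2),
                 omega = c(0.95, 0.05))
  comp <- fit$components
  merged <- nrow(comp) == 1 ||
    abs(diff(comp$mean)) < 0.5 || min(comp$weight) < 0.05
  expect_true(merged)
})

test_that("per-event variance factors enter the E and M steps", {
  withr::local_seed(304)
  # half the events come from a read with doubled variance factor
  v <- rep(c(1, 2), each = 2000)
  x <- rnorm(4000, 100, 2 * v)
  fit <- fit_gmm(x, v = v, mu = 100, sigma = 3, omega = 1)
  # the sd estimate is on the reference scale: ~2, not the pooled ~3.2
  expect_lt(abs(fit$components$sd - 2), 0.2)
})

test_that("insufficient events are rejected", {
  expect_error(fit_gmm(rnorm(15), v = 1, mu = c(0, 1), sigma = c(1, 1)),
               "insufficient")
})

test_that("parameter assignment follows the consistency rule", {
  mk_fit <- function(mu, w = rep(1 / length(mu), length(mu)), ll = 0) {
    structure(list(components = tibble::tibble(weight = w, mean = mu,
                                               sd = rep(2, length(mu))),
                   loglik = ll, converged = TRUE, n_iter = 5,
                   n = 100), class = "nj_gmm")
  }
  # consistent two-component fits: the far-from-reference mean is chosen
  fits <- list(mk_fit(c(100.0, 106.1)), mk_fit(c(106.15, 100.05)),
               mk_fit(c(100.0, 106.05)))
  asg <- assign_parameters(fits, ref_mean = 100, ref_sd = 2,
                           kind = "two_component")
  expect_true(asg$trained)
  expect_equal(asg$components$mean, 106.1, tolerance = 1e-3)
  expect_equal(asg$components$weight, 1)

  # label-switching immunity: permuting component order changes nothing
  fits_perm <- lapply(fits, function(f) {
    f$components <- f$components[rev(seq_len(nrow(f$components))), ]
    f
  })
  expect_equal(assign_parameters(fits_perm, 100, 2, "two_component"),
               asg)

  # multi-component: the reference-matching mean is dropped, weights
  # renormalised
  fits3 <- list(mk_fit(c(100.1, 105.9, 111.8), w = c(0.5, 0.3, 0.2)),
                mk_fit(c(100.0, 105.85, 111.9), w = c(0.48, 0.32, 0.2)))
  asg3 <- assign_parameters(fits3, 100, 2, "multi_component")
  expect_true(asg3$trained)
  expect_equal(asg3$components$mean, c(105.9, 111.8))
  expect_equal(sum(asg3$components$weight), 1)
  expect_equal(asg3$components$weight, c(0.6, 0.4))

  # no consensus across the grid: untrained
  fits_bad <- list(mk_fit(c(100, 103)), mk_fit(c(100, 108)),
                   mk_fit(c(100, 113)), mk_fit(c(100, 118)))
  expect_false(assign_parameters(fits_bad, 100, 2, "two_component")$trained)

  # single surviving component, consistent: assigned as-is
  fits1 <- list(mk_fit(104.2), mk_fit(104.3))
  asg1 <- assign_parameters(fits1, 100, 2, "two_component")
  expect_true(asg1$trained)
  expect_equal(asg1$components$mean, 104.2, tolerance = 0.2)
})

test_that("grid fitting produces one fit per initialisation", {
  withr::local_seed(305)
  x <- rnorm(600, c(100, 107), 2)
  fits <- fit_gmm_grid(x, 1, ref_mean = 100, ref_sd = 2, n_components = 2)
  # 4 mean offsets x 2 sd choices
  expect_length(fits, 8)
  expect_true(all(vapply(fits, inherits, logical(1), "nj_gmm")))
})

test_that("tidy and glance summarise a mixture fit", {
  withr::local_seed(306)
  x <- rnorm(500, c(90, 97), 2)
  fit <- fit_gmm(x, 1, mu = c(90, 96), sigma = c(2, 2))
  td <- tidy(fit)
  expect_named(td, c("component", "weight", "mean", "sd"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n, 500)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit, x), "ggplot")
})
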