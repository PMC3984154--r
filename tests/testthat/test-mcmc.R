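test_that("chains are reproducible bit-exactly from the seed", {
  sim <- simulate_dataset(sim_design(n_sites = 8, n_species = 4), seed = 201)
  f1 <- quick_fit(sim, n_iter = 600, n_burn = 200, seed = 33)
  f2 <- quick_fit(sim, n_iter = 600, n_burn = 200, seed = 33)
  expect_identical(f1$draws, f2$draws)
  f3 <- quick_fit(sim, n_iter = 600, n_burn = 200, seed = 34)
  expect_false(identical(f1$draws$hyper, f3$draws$hyper))
})

test_that("with detection fixed at one the latent abundance is the max count", {
  sim <- simulate_dataset(sim_design(n_sites = 10, n_species = 4,
                                     perfect_detection = TRUE), seed = 202)
  fit <- suppressWarnings(quick_fit(sim, mode = "independent",
                                    fix_p = rep(1, 4),
                                    n_iter = 800, n_burn = 300))
  ymax <- apply(sim$data$counts, c(1, 2), max)
  Nbar <- matrix(colMeans(fit$draws$N), 10, 4)
  expect_equal(Nbar, unname(ymax), tolerance = 1e-12)
  expect_true(all(t(matrix(fit$draws$N[1, ], 10, 4)) == t(ymax)))
})

test_that("retained draws respect parameter supports", {
  sim <- simulate_dataset(sim_design(n_sites = 8, n_species = 5), seed = 203)
  fit <- quick_fit(sim, n_iter = 1200, n_burn = 400)
  h <- fit$draws$hyper
  expect_true(all(h[, "sigma0"] > 0))
  expect_true(all(h[, "sigma_alpha"] > 0))
  expect_true(all(h[, "sigma_beta_x1"] > 0))
  expect_true(all(h[, "theta"] > 0 & h[, "theta"] < fit$priors$theta_max))
  ymax <- as.vector(apply(sim$data$counts, c(1, 2), max))
  expect_true(all(sweep(fit$draws$N, 2, ymax, `>=`)))
})

test_that("summary quantiles are ordered and the table covers every parameter", {
  sim <- simulate_dataset(sim_design(n_sites = 8, n_species = 4), seed = 204)
  fit <- quick_fit(sim, n_iter = 1200, n_burn = 400)
  s <- summary(fit, pars = "all")
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  expect_equal(sum(s$parameter %in% c("mu0", "sigma0", "theta", "mu_alpha",
                                      "sigma_alpha", "mu_beta_x1",
                                      "sigma_beta_x1", "alpha_v1")), 8L)
  # every species-level parameter appears exactly once
  expect_equal(sum(grepl("^beta0_", s$parameter)), 4L)
  expect_equal(sum(grepl("^beta_sp", s$parameter)), 4L)
  expect_equal(sum(grepl("^alpha0_", s$parameter)), 4L)
  expect_false(anyDuplicated(s$parameter) > 0)
})

test_that("batch-means MCSE approximates sd/sqrt(n) for independent draws", {
  set.seed(205)
  x <- rnorm(10000, sd = 2.5)
  expect_lt(abs(mcse_batch_means(x) - 2.5 / 100) / (2.5 / 100), 0.2)
  expect_equal(mcse_batch_means(rep(3, 500)), 0)
})

test_that("split R-hat flags disagreement and accepts mixed chains", {
  set.seed(206)
  mixed <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(split_rhat(mixed), 1.02)
  apart <- cbind(rnorm(2000), rnorm(2000) + 5)
  expect_gt(split_rhat(apart), 1.5)
  expect_true(is.na(split_rhat(cbind(rep(1, 100), rep(1, 100)))))
})

test_that("a constant (fixed) block yields zero-width summaries", {
  sim <- simulate_dataset(sim_design(n_sites = 6, n_species = 3), seed = 207)
  fit <- suppressWarnings(quick_fit(sim, mode = "independent",
                                    fix_p = rep(0.5, 3),
                                    n_iter = 600, n_burn = 200))
  s <- summary(fit, pars = "all")
  a0 <- s[grepl("^alpha0_", s$parameter), ]   # never updated: constant chain
  expect_equal(a0$mcse, rep(0, 3))
  expect_equal(a0$q97.5 - a0$q2.5, rep(0, 3))
})

test_that("correlation summaries: d = 0 pairs are exactly 1 in every draw", {
  set.seed(208)
  traits <- matrix(rnorm(5 * 5), 5, 5)
  traits[2, ] <- traits[1, ]                  # tied trait vectors
  sim <- suppressWarnings(
    simulate_dataset(sim_design(n_sites = 8, n_species = 5, traits = traits),
                     seed = 208))
  fit <- suppressWarnings(quick_fit(sim, n_iter = 900, n_burn = 300))
  cs <- correlation_summary(fit)
  tied <- cs[cs$d == 0, ]
  expect_equal(nrow(tied), 1L)
  expect_equal(tied$median, 1)
  expect_equal(tied$q2.5, 1)
  expect_equal(tied$q97.5, 1)
  expect_true(all(cs$q2.5 <= cs$median & cs$median <= cs$q97.5))
})

test_that("no spurious correlation is estimated from independent data", {
  sim <- simulate_dataset(sim_design(n_sites = 40, n_species = 15,
                                     mode = "independent"), seed = 209)
  fit <- quick_fit(sim, mode = "full", n_iter = 3000, n_burn = 1200, thin = 2)
  cs <- correlation_summary(fit)
  far <- cs$d > median(cs$d)
  expect_true(all(cs$median[far] < 0.2))
})

test_that("Gibbs transitions leave the joint detection model invariant (Geweke-style)", {
  # Successive-conditional simulation on the detection half of the model
  # (lambda fixed): alternate one sampler scan with a redraw of y given the
  # state. Marginal statistics of the chain must match direct prior draws.
  set.seed(210)
  n <- 3L; I <- 3L; J <- 2L
  lam_fix <- matrix(c(1.5, 2.5, 0.8), n, I, byrow = TRUE)
  V <- matrix(c(-0.5, 0.2, 1.1), I, 1)
  D <- dissimilarity_matrix(matrix(rnorm(I * 2), I, 2))
  mu_sd <- 1; sig_scale <- 0.5
  n_prior <- 4000L; n_sc <- 3000L

  draw_prior <- function() {
    mu_alpha <- rnorm(1, 0, mu_sd)
    sigma_alpha <- abs(sig_scale * tan(pi * runif(1) / 2))  # half-Cauchy
    alpha <- rnorm(1, 0, mu_sd)
    alpha0 <- rnorm(I, mu_alpha, sigma_alpha)
    p <- plogis(alpha0 + V[, 1] * alpha)
    N <- matrix(rpois(n * I, lam_fix), n, I)
    list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha, alpha = alpha,
         alpha0 = alpha0, p = p, N = N)
  }
  prior <- replicate(n_prior, {
    s <- draw_prior()
    c(s$mu_alpha, s$alpha, mean(s$N), mean(s$sigma_alpha < sig_scale))
  })

  priors <- list(mu_sd = mu_sd, sigma_scale = sig_scale, theta_max = 2)
  ctl <- list(n_iter = 1L, n_burn = 0L, thin = 1L, adapt = FALSE,
              save_N = FALSE, fix_lambda = lam_fix, fix_p = NULL)
  st <- draw_prior()
  state <- list(beta0 = rep(0, I), beta = matrix(0, I, 1),
                alpha0 = st$alpha0, alpha = st$alpha, mu0 = 0, sigma0 = 1,
                theta = 1, mu_beta = 0, sigma_beta = 1,
                mu_alpha = st$mu_alpha, sigma_alpha = st$sigma_alpha,
                N = st$N)
  storage.mode(state$N) <- "integer"
  draw_y <- function(N, p) {
    y <- array(0L, c(n, I, J))
    for (j in seq_len(J))
      y[, , j] <- rbinom(n * I, size = N, prob = rep(p, each = n))
    y
  }
  y <- draw_y(st$N, st$p)
  sc <- matrix(NA_real_, 4, n_sc)
  for (t in seq_len(n_sc)) {
    res <- msnmix:::run_sampler_cpp(
      as.integer(y), c(n, I, J), matrix(1L, n, J),
      matrix(0, n, 1), V, D, rep(1L, I), 2L, 0L, priors, state, ctl)
    state <- res$final_state
    storage.mode(state$N) <- "integer"
    p <- plogis(as.numeric(state$alpha0) + V[, 1] * as.numeric(state$alpha))
    y <- draw_y(state$N, p)
    sc[, t] <- c(state$mu_alpha, as.numeric(state$alpha), mean(state$N),
                 state$sigma_alpha < 0.5)
  }
  for (r in 1:4) {
    se_p <- sd(prior[r, ]) / sqrt(n_prior)
    se_s <- mcse_batch_means(sc[r, ])
    diff <- abs(mean(prior[r, ]) - mean(sc[r, ]))
    expect_lt(diff, 5 * sqrt(se_p^2 + se_s^2) + 1e-6)
  }
})
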