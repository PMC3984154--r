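test_that("expected abundance follows the log link", {
  expect_equal(expected_abundance(0, 0, 0), 1)
  expect_equal(expected_abundance(1, 0.5, 0.25), exp(0.75))
  expect_equal(expected_abundance(c(1, 2), 0.1, c(0.2, -0.3)), exp(-0.3))
  # monotone in the covariate for a fixed slope sign
  grid <- seq(-2, 2, by = 0.5)
  lam_up <- vapply(grid, expected_abundance, numeric(1), beta0 = 0, beta = 0.4)
  lam_dn <- vapply(grid, expected_abundance, numeric(1), beta0 = 0, beta = -0.4)
  expect_true(all(diff(lam_up) > 0))
  expect_true(all(diff(lam_dn) < 0))
  expect_error(expected_abundance(1, 1e6, 1e6), "finite")
})

test_that("detection probability follows the logit link with saturation", {
  expect_equal(detection_prob(0, 0, 0), 0.5)
  expect_equal(detection_prob(2, 1, -0.5), plogis(0))
  expect_equal(detection_prob(0, Inf, 0), 1)
  expect_equal(detection_prob(0, -Inf, 0), 0)
  # negative covariate effect => p decreasing in the covariate
  v <- seq(-2, 2, by = 0.5)
  p <- vapply(v, detection_prob, numeric(1), alpha0 = -1, alpha = -0.63)
  expect_true(all(diff(p) < 0))
})

test_that("count likelihood handles support violations and empty cells", {
  expect_equal(loglik_counts(1, 2, 0.5), log(0.5))  # 2 * 0.5 * 0.5
  expect_equal(loglik_counts(c(0, 0, 0), 0, 0.3), 0)
  expect_equal(loglik_counts(integer(0), 5, 0.3), 0)
  expect_identical(loglik_counts(3, 2, 0.5), -Inf)
  expect_equal(loglik_counts(c(1, 2), 4, 0.3),
               dbinom(1, 4, 0.3, log = TRUE) + dbinom(2, 4, 0.3, log = TRUE))
  expect_error(loglik_counts(-1, 2, 0.5), "nonnegative")
})

test_that("intercept prior collapses to known normal densities", {
  expect_equal(logprior_intercepts(0.7, 0.2, 1.3, matrix(1)),
               dnorm(0.7, 0.2, 1.3, log = TRUE))
  b <- c(-0.5, 1.1)
  expect_equal(logprior_intercepts(b, 0.3, 0.8, diag(2)),
               sum(dnorm(b, 0.3, 0.8, log = TRUE)))
})

test_that("intercept prior matches the explicit inverse/determinant formula", {
  set.seed(13)
  D <- dissimilarity_matrix(matrix(rnorm(6), 3, 2))
  R <- build_corr(D, 1.5, "full")$R
  b <- rnorm(3); mu <- -0.4; s <- 1.2
  Sigma <- s^2 * R
  ref <- -0.5 * (3 * log(2 * pi) + log(det(Sigma)) +
                   t(b - mu) %*% solve(Sigma) %*% (b - mu))
  expect_equal(logprior_intercepts(b, mu, s, R), as.numeric(ref),
               tolerance = 1e-10)
  expect_error(logprior_intercepts(b, mu, s, matrix(1, 3, 3)),
               "positive definite")
  expect_error(logprior_intercepts(b, mu, 0, R), "positive")
})

toy_logjoint_setup <- function() {
  y <- array(c(1L, 2L, 1L), c(1, 1, 3))
  data <- survey_data(y, site_covariates = data.frame(x = 0.5))
  X <- matrix(0.5, 1, 1, dimnames = list(NULL, "x"))
  V <- matrix(1.2, 1, 1, dimnames = list(NULL, "v"))
  params <- list(beta0 = 0.4, mu0 = -0.2, sigma0 = 1.1, theta = 1,
                 beta = matrix(0.3), mu_beta = 0.1, sigma_beta = 0.9,
                 alpha0 = -0.6, mu_alpha = -1, sigma_alpha = 0.7,
                 alpha = -0.5)
  N <- matrix(4L, 1, 1)
  structure_ <- list(D = matrix(0, 1, 1), mode = "independent",
                     convention = "range", guilds = "all")
  list(data = data, X = X, V = V, params = params, N = N,
       structure = structure_)
}

test_that("joint density equals a term-by-term hand computation on a toy", {
  s <- toy_logjoint_setup()
  pr <- default_priors()
  got <- logjoint(s$params, s$N, s$data, s$X, s$V, s$structure, pr)
  p <- s$params
  lam <- exp(p$beta0 + 0.5 * p$beta[1])
  pdet <- plogis(p$alpha0 + 1.2 * p$alpha)
  lhc <- function(x, sc) log(2) - log(pi * sc * (1 + (x / sc)^2))
  expected <- dnorm(p$mu0, 0, 10, log = TRUE) +
    dnorm(p$mu_beta, 0, 10, log = TRUE) +
    dnorm(p$mu_alpha, 0, 10, log = TRUE) +
    dnorm(p$alpha, 0, 10, log = TRUE) +
    lhc(p$sigma0, 2.5) + lhc(p$sigma_beta, 2.5) + lhc(p$sigma_alpha, 2.5) +
    dnorm(p$beta0, p$mu0, p$sigma0, log = TRUE) +
    dnorm(p$beta[1], p$mu_beta, p$sigma_beta, log = TRUE) +
    dnorm(p$alpha0, p$mu_alpha, p$sigma_alpha, log = TRUE) +
    dpois(4, lam, log = TRUE) +
    sum(dbinom(c(1, 2, 1), 4, pdet, log = TRUE))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("joint density is -Inf on support violations", {
  s <- toy_logjoint_setup()
  s$N[1, 1] <- 1L  # below max visit count 2
  expect_identical(logjoint(s$params, s$N, s$data, s$X, s$V, s$structure),
                   -Inf)
  s2 <- toy_logjoint_setup()
  s2$params$sigma0 <- -1
  expect_identical(logjoint(s2$params, s2$N, s2$data, s2$X, s2$V, s2$structure),
                   -Inf)
  s3 <- toy_logjoint_setup()
  s3$params$beta0 <- c(1, 2)
  expect_error(logjoint(s3$params, s3$N, s3$data, s3$X, s3$V, s3$structure),
               "dimensions")
})

test_that("replicating sites adds identical data terms (additivity)", {
  set.seed(30)
  sim <- simulate_dataset(sim_design(n_sites = 4, n_species = 3), seed = 30)
  ts <- sim$truth$trait_space
  structure_ <- list(D = ts$D, mode = "full", convention = "range",
                     guilds = sim$meta$guild)
  pr <- default_priors(theta_max = 10)
  params <- sim$truth[c("beta0", "beta", "alpha0", "alpha", "mu0", "sigma0",
                        "theta", "mu_beta", "sigma_beta", "mu_alpha",
                        "sigma_alpha")]
  rep_data <- function(times) {
    idx <- rep(seq_len(4), times)
    survey_data(sim$data$counts[idx, , , drop = FALSE],
                site_covariates = sim$data$site_covariates[idx, , drop = FALSE],
                species_ids = sim$data$species_ids,
                site_ids = paste0("s", seq_along(idx)))
  }
  lj <- vapply(1:3, function(times)
    logjoint(params, sim$truth$N[rep(1:4, times), , drop = FALSE],
             rep_data(times), sim$truth$X[rep(1:4, times), , drop = FALSE],
             sim$truth$V, structure_, pr), numeric(1))
  expect_equal(lj[3] - lj[2], lj[2] - lj[1], tolerance = 1e-8)
})

test_that("joint density is invariant to consistent species relabeling", {
  set.seed(31)
  sim <- simulate_dataset(sim_design(n_sites = 5, n_species = 4), seed = 31)
  ts <- sim$truth$trait_space
  pr <- default_priors(theta_max = 10)
  params <- sim$truth[c("beta0", "beta", "alpha0", "alpha", "mu0", "sigma0",
                        "theta", "mu_beta", "sigma_beta", "mu_alpha",
                        "sigma_alpha")]
  structure_ <- list(D = ts$D, mode = "full", convention = "range",
                     guilds = sim$meta$guild)
  lj1 <- logjoint(params, sim$truth$N, sim$data, sim$truth$X, sim$truth$V,
                  structure_, pr)
  perm <- c(3, 1, 4, 2)
  data_p <- survey_data(sim$data$counts[, perm, , drop = FALSE],
                        site_covariates = sim$data$site_covariates,
                        species_ids = sim$data$species_ids[perm],
                        site_ids = sim$data$site_ids)
  params_p <- params
  params_p$beta0 <- params$beta0[perm]
  params_p$beta <- params$beta[perm, , drop = FALSE]
  params_p$alpha0 <- params$alpha0[perm]
  structure_p <- structure_
  structure_p$D <- ts$D[perm, perm]
  structure_p$guilds <- sim$meta$guild[perm]
  lj2 <- logjoint(params_p, sim$truth$N[, perm, drop = FALSE], data_p,
                  sim$truth$X, sim$truth$V[perm, , drop = FALSE],
                  structure_p, pr)
  expect_equal(lj2, lj1, tolerance = 1e-10)
})

test_that("multi-visit latent conditional matches an independent enumeration", {
  cases <- list(list(y = c(2, 0, 1), lambda = 3, p = 0.4),
                list(y = c(0, 0), lambda = 0.5, p = 0.2),
                list(y = c(5, 3), lambda = 8, p = 0.7))
  for (cs in cases) {
    got <- latent_conditional(cs$y, cs$lambda, cs$p)
    ref <- enum_latent_pmf(cs$y, cs$lambda, cs$p)
    m <- min(nrow(got), nrow(ref))
    expect_equal(got$prob[1:m], ref$prob[1:m], tolerance = 1e-10)
  }
  # perfect detection degenerates at the maximum count
  expect_equal(latent_conditional(c(3, 1), 2, 1),
               data.frame(N = 3, prob = 1))
})
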