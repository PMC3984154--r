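test_that("perfect detection makes every count equal the latent abundance", {
  sim <- simulate_dataset(sim_design(n_sites = 12, n_species = 5,
                                     perfect_detection = TRUE), seed = 101)
  for (j in 1:3)
    expect_identical(unname(sim$data$counts[, , j]),
                     matrix(as.integer(sim$truth$N), 12, 5))
  expect_equal(sim$truth$p, rep(1, 5))
})

test_that("degenerate heterogeneity collapses species to a shared intercept", {
  d <- sim_design(n_sites = 800, n_species = 4, n_visits = 1, sigma0 = 0,
                  mu0 = log(2), P = 1, mu_beta = 0, sigma_beta = 0,
                  mu_alpha = 0.4, sigma_alpha = 0, M = 0, alpha = numeric(0))
  sim <- suppressWarnings(simulate_dataset(d, seed = 102))  # single-visit design
  expect_equal(sim$truth$beta0, rep(log(2), 4))
  pbar <- plogis(0.4)
  emp <- mean(sim$data$counts)
  # E[y] = exp(mu0 + sigma_x^2 slope...)*p with slope 0: exp(mu0)*p
  se <- sd(sim$data$counts) / sqrt(length(sim$data$counts))
  expect_lt(abs(emp - 2 * pbar), 4 * se)
})

test_that("binomial thinning of Poisson abundance gives Poisson(lambda p) moments", {
  d <- sim_design(n_sites = 5000, n_species = 2, n_visits = 1, sigma0 = 0,
                  mu0 = log(10), P = 1, mu_beta = 0, sigma_beta = 0,
                  mu_alpha = 0, sigma_alpha = 0, M = 0, alpha = numeric(0))
  sim <- suppressWarnings(simulate_dataset(d, seed = 103))  # single-visit design
  y <- as.numeric(sim$data$counts)          # 10000 iid Poisson(5) draws
  expect_equal(length(y), 10000L)
  se_mean <- sqrt(5 / length(y))
  expect_lt(abs(mean(y) - 5), 3 * se_mean)
  # var of the sample variance of Poisson(5): (mu4 - sigma^4 (n-3)/(n-1))/n
  mu4 <- 5 + 3 * 5 + 3 * 5^2  # E(X-mu)^4 for Poisson(5) = lam(1+3lam)...
  se_var <- sqrt((mu4 - 25) / length(y))
  expect_lt(abs(var(y) - 5), 4 * se_var)
})

test_that("empirical correlation of intercepts across communities converges to R", {
  set.seed(104)
  traits <- matrix(rnorm(4 * 5), 4, 5)
  d <- sim_design(n_sites = 2, n_species = 4, theta = 2, sigma0 = 1,
                  traits = traits)
  R <- NULL
  b <- t(replicate(800, {
    s <- simulate_dataset(d)
    R <<- s$truth$R
    s$truth$beta0
  }))
  emp <- cor(b)
  expect_lt(max(abs(emp - R)), 0.15)
})

test_that("simulation is reproducible bit-exactly from the seed", {
  s1 <- simulate_dataset(sim_design(n_sites = 6, n_species = 3), seed = 105)
  s2 <- simulate_dataset(sim_design(n_sites = 6, n_species = 3), seed = 105)
  expect_identical(s1$data$counts, s2$data$counts)
  expect_identical(s1$truth$beta0, s2$truth$beta0)
  expect_identical(s1$meta$traits, s2$meta$traits)
  s3 <- simulate_dataset(sim_design(n_sites = 6, n_species = 3), seed = 106)
  expect_false(identical(s1$data$counts, s3$data$counts))
})

test_that("simulator output round-trips through the CSV loaders", {
  sim <- simulate_dataset(sim_design(n_sites = 8, n_species = 4), seed = 107)
  paths <- write_sim(sim, tempfile())
  data <- load_survey(paths[["counts"]], paths[["covariates"]])
  meta <- load_species_meta(paths[["species"]], species_order = data$species_ids,
                            detect_cols = "v1")
  expect_identical(data$counts, sim$data$counts)
  expect_equal(meta$traits, sim$meta$traits, tolerance = 1e-12)
  expect_identical(meta$guild, sim$meta$guild)
  expect_equal(unname(meta$detect_covariates), unname(sim$meta$detect_covariates),
               tolerance = 1e-12)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 107L)
})

test_that("posterior replicates honor fixed detection and the visit mask", {
  sim <- simulate_dataset(sim_design(n_sites = 6, n_species = 3), seed = 108)
  sim$data$visit_mask[4L, 2L] <- FALSE
  sim$data$counts[4L, , 2L] <- 0L
  fit <- suppressWarnings(
    fit_msnmix(sim$data, sim$meta, mode = "independent",
               site_transform = "none", detect_transform = "none",
               fix_p = rep(1, 3),
               control = mcmc_control(1, 400, 200, 2, seed = 5)))
  yrep <- simulate_from_posterior(fit)
  expect_equal(dim(yrep), c(100, 6, 3, 3))
  # p = 1: every replicate visit equals the latent N draw
  for (j in c(1, 3))
    expect_equal(matrix(yrep[, , , j], 100), matrix(fit$draws$N, 100))
  expect_true(all(is.na(yrep[, 4, , 2])))
  expect_true(all(!is.na(yrep[, -4, , 2])))
})

test_that("replicate means track the conditional expectation N * p", {
  sim <- simulate_dataset(sim_design(n_sites = 10, n_species = 4), seed = 109)
  fit <- quick_fit(sim, mode = "independent", n_iter = 1600, n_burn = 600)
  yrep <- simulate_from_posterior(fit)
  TT <- dim(yrep)[1]
  p <- plogis(fit$draws$alpha0 +
                fit$draws$hyper[, "alpha_v1"] %o% fit$V[, 1])
  cond_mean <- sapply(1:4, function(i)
    colMeans(matrix(fit$draws$N[, (i - 1) * 10 + (1:10)], TT) * p[, i]))
  emp_mean <- apply(yrep, c(2, 3), mean)   # averaged over draws and visits
  se <- sqrt(apply(yrep, c(2, 3), function(z) var(as.vector(z))) / (TT * 3))
  expect_true(all(abs(emp_mean - cond_mean) < 5 * se + 0.02))
})
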