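#' Design of a synthetic multispecies point-count study
#'
#' Defines the dimensions and community-level parameters from which
#' [simulate_dataset()] draws a complete data set. Default hyperparameter
#' magnitudes follow estimates typical of temperate forest-bird point-count
#' surveys: mean log abundance about -0.75 with standard deviation 1.5 among
#' species, a weak community-mean habitat effect with substantial
#' among-species variation, mean detectability around 0.16 per visit on the
#' probability scale, and a negative effect of the (log, standardized)
#' sound-power covariate on detectability. The decay parameter `theta`
#' defaults to 2 under the range convention so that correlations span roughly
#' 0 to 0.7 over the dissimilarity range produced by the default synthetic
#' trait space.
#'
#' @param n_sites,n_species,n_visits study dimensions.
#' @param P,M,Q numbers of site covariates, detection covariates, traits.
#' @param mu0,sigma0 mean and standard deviation of species log-abundance
#'   intercepts.
#' @param theta correlation decay parameter (see [corr_value()]).
#' @param mu_beta,sigma_beta length-`P` means and standard deviations of the
#'   species-specific covariate effects.
#' @param mu_alpha,sigma_alpha mean and standard deviation of species
#'   logit-detection intercepts.
#' @param alpha length-`M` effects of the detection covariates.
#' @param mode correlation structure passed to [build_corr()].
#' @param convention parameterization of the exponential correlation.
#' @param n_guilds number of foraging guilds assigned to the synthetic
#'   species (round-robin).
#' @param perfect_detection if `TRUE`, detection is fixed at 1 (every
#'   individual counted on every visit), overriding the detection parameters.
#' @param traits optional user trait matrix (`n_species x Q`); by default
#'   traits are i.i.d. standard normal.
#' @param site_covariates,detect_covariates optional design matrices; by
#'   default i.i.d. standard normal (interpreted as already standardized).
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_sites = 50L, n_species = 20L, n_visits = 3L,
                       P = 1L, M = 1L, Q = 5L,
                       mu0 = -0.75, sigma0 = 1.5, theta = 2,
                       mu_beta = rep(-0.11, P), sigma_beta = rep(0.7, P),
                       mu_alpha = -1.64, sigma_alpha = 0.84,
                       alpha = rep(-0.63, length.out = M),
                       mode = c("full", "guild_block", "independent"),
                       convention = c("range", "rate"),
                       n_guilds = 4L, perfect_detection = FALSE,
                       traits = NULL, site_covariates = NULL,
                       detect_covariates = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(n_sites >= 1, n_species >= 1, n_visits >= 1, Q >= 2,
            sigma0 >= 0, theta > 0, all(sigma_beta >= 0), sigma_alpha >= 0,
            length(mu_beta) == P, length(sigma_beta) == P,
            length(alpha) == M)
  structure(list(n_sites = as.integer(n_sites),
                 n_species = as.integer(n_species),
                 n_visits = as.integer(n_visits),
                 P = as.integer(P), M = as.integer(M), Q = as.integer(Q),
                 mu0 = mu0, sigma0 = sigma0, theta = theta,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 alpha = alpha, mode = mode, convention = convention,
                 n_guilds = as.integer(n_guilds),
                 perfect_detection = perfect_detection,
                 traits = traits, site_covariates = site_covariates,
                 detect_covariates = detect_covariates),
            class = "sim_design")
}

#' Simulate a complete data set from the hierarchical model
#'
#' Draws every layer of the model forward: synthetic traits, the trait space
#' and dissimilarity matrix, the correlation matrix `R`, species intercepts
#' `beta0 ~ MVN(mu0 1, sigma0^2 R)`, exchangeable covariate and detection
#' parameters, latent abundances `N ~ Poisson(lambda)` (constant across the
#' visits of a site: the population is closed during sampling), and counts
#' `y ~ Binomial(N, p)` per visit. The generating parameter values ("truth")
#' are returned alongside the data for parameter-recovery experiments.
#'
#' @param design a [sim_design()].
#' @param seed integer seed; recorded in the result.
#' @return A list of class `msn_sim` with elements `data` ([survey_data]),
#'   `meta` ([species_meta]), `truth` (all generating parameters, `N`,
#'   `lambda`, `p`, `R`, the [trait_space]), `design`, and `seed`.
#' @export
simulate_dataset <- function(design = sim_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- design
  n <- d$n_sites; I <- d$n_species; J <- d$n_visits
  sp <- sprintf("sp%02d", seq_len(I))
  traits <- d$traits %||%
    matrix(rnorm(I * d$Q), I, d$Q,
           dimnames = list(sp, paste0("trait", seq_len(d$Q))))
  ts <- trait_space(traits)
  guild <- paste0("guild", rep_len(seq_len(d$n_guilds), I))
  cs <- build_corr(ts$D, theta = if (d$mode == "independent") NULL else d$theta,
                   mode = d$mode, guilds = guild, convention = d$convention)
  L <- t(chol(cs$R))
  beta0 <- d$mu0 + d$sigma0 * as.vector(L %*% rnorm(I))
  beta <- matrix(rnorm(I * d$P, rep(d$mu_beta, each = I),
                       rep(d$sigma_beta, each = I)), I, d$P)
  X <- d$site_covariates %||% matrix(rnorm(n * d$P), n, d$P)
  X <- as.matrix(X)
  if (d$P > 0)
    colnames(X) <- colnames(X) %||% paste0("x", seq_len(d$P))
  V <- d$detect_covariates %||% matrix(rnorm(I * d$M), I, d$M)
  V <- as.matrix(V)
  if (d$M > 0)
    colnames(V) <- colnames(V) %||% paste0("v", seq_len(d$M))
  alpha0 <- rnorm(I, d$mu_alpha, d$sigma_alpha)
  p <- if (d$perfect_detection) rep(1, I)
       else plogis(alpha0 + as.vector(V %*% d$alpha))
  lambda <- exp(matrix(beta0, n, I, byrow = TRUE) + X %*% t(beta))
  N <- matrix(rpois(n * I, lambda), n, I)
  y <- array(0L, c(n, I, J))
  for (j in seq_len(J))
    y[, , j] <- rbinom(n * I, size = N, prob = rep(p, each = n))
  data <- survey_data(y, site_covariates = as.data.frame(X),
                      species_ids = sp,
                      site_ids = sprintf("site%03d", seq_len(n)))
  meta <- species_meta(traits, guild = guild, detect_covariates = V)
  truth <- list(beta0 = beta0, beta = beta, alpha0 = alpha0,
                alpha = d$alpha, mu0 = d$mu0, sigma0 = d$sigma0,
                theta = if (d$mode == "independent") NA_real_ else d$theta,
                mu_beta = d$mu_beta, sigma_beta = d$sigma_beta,
                mu_alpha = d$mu_alpha, sigma_alpha = d$sigma_alpha,
                N = N, lambda = lambda, p = p, R = cs$R, trait_space = ts,
                X = X, V = V)
  structure(list(data = data, meta = meta, truth = truth, design = d,
                 seed = seed),
            class = "msn_sim")
}

#' Write a simulated data set as a CSV bundle
#'
#' Emits the counts, site covariates, and species metadata in the same CSV
#' dialects that [load_survey()] and [load_species_meta()] read, plus a JSON
#' manifest recording the seed and file checksums, so every downstream stage
#' can be exercised without field data.
#'
#' @param sim an `msn_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param layout a [survey_layout()] for the counts file.
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim <- function(sim, dir, layout = survey_layout()) {
  stopifnot(inherits(sim, "msn_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.csv"),
             covariates = file.path(dir, "site_covariates.csv"),
             species = file.path(dir, "species_meta.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_survey(sim$data, paths[["counts"]], paths[["covariates"]],
               layout = layout)
  meta_df <- data.frame(species = sim$data$species_ids,
                        sim$meta$traits,
                        guild = sim$meta$guild,
                        sim$meta$detect_covariates,
                        check.names = FALSE)
  write.csv(meta_df, paths[["species"]], row.names = FALSE, quote = FALSE)
  write_manifest(paths[["manifest"]],
                 files = as.list(paths[c("counts", "covariates", "species")]),
                 layout = layout,
                 transforms = list(site_covariates = "simulated standardized",
                                   detect_covariates = "simulated standardized"),
                 seed = sim$seed)
  invisible(paths)
}

#' Posterior-predictive replicate counts
#'
#' For each retained posterior draw, generates one replicate count tensor with
#' the same shape and visit mask as the data: `y_rep[t, k, i, j] ~
#' Binomial(N_t[k, i], p_t[i])` for surveyed visits, `NA` for masked visits.
#'
#' @param fit an `msn_fit` from [fit_msnmix()] (latent `N` draws must have
#'   been saved, the default).
#' @param data a [survey_data]; defaults to the data the model was fitted to.
#' @return Numeric array `n_draws x n_sites x n_species x n_visits`.
#' @export
simulate_from_posterior <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "msn_fit"))
  dr <- fit$draws
  if (is.null(dr$N) || ncol(dr$N) == 0L)
    stop("latent N draws were not saved; refit with save_N = TRUE")
  n <- dim(data$counts)[1L]; I <- dim(data$counts)[2L]
  J <- dim(data$counts)[3L]
  if (ncol(dr$N) != n * I)
    stop("shape mismatch: chain has ", ncol(dr$N), " latent cells, data has ",
         n * I)
  TT <- nrow(dr$N)
  p_draws <- posterior_pdet(fit)       # TT x I
  yrep <- array(NA_real_, c(TT, n, I, J))
  for (t in seq_len(TT)) {
    Nt <- matrix(dr$N[t, ], n, I)
    pt <- rep(p_draws[t, ], each = n)
    for (j in seq_len(J)) {
      yj <- rbinom(n * I, size = Nt, prob = pt)
      yj[!data$visit_mask[, j]] <- NA_real_
      yrep[t, , , j] <- yj
    }
  }
  yrep
}

# detection probability per draw and species (TT x I)
posterior_pdet <- function(fit) {
  dr <- fit$draws
  if (!is.null(fit$fixed_p))
    return(matrix(fit$fixed_p, nrow(dr$alpha0), length(fit$fixed_p),
                  byrow = TRUE))
  eta <- dr$alpha0
  M <- length(fit$alpha_names)
  if (M > 0) {
    a <- dr$hyper[, fit$alpha_names, drop = FALSE]
    eta <- eta + a %*% t(fit$V)
  }
  plogis(eta)
}
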