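#' MCMC run configuration
#'
#' @param n_chains number of independent chains (run sequentially with seeds
#'   `seed`, `seed + 1`, ...).
#' @param n_iter,n_burn total and burn-in iterations per chain.
#' @param thin post-burn-in thinning interval.
#' @param adapt adapt proposal step sizes during burn-in (targets 0.234 for
#'   the joint intercept block, 0.44 for scalar updates).
#' @param seed integer seed for the run.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3L, n_iter = 50000L, n_burn = 25000L,
                         thin = 5L, adapt = TRUE, seed = 1L) {
  stopifnot(n_iter > n_burn, n_burn >= 0, thin >= 1, n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 adapt = isTRUE(adapt), seed = as.integer(seed)),
            class = "mcmc_control")
}

apply_transform <- function(m, transform, what) {
  m <- as.matrix(m)
  info <- list(transform = transform)
  if (transform == "none") return(list(m = m, info = info))
  if (transform == "log_standardize") {
    if (any(m <= 0))
      stop(what, " contains nonpositive values; 'log_standardize' requires ",
           "strictly positive inputs (use 'standardize' or 'none')")
    m <- log(m)
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2L, sd)
  if (any(scl == 0)) stop("constant column in ", what, "; cannot standardize")
  m <- scale(m, center = ctr, scale = scl)[, , drop = FALSE]
  info$center <- ctr; info$scale <- scl
  list(m = m, info = info)
}

#' Fit the multispecies N-mixture model by MCMC
#'
#' Fits the hierarchical model (Poisson latent abundances with log-linear
#' habitat effects; species intercepts multivariate normal with an
#' exponential trait-distance correlation structure; binomial observation
#' layer with logit-linear species detectability) using an adaptive
#' Metropolis-within-Gibbs sampler with exact discrete updates of the latent
#' abundances. Chains are deterministic given `control$seed`.
#'
#' @param data a [survey_data] object.
#' @param meta a [species_meta] object (required unless `mode =
#'   "independent"` and no detection covariates are used).
#' @param mode correlation structure: `"full"`, `"guild_block"`, or
#'   `"independent"`.
#' @param convention exponential correlation parameterization (see
#'   [corr_value()]).
#' @param site_transform,detect_transform transformation applied to site and
#'   detection covariates: `"standardize"` (z-score), `"log_standardize"`
#'   (log, then z-score; the default for detection covariates such as sound
#'   power in mW), or `"none"`.
#' @param n_components,scale_scores trait-space options (see [trait_space()]).
#' @param priors a [default_priors()] configuration.
#' @param control an [mcmc_control()] configuration.
#' @param fix_lambda,fix_p optional fixed abundance-mean matrix (`n x I`) and
#'   detection-probability vector (length `I`); when supplied the
#'   corresponding model layer is held fixed (used for toy posteriors and
#'   diagnostics).
#' @param save_N save latent abundance draws (needed for posterior-predictive
#'   replication; default `TRUE`).
#' @return An object of class `msn_fit`.
#' @export
fit_msnmix <- function(data, meta = NULL,
                       mode = c("full", "guild_block", "independent"),
                       convention = c("range", "rate"),
                       site_transform = c("standardize", "log_standardize", "none"),
                       detect_transform = c("log_standardize", "standardize", "none"),
                       n_components = 2L, scale_scores = FALSE,
                       priors = default_priors(), control = mcmc_control(),
                       fix_lambda = NULL, fix_p = NULL, save_N = TRUE) {
  stopifnot(inherits(data, "survey_data"))
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  site_transform <- match.arg(site_transform)
  detect_transform <- match.arg(detect_transform)
  y <- data$counts
  n <- dim(y)[1L]; I <- dim(y)[2L]; J <- dim(y)[3L]
  Jk <- rowSums(data$visit_mask)
  if (is.null(fix_p) && !any(Jk >= 2))
    stop("detection is not estimable: no site was surveyed at least twice")

  transforms <- list()
  if (!is.null(data$site_covariates)) {
    num <- vapply(data$site_covariates, is.numeric, logical(1L))
    tx <- apply_transform(data$site_covariates[num], site_transform,
                          "site covariates")
    X <- tx$m; transforms$site <- tx$info
  } else X <- matrix(0, n, 0)
  P <- ncol(X)

  ts <- NULL
  guilds <- rep("all", I)
  if (!is.null(meta)) {
    stopifnot(inherits(meta, "species_meta"))
    if (nrow(meta$traits) != I)
      stop("species_meta has ", nrow(meta$traits), " species, data has ", I)
    ts <- trait_space(meta$traits, n_components = n_components,
                      scale_scores = scale_scores)
    guilds <- meta$guild
    if (!is.null(meta$detect_covariates)) {
      tx <- apply_transform(meta$detect_covariates, detect_transform,
                            "detection covariates")
      V <- tx$m; transforms$detect <- tx$info
    } else V <- matrix(0, I, 0)
  } else {
    if (mode != "independent")
      stop("mode '", mode, "' requires species_meta (traits)")
    V <- matrix(0, I, 0)
  }
  M <- ncol(V)
  D <- if (is.null(ts)) matrix(0, I, I) else ts$D
  theta_max <- if (mode == "independent") 1
               else resolve_theta_max(priors, D, convention)

  # --- initial values ---
  obs <- aperm(array(data$visit_mask, c(n, J, I)), c(1L, 3L, 2L))
  mean_count <- vapply(seq_len(I), function(i) {
    yi <- y[, i, ]
    mean(yi[obs[, i, ]])
  }, numeric(1L))
  yz <- y
  yz[!obs] <- 0L
  ymax <- apply(yz, c(1L, 2L), max)
  init <- list(
    beta0 = log(mean_count + 0.5),
    beta = matrix(0, I, P),
    alpha0 = rep(0, I),
    alpha = rep(0, M),
    mu0 = mean(log(mean_count + 0.5)),
    sigma0 = if (I < 2L) 0.5 else max(sd(log(mean_count + 0.5)), 0.25),
    theta = if (mode == "independent") 1 else {
      d <- D[upper.tri(D)]
      th <- if (convention == "range") median(d) else 1 / max(median(d), 1e-8)
      min(th, 0.9 * theta_max)
    },
    mu_beta = rep(0, P), sigma_beta = rep(1, P),
    mu_alpha = 0, sigma_alpha = 1,
    N = ymax)
  storage.mode(init$N) <- "integer"

  # validate the starting state against the joint density
  lj <- logjoint(init, init$N, data, X, V,
                 structure = list(D = D, mode = mode, convention = convention,
                                  guilds = guilds),
                 priors = default_priors(priors$mu_sd, priors$sigma_scale,
                                         theta_max))
  if (!is.finite(lj))
    stop("initial state has zero posterior density (log joint = ", lj,
         "); check counts, masks and covariates")

  pr <- list(mu_sd = priors$mu_sd, sigma_scale = priors$sigma_scale,
             theta_max = theta_max)
  ctl <- list(n_iter = control$n_iter, n_burn = control$n_burn,
              thin = control$thin, adapt = control$adapt,
              save_N = isTRUE(save_N),
              fix_lambda = fix_lambda, fix_p = fix_p)
  guild_codes <- as.integer(factor(guilds))
  mode_code <- match(mode, c("independent", "guild_block", "full")) - 1L
  conv_code <- match(convention, c("range", "rate")) - 1L

  sp <- data$species_ids
  hyper_names <- c("mu0", "sigma0", "theta", "mu_alpha", "sigma_alpha",
                   if (P) paste0("mu_beta_", colnames(X)),
                   if (P) paste0("sigma_beta_", colnames(X)),
                   if (M) paste0("alpha_", colnames(V)))
  alpha_names <- if (M) paste0("alpha_", colnames(V)) else character(0)

  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", control$n_chains)
  for (cc in seq_len(control$n_chains)) {
    set.seed(control$seed + cc - 1L)
    res <- run_sampler_cpp(as.integer(y), dim(y),
                           matrix(as.integer(data$visit_mask), n, J),
                           X, V, D, guild_codes, mode_code, conv_code,
                           pr, init, ctl)
    colnames(res$hyper) <- hyper_names
    colnames(res$beta0) <- paste0("beta0_", sp)
    if (P) colnames(res$beta) <-
      paste0("beta_", rep(sp, P), "_", rep(colnames(X), each = I))
    colnames(res$alpha0) <- paste0("alpha0_", sp)
    chains[[cc]] <- res
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  draws <- list(
    hyper = do.call(rbind, lapply(chains, `[[`, "hyper")),
    beta0 = do.call(rbind, lapply(chains, `[[`, "beta0")),
    beta = do.call(rbind, lapply(chains, `[[`, "beta")),
    alpha0 = do.call(rbind, lapply(chains, `[[`, "alpha0")),
    N = do.call(rbind, lapply(chains, `[[`, "N")))

  structure(list(
    chains = chains, draws = draws, data = data, meta = meta,
    trait_space = ts, mode = mode, convention = convention,
    guilds = guilds, X = X, V = V, D = D,
    transforms = transforms,
    priors = pr, control = control, init = init,
    hyper_names = hyper_names, alpha_names = alpha_names,
    fixed_lambda = fix_lambda, fixed_p = fix_p,
    acceptance = lapply(chains, `[[`, "acceptance"),
    elapsed = elapsed), class = "msn_fit")
}

#' @export
print.msn_fit <- function(x, ...) {
  d <- dim(x$data$counts)
  cat(sprintf("msn_fit: mode '%s' (%s convention), %d sites x %d species\n",
              x$mode, x$convention, d[1L], d[2L]))
  cat(sprintf("  %d chain(s) x %d iterations (%d burn-in, thin %d); %.1f s\n",
              x$control$n_chains, x$control$n_iter, x$control$n_burn,
              x$control$thin, x$elapsed))
  acc <- x$acceptance[[1L]]
  cat(sprintf("  acceptance: beta0 joint %.2f, scalar %.2f; sigma0 %.2f; theta %s\n",
              acc$beta0_joint, acc$beta0_scalar, acc$sigma0,
              ifelse(is.na(acc$theta), "-", sprintf("%.2f", acc$theta))))
  invisible(x)
}

#' Monte Carlo standard error by batch means
#'
#' @param x numeric vector of (correlated) MCMC draws.
#' @return Estimated standard error of the mean of `x`.
#' @export
mcse_batch_means <- function(x) {
  T_ <- length(x)
  if (T_ < 4L) return(NA_real_)
  nb <- max(2L, floor(sqrt(T_)))
  bs <- T_ %/% nb
  bm <- colMeans(matrix(x[seq_len(nb * bs)], bs, nb))
  sd(bm) / sqrt(nb)
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws with
#' each chain split in half.
#'
#' @param x matrix of draws, one column per chain (or a vector for a single
#'   chain).
#' @return Scalar R-hat (1 indicates convergence; `NA` for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  if (T_ < 4L) return(NA_real_)
  half <- T_ %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(T_ - half + 1L):T_, , drop = FALSE])
  if (anyNA(xs) || sd(as.vector(xs)) == 0) return(NA_real_)
  r <- matrix(rank(as.vector(xs), ties.method = "average"), nrow(xs), ncol(xs))
  z <- qnorm((r - 3 / 8) / (length(xs) + 1 / 4))
  m <- ncol(z); nn <- nrow(z)
  mu <- colMeans(z)
  B <- nn * var(mu)
  W <- mean(apply(z, 2L, var))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

summary_row <- function(draws_mat, per_chain = NULL) {
  t(vapply(seq_len(ncol(draws_mat)), function(j) {
    x <- draws_mat[, j]
    qs <- quantile(x, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
    rh <- if (!is.null(per_chain))
      split_rhat(vapply(per_chain, function(m) m[, j], numeric(nrow(per_chain[[1L]]))))
    else NA_real_
    c(mean = mean(x), sd = sd(x), `q2.5` = qs[1L], median = qs[2L],
      `q97.5` = qs[3L], mcse = mcse_batch_means(x), rhat = rh)
  }, numeric(7L)))
}

#' Posterior summary table
#'
#' Means, 2.5/50/97.5 percent posterior quantiles, Monte Carlo standard
#' errors (batch means) and rank-normalized split R-hat for the community
#' hyperparameters and, optionally, all species-level parameters.
#'
#' @param object an `msn_fit`.
#' @param pars `"hyper"` (community-level only) or `"all"` (adds species
#'   intercepts, covariate effects and detection intercepts).
#' @param ... unused.
#' @return A data frame, one row per parameter.
#' @export
summary.msn_fit <- function(object, pars = c("hyper", "all"), ...) {
  pars <- match.arg(pars)
  blocks <- c("hyper", if (pars == "all") c("beta0", "beta", "alpha0"))
  out <- do.call(rbind, lapply(blocks, function(b) {
    dm <- object$draws[[b]]
    if (is.null(dm) || ncol(dm) == 0L) return(NULL)
    per_chain <- lapply(object$chains, `[[`, b)
    s <- summary_row(dm, per_chain)
    data.frame(parameter = colnames(dm), s, row.names = NULL,
               check.names = FALSE)
  }))
  if (object$mode == "independent")
    out <- out[out$parameter != "theta", ]
  rownames(out) <- NULL
  out
}

#' Posterior summaries of the latent abundances
#'
#' @param fit an `msn_fit` with saved latent draws.
#' @return Data frame with one row per site-species cell: posterior mean,
#'   median and 95 percent credible interval of `N`, plus the maximum
#'   observed count of the cell.
#' @export
latent_summary <- function(fit) {
  stopifnot(inherits(fit, "msn_fit"))
  Nd <- fit$draws$N
  if (is.null(Nd) || ncol(Nd) == 0L) stop("latent N draws were not saved")
  n <- length(fit$data$site_ids); I <- length(fit$data$species_ids)
  qs <- apply(Nd, 2L, quantile, c(0.025, 0.5, 0.975), names = FALSE)
  J <- dim(fit$data$counts)[3L]
  ymax <- apply(sweep(fit$data$counts, c(1L, 3L),
                      array(fit$data$visit_mask, c(n, J)), `*`), c(1L, 2L), max)
  data.frame(site = rep(fit$data$site_ids, I),
             species = rep(fit$data$species_ids, each = n),
             mean = colMeans(Nd), q2.5 = qs[1L, ], median = qs[2L, ],
             q97.5 = qs[3L, ], max_count = as.vector(ymax))
}

#' Posterior summaries of pairwise abundance correlations
#'
#' Pushes each retained draw of `theta` through the exponential correlation
#' function at each pair's trait dissimilarity (zeroed across guilds under
#' the guild-block structure; identically zero off-diagonal under the
#' independent structure).
#'
#' @param fit an `msn_fit`.
#' @return Data frame with one row per unordered species pair: dissimilarity
#'   `d`, same-guild flag, posterior median and 95 percent credible interval
#'   of the correlation.
#' @export
correlation_summary <- function(fit) {
  stopifnot(inherits(fit, "msn_fit"))
  I <- length(fit$data$species_ids)
  ij <- which(upper.tri(fit$D), arr.ind = TRUE)
  d <- fit$D[ij]
  same <- fit$guilds[ij[, 1L]] == fit$guilds[ij[, 2L]]
  if (fit$mode == "independent") {
    rho <- matrix(0, 1L, nrow(ij))
  } else {
    th <- fit$draws$hyper[, "theta"]
    rho <- if (fit$convention == "range") exp(-outer(1 / th, d))
           else exp(-outer(th, d))
    if (fit$mode == "guild_block") rho[, !same] <- 0
  }
  qs <- apply(rho, 2L, quantile, c(0.025, 0.5, 0.975), names = FALSE)
  data.frame(species_i = fit$data$species_ids[ij[, 1L]],
             species_j = fit$data$species_ids[ij[, 2L]],
             d = d, same_guild = same,
             q2.5 = qs[1L, ], median = qs[2L, ], q97.5 = qs[3L, ])
}

#' Species whose habitat effect is credibly nonzero
#'
#' Flags each species whose 95 percent credible interval for the effect of a
#' site covariate excludes zero, the conventional Bayesian reading of a
#' "significant" effect.
#'
#' @param fit an `msn_fit` with at least one site covariate.
#' @param covariate covariate name or index (default first).
#' @return Data frame per species: posterior mean, interval, `significant`
#'   flag and its sign.
#' @export
significant_effects <- function(fit, covariate = 1L) {
  stopifnot(inherits(fit, "msn_fit"))
  P <- ncol(fit$X)
  if (P == 0L) stop("model has no site covariates")
  cn <- colnames(fit$X)
  cov_name <- if (is.numeric(covariate)) cn[covariate] else covariate
  I <- length(fit$data$species_ids)
  idx <- match(paste0("beta_", fit$data$species_ids, "_", cov_name),
               colnames(fit$draws$beta))
  b <- fit$draws$beta[, idx, drop = FALSE]
  qs <- apply(b, 2L, quantile, c(0.025, 0.975), names = FALSE)
  sig <- qs[1L, ] > 0 | qs[2L, ] < 0
  data.frame(species = fit$data$species_ids, covariate = cov_name,
             mean = colMeans(b), q2.5 = qs[1L, ], q97.5 = qs[2L, ],
             significant = sig,
             direction = ifelse(!sig, "none",
                                ifelse(qs[1L, ] > 0, "positive", "negative")))
}
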