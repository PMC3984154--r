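#' Expected abundance under the log-linear habitat model
#'
#' `lambda = exp(beta0_i + x_k' beta_i)`: the Poisson mean abundance of
#' species `i` at site `k`. With covariates centered at zero, `beta0_i` is the
#' log-scale expected abundance at an average site.
#'
#' @param x site covariate vector (length `P`), already centered/standardized
#'   as configured.
#' @param beta0 species intercept (log scale).
#' @param beta species covariate effects (length `P`).
#' @return Positive scalar `lambda`.
#' @export
expected_abundance <- function(x, beta0, beta) {
  lam <- exp(beta0 + sum(x * beta))
  if (!is.finite(lam)) stop("expected abundance is not finite")
  lam
}

#' Per-individual detection probability under the logit-linear model
#'
#' `p = plogis(alpha0_i + v_i' alpha)` where `v_i` are species-level detection
#' covariates (for example log sound power output).
#'
#' @param v detection covariate vector (length `M`).
#' @param alpha0 species detection intercept (logit scale).
#' @param alpha covariate effects (length `M`).
#' @return Detection probability in `(0, 1)` (limits 0/1 only at infinite
#'   linear predictor).
#' @export
detection_prob <- function(v, alpha0, alpha) {
  eta <- alpha0 + sum(v * alpha)
  if (is.na(eta)) stop("detection linear predictor is not finite")
  plogis(eta)
}

#' Binomial log-likelihood of repeated counts for one site-species cell
#'
#' Sum over surveyed visits of `log Binomial(y_j; N, p)`. A visit count
#' exceeding `N` returns `-Inf` (support violation) rather than an error, so
#' samplers can reject such states.
#'
#' @param y integer visit counts for the cell (surveyed visits only).
#' @param N latent abundance (closed population size during the surveys).
#' @param p per-individual, per-visit detection probability.
#' @return Log-likelihood (scalar; 0 for an empty `y`).
#' @export
loglik_counts <- function(y, N, p) {
  if (length(y) == 0L) return(0)
  if (any(y < 0)) stop("counts must be nonnegative")
  if (any(y > N)) return(-Inf)
  sum(dbinom(y, size = N, prob = p, log = TRUE))
}

#' Multivariate normal log-prior of the species intercepts
#'
#' Log-density of `beta0 ~ MVN(mu0 * 1, sigma0^2 * R)`, evaluated via the
#' Cholesky factor of `R`.
#'
#' @param beta0 length-`I` intercept vector.
#' @param mu0 community mean intercept.
#' @param sigma0 positive standard deviation among intercepts.
#' @param R `I x I` correlation matrix (must be positive definite).
#' @return Log-density (scalar).
#' @export
logprior_intercepts <- function(beta0, mu0, sigma0, R) {
  I <- length(beta0)
  if (!isTRUE(all(dim(R) == c(I, I)))) stop("dim(R) must match length(beta0)")
  if (sigma0 <= 0) stop("sigma0 must be positive")
  L <- tryCatch(chol(R), error = function(e)
    stop("R is not positive definite: ", conditionMessage(e)))
  z <- backsolve(L, beta0 - mu0, transpose = TRUE) / sigma0
  -0.5 * I * log(2 * pi) - I * log(sigma0) - sum(log(diag(L))) -
    0.5 * sum(z^2)
}

log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) - log(pi * scale * (1 + (x / scale)^2)), -Inf)
}

#' Default hyperprior configuration
#'
#' Community-level means and detection-covariate effects receive Normal(0,
#' sd = `mu_sd`) priors; standard deviations receive half-Cauchy(`sigma_scale`)
#' priors; the correlation decay parameter `theta` receives a Uniform(0,
#' `theta_max`) prior. When `theta_max` is `NULL` it is resolved at fit time
#' from the observed dissimilarities (95th percentile of off-diagonal `d`
#' under the range convention; `100 / median(d)` under the rate convention).
#'
#' @param mu_sd,sigma_scale,theta_max positive scalars (see above).
#' @return A list of class `msn_priors`.
#' @export
default_priors <- function(mu_sd = 10, sigma_scale = 2.5, theta_max = NULL) {
  stopifnot(mu_sd > 0, sigma_scale > 0, is.null(theta_max) || theta_max > 0)
  structure(list(mu_sd = mu_sd, sigma_scale = sigma_scale,
                 theta_max = theta_max), class = "msn_priors")
}

resolve_theta_max <- function(priors, D, convention) {
  if (!is.null(priors$theta_max)) return(priors$theta_max)
  d <- D[upper.tri(D)]
  if (convention == "range") unname(quantile(d, 0.95))
  else 100 / max(median(d), .Machine$double.eps)
}

#' Joint log-density of the full hierarchical model
#'
#' Sum of every model term: hyperpriors, the multivariate normal prior of the
#' species intercepts (correlation matrix built from `structure`), exchangeable
#' normal priors of the covariate and detection parameters, the Poisson layer
#' of the latent abundances, and the binomial layer of the observed counts.
#' Returns `-Inf` on any support violation (e.g. a latent abundance below the
#' maximum observed count of its cell).
#'
#' @param params list with elements `beta0` (length `I`), `mu0`, `sigma0`,
#'   `theta`, `beta` (`I x P`), `mu_beta` (length `P`), `sigma_beta` (length
#'   `P`), `alpha0` (length `I`), `mu_alpha`, `sigma_alpha`, `alpha` (length
#'   `M`).
#' @param N integer matrix `n x I` of latent abundances.
#' @param data a [survey_data] object.
#' @param X design matrix `n x P` of (transformed) site covariates.
#' @param V design matrix `I x M` of (transformed) detection covariates.
#' @param structure list with `D`, `mode`, `convention`, `guilds` describing
#'   the correlation structure (see [build_corr()]).
#' @param priors a [default_priors()] list.
#' @return Scalar log-density (possibly `-Inf`).
#' @export
logjoint <- function(params, N, data, X, V, structure, priors = default_priors()) {
  y <- data$counts
  n <- dim(y)[1L]; I <- dim(y)[2L]; J <- dim(y)[3L]
  P <- ncol(X); M <- ncol(V)
  pa <- params
  beta <- matrix(pa$beta, I, P)
  if (length(pa$beta0) != I || length(pa$alpha0) != I ||
      length(pa$alpha) != M || length(pa$mu_beta) != P ||
      !isTRUE(all(dim(N) == c(n, I))))
    stop("parameter dimensions do not match the data")
  if (pa$sigma0 <= 0 || any(pa$sigma_beta <= 0) || pa$sigma_alpha <= 0)
    return(-Inf)
  lp <- dnorm(pa$mu0, 0, priors$mu_sd, log = TRUE) +
    sum(dnorm(pa$mu_beta, 0, priors$mu_sd, log = TRUE)) +
    dnorm(pa$mu_alpha, 0, priors$mu_sd, log = TRUE) +
    sum(dnorm(pa$alpha, 0, priors$mu_sd, log = TRUE)) +
    log_half_cauchy(pa$sigma0, priors$sigma_scale) +
    sum(log_half_cauchy(pa$sigma_beta, priors$sigma_scale)) +
    log_half_cauchy(pa$sigma_alpha, priors$sigma_scale)
  if (structure$mode != "independent") {
    tmax <- resolve_theta_max(priors, structure$D, structure$convention)
    if (pa$theta <= 0 || pa$theta >= tmax) return(-Inf)
    lp <- lp - log(tmax)  # Uniform(0, theta_max)
  }
  cs <- build_corr(structure$D,
                   theta = if (structure$mode == "independent") NULL else pa$theta,
                   mode = structure$mode, guilds = structure$guilds,
                   convention = structure$convention)
  lp <- lp + logprior_intercepts(pa$beta0, pa$mu0, pa$sigma0, cs$R)
  for (p_ in seq_len(P))
    lp <- lp + sum(dnorm(beta[, p_], pa$mu_beta[p_], pa$sigma_beta[p_],
                         log = TRUE))
  lp <- lp + sum(dnorm(pa$alpha0, pa$mu_alpha, pa$sigma_alpha, log = TRUE))
  lambda <- exp(matrix(pa$beta0, n, I, byrow = TRUE) + X %*% t(beta))
  lp <- lp + sum(dpois(N, lambda, log = TRUE))
  pdet <- plogis(pa$alpha0 + as.vector(V %*% pa$alpha))
  for (i in seq_len(I)) for (k in seq_len(n)) {
    yk <- y[k, i, data$visit_mask[k, ]]
    ll <- loglik_counts(yk, N[k, i], pdet[i])
    if (!is.finite(ll)) return(-Inf)
    lp <- lp + ll
  }
  lp
}

#' Exact discrete full conditional of a latent abundance
#'
#' Normalized probability mass function of `N` given the visit counts `y` of
#' one site-species cell, `N ~ Poisson(lambda)` a priori and
#' `y_j | N ~ Binomial(N, p)` independently across visits. The support is
#' enumerated from `max(y)` upward until the unnormalized tail mass falls
#' below `tol` relative to the mode (this is the distribution the sampler
#' draws latent abundances from).
#'
#' @param y integer visit counts for the cell.
#' @param lambda Poisson mean abundance.
#' @param p detection probability in `(0, 1]`.
#' @param tol relative tail-mass tolerance for truncating the enumeration.
#' @return A data frame with columns `N` and `prob` (summing to 1).
#' @export
latent_conditional <- function(y, lambda, p, tol = 1e-14) {
  stopifnot(lambda > 0, p > 0, p <= 1)
  ymax <- max(y, 0L)
  if (p == 1)
    return(data.frame(N = ymax, prob = 1))
  cap <- ymax + qpois(1 - 1e-12, lambda * (1 - p)) + 10L
  repeat {
    Ns <- ymax:cap
    lw <- dpois(Ns, lambda, log = TRUE) +
      vapply(Ns, function(Nv) sum(dbinom(y, Nv, p, log = TRUE)), numeric(1L))
    if (lw[length(lw)] - max(lw) < log(tol) || cap - ymax > 100000L) break
    cap <- cap + max(16L, (cap - ymax) %/% 2L)
  }
  w <- exp(lw - max(lw))
  data.frame(N = Ns, prob = w / sum(w))
}
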