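#' Exponential trait-distance correlation function
#'
#' Correlation between the log-scale abundances of two species as an
#' exponential decay in their trait dissimilarity `d`. Two parameterizations
#' are supported: `"range"`, `exp(-d / theta)`, in which `theta` acts as a
#' correlation range on the distance scale, and `"rate"`, `exp(-theta * d)`,
#' in which it acts as a decay rate. The value is 1 exactly when `d = 0` and
#' strictly decreasing in `d`.
#'
#' @param d nonnegative dissimilarity (vectorized).
#' @param theta positive decay parameter.
#' @param convention `"range"` (default) or `"rate"`.
#' @return Correlation value(s) in `(0, 1]`.
#' @export
corr_value <- function(d, theta, convention = c("range", "rate")) {
  convention <- match.arg(convention)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("`theta` must be a positive scalar")
  if (any(d < 0)) stop("`d` must be nonnegative")
  if (convention == "range") exp(-d / theta) else exp(-theta * d)
}

#' Build the species correlation matrix R
#'
#' Constructs the `I x I` correlation matrix of species log-abundance
#' intercepts from the trait dissimilarity matrix `D` under one of three
#' structures: `"independent"` (identity: abundances uncorrelated),
#' `"guild_block"` (correlations only within foraging guilds; block-diagonal
#' when species are ordered by guild), or `"full"` (correlations among all
#' species). Positive definiteness is guaranteed by a diagonal-jitter repair:
#' if the Cholesky factorization fails, `eps` is added to the diagonal and the
#' matrix renormalized to unit diagonal, with `eps` doubling from 1e-10 up to
#' 1e-6; failure beyond that is an error.
#'
#' @param D symmetric nonnegative dissimilarity matrix with zero diagonal.
#' @param theta positive decay parameter (ignored for `"independent"`).
#' @param mode correlation structure.
#' @param guilds guild labels, length `I` (required for `"guild_block"`).
#' @param convention passed to [corr_value()].
#' @return An object of class `corr_structure`: `R`, `mode`, `theta`,
#'   `convention`, `guilds`, `jitter_used` (0 when no repair was needed).
#' @export
build_corr <- function(D, theta = NULL,
                       mode = c("full", "guild_block", "independent"),
                       guilds = NULL, convention = c("range", "rate")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  D <- as.matrix(D)
  I <- nrow(D)
  if (ncol(D) != I) stop("`D` must be square")
  if (mode == "independent") {
    R <- diag(I)
    dimnames(R) <- dimnames(D)
    return(structure(list(R = R, mode = mode, theta = NA_real_,
                          convention = convention, guilds = guilds,
                          jitter_used = 0), class = "corr_structure"))
  }
  if (mode == "guild_block" && is.null(guilds))
    stop("mode 'guild_block' requires guild labels")
  R <- corr_value(D, theta, convention)
  if (mode == "guild_block") {
    same <- outer(guilds, guilds, "==")
    R[!same] <- 0
  }
  diag(R) <- 1
  # d = 0 off-diagonal (tied trait vectors) makes R singular
  same_guild <- if (mode == "guild_block") outer(guilds, guilds, "==") else TRUE
  ties <- which(D == 0 & upper.tri(D) & same_guild, arr.ind = TRUE)
  if (nrow(ties) > 0L)
    warning(sprintf(
      "species pair (%s, %s) has zero trait dissimilarity; R is singular and will be jittered",
      rownames(D)[ties[1L, 1L]] %||% ties[1L, 1L],
      colnames(D)[ties[1L, 2L]] %||% ties[1L, 2L]))
  jit <- 0
  Rj <- R
  eps <- 1e-10
  while (inherits(try(chol(Rj), silent = TRUE), "try-error")) {
    if (eps > 1e-6) {
      ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      stop(sprintf(
        "R is not positive definite (smallest eigenvalue %.3g) and could not be repaired within the jitter budget",
        ev))
    }
    Rj <- (R + diag(eps, I)) / (1 + eps)
    jit <- eps
    eps <- eps * 2
  }
  dimnames(Rj) <- dimnames(D)
  structure(list(R = Rj, mode = mode, theta = theta, convention = convention,
                 guilds = guilds, jitter_used = jit),
            class = "corr_structure")
}

#' @export
print.corr_structure <- function(x, ...) {
  cat(sprintf("corr_structure: mode '%s', %d species", x$mode, nrow(x$R)))
  if (!is.na(x$theta))
    cat(sprintf(", theta = %g (%s convention)", x$theta, x$convention))
  if (x$jitter_used > 0)
    cat(sprintf(", diagonal jitter %g applied", x$jitter_used))
  cat("\n")
  invisible(x)
}
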