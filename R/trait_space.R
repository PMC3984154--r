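#' Standardize trait columns to zero mean and unit standard deviation
#'
#' @param traits numeric matrix `n_species x Q`.
#' @return Matrix of z-scores (sample standard deviation, denominator
#'   `n - 1`), same dimnames.
#' @export
standardize_traits <- function(traits) {
  traits <- as.matrix(traits)
  sds <- apply(traits, 2L, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    j <- which(sds == 0 | !is.finite(sds))[1L]
    stop("trait '", colnames(traits)[j] %||% j,
         "' is constant; cannot standardize")
  }
  scale(traits, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Morphological trait space of a species assemblage
#'
#' Standardizes the trait matrix, performs a principal components analysis on
#' the trait correlation matrix, projects species onto the leading
#' eigenvectors, and computes the pairwise Euclidean dissimilarity matrix `D`
#' between species scores. Each eigenvector is oriented so that its
#' largest-magnitude loading is positive (distances are unaffected; reported
#' scores are stabilized).
#'
#' @param traits numeric matrix `n_species x Q` of raw traits.
#' @param n_components number of principal components retained (default 2).
#' @param scale_scores if `TRUE`, scores are divided by the square root of the
#'   corresponding eigenvalue (unit-variance scores). The default (`FALSE`)
#'   uses raw projections onto unit-norm eigenvectors.
#' @return An object of class `trait_space`: `scores` (`I x n_components`),
#'   `eigenvalues` (length `Q`, nonincreasing, summing to `Q`), `loadings`
#'   (`Q x n_components`), `D` (`I x I` symmetric dissimilarity matrix).
#' @export
trait_space <- function(traits, n_components = 2L, scale_scores = FALSE) {
  traits <- as.matrix(traits)
  I <- nrow(traits); Q <- ncol(traits)
  if (I < 2L) stop("at least two species are required")
  if (n_components > Q)
    stop("n_components (", n_components, ") exceeds the number of traits (",
         Q, ")")
  z <- standardize_traits(traits)
  e <- eigen(cor(traits), symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, j]))
    if (vecs[m, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- z %*% vecs
  if (scale_scores) {
    lam <- vals[seq_len(n_components)]
    scores <- sweep(scores, 2L, sqrt(pmax(lam, .Machine$double.eps)), "/")
  }
  dimnames(scores) <- list(rownames(traits), paste0("PC", seq_len(n_components)))
  dimnames(vecs) <- list(colnames(traits), colnames(scores))
  structure(list(scores = scores, eigenvalues = vals, loadings = vecs,
                 D = dissimilarity_matrix(scores)),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species, %d components retained of %d traits\n",
              nrow(x$scores), ncol(x$scores), length(x$eigenvalues)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  cat(sprintf("  dissimilarity range: [0, %.3g]\n", max(x$D)))
  invisible(x)
}

#' Pairwise Euclidean dissimilarity between species score vectors
#'
#' @param scores numeric matrix, one row per species.
#' @return Symmetric matrix `D` with zero diagonal, `D[i, j]` the Euclidean
#'   distance between score rows `i` and `j`.
#' @export
dissimilarity_matrix <- function(scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  D <- as.matrix(dist(scores, method = "euclidean"))
  dimnames(D) <- list(rownames(scores), rownames(scores))
  D
}
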