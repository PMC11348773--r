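#' Iterative SVD imputation of missing genotypes
#'
#' Low-rank matrix completion by alternating truncated SVD: missing cells
#' are initialized with locus (column) means over observed genotypes, then
#' repeatedly replaced by the rank-`rank` SVD reconstruction of the current
#' matrix until the largest absolute change on a missing cell drops below
#' `tol` or `max_iter` is reached.  Observed cells are never altered.
#' Imputed values are left real-valued (suitable for PCA); use
#' `round_to_genotype = TRUE` to clamp and round them to \{0, 1, 2\} for
#' export.
#'
#' @param gm a [genotype_matrix()] or numeric matrix with NAs
#' @param rank number of singular vectors retained (default 10, capped at
#'   the matrix dimensions)
#' @param tol convergence threshold on the max change of imputed cells
#' @param max_iter iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error
#' @param round_to_genotype clamp and round imputed cells to \{0,1,2\}
#' @return object of class `svd_impute` with elements `x` (completed
#'   matrix), `mask` (logical matrix marking imputed cells), `rank`,
#'   `iterations`, `delta` (final max change) and `converged`
#' @export
svd_impute <- function(gm, rank = 10, tol = 1e-6, max_iter = 100,
                       round_to_genotype = FALSE) {
  tab <- if (inherits(gm, "geno_matrix")) gm$tab else as.matrix(gm)
  mask <- is.na(tab)
  if (any(rowSums(!mask) == 0)) stop("sample with all genotypes missing")
  if (any(colSums(!mask) == 0)) stop("locus with all genotypes missing")
  rank <- max(1L, min(as.integer(rank), nrow(tab), ncol(tab)))
  x <- tab
  if (!any(mask)) {
    return(structure(list(x = x, mask = mask, rank = rank, iterations = 0L,
                          delta = 0, converged = TRUE), class = "svd_impute"))
  }
  m <- locus_means(tab)
  idx <- which(mask, arr.ind = TRUE)
  x[idx] <- m[idx[, 2]]
  delta <- Inf
  it <- 0L
  trace <- numeric(0)
  while (it < max_iter && delta > tol) {
    it <- it + 1L
    s <- svd(x, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    new_vals <- recon[idx]
    delta <- max(abs(new_vals - x[idx]))
    trace <- c(trace, delta)
    x[idx] <- new_vals
  }
  if (round_to_genotype) x[idx] <- pmin(2, pmax(0, round(x[idx])))
  structure(list(x = x, mask = mask, rank = rank, iterations = it,
                 delta = delta, delta_trace = trace, converged = delta <= tol),
            class = "svd_impute")
}

#' @export
print.svd_impute <- function(x, ...) {
  cat(sprintf("svd_impute: %d cells imputed at rank %d (%d iterations, final change %.2e%s)\n",
              sum(x$mask), x$rank, x$iterations, x$delta,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Exact PCA via singular value decomposition of the column-centered
#' (optionally unit-variance scaled) matrix.  Each component's sign is fixed
#' so that its largest-magnitude loading is positive, which makes results
#' reproducible across platforms and BLAS builds.
#'
#' @param x complete numeric matrix (samples x variables); a
#'   [genotype_matrix()] is mean-filled first
#' @param k number of components to keep (default: full rank)
#' @param scale divide each column by its standard deviation; zero-variance
#'   columns are dropped with a warning
#' @return object of class `pca_result` with `loadings` (variables x k,
#'   orthonormal), `scores` (samples x k), `eig` (variances, length k,
#'   non-increasing), `center`, `scale` (NULL when unscaled) and `dropped`
#'   (ids of zero-variance columns removed under scaling)
#' @export
pca <- function(x, k = NULL, scale = FALSE) {
  if (inherits(x, "geno_matrix")) x <- mean_fill(x)
  x <- as.matrix(x)
  if (anyNA(x)) stop("pca requires a complete matrix; impute first")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- NULL
  dropped <- character(0)
  if (scale) {
    sdv <- apply(xc, 2, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning(sprintf("dropping %d zero-variance column(s) under scaling", sum(zero)))
      dropped <- colnames(xc)[zero]
      xc <- xc[, !zero, drop = FALSE]
      ctr <- ctr[!zero]
      sdv <- sdv[!zero]
    }
    xc <- sweep(xc, 2, sdv, "/")
    scl <- sdv
  }
  full <- min(dim(xc))
  if (is.null(k)) k <- full
  if (k < 1 || k > full) stop("k out of range")
  s <- svd(xc, nu = k, nv = k)
  load <- s$v
  # sign convention: largest-|loading| entry of each component positive
  for (a in seq_len(k)) {
    j <- which.max(abs(load[, a]))
    if (load[j, a] < 0) {
      load[, a] <- -load[, a]
      s$u[, a] <- -s$u[, a]
    }
  }
  scores <- s$u %*% diag(s$d[seq_len(k)], k)
  dimnames(load) <- list(colnames(xc), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(xc), paste0("PC", seq_len(k)))
  structure(list(loadings = load, scores = scores,
                 eig = s$d[seq_len(k)]^2 / (nrow(xc) - 1),
                 center = ctr, scale = scl, dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$eig)
  cat(sprintf("pca_result: %d components; leading variances %s\n",
              k, paste(signif(utils::head(x$eig, 5), 4), collapse = ", ")))
  invisible(x)
}
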