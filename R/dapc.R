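#' Discriminant Analysis of Principal Components
#'
#' Fits the two-stage classifier used throughout this package: genotypes are
#' centered (optionally unit-scaled), projected onto their leading `n_pca`
#' principal components, and a Fisher linear discriminant analysis is run on
#' the PC scores, maximizing the ratio of between-group to within-group
#' variance.  Running the LDA in a reduced PC space keeps the within-group
#' scatter well conditioned when loci outnumber samples, which is the usual
#' regime for SNP panels.
#'
#' Missing genotypes are filled with locus means before fitting.  The
#' within-group covariance is regularized with a small ridge
#' (`1e-8 * mean(diag(W))`) so that tiny groups cannot make it singular.
#' Discriminant axes are scaled to unit within-group variance, so group
#' posteriors reduce to Gaussian class-conditional densities with a shared
#' spherical covariance in discriminant space.
#'
#' @param x a [genotype_matrix()] or numeric matrix (samples x loci)
#' @param labels factor or character vector of group labels, one per sample
#' @param n_pca number of principal components retained (default: all)
#' @param n_da number of discriminant axes retained; capped at
#'   `min(n_pca, nlevels - 1)`
#' @param scale unit-scale loci before PCA (default FALSE)
#' @param priors `"proportional"` (group sizes) or `"uniform"`, or a named
#'   numeric vector summing to 1
#' @return object of class `dapc_model` holding the centering/scaling stats,
#'   PCA loadings, discriminant coefficients, group centroids in
#'   discriminant space, priors and per-locus contributions
#' @seealso [predict.dapc_model()], [variable_contributions()],
#'   [xval_select_npca()]
#' @export
fit_dapc <- function(x, labels, n_pca = NULL, n_da = NULL, scale = FALSE,
                     priors = c("proportional", "uniform")) {
  tab <- if (inherits(x, "geno_matrix")) x$tab else as.matrix(x)
  labels <- factor(labels)
  if (length(labels) != nrow(tab)) stop("one label per sample required")
  counts <- table(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(counts < 2)) stop(sprintf("group '%s' has fewer than 2 samples",
                                    names(counts)[counts < 2][1]))
  tab <- mean_fill(tab)
  if (is.character(priors)) {
    priors <- match.arg(priors)
    pr <- if (priors == "proportional") as.numeric(counts) / sum(counts)
          else rep(1 / nlevels(labels), nlevels(labels))
    names(pr) <- levels(labels)
  } else {
    pr <- priors[levels(labels)]
    if (anyNA(pr) || abs(sum(pr) - 1) > 1e-8)
      stop("priors must be named over all groups and sum to 1")
  }

  full <- min(nrow(tab) - 1L, ncol(tab))
  if (is.null(n_pca)) n_pca <- full
  n_pca <- max(1L, min(as.integer(n_pca), full))
  pc <- pca(tab, k = n_pca, scale = scale)
  sc <- pc$scores

  g <- nlevels(labels)
  n_da_max <- min(n_pca, g - 1L)
  if (is.null(n_da)) n_da <- n_da_max
  n_da <- max(1L, min(as.integer(n_da), n_da_max))

  # pooled within-group and between-group covariance of the PC scores
  mu_g <- rowsum(sc, labels) / as.numeric(counts)
  centered <- sc - mu_g[labels, , drop = FALSE]
  W <- crossprod(centered) / (nrow(sc) - g)
  grand <- colMeans(sc)
  dev <- sweep(mu_g, 2, grand)
  B <- crossprod(dev * sqrt(as.numeric(counts))) / (g - 1)

  ridge <- 1e-8 * mean(diag(W))
  if (mean(diag(W)) < .Machine$double.eps) ridge <- 1e-8
  eW <- eigen((W + t(W)) / 2 + ridge * diag(n_pca), symmetric = TRUE)
  pos <- pmax(eW$values, ridge)
  W_half_inv <- eW$vectors %*% (t(eW$vectors) / sqrt(pos))
  M <- t(W_half_inv) %*% B %*% W_half_inv
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  coef <- W_half_inv %*% eM$vectors[, seq_len(n_da), drop = FALSE]
  # deterministic sign: largest-|weight| coefficient positive per axis
  for (a in seq_len(n_da)) {
    j <- which.max(abs(coef[, a]))
    if (coef[j, a] < 0) coef[, a] <- -coef[, a]
  }
  dimnames(coef) <- list(colnames(sc), paste0("LD", seq_len(n_da)))

  da_scores <- sc %*% coef
  centroids <- rowsum(da_scores, labels) / as.numeric(counts)

  model <- structure(list(
    center = pc$center, scale = pc$scale, dropped = pc$dropped,
    loadings = pc$loadings, coef = coef,
    n_pca = n_pca, n_da = n_da,
    groups = levels(labels), centroids = centroids, priors = pr,
    eig = eM$values[seq_len(n_da)],
    loci = rownames(pc$loadings)), class = "dapc_model")
  model$contrib <- variable_contributions(model)
  model
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d loci -> %d PCs -> %d discriminant axes; groups: %s\n",
              length(x$loci), x$n_pca, x$n_da,
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

# project raw genotype rows into the model's discriminant space;
# missing / absent loci are filled with the model's locus means, i.e. they
# contribute zero after centering
project_dapc <- function(model, tab) {
  loci <- model$loci
  new <- matrix(NA_real_, nrow(tab), length(loci),
                dimnames = list(rownames(tab), loci))
  shared <- intersect(colnames(tab), loci)
  if (length(shared) == 0) stop("no overlap between sample loci and model loci")
  new[, shared] <- tab[, shared]
  xc <- sweep(new, 2, model$center)
  xc[is.na(xc)] <- 0
  if (!is.null(model$scale)) xc <- sweep(xc, 2, model$scale, "/")
  (xc %*% model$loadings) %*% model$coef
}

#' Posterior group membership for new samples
#'
#' Projects new genotypes through the stored centering, PCA basis and
#' discriminant coefficients, then evaluates Gaussian class-conditional
#' densities with shared spherical covariance around the group centroids:
#' `posterior_k propto prior_k * exp(-d_k^2 / 2)` where `d_k` is Euclidean
#' distance in discriminant space.  Loci absent from the new data, and
#' missing genotypes, are mean-filled from the training data.  Ties on the
#' maximum posterior break lexicographically on the group label.
#'
#' @param object a fitted `dapc_model`
#' @param newdata a [genotype_matrix()] or numeric matrix; loci matched by
#'   name (must share at least one locus with the model)
#' @param ... unused
#' @return list with `posterior` (samples x groups, rows sum to 1),
#'   `assign` (character vector of winning labels) and `da_scores`
#' @export
predict.dapc_model <- function(object, newdata, ...) {
  tab <- if (inherits(newdata, "geno_matrix")) newdata$tab else as.matrix(newdata)
  z <- project_dapc(object, tab)
  d2 <- outer(rowSums(z^2), rep(1, nrow(object$centroids))) -
    2 * z %*% t(object$centroids) +
    outer(rep(1, nrow(z)), rowSums(object$centroids^2))
  logp <- -0.5 * d2 + matrix(log(object$priors), nrow(z),
                             length(object$priors), byrow = TRUE)
  logp <- logp - apply(logp, 1, max)
  post <- exp(logp)
  post <- post / rowSums(post)
  colnames(post) <- object$groups
  rownames(post) <- rownames(tab)
  # argmax with lexicographic tie-break: scan groups in sorted label order
  ord <- order(object$groups)
  win <- apply(post[, ord, drop = FALSE], 1, which.max)
  assign <- object$groups[ord][win]
  names(assign) <- rownames(tab)
  list(posterior = post, assign = assign, da_scores = z)
}

#' Per-locus contributions to the discriminant axes
#'
#' The total weight of locus `j` on discriminant axis `a` is the composition
#' of the PCA loadings with the discriminant coefficients (divided by the
#' locus scale when scaling was used).  The contribution is the squared
#' total weight, normalized to sum to 1 within each axis.  These are the
#' "LD values" used to rank SNPs by diagnosticity.
#'
#' @param model a fitted `dapc_model`
#' @return matrix (loci x n_da) of contributions, each column summing to 1
#' @export
variable_contributions <- function(model) {
  w <- model$loadings %*% model$coef        # loci x n_da, in scaled units
  if (!is.null(model$scale)) w <- w / model$scale
  contrib <- w^2
  contrib <- sweep(contrib, 2, colSums(contrib), "/")
  dimnames(contrib) <- list(model$loci, colnames(model$coef))
  contrib
}

#' Rank loci by total discriminant contribution (LD value)
#'
#' @param model a fitted `dapc_model`
#' @return character vector of locus ids, most diagnostic first
#' @export
rank_loci <- function(model) {
  total <- rowSums(model$contrib)
  names(sort(total, decreasing = TRUE))
}

#' Cross-validated choice of the number of retained PCs
#'
#' For each candidate `n_pca`, repeatedly splits every group into a
#' stratified training fraction (default 90%) and a held-out remainder, fits
#' the DAPC on the training part and scores the proportion of held-out
#' samples re-assigned to their true group.  The chosen `n_pca` maximizes
#' the mean held-out success; ties go to the smallest candidate (the most
#' parsimonious model).  Root-mean-square error of `1 - posterior(true
#' group)` is reported secondarily.
#'
#' @param x genotypes (matrix or [genotype_matrix()])
#' @param labels group labels
#' @param grid candidate `n_pca` values; default `seq(10, rank, by = 10)`
#'   capped at 300
#' @param training_fraction fraction of each group used for training
#' @param reps number of random splits per candidate
#' @param seed integer seed fixing the splits
#' @param ... passed to [fit_dapc()] (e.g. `scale`, `priors`)
#' @return object of class `xval_report`: data.frame `grid` with mean
#'   success and RMSE per candidate, plus `chosen`, `reps`, `seed`
#' @export
xval_select_npca <- function(x, labels, grid = NULL, training_fraction = 0.9,
                             reps = 30, seed = 1, ...) {
  tab <- if (inherits(x, "geno_matrix")) mean_fill(x) else as.matrix(x)
  labels <- factor(labels)
  if (training_fraction <= 0 || training_fraction >= 1)
    stop("training_fraction must be in (0,1)")
  counts <- table(labels)
  n_test <- pmax(1, round(as.numeric(counts) * (1 - training_fraction)))
  if (any(as.numeric(counts) - n_test < 2))
    stop("a group would have fewer than 2 training samples")
  full <- min(nrow(tab) - sum(n_test) - 1, ncol(tab))
  if (is.null(grid)) grid <- unique(pmin(seq(10, 300, by = 10), full))
  grid <- sort(unique(as.integer(pmin(grid, full))))
  grid <- grid[grid >= 1]
  if (length(grid) == 0) stop("empty candidate grid")

  res <- matrix(NA_real_, length(grid), reps)
  rmse <- matrix(NA_real_, length(grid), reps)
  set.seed(seed)
  for (r in seq_len(reps)) {
    test_idx <- unlist(lapply(levels(labels), function(g) {
      idx <- which(labels == g)
      sample(idx, n_test[match(g, levels(labels))])
    }))
    train_idx <- setdiff(seq_len(nrow(tab)), test_idx)
    for (i in seq_along(grid)) {
      fit <- fit_dapc(tab[train_idx, , drop = FALSE], labels[train_idx],
                      n_pca = grid[i], ...)
      pred <- predict(fit, tab[test_idx, , drop = FALSE])
      truth <- as.character(labels[test_idx])
      res[i, r] <- mean(pred$assign == truth)
      p_true <- pred$posterior[cbind(seq_along(test_idx),
                                     match(truth, colnames(pred$posterior)))]
      rmse[i, r] <- sqrt(mean((1 - p_true)^2))
    }
  }
  mean_success <- rowMeans(res)
  chosen <- grid[which.max(mean_success)]  # which.max -> first, i.e. smallest
  structure(list(grid = data.frame(n_pca = grid,
                                   mean_success = mean_success,
                                   mean_rmse = rowMeans(rmse)),
                 chosen = chosen, reps = reps, seed = seed,
                 training_fraction = training_fraction),
            class = "xval_report")
}

#' @export
print.xval_report <- function(x, ...) {
  cat(sprintf("xval_report: chosen n_pca = %d (%d reps, training fraction %.2f)\n",
              x$chosen, x$reps, x$training_fraction))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Serialize a DAPC model to JSON
#'
#' Writes every field needed for out-of-sample prediction in a portable
#' JSON container (full double precision), so a model can be rebuilt
#' elsewhere and produce identical posteriors.
#'
#' @param model a `dapc_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_dapc <- function(model, path) {
  payload <- list(
    format = "snpcascade-dapc", version = 1L,
    center = as.list(model$center),
    scale = if (is.null(model$scale)) NULL else as.list(model$scale),
    loadings = model$loadings, coef = model$coef,
    n_pca = model$n_pca, n_da = model$n_da,
    groups = model$groups, centroids = model$centroids,
    priors = as.list(model$priors), eig = model$eig, loci = model$loci)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a DAPC model written by [write_dapc()]
#' @param path JSON file
#' @return a `dapc_model`
#' @export
read_dapc <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "snpcascade-dapc")) stop("not a DAPC model file")
  load <- as.matrix(p$loadings)
  coef <- as.matrix(p$coef)
  dimnames(load) <- list(p$loci, paste0("PC", seq_len(ncol(load))))
  dimnames(coef) <- list(paste0("PC", seq_len(nrow(coef))),
                         paste0("LD", seq_len(ncol(coef))))
  cent <- as.matrix(p$centroids)
  dimnames(cent) <- list(p$groups, colnames(coef))
  model <- structure(list(
    center = stats::setNames(unlist(p$center), p$loci),
    scale = if (is.null(p$scale)) NULL else stats::setNames(unlist(p$scale), p$loci),
    dropped = character(0),
    loadings = load, coef = coef, n_pca = p$n_pca, n_da = p$n_da,
    groups = p$groups, centroids = cent,
    priors = stats::setNames(unlist(p$priors), p$groups),
    eig = p$eig, loci = p$loci), class = "dapc_model")
  model$contrib <- variable_contributions(model)
  model
}
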