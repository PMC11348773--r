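#' Posterior-purity separation criterion for one target group
#'
#' A target group counts as separated when (a) every target sample's
#' posterior for the target group is at least `tau` and (b) no non-target
#' sample is assigned to the target group.  The reported metric is the
#' minimum target-posterior over the target samples, so it increases as the
#' target cluster pulls away from the rest.  At `tau = 0` the criterion
#' reduces to pure assignment-based non-overlap.
#'
#' @param posterior samples x groups posterior matrix (rows sum to 1)
#' @param assign character vector of assigned labels, one per sample
#' @param labels true labels
#' @param target the group being separated
#' @param tau posterior purity threshold in `[0, 1]`
#' @return list with `separated` (logical) and `metric` (min target
#'   posterior over target samples)
#' @export
separation_criterion <- function(posterior, assign, labels, target, tau = 0.95) {
  labels <- as.character(labels)
  if (!target %in% labels) stop(sprintf("empty target group '%s'", target))
  in_target <- labels == target
  p_target <- posterior[in_target, target]
  metric <- min(p_target)
  pure <- metric >= tau && all(assign[in_target] == target)
  no_intruder <- !any(assign[!in_target] == target)
  list(separated = pure && no_intruder, metric = metric)
}

#' Iterative discovery of a diagnostic SNP set for one group
#'
#' Implements the sequential panel-growing procedure: a DAPC over the full
#' candidate pool ranks loci by their total discriminant contribution (LD
#' value); the top `batch_size` loci seed the panel.  Each round refits the
#' DAPC on the current panel and checks [separation_criterion()] for the
#' target group.  While the target is not yet separated, the next batch of
#' loci down the ranking is tried: batches that raise the separation metric
#' by at least `eps` (or achieve separation outright) are retained, batches
#' that do not are discarded and never revisited for this target.
#'
#' @param x genotypes (matrix or [genotype_matrix()])
#' @param labels group labels
#' @param target group to separate
#' @param batch_size loci added per round (default 25)
#' @param tau posterior purity threshold (default 0.95)
#' @param eps minimum metric improvement for a batch to count as useful
#' @param max_rounds round cap; hitting it returns the best panel found,
#'   flagged unconverged
#' @param n_pca PCs retained in each refit (default: min(50, rank))
#' @param pool candidate locus ids (default: all loci of `x`)
#' @param ... passed to [fit_dapc()]
#' @return object of class `snp_selection`: `selected` (locus ids),
#'   `separated` (logical), `metric`, `log` (one row per round: action,
#'   panel size, metric), `target`, `discarded`
#' @export
iterative_select <- function(x, labels, target, batch_size = 25, tau = 0.95,
                             eps = 0.01, max_rounds = 40, n_pca = NULL,
                             pool = NULL, ...) {
  tab <- if (inherits(x, "geno_matrix")) mean_fill(x) else as.matrix(x)
  if (is.null(pool)) pool <- colnames(tab)
  if (length(pool) == 0) stop("empty candidate pool")
  if (batch_size < 1) stop("batch_size must be >= 1")
  labels <- as.character(labels)
  npca_for <- function(p) {
    if (!is.null(n_pca)) min(n_pca, p, nrow(tab) - 1)
    else min(50, p, nrow(tab) - 1)
  }

  full_fit <- fit_dapc(tab[, pool, drop = FALSE], labels,
                       n_pca = npca_for(length(pool)), ...)
  ranking <- rank_loci(full_fit)

  eval_panel <- function(loci) {
    fit <- fit_dapc(tab[, loci, drop = FALSE], labels,
                    n_pca = npca_for(length(loci)), ...)
    pred <- predict(fit, tab[, loci, drop = FALSE])
    separation_criterion(pred$posterior, pred$assign, labels, target, tau)
  }

  selected <- ranking[seq_len(min(batch_size, length(ranking)))]
  remaining <- setdiff(ranking, selected)
  discarded <- character(0)
  state <- eval_panel(selected)
  log <- data.frame(round = 1L, action = "seed", n_selected = length(selected),
                    metric = state$metric, separated = state$separated)
  round <- 1L
  while (!state$separated && round < max_rounds && length(remaining) > 0) {
    round <- round + 1L
    batch <- remaining[seq_len(min(batch_size, length(remaining)))]
    remaining <- setdiff(remaining, batch)
    cand_state <- eval_panel(c(selected, batch))
    useful <- cand_state$separated || cand_state$metric >= state$metric + eps
    if (useful) {
      selected <- c(selected, batch)
      state <- cand_state
      action <- "retain"
    } else {
      discarded <- c(discarded, batch)
      action <- "discard"
    }
    log <- rbind(log, data.frame(round = round, action = action,
                                 n_selected = length(selected),
                                 metric = state$metric,
                                 separated = state$separated))
  }
  structure(list(selected = selected, separated = state$separated,
                 metric = state$metric, log = log, target = target,
                 discarded = discarded), class = "snp_selection")
}

#' @export
print.snp_selection <- function(x, ...) {
  cat(sprintf("snp_selection for '%s': %d loci, metric %.3f (%sseparated, %d rounds)\n",
              x$target, length(x$selected), x$metric,
              if (x$separated) "" else "NOT ", max(x$log$round)))
  invisible(x)
}

#' Diagnostic SNP sets for every group, and their union panel
#'
#' Runs [iterative_select()] once per group, in the given order (broad,
#' well-separated groups first mirrors the intended workflow), and returns
#' the per-group diagnostic sets together with their union — the combined
#' diagnostic panel.
#'
#' @param x genotypes
#' @param labels group labels
#' @param order group processing order (default: sorted unique labels)
#' @param ... passed to [iterative_select()]
#' @return list with `per_group` (named list of `snp_selection`) and
#'   `panel` (character union of selected loci)
#' @export
select_all_groups <- function(x, labels, order = NULL, ...) {
  labels <- as.character(labels)
  if (is.null(order)) order <- sort(unique(labels))
  if (!setequal(order, unique(labels))) stop("order must cover all groups")
  per_group <- lapply(order, function(g) iterative_select(x, labels, g, ...))
  names(per_group) <- order
  list(per_group = per_group,
       panel = sort(unique(unlist(lapply(per_group, `[[`, "selected")))))
}
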