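#' Ward hierarchical agglomerative clustering of genotypes
#'
#' Bottom-up minimum-variance clustering: every sample starts as its own
#' cluster and the pair whose merge least increases the total within-cluster
#' sum of squares is joined at each step, using Lance-Williams updates on
#' squared Euclidean distances.  Missing genotypes are locus-mean filled
#' first.  Merge heights equal twice the increase in within-cluster sum of
#' squares (for two singletons this is their squared Euclidean distance),
#' and are non-decreasing along the agenda.
#'
#' Ties are broken deterministically: among equal-cost pairs the
#' lexicographically smallest pair wins, where a cluster is indexed by the
#' smallest original sample index it contains.
#'
#' @param x a [genotype_matrix()] or numeric matrix
#' @return object of class `ward_dendro` with `merge` and `height` in
#'   `stats::hclust` convention, `labels`, and `order` (leaf permutation
#'   for plotting); convert with [as.hclust()] for `cutree`, plotting or
#'   [export_newick()]
#' @export
ward_cluster <- function(x) {
  tab <- if (inherits(x, "geno_matrix")) mean_fill(x) else as.matrix(x)
  n <- nrow(tab)
  if (n < 2) stop("need at least two samples")
  D <- as.matrix(stats::dist(tab))^2
  if (any(!is.finite(D))) stop("non-finite distances")
  # slot i always holds the cluster whose smallest member index is i
  active <- rep(TRUE, n)
  size <- rep(1, n)
  code <- -seq_len(n)              # hclust codes: negative leaf, positive merge
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(D) <- Inf
  D[lower.tri(D)] <- Inf           # keep only i < j entries
  for (step in seq_len(n - 1L)) {
    m <- min(D[active, active, drop = FALSE])
    hit <- which(D == m, arr.ind = TRUE)
    hit <- hit[active[hit[, 1]] & active[hit[, 2]], , drop = FALSE]
    pick <- hit[order(hit[, 1], hit[, 2])[1], ]
    i <- pick[1]; j <- pick[2]     # i < j by construction
    height[step] <- m
    merge[step, ] <- c(code[i], code[j])
    # Lance-Williams update for the Ward criterion
    others <- which(active); others <- others[others != i & others != j]
    for (k in others) {
      dik <- D[min(i, k), max(i, k)]
      djk <- D[min(j, k), max(j, k)]
      dnew <- ((size[i] + size[k]) * dik + (size[j] + size[k]) * djk -
                 size[k] * m) / (size[i] + size[j] + size[k])
      D[min(i, k), max(i, k)] <- dnew
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    code[i] <- step
  }
  labels <- rownames(tab)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  ord_of <- function(node) {
    if (node < 0) return(-node)
    c(ord_of(merge[node, 1]), ord_of(merge[node, 2]))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 order = ord_of(n - 1L), n = n),
            class = "ward_dendro")
}

#' @export
print.ward_dendro <- function(x, ...) {
  cat(sprintf("ward_dendro: %d samples, root height %.3f\n",
              x$n, max(x$height)))
  invisible(x)
}

#' @export
as.hclust.ward_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "ward",
                 dist.method = "squared euclidean",
                 call = match.call()), class = "hclust")
}

#' Member sample sets of every merge node
#' @param dendro a `ward_dendro`
#' @return list (length n-1) of character vectors of sample labels
#' @export
dendro_members <- function(dendro) {
  members <- vector("list", nrow(dendro$merge))
  for (k in seq_len(nrow(dendro$merge))) {
    pick <- function(code) {
      if (code < 0) dendro$labels[-code] else members[[code]]
    }
    members[[k]] <- c(pick(dendro$merge[k, 1]), pick(dendro$merge[k, 2]))
  }
  members
}

#' Cut a dendrogram into flat clusters
#' @param dendro a `ward_dendro`
#' @param k number of clusters, or
#' @param h height to cut at
#' @return named integer vector of cluster memberships
#' @export
cut_dendrogram <- function(dendro, k = NULL, h = NULL) {
  if (!is.null(h) && h < 0) stop("height must be non-negative")
  if (!is.null(k) && (k < 1 || k > dendro$n)) stop("k out of range")
  stats::cutree(stats::as.hclust(dendro), k = k, h = h)
}

#' Export a dendrogram as Newick with branch lengths
#' @param dendro a `ward_dendro`
#' @param path output file
#' @return `path`, invisibly
#' @export
export_newick <- function(dendro, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(dendro)), file = path)
  invisible(path)
}

#' Per-locus genotype-state proportions within a node
#'
#' For each locus, the fraction of the node's members (over non-missing
#' calls) carrying genotype 0, 1 and 2 — the profile displayed under
#' dendrogram nodes to show how a cluster's genotype composition shifts.
#'
#' @param gm a [genotype_matrix()]
#' @param members sample ids of the node
#' @return 3 x loci matrix with rows `"0"`, `"1"`, `"2"`; columns sum to 1
#'   except all-missing loci, which are NA and listed in the `"undefined"`
#'   attribute
#' @export
node_genotype_profile <- function(gm, members) {
  if (length(members) == 0) stop("member set is empty")
  tab <- gm$tab[members, , drop = FALSE]
  prof <- vapply(seq_len(ncol(tab)), function(j) {
    v <- tab[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(v == 0), mean(v == 1), mean(v == 2))
  }, numeric(3))
  dimnames(prof) <- list(c("0", "1", "2"), colnames(tab))
  attr(prof, "undefined") <- colnames(tab)[colSums(is.na(prof)) > 0]
  prof
}

## ---- topology ------------------------------------------------------------

#' Construct a classifier-cascade topology node
#'
#' A topology is a rooted tree supplied as config: internal nodes partition
#' their terminal labels among their children; terminal nodes carry one
#' population label, or two for double-assignation terminals that get a
#' secondary (Tier II) resolver between the two confounded groups.
#'
#' @param id node id (e.g. `"A_1"`, `"B_1_1"`)
#' @param children list of child `kbn_node`s (internal node), or NULL
#' @param labels terminal label(s): length 1, or 2 for a double-assignation
#'   terminal
#' @return a `kbn_node` list
#' @export
kbn_node <- function(id, children = NULL, labels = NULL) {
  if (is.null(children) && is.null(labels))
    stop(sprintf("node '%s' needs children or terminal labels", id))
  if (!is.null(children)) {
    if (length(children) < 2)
      stop(sprintf("internal node '%s' needs at least 2 children", id))
    if (!is.null(labels)) stop("a node is either internal or terminal")
  } else if (!length(labels) %in% 1:2) {
    stop("terminal nodes carry 1 label, or 2 for double-assignation")
  }
  structure(list(id = id, children = children, labels = labels),
            class = "kbn_node")
}

# all terminal labels under a node
node_labels <- function(node) {
  if (is.null(node$children)) return(node$labels)
  unlist(lapply(node$children, node_labels), use.names = FALSE)
}

# flat list of all nodes (preorder)
flatten_topology <- function(node) {
  c(list(node), if (!is.null(node$children))
    unlist(lapply(node$children, flatten_topology), recursive = FALSE))
}

validate_topology <- function(node) {
  nodes <- flatten_topology(node)
  ids <- vapply(nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate node ids in topology")
  labs <- node_labels(node)
  if (anyDuplicated(labs)) stop("a terminal label appears under two terminals")
  invisible(node)
}

#' Derive a cascade topology from a dendrogram of group centroids
#'
#' Builds a binary topology following the merge structure of a Ward
#' dendrogram whose leaves are groups (e.g. clustered group centroids).
#' Node ids encode level and path (`"A_1"`, `"B_1_2"`, ...), mirroring the
#' level-A..E naming of tiered cascades; leaves become single-label
#' terminals.  Intended as a proposal the user can inspect and edit —
#' hand-curated topologies are supplied through [kbn_node()] directly.
#'
#' @param dendro a `ward_dendro` whose labels are group names
#' @return a `kbn_node` topology
#' @export
topology_from_dendrogram <- function(dendro) {
  build <- function(code, level, path) {
    id <- if (length(path) == 0) "root"
          else paste(c(LETTERS[level], path), collapse = "_")
    if (code < 0) return(kbn_node(id, labels = dendro$labels[-code]))
    kids <- lapply(1:2, function(side) {
      build(dendro$merge[code, side], level + 1L, c(path, side))
    })
    kbn_node(id, children = kids)
  }
  # children of the root sit at level A; the root itself is unlettered
  root_code <- nrow(dendro$merge)
  kids <- lapply(1:2, function(side) {
    build(dendro$merge[root_code, side], 1L, side)
  })
  validate_topology(kbn_node("root", children = kids))
}

#' Default honey-bee cascade topology (reconstruction)
#'
#' A skeleton of the tiered honey-bee classifier: the root splits into an
#' African line (`A_1`) and a Europe/Asia line (`A_2`); double-assignation
#' terminals pair *A. m. scutellata*/*A. m. capensis* (`B_1_1`),
#' Madagascar/Seychelles (`C_1_2_1`) and Malta/Tunisia (`D_1_2_2_2`), each
#' resolved by a secondary classifier.  This is a faithful skeleton of the
#' published network's named nodes, not the full reference tree — users
#' with their own reference panel should derive a topology from
#' [ward_cluster()] via [topology_from_dendrogram()] or write one by hand.
#'
#' @return a `kbn_node` topology over the honey-bee terminal vocabulary
#' @export
default_bee_topology <- function() {
  validate_topology(kbn_node("root", children = list(
    kbn_node("A_1", children = list(                        # Africa line
      kbn_node("B_1_1", labels = c("A_m_scutellata", "A_m_capensis")),
      kbn_node("B_1_2", children = list(
        kbn_node("C_1_2_1", labels = c("Madagascar", "Seychelles")),
        kbn_node("C_1_2_2", children = list(
          kbn_node("D_1_2_2_1", children = list(
            kbn_node("E_1_2_2_1_1", labels = "Puerto_Rico"),
            kbn_node("E_1_2_2_1_2", labels = "America_Africanized"))),
          kbn_node("D_1_2_2_2", labels = c("Malta", "Tunisia")))))))),
    kbn_node("A_2", children = list(                        # Europe/Asia line
      kbn_node("B_2_1", children = list(
        kbn_node("C_2_1_1", labels = "EU_lig_like"),
        kbn_node("C_2_1_2", labels = "A_m_iberiensis"))),
      kbn_node("B_2_2", children = list(
        kbn_node("C_2_2_1", labels = "Georgia_Turkey"),
        kbn_node("C_2_2_2", labels = "Turkey"))))))))
}

## ---- knowledge-base network ----------------------------------------------

#' Build the knowledge-base network of per-node classifiers
#'
#' For every internal node of the topology a DAPC is fitted on that node's
#' reference samples with one class per child branch; the number of
#' retained PCs is chosen by cross-validation ([xval_select_npca()], 90/10
#' stratified splits by default).  Double-assignation terminals get a
#' secondary (Tier II) DAPC over just their two confounded groups.
#'
#' @param gm reference genotypes (matrix or [genotype_matrix()])
#' @param labels terminal population label per reference sample; every
#'   label must appear in the topology
#' @param topology a `kbn_node` tree (see [kbn_node()],
#'   [topology_from_dendrogram()])
#' @param xval_grid candidate `n_pca` values per node (default
#'   `c(5, 10, 20, 40)` capped at the node's rank)
#' @param xval_reps cross-validation replicates per node (default 5)
#' @param training_fraction training share of each 90/10-style split
#' @param min_group_size smallest allowed class size at a node (default 3)
#' @param seed base seed; each node derives its own split seed from it
#' @param ... passed to [fit_dapc()] (e.g. `scale`, `priors`)
#' @return object of class `kbn`: `topology`, `models` (per internal node),
#'   `tier2` (per double terminal), `loci` (panel), `chosen_npca`, `seed`
#' @export
build_kbn <- function(gm, labels, topology, xval_grid = c(5, 10, 20, 40),
                      xval_reps = 5, training_fraction = 0.9,
                      min_group_size = 3, seed = 1, ...) {
  tab <- if (inherits(gm, "geno_matrix")) mean_fill(gm) else as.matrix(gm)
  labels <- as.character(labels)
  validate_topology(topology)
  vocab <- node_labels(topology)
  unknown <- setdiff(unique(labels), vocab)
  if (length(unknown) > 0)
    stop(sprintf("label(s) not in topology: %s", paste(unknown, collapse = ", ")))
  sizes <- table(factor(labels, levels = vocab))
  if (any(sizes < min_group_size))
    stop(sprintf("group '%s' has %d < min_group_size = %d reference samples",
                 names(sizes)[sizes < min_group_size][1],
                 min(sizes), min_group_size))

  nodes <- flatten_topology(topology)
  models <- list()
  tier2 <- list()
  chosen <- list()
  node_seed <- 0L
  for (node in nodes) {
    node_seed <- node_seed + 1L
    if (is.null(node$children)) {
      if (length(node$labels) == 2) {     # Tier II resolver
        members <- labels %in% node$labels
        fit <- xval_fit(tab[members, , drop = FALSE], labels[members],
                        xval_grid, xval_reps, training_fraction,
                        seed + 1000L + node_seed, ...)
        tier2[[node$id]] <- fit$model
        chosen[[paste0(node$id, ":tier2")]] <- fit$chosen
      }
      next
    }
    child_of <- stats::setNames(
      rep(vapply(node$children, `[[`, character(1), "id"),
          vapply(node$children, function(ch) length(node_labels(ch)), 1L)),
      unlist(lapply(node$children, node_labels)))
    members <- labels %in% names(child_of)
    classes <- child_of[labels[members]]
    fit <- xval_fit(tab[members, , drop = FALSE], classes,
                    xval_grid, xval_reps, training_fraction,
                    seed + node_seed, ...)
    models[[node$id]] <- fit$model
    chosen[[node$id]] <- fit$chosen
  }
  structure(list(topology = topology, models = models, tier2 = tier2,
                 loci = colnames(tab), chosen_npca = chosen, seed = seed),
            class = "kbn")
}

# choose n_pca by cross-validation, then fit on all samples
xval_fit <- function(tab, classes, grid, reps, training_fraction, seed, ...) {
  grid <- unique(pmin(grid, min(nrow(tab) - 1, ncol(tab))))
  xv <- xval_select_npca(tab, classes, grid = grid, reps = reps,
                         training_fraction = training_fraction, seed = seed,
                         ...)
  list(model = fit_dapc(tab, classes, n_pca = xv$chosen, ...),
       chosen = xv$chosen)
}

#' @export
print.kbn <- function(x, ...) {
  cat(sprintf("kbn: %d internal node(s), %d secondary resolver(s), %d panel loci\n",
              length(x$models), length(x$tier2), length(x$loci)))
  cat("terminal labels:", paste(node_labels(x$topology), collapse = ", "), "\n")
  invisible(x)
}

#' Route unknown samples through the classifier cascade
#'
#' Each sample descends from the root: the node's DAPC posterior picks the
#' child branch with maximum posterior, until a terminal is reached;
#' samples landing on a double-assignation terminal are forwarded to its
#' secondary resolver for the single final label.  Missing panel loci
#' (absent columns or missing calls) are mean-filled from the *current
#' node's* reference subset at every step, so the fill adapts as the sample
#' moves into more specific reference groups.  Samples missing more than
#' `max_missing` panel loci are rejected, not labeled.
#'
#' @param kbn a fitted [build_kbn()] network
#' @param gm unknown genotypes; loci are matched by name and must be a
#'   subset of the panel
#' @param max_missing reject samples with more missing panel loci than this
#'   (default 96)
#' @param min_posterior optional abstention threshold: when the maximum
#'   posterior at any node falls below it the sample is left `"unassigned"`
#'   (default NULL, no abstention)
#' @return object of class `kbn_assignment`: `assignments` (data.frame:
#'   sample, final label, node path, minimum routing posterior, n_missing),
#'   `rejected` (data.frame), `details` (per-sample node posteriors)
#' @export
predict_kbn <- function(kbn, gm, max_missing = 96, min_posterior = NULL) {
  tab <- if (inherits(gm, "geno_matrix")) gm$tab else as.matrix(gm)
  extra <- setdiff(colnames(tab), kbn$loci)
  if (length(extra) > 0)
    stop(sprintf("unknown loci not in panel: %s%s",
                 paste(utils::head(extra, 3), collapse = ", "),
                 if (length(extra) > 3) ", ..." else ""))
  absent <- setdiff(kbn$loci, colnames(tab))
  n_missing <- rowSums(is.na(tab[, intersect(colnames(tab), kbn$loci),
                                 drop = FALSE])) + length(absent)
  reject <- n_missing > max_missing
  rejected <- data.frame(sample = rownames(tab)[reject],
                         n_missing = n_missing[reject], row.names = NULL)

  keep_idx <- which(!reject)
  assignments <- data.frame(sample = character(0), final = character(0),
                            path = character(0), min_posterior = numeric(0),
                            n_missing = integer(0))
  details <- list()
  by_id <- stats::setNames(flatten_topology(kbn$topology),
                           vapply(flatten_topology(kbn$topology), `[[`,
                                  character(1), "id"))
  for (s in keep_idx) {
    row <- tab[s, , drop = FALSE]
    node <- kbn$topology
    path <- node$id
    posts <- list()
    minp <- 1
    final <- NA_character_
    while (TRUE) {
      if (is.null(node$children)) {
        if (length(node$labels) == 1) {
          final <- node$labels
        } else {
          pred <- predict(kbn$tier2[[node$id]], row)
          posts[[paste0(node$id, ":tier2")]] <- pred$posterior[1, ]
          minp <- min(minp, max(pred$posterior[1, ]))
          final <- pred$assign[1]
        }
        break
      }
      pred <- predict(kbn$models[[node$id]], row)
      posts[[node$id]] <- pred$posterior[1, ]
      pmax_node <- max(pred$posterior[1, ])
      minp <- min(minp, pmax_node)
      if (!is.null(min_posterior) && pmax_node < min_posterior) {
        final <- "unassigned"
        break
      }
      node <- by_id[[pred$assign[1]]]
      path <- c(path, node$id)
    }
    assignments <- rbind(assignments, data.frame(
      sample = rownames(tab)[s], final = final,
      path = paste(path, collapse = ">"), min_posterior = minp,
      n_missing = n_missing[s]))
    details[[rownames(tab)[s]]] <- posts
  }
  structure(list(assignments = assignments, rejected = rejected,
                 details = details), class = "kbn_assignment")
}

#' @export
print.kbn_assignment <- function(x, ...) {
  cat(sprintf("kbn_assignment: %d sample(s) assigned, %d rejected\n",
              nrow(x$assignments), nrow(x$rejected)))
  if (nrow(x$assignments) > 0)
    print(utils::head(x$assignments, 10), row.names = FALSE)
  invisible(x)
}

#' Serialize a knowledge-base network to a directory
#'
#' Writes the topology as JSON plus one JSON model file per node, so a
#' network can be rebuilt elsewhere and produce identical routing.
#'
#' @param kbn a `kbn`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_kbn <- function(kbn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo_json <- function(node) {
    list(id = node$id, labels = node$labels,
         children = if (!is.null(node$children))
           lapply(node$children, topo_json))
  }
  jsonlite::write_json(list(format = "snpcascade-kbn", version = 1L,
                            topology = topo_json(kbn$topology),
                            loci = kbn$loci, seed = kbn$seed),
                       file.path(dir, "topology.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  for (id in names(kbn$models))
    write_dapc(kbn$models[[id]], file.path(dir, paste0("node_", id, ".json")))
  for (id in names(kbn$tier2))
    write_dapc(kbn$tier2[[id]], file.path(dir, paste0("tier2_", id, ".json")))
  invisible(dir)
}

#' Read a knowledge-base network written by [write_kbn()]
#' @param dir directory holding `topology.json` and node model files
#' @return a `kbn`
#' @export
read_kbn <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "topology.json"),
                              simplifyVector = FALSE)
  if (!identical(meta$format, "snpcascade-kbn")) stop("not a KBN directory")
  rebuild <- function(n) {
    kbn_node(n$id,
             children = if (!is.null(n$children) && length(n$children) > 0)
               lapply(n$children, rebuild),
             labels = if (!is.null(n$labels)) unlist(n$labels))
  }
  topo <- rebuild(meta$topology)
  nodes <- flatten_topology(topo)
  models <- list(); tier2 <- list()
  for (node in nodes) {
    mf <- file.path(dir, paste0("node_", node$id, ".json"))
    if (file.exists(mf)) models[[node$id]] <- read_dapc(mf)
    tf <- file.path(dir, paste0("tier2_", node$id, ".json"))
    if (file.exists(tf)) tier2[[node$id]] <- read_dapc(tf)
  }
  structure(list(topology = topo, models = models, tier2 = tier2,
                 loci = unlist(meta$loci), chosen_npca = NULL,
                 seed = meta$seed), class = "kbn")
}
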