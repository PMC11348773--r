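# Independent oracles used to cross-check the package implementations.
# These deliberately recompute everything from first principles rather than
# sharing code with the package.

# Brute-force Ward agglomeration: recompute the merge cost of every active
# pair from the raw cluster means at each step (no Lance-Williams updates).
# Cost = 2 * increase in within-cluster sum of squares
#      = 2 * |A||B| / (|A| + |B|) * ||mean_A - mean_B||^2.
# Tie-break: smallest (min member index of A, min member index of B).
# Returns the merge sequence as a list of (sorted pair of min member
# indices) and the merge heights.
brute_force_ward <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  pairs <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        A <- clusters[[a]]; B <- clusters[[b]]
        mu_a <- colMeans(x[A, , drop = FALSE])
        mu_b <- colMeans(x[B, , drop = FALSE])
        cost <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          sum((mu_a - mu_b)^2)
        key <- sort(c(min(A), min(B)))
        better <- cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(a, b); best_cost <- cost; best_key <- key
        }
      }
    }
    pairs[[length(pairs) + 1]] <- best_key
    heights <- c(heights, best_cost)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  list(pairs = pairs, heights = heights)
}

# Merge sequence of a ward_dendro in the oracle's representation:
# the pair of smallest member indices of the two clusters joined per step.
ward_merge_pairs <- function(dendro) {
  members <- vector("list", nrow(dendro$merge))
  pairs <- vector("list", nrow(dendro$merge))
  idx_of <- function(code) {
    if (code < 0) -code else members[[code]]
  }
  for (k in seq_len(nrow(dendro$merge))) {
    left <- idx_of(dendro$merge[k, 1])
    right <- idx_of(dendro$merge[k, 2])
    pairs[[k]] <- sort(c(min(left), min(right)))
    members[[k]] <- c(left, right)
  }
  pairs
}

# Weir & Cockerham (1984) multi-locus FST ("theta") from 0/1/2 genotypes.
wc_fst <- function(tab, labels) {
  labels <- as.character(labels)
  pops <- unique(labels)
  r <- length(pops)
  num <- den <- 0
  for (j in seq_len(ncol(tab))) {
    g <- tab[, j]
    keep <- !is.na(g)
    gj <- g[keep]; lj <- labels[keep]
    n_i <- as.numeric(table(factor(lj, levels = pops)))
    if (any(n_i == 0)) next
    p_i <- vapply(pops, function(p) mean(gj[lj == p]) / 2, numeric(1))
    h_i <- vapply(pops, function(p) mean(gj[lj == p] == 1), numeric(1))
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Per-locus WC FST, for ranking oracles.
wc_fst_per_locus <- function(tab, labels) {
  vapply(seq_len(ncol(tab)), function(j)
    wc_fst(tab[, j, drop = FALSE], labels), numeric(1))
}

# Write a small VCF from a data.frame of site fields (+ optional GT matrix).
write_toy_vcf <- function(path, sites, gt = NULL, sample_names = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"x\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) cols <- c(cols, "FORMAT", sample_names)
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    info_keys <- setdiff(names(sites), c("chrom", "pos", "ref", "alt", "qual"))
    info_keys <- info_keys[!is.na(unlist(s[info_keys]))]
    info <- if (length(info_keys) == 0) "." else
      paste(sprintf("%s=%s", info_keys, unlist(s[info_keys])), collapse = ";")
    line <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                  if (is.na(s$qual)) "." else s$qual, ".", info, sep = "\t")
    if (!is.null(gt))
      line <- paste(c(line, "GT", gt[i, ]), collapse = "\t")
    line
  }, character(1))
  writeLines(c(hdr, paste(cols, collapse = "\t"), rows), path)
  path
}

# Deterministic per-test seeds kept below 2^31.
test_seed <- function(k) 20260900L + as.integer(k)
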