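#' Simulate structured genotypes under the Balding-Nichols F-model
#'
#' Draws an ancestral allele frequency `p ~ Uniform(freq_range)` per locus,
#' then a population-specific frequency
#' `q ~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` per population (at `F = 0`
#' the population frequency equals the ancestral one), and genotypes
#' `~ Binomial(2, q)`.  `F` is the fixation index FST: the expected variance
#' of population frequencies around the ancestral frequency is
#' `F p (1 - p)`.  Loci are independent (no linkage), which matches panels
#' of widely spaced diagnostic SNPs.
#'
#' Admixed samples can be appended through `admixture`: each row defines one
#' sample by its mixing proportions over the populations; its per-locus
#' allele frequency is the proportion-weighted mean of the population
#' frequencies.  Missing genotypes are inserted completely at random at
#' `missing_rate`.
#'
#' @param n_pop number of populations
#' @param n_per_pop samples per population (scalar or vector of length
#'   `n_pop`)
#' @param n_loci number of independent SNP loci
#' @param fst differentiation parameter `F` in `[0, 1)`
#' @param freq_range bounds of the uniform ancestral-frequency distribution
#' @param admixture optional matrix (admixed samples x `n_pop`) of mixing
#'   proportions, rows summing to 1; admixed samples are labeled
#'   `"admixed"`
#' @param missing_rate fraction of cells set to missing, in `[0, 1)`
#' @param seed integer seed; fixes the full output
#' @param pop_names population labels (default `"pop1"..."popK"`)
#' @return list with `geno` (a [genotype_matrix()]), `labels` (character,
#'   one per sample), `ancestral_freq` (length `n_loci`) and `pop_freq`
#'   (`n_pop` x `n_loci`)
#' @export
simulate_populations <- function(n_pop, n_per_pop, n_loci, fst,
                                 freq_range = c(0.05, 0.95),
                                 admixture = NULL, missing_rate = 0,
                                 seed = NULL, pop_names = NULL) {
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pop)
  stopifnot(length(n_per_pop) == n_pop)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pop))

  p <- stats::runif(n_loci, freq_range[1], freq_range[2])
  if (fst == 0) {
    q <- matrix(p, n_pop, n_loci, byrow = TRUE)
  } else {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    q <- matrix(stats::rbeta(n_pop * n_loci, rep(a, each = n_pop),
                             rep(b, each = n_pop)), n_pop, n_loci)
  }
  rownames(q) <- pop_names

  labels <- rep(pop_names, n_per_pop)
  n <- length(labels)
  freq_rows <- q[labels, , drop = FALSE]
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (ncol(admixture) != n_pop) stop("admixture needs one column per population")
    if (any(abs(rowSums(admixture) - 1) > 1e-8)) stop("admixture rows must sum to 1")
    freq_rows <- rbind(freq_rows, admixture %*% q)
    labels <- c(labels, rep("admixed", nrow(admixture)))
    n <- length(labels)
  }
  geno <- matrix(stats::rbinom(n * n_loci, 2, freq_rows), n, n_loci)
  dimnames(geno) <- list(sprintf("s%03d", seq_len(n)),
                         sprintf("L%04d", seq_len(n_loci)))
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA
  }
  list(geno = genotype_matrix(geno), labels = labels,
       ancestral_freq = p, pop_freq = q)
}

#' Simulate an admixture cline between two parental populations
#'
#' Generates hybrids whose ancestry proportion `q` runs along `q_grid`
#' between population 1 (`q = 0`) and population 2 (`q = 1`): each hybrid's
#' per-locus allele frequency is `(1 - q) q1 + q q2`.  This emulates the
#' trailing pattern that admixed samples form between parental clusters in
#' a PCA: the expected PC1 score is linear, hence monotone, in `q`.
#'
#' @param n_loci number of loci
#' @param fst differentiation between the two parental populations
#' @param q_grid ancestry proportions in `[0, 1]`, one hybrid per entry
#' @param n_parental parental samples per population (default 30)
#' @param freq_range,missing_rate,seed as in [simulate_populations()]
#' @return list with `geno`, `labels` (`"pop1"`, `"pop2"` or `"hybrid"`),
#'   `q` (ancestry proportion per sample: 0 / 1 for parentals) and
#'   `pop_freq`
#' @export
simulate_hybrid_cline <- function(n_loci, fst, q_grid, n_parental = 30,
                                  freq_range = c(0.05, 0.95),
                                  missing_rate = 0, seed = NULL) {
  if (any(q_grid < 0 | q_grid > 1)) stop("q_grid values must be in [0, 1]")
  adm <- cbind(1 - q_grid, q_grid)
  sim <- simulate_populations(2, n_parental, n_loci, fst,
                              freq_range = freq_range, admixture = adm,
                              missing_rate = missing_rate, seed = seed)
  q <- c(rep(0, n_parental), rep(1, n_parental), q_grid)
  labels <- sim$labels
  labels[labels == "admixed"] <- "hybrid"
  list(geno = sim$geno, labels = labels, q = q, pop_freq = sim$pop_freq)
}

#' Plant diagnostic loci on an undifferentiated background
#'
#' Convenience generator for panel-selection experiments: most loci are
#' drawn at a background differentiation `fst_background` while
#' `n_diagnostic` randomly placed loci are drawn at `fst_diagnostic`,
#' making them the truly informative markers.  Because an ancestry
#' informative marker is by definition divergent, the planted loci are
#' additionally required to show a realized between-population allele
#' frequency range of at least `min_divergence` (rejection sampling of the
#' population frequencies); a high-F draw can otherwise fix the same allele
#' in every population, leaving a "diagnostic" locus with no signal.
#' Ground truth is returned.
#'
#' @param n_pop,n_per_pop,n_loci,seed as in [simulate_populations()]
#' @param n_diagnostic number of planted high-differentiation loci
#' @param fst_diagnostic,fst_background differentiation of the two classes
#' @param min_divergence minimum realized frequency range (max - min over
#'   populations) of each planted locus (default 0.4)
#' @return list with `geno`, `labels`, `diagnostic_loci` (character ids of
#'   the planted loci)
#' @export
simulate_planted_panel <- function(n_pop, n_per_pop, n_loci, n_diagnostic,
                                   fst_diagnostic = 0.5,
                                   fst_background = 0.01,
                                   min_divergence = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bg <- simulate_populations(n_pop, n_per_pop, n_loci - n_diagnostic,
                             fst_background)
  # per-locus rejection sampling of the diagnostic population frequencies
  a_of <- function(p) p * (1 - fst_diagnostic) / fst_diagnostic
  q_diag <- matrix(NA_real_, n_pop, n_diagnostic)
  for (j in seq_len(n_diagnostic)) {
    repeat {
      p <- stats::runif(1, 0.05, 0.95)
      q <- stats::rbeta(n_pop, a_of(p), a_of(1 - p))
      if (max(q) - min(q) >= min_divergence) break
    }
    q_diag[, j] <- q
  }
  if (length(n_per_pop) == 1) n_per_pop <- rep(n_per_pop, n_pop)
  pop_idx <- rep(seq_len(n_pop), n_per_pop)
  dg_tab <- matrix(stats::rbinom(length(pop_idx) * n_diagnostic, 2,
                                 q_diag[pop_idx, , drop = FALSE]),
                   length(pop_idx), n_diagnostic)
  tab <- cbind(bg$geno$tab, dg_tab)
  perm <- sample(n_loci)           # shuffle locus order
  tab <- tab[, perm, drop = FALSE]
  ids <- sprintf("L%04d", seq_len(n_loci))
  diag_ids <- ids[perm > n_loci - n_diagnostic]
  colnames(tab) <- ids
  list(geno = genotype_matrix(tab), labels = bg$labels,
       diagnostic_loci = sort(diag_ids))
}
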