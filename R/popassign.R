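#' Per-population alternate-allele frequencies with pseudocount
#'
#' For each population and locus the alternate-allele frequency is
#' estimated as `(alt count + pseudocount) / (2 n + 2 pseudocount)` over
#' the non-missing genotypes.  The default pseudocount of 0.5 keeps
#' frequencies strictly inside (0, 1) so fixed loci cannot produce
#' infinite log-likelihoods during assignment.
#'
#' @param gm reference genotypes (matrix or [genotype_matrix()])
#' @param labels population label per sample
#' @param pseudocount added allele count (default 0.5)
#' @return object of class `pop_freqs`: `freq` (populations x loci),
#'   `n` (non-missing sample count per population x locus), `pseudocount`
#' @export
estimate_frequencies <- function(gm, labels, pseudocount = 0.5) {
  tab <- if (inherits(gm, "geno_matrix")) gm$tab else as.matrix(gm)
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  if (any(table(labels) < 1)) stop("empty population")
  freq <- matrix(NA_real_, length(pops), ncol(tab),
                 dimnames = list(pops, colnames(tab)))
  nobs <- freq
  for (p in pops) {
    sub <- tab[labels == p, , drop = FALSE]
    n <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    freq[p, ] <- (alt + pseudocount) / (2 * n + 2 * pseudocount)
    nobs[p, ] <- n
  }
  structure(list(freq = freq, n = nobs, pseudocount = pseudocount),
            class = "pop_freqs")
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat(sprintf("pop_freqs: %d populations x %d loci (pseudocount %.2f)\n",
              nrow(x$freq), ncol(x$freq), x$pseudocount))
  invisible(x)
}

#' Assign a sample to the closest reference population
#'
#' Scores one sample against every reference population and ranks them.
#' `method = "loglik"` sums, over the sample's non-missing loci, the log
#' probability of its genotype under Hardy-Weinberg proportions at the
#' population's allele frequencies (higher is better).  `method =
#' "distance"` computes the Euclidean distance between the sample's allele
#' dosage / 2 and the population frequency vector (smaller is better, the
#' "smallest genetic distance" criterion).  Missing loci are skipped; ties
#' break lexicographically on the population label and are flagged
#' ambiguous.
#'
#' @param freqs a [estimate_frequencies()] result
#' @param sample named numeric vector (or 1-row matrix) of 0/1/2 genotypes
#' @param method `"loglik"` or `"distance"`
#' @return list with `ranking` (data.frame population/score, best first),
#'   `winner`, `ambiguous` (TRUE when the top two scores tie)
#' @export
assign_sample <- function(freqs, sample, method = c("loglik", "distance")) {
  method <- match.arg(method)
  if (is.matrix(sample)) sample <- sample[1, ]
  shared <- intersect(names(sample)[!is.na(sample)], colnames(freqs$freq))
  if (length(shared) == 0) stop("no shared non-missing loci with the reference")
  g <- sample[shared]
  f <- freqs$freq[, shared, drop = FALSE]
  if (method == "loglik") {
    # HWE genotype probabilities: (1-p)^2, 2p(1-p), p^2
    logp <- log(1 - f) * 2
    logp[, g == 1] <- (log(2) + log(f) + log(1 - f))[, g == 1]
    logp[, g == 2] <- (2 * log(f))[, g == 2]
    score <- rowSums(logp)
    ord <- order(-score, rownames(f))
  } else {
    d2 <- rowSums(sweep(f, 2, g / 2)^2)
    score <- sqrt(d2)
    ord <- order(score, rownames(f))
  }
  ranking <- data.frame(population = rownames(f)[ord], score = score[ord],
                        row.names = NULL)
  ambiguous <- nrow(ranking) > 1 &&
    isTRUE(all.equal(ranking$score[1], ranking$score[2]))
  list(ranking = ranking, winner = ranking$population[1],
       ambiguous = ambiguous, method = method, n_loci = length(shared))
}

#' Assign every sample of a genotype matrix
#'
#' @param freqs a [estimate_frequencies()] result
#' @param gm genotypes of the unknowns
#' @param method see [assign_sample()]
#' @return data.frame: sample, winner, score of winner, runner-up,
#'   ambiguous flag, loci used
#' @export
assign_all <- function(freqs, gm, method = c("loglik", "distance")) {
  method <- match.arg(method)
  tab <- if (inherits(gm, "geno_matrix")) gm$tab else as.matrix(gm)
  res <- lapply(seq_len(nrow(tab)), function(i)
    assign_sample(freqs, tab[i, ], method = method))
  data.frame(sample = rownames(tab),
             winner = vapply(res, `[[`, character(1), "winner"),
             score = vapply(res, function(r) r$ranking$score[1], numeric(1)),
             runner_up = vapply(res, function(r)
               if (nrow(r$ranking) > 1) r$ranking$population[2] else NA_character_,
               character(1)),
             ambiguous = vapply(res, `[[`, logical(1), "ambiguous"),
             n_loci = vapply(res, `[[`, numeric(1), "n_loci"),
             row.names = NULL)
}

## ---- GenePop interchange format ------------------------------------------

#' Write genotypes in GenePop format
#'
#' GenePop is the classic text interchange format of population-assignment
#' software: a title line, one locus name per line, then one `Pop` section
#' per population with lines `sample ,  0101 0102 ...` using two-digit
#' allele codes.  Dosage 0 maps to `0101`, 1 to `0102`, 2 to `0202` and
#' missing to `0000`.
#'
#' @param gm a [genotype_matrix()]
#' @param labels population label per sample
#' @param path output file
#' @param title first line of the file
#' @return `path`, invisibly
#' @export
write_genepop <- function(gm, labels, path, title = "snpcascade genotypes") {
  tab <- gm$tab
  labels <- as.character(labels)
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(tab), con)
  for (p in unique(labels)) {
    writeLines("Pop", con)
    for (i in which(labels == p)) {
      cells <- code[as.character(tab[i, ])]
      cells[is.na(cells)] <- "0000"
      writeLines(paste0(rownames(tab)[i], " ,  ",
                        paste(cells, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GenePop file into a genotype matrix
#'
#' Accepts the two-digit biallelic dialect written by [write_genepop()]:
#' alleles `01` (reference) and `02` (alternate), `0000` missing.
#'
#' @param path GenePop file
#' @return list with `geno` (a [genotype_matrix()]) and `labels`
#'   (population index per sample, `"pop1"`, `"pop2"`, ... in file order)
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no Pop section found")
  loci_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  rows <- list(); labs <- character(0); ids <- character(0)
  pop_i <- 0L
  for (ln in lines[first_pop:length(lines)]) {
    if (toupper(trimws(ln)) == "POP") { pop_i <- pop_i + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop(sprintf("malformed GenePop line: '%s'", ln))
    id <- trimws(parts[1])
    cells <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(cells) != length(loci))
      stop(sprintf("sample '%s' has %d genotypes, expected %d",
                   id, length(cells), length(loci)))
    dosage <- vapply(cells, function(c4) {
      if (c4 == "0000" || c4 == "000000") return(NA_real_)
      a <- c(substr(c4, 1, nchar(c4) / 2),
             substr(c4, nchar(c4) / 2 + 1, nchar(c4)))
      sum(as.integer(a) == 2L)   # allele 02 = alternate
    }, numeric(1), USE.NAMES = FALSE)
    rows[[length(rows) + 1L]] <- dosage
    ids <- c(ids, id)
    labs <- c(labs, paste0("pop", pop_i))
  }
  tab <- do.call(rbind, rows)
  dimnames(tab) <- list(ids, loci)
  list(geno = genotype_matrix(tab), labels = labs)
}
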