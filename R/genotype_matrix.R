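#' Genotype matrix over the 0/1/2 allele-dosage encoding
#'
#' A `geno_matrix` holds diploid genotypes as allele dosages: 0 for the
#' homozygous reference state, 1 for heterozygotes, 2 for the homozygous
#' alternate state, and `NA` for missing calls.  Rows are samples, columns
#' are SNP loci; both carry unique identifiers.  Optional per-sample
#' metadata (country, region, free-text label) rides along.
#'
#' @param tab numeric matrix with values in \{0, 1, 2, NA\}; rownames are
#'   sample ids, colnames are locus ids.  A data.frame is coerced.
#' @param meta optional data.frame of per-sample metadata, one row per
#'   sample (matched by rowname or a `sample_id` column).
#' @return an object of class `geno_matrix` with elements `tab` (the
#'   integer-valued matrix) and `meta`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("l1", "l2"))))
#' dim(g)
#' @export
genotype_matrix <- function(tab, meta = NULL) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab)) stop("'tab' must be a matrix")
  storage.mode(tab) <- "double"
  if (is.null(rownames(tab))) rownames(tab) <- paste0("sample", seq_len(nrow(tab)))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("locus", seq_len(ncol(tab)))
  if (anyDuplicated(rownames(tab))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(tab))) stop("duplicate locus ids")
  bad <- !(is.na(tab) | tab == 0 | tab == 1 | tab == 2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal genotype value %s at sample '%s', locus '%s'",
                 format(tab[idx[1], idx[2]]),
                 rownames(tab)[idx[1]], colnames(tab)[idx[2]]))
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(tab)) stop("meta must have one row per sample")
    rownames(meta) <- rownames(tab)
  }
  structure(list(tab = tab, meta = meta), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$tab)

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$tab))
  cat(sprintf("geno_matrix: %d samples x %d loci (%d missing calls, %.1f%%)\n",
              nrow(x$tab), ncol(x$tab), nmiss,
              100 * nmiss / length(x$tab)))
  invisible(x)
}

#' Sample and locus identifiers
#' @param x a `geno_matrix`
#' @return character vector of ids
#' @export
sample_ids <- function(x) rownames(x$tab)

#' @rdname sample_ids
#' @export
locus_ids <- function(x) colnames(x$tab)

#' Subset a genotype matrix by samples and/or loci
#' @param x a `geno_matrix`
#' @param i,j sample / locus index (ids, logical or integer)
#' @param ... ignored
#' @param drop ignored; the result is always a `geno_matrix`
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$tab))
  if (missing(j)) j <- seq_len(ncol(x$tab))
  genotype_matrix(x$tab[i, j, drop = FALSE],
                  meta = if (!is.null(x$meta)) x$meta[i, , drop = FALSE])
}

#' Read a tabular 0/1/2 genotype file
#'
#' The expected dialect is a tab-delimited table whose header row lists the
#' locus ids, whose first column holds sample ids, and whose cells are 0, 1,
#' 2 or the missing token.
#'
#' @param path file to read
#' @param missing_token string representing a missing genotype (default "NA")
#' @param sep field separator (default tab)
#' @return a [genotype_matrix()]
#' @export
read_genotype_table <- function(path, missing_token = "NA", sep = "\t") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2) stop("genotype table needs a header and at least one sample row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  loci <- header[-1]
  ncell <- length(loci)
  rows <- fields[-1]
  widths <- lengths(rows)
  if (any(widths != ncell + 1)) {
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 which(widths != ncell + 1)[1] + 1, widths[widths != ncell + 1][1],
                 ncell + 1))
  }
  samples <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(samples)) stop("duplicate sample ids in table")
  if (anyDuplicated(loci)) stop("duplicate locus ids in table")
  cells <- t(vapply(rows, function(r) r[-1], character(ncell)))
  if (ncell == 1) cells <- matrix(cells, ncol = 1)
  vals <- matrix(NA_real_, nrow(cells), ncol(cells),
                 dimnames = list(samples, loci))
  is_miss <- cells == missing_token
  ok <- cells %in% c("0", "1", "2")
  if (any(!ok & !is_miss)) {
    idx <- which(!ok & !is_miss, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable cell '%s' at sample '%s', locus '%s'",
                 cells[idx[1], idx[2]], samples[idx[1]], loci[idx[2]]))
  }
  vals[ok] <- as.numeric(cells[ok])
  genotype_matrix(vals)
}

#' Write a genotype matrix in the tabular 0/1/2 dialect
#'
#' @param gm a `geno_matrix`
#' @param path output file
#' @param missing_token serialization of missing genotypes
#' @param sep field separator
#' @param header optional comment lines (written prefixed with `#`)
#' @return `path`, invisibly
#' @export
write_genotype_table <- function(gm, path, missing_token = "NA", sep = "\t",
                                 header = NULL) {
  tab <- gm$tab
  cells <- matrix(as.character(tab), nrow(tab), ncol(tab))
  cells[is.na(tab)] <- missing_token
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("sample", colnames(tab)), collapse = sep), con)
  writeLines(paste(rownames(tab),
                   apply(cells, 1, paste, collapse = sep), sep = sep), con)
  invisible(path)
}

#' Count missing genotypes per sample
#' @param gm a `geno_matrix`
#' @return integer vector, one count per sample
#' @export
missing_per_sample <- function(gm) rowSums(is.na(gm$tab))

#' Drop samples with excessive missing data
#'
#' A sample is dropped when its missing-genotype count exceeds
#' `max_missing_count` or its missing fraction exceeds `max_missing_frac`
#' (either threshold alone suffices).  Both cutoffs are inclusive-keep: a
#' sample exactly at the threshold is retained.
#'
#' @param gm a `geno_matrix`
#' @param max_missing_count drop when more than this many genotypes are
#'   missing (e.g. 96 on a 272-SNP panel)
#' @param max_missing_frac drop when more than this fraction is missing
#'   (e.g. 0.5)
#' @return list with `kept` (a `geno_matrix`) and `dropped` (data.frame of
#'   sample id, missing count, missing fraction)
#' @export
qc_samples <- function(gm, max_missing_count = NULL, max_missing_frac = NULL) {
  if (is.null(max_missing_count) && is.null(max_missing_frac))
    stop("supply at least one of max_missing_count / max_missing_frac")
  if (!is.null(max_missing_count) && max_missing_count < 0)
    stop("max_missing_count must be non-negative")
  if (!is.null(max_missing_frac) && max_missing_frac < 0)
    stop("max_missing_frac must be non-negative")
  n_miss <- missing_per_sample(gm)
  frac <- n_miss / ncol(gm$tab)
  drop <- rep(FALSE, length(n_miss))
  if (!is.null(max_missing_count)) drop <- drop | n_miss > max_missing_count
  if (!is.null(max_missing_frac)) drop <- drop | frac > max_missing_frac
  list(kept = gm[!drop, ],
       dropped = data.frame(sample = sample_ids(gm)[drop],
                            n_missing = n_miss[drop],
                            frac_missing = frac[drop],
                            row.names = NULL))
}

#' Drop monomorphic loci
#'
#' A locus is dropped when all its non-missing genotypes are identical
#' (including loci that are entirely missing), since such loci carry no
#' discriminating information.
#'
#' @param gm a `geno_matrix`
#' @return list with `kept` (a `geno_matrix`) and `dropped` (data.frame of
#'   locus id and the constant observed value, NA if all-missing)
#' @export
qc_loci <- function(gm) {
  n_distinct <- apply(gm$tab, 2, function(col) length(unique(col[!is.na(col)])))
  drop <- n_distinct < 2
  const_val <- apply(gm$tab, 2, function(col) {
    v <- unique(col[!is.na(col)])
    if (length(v) == 1) v else NA_real_
  })
  list(kept = gm[, !drop],
       dropped = data.frame(locus = locus_ids(gm)[drop],
                            constant_value = const_val[drop],
                            row.names = NULL))
}

#' Keep loci with variant-free flanking windows
#'
#' For assay-primer design a diagnostic SNP must not have another variant
#' within `window` bases up- or downstream.  A locus is kept iff no other
#' variant on the same chromosome lies at distance `<= window` (the window
#' is closed: a neighbour exactly at `window` bases excludes the locus).
#'
#' @param loci data.frame with columns `locus_id`, `chrom`, `pos` (1-based)
#' @param variants data.frame with columns `chrom`, `pos` listing all known
#'   variant positions; defaults to the loci themselves
#' @param window flank width in bases (default 32)
#' @return character vector of kept locus ids
#' @export
flank_filter <- function(loci, variants = loci, window = 32) {
  if (window < 0) stop("window must be non-negative")
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(loci)),
            all(c("chrom", "pos") %in% names(variants)))
  keep <- vapply(seq_len(nrow(loci)), function(i) {
    same <- variants$chrom == loci$chrom[i]
    d <- abs(variants$pos[same] - loci$pos[i])
    # a variant at the locus' own position is the locus itself, not a neighbour
    !any(d <= window & d > 0)
  }, logical(1))
  loci$locus_id[keep]
}

#' Column (locus) means over observed genotypes
#' @param tab numeric matrix possibly containing NA
#' @return numeric vector of per-column means (0 for all-missing columns)
#' @keywords internal
locus_means <- function(tab) {
  m <- colMeans(tab, na.rm = TRUE)
  m[is.nan(m)] <- 0
  m
}

#' Fill missing genotypes with locus means
#'
#' Simple mean imputation used ahead of discriminant analysis and Ward
#' clustering; for PCA-grade imputation see [svd_impute()].
#'
#' @param gm a `geno_matrix` or numeric matrix
#' @return numeric matrix with no missing values
#' @export
mean_fill <- function(gm) {
  tab <- if (inherits(gm, "geno_matrix")) gm$tab else gm
  if (!anyNA(tab)) return(tab)
  m <- locus_means(tab)
  idx <- which(is.na(tab), arr.ind = TRUE)
  tab[idx] <- m[idx[, 2]]
  tab
}
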