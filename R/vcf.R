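#' Convert VCF genotype calls to a 0/1/2 dosage matrix
#'
#' Diploid GT fields map by alternate-allele count: `0/0 -> 0`,
#' `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./.` (or any call containing `.`)
#' to missing.  Phased separators (`|`) are treated like `/`.  With
#' `diplotize = TRUE` haploid calls are doubled: `0 -> 0`, `1 -> 2`, so a
#' haploid callset can be merged with diploid references.
#'
#' @param vcf_path path to a VCF (v4.x, plain text or gzipped)
#' @param diplotize double haploid genotypes instead of erroring on them
#' @param multiallelic `"skip"` drops records with more than one ALT allele;
#'   `"error"` aborts on them
#' @return a [genotype_matrix()] with loci keyed `"chrom:pos"`
#' @export
vcf_to_genotypes <- function(vcf_path, diplotize = FALSE,
                             multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sprintf("%d multiallelic record(s); first at %s:%s",
                   sum(multi), fix[multi, "CHROM"][1], fix[multi, "POS"][1]))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in VCF")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF record without GT in FORMAT")
  gt <- vcfR::extract.gt(v, element = "GT")
  keys <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  out <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), keys))
  for (i in seq_len(nrow(gt))) {
    out[, i] <- vapply(gt[i, ], gt_to_dosage, numeric(1),
                       diplotize = diplotize, USE.NAMES = FALSE)
  }
  genotype_matrix(out)
}

# single GT string -> dosage in {0,1,2,NA}
gt_to_dosage <- function(g, diplotize = FALSE) {
  if (is.na(g) || g == ".") return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a) || any(a > 1)) stop(sprintf("non-biallelic GT '%s'", g))
  if (length(a) == 1) {
    if (!diplotize)
      stop(sprintf("haploid GT '%s'; set diplotize = TRUE to double it", g))
    return(2 * a)
  }
  if (length(a) != 2) stop(sprintf("GT '%s' has ploidy %d", g, length(a)))
  sum(a)
}

#' Read variant records with hard-filter annotations from a VCF
#'
#' Extracts the site-level fields used by [hard_filter_variants()]: QUAL and
#' the INFO annotations QD, MQ, MQRankSum, ReadPosRankSum, FS and SOR.
#'
#' @param vcf_path path to a VCF
#' @return data.frame with one row per record: `chrom`, `pos`, `ref`, `alt`,
#'   `qual` and one numeric column per annotation (NA when absent)
#' @export
read_variant_records <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ann <- vapply(c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "FS", "SOR"),
                function(key) {
                  x <- suppressWarnings(
                    as.numeric(vcfR::extract.info(v, element = key)))
                  if (length(x) == 0) rep(NA_real_, nrow(fix)) else x
                }, numeric(nrow(fix)))
  if (nrow(fix) == 1) ann <- matrix(ann, nrow = 1, dimnames = list(NULL, colnames(ann)))
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
             ann, row.names = NULL)
}

#' Default hard-filter thresholds
#'
#' Site-level thresholds for flagging likely false-positive variant calls:
#' QUAL < 30 (Phred; retains calls with false-positive probability below
#' 0.001), QD < 2.0, MQ < 4.0, MQRankSum < -12.4, ReadPosRankSum < -8.0,
#' FS > 60.0, SOR > 3.0.  Note the widely used GATK convention is MQ < 40
#' and MQRankSum < -12.5; pass adjusted values to
#' [hard_filter_variants()] to use it.
#'
#' @return named list of thresholds
#' @export
hard_filter_defaults <- function() {
  list(QUAL = 30, QD = 2.0, MQ = 4.0, MQRankSum = -12.4,
       ReadPosRankSum = -8.0, FS = 60.0, SOR = 3.0)
}

#' Hard-filter variant records on site annotations
#'
#' A record is rejected iff at least one rule fires; all comparisons are
#' strict, so a record sitting exactly on every threshold is kept.  QUAL,
#' QD, MQ, MQRankSum and ReadPosRankSum reject below their thresholds; FS
#' and SOR reject above.  In lenient mode (default) a missing annotation
#' simply cannot fire its rule; with `strict = TRUE` it is an error.
#'
#' @param records data.frame as returned by [read_variant_records()]
#' @param thresholds named list overriding [hard_filter_defaults()]
#' @param strict error when an annotation referenced by a rule is missing
#' @return list with `kept` (data.frame), `rejected` (data.frame with a
#'   `reasons` column listing fired rules, comma-separated)
#' @export
hard_filter_variants <- function(records, thresholds = hard_filter_defaults(),
                                 strict = FALSE) {
  thr <- utils::modifyList(hard_filter_defaults(), thresholds)
  low_rules <- c(QUAL = "qual", QD = "QD", MQ = "MQ",
                 MQRankSum = "MQRankSum", ReadPosRankSum = "ReadPosRankSum")
  high_rules <- c(FS = "FS", SOR = "SOR")
  fired <- matrix(FALSE, nrow(records), length(low_rules) + length(high_rules),
                  dimnames = list(NULL, c(names(low_rules), names(high_rules))))
  for (rule in names(low_rules)) {
    x <- records[[low_rules[[rule]]]]
    if (strict && anyNA(x))
      stop(sprintf("annotation %s missing in strict mode", rule))
    fired[, rule] <- !is.na(x) & x < thr[[rule]]
  }
  for (rule in names(high_rules)) {
    x <- records[[high_rules[[rule]]]]
    if (strict && anyNA(x))
      stop(sprintf("annotation %s missing in strict mode", rule))
    fired[, rule] <- !is.na(x) & x > thr[[rule]]
  }
  reject <- rowSums(fired) > 0
  rejected <- records[reject, , drop = FALSE]
  rejected$reasons <- apply(fired[reject, , drop = FALSE], 1,
                            function(f) paste(colnames(fired)[f], collapse = ","))
  list(kept = records[!reject, , drop = FALSE], rejected = rejected)
}
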