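#' Read a VCF into a flat variant-record table
#'
#' Thin wrapper around [vcfR::read.vcfR()] that flattens the first sample's
#' `GT:AD:DP` fields into one row per record. Alternate alleles stay
#' comma-separated in `alts` with matching allele depths in `ad` (reference
#' depth first).
#'
#' @param path VCF file (plain or bgzipped).
#' @return data.frame with columns `contig`, `pos`, `ref`, `alts`, `dp`,
#'   `ad`, `gt`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1]))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  gt <- vcfR::extract.gt(v, "GT")[, 1]
  data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alts = fix[, "ALT"], dp = dp,
             ad = unname(ad), gt = unname(gt), stringsAsFactors = FALSE)
}

# split "12,3,0" depth strings into integer lists
split_ad <- function(ad) lapply(strsplit(ad, ",", fixed = TRUE), as.integer)

#' Apply the study's variant site filters
#'
#' A record survives iff its read depth is at least `min_dp` and at least one
#' alternate allele is supported by at least `min_af` of the reads
#' (`AD_alt / DP`, boundary inclusive: exactly 10% survives the default).
#' Alternate alleles individually below `min_af` are dropped from surviving
#' records (their `AD` entries with them). Records with missing `DP` or `AD`
#' are rejected and counted in the `n_missing` attribute with one warning.
#'
#' @param records data.frame from [read_vcf_records()].
#' @param min_dp minimum read depth (default 8).
#' @param min_af minimum per-alternate allele fraction (default 0.10).
#' @return filtered data.frame with an added logical `multiallelic` column
#'   (TRUE when the original record carried several alternates, even if
#'   pruning left one); attributes `n_missing` (records dropped for missing
#'   fields) and `n_input`.
#' @export
filter_variants <- function(records, min_dp = 8, min_af = 0.10) {
  stopifnot(is.data.frame(records))
  n_input <- nrow(records)
  missing <- is.na(records$dp) | is.na(records$ad) | records$ad == "."
  if (any(missing))
    warning(sprintf("%d record(s) missing DP/AD rejected", sum(missing)))
  rec <- records[!missing, , drop = FALSE]
  keep <- logical(nrow(rec))
  alts_out <- ad_out <- character(nrow(rec))
  ads <- split_ad(rec$ad)
  alts <- strsplit(rec$alts, ",", fixed = TRUE)
  for (i in seq_len(nrow(rec))) {
    dp <- rec$dp[i]
    if (dp < min_dp) next
    a <- ads[[i]]
    alt_frac <- a[-1] / dp
    ok <- alt_frac >= min_af
    if (!any(ok)) next
    keep[i] <- TRUE
    alts_out[i] <- paste(alts[[i]][ok], collapse = ",")
    ad_out[i] <- paste(a[c(TRUE, ok)], collapse = ",")
  }
  multi <- lengths(alts) > 1
  out <- rec[keep, , drop = FALSE]
  out$alts <- alts_out[keep]
  out$ad <- ad_out[keep]
  if (!"multiallelic" %in% names(out)) out$multiallelic <- multi[keep]
  rownames(out) <- NULL
  attr(out, "n_missing") <- sum(missing)
  attr(out, "n_input") <- n_input
  out
}

#' Classify a ref/alt allele pair
#'
#' SNP when both alleles are single bases; insertion/deletion by length
#' difference; equal multi-base lengths are multi-nucleotide substitutions
#' (`MNP`, downstream counted as one SNP per differing base). Symbolic
#' alleles (`<DEL>`, `*`, breakends) return `NA` with a warning.
#'
#' @param ref,alt character vectors of alleles (recycled to common length).
#' @return character vector: `"SNP"`, `"insertion"`, `"deletion"`, `"MNP"`
#'   or `NA` for symbolic alleles.
#' @export
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  symbolic <- grepl("[<>*]|\\[|\\]", alt) | grepl("[<>*]|\\[|\\]", ref)
  if (any(symbolic)) warning(sprintf("%d symbolic allele(s) rejected", sum(symbolic)))
  out <- ifelse(nchar(alt) > nchar(ref), "insertion",
         ifelse(nchar(alt) < nchar(ref), "deletion",
         ifelse(nchar(ref) == 1, "SNP", "MNP")))
  out[symbolic] <- NA_character_
  out
}

#' Extract allele-balance observations for ploidy estimation
#'
#' Keeps biallelic SNP records with heterozygous evidence (both the
#' reference and the alternate allele observed) and computes the alternate
#' fraction `y = AD_alt / (AD_ref + AD_alt)`, which lies strictly in (0,1).
#' Multiallelic records are skipped and counted in the `n_multiallelic`
#' attribute.
#'
#' @param records filtered data.frame from [filter_variants()].
#' @return data.frame with `contig`, `pos`, `depth`, `y`; attribute
#'   `n_multiallelic`.
#' @export
extract_allele_balance <- function(records) {
  multi <- grepl(",", records$alts, fixed = TRUE)
  if ("multiallelic" %in% names(records))
    multi <- multi | records$multiallelic
  rec <- records[!multi, , drop = FALSE]
  is_snp <- nchar(rec$ref) == 1 & nchar(rec$alts) == 1
  rec <- rec[is_snp, , drop = FALSE]
  ads <- split_ad(rec$ad)
  ad_ref <- vapply(ads, `[`, integer(1), 1)
  ad_alt <- vapply(ads, `[`, integer(1), 2)
  het <- ad_ref > 0 & ad_alt > 0
  out <- data.frame(contig = rec$contig[het], pos = rec$pos[het],
                    depth = (ad_ref + ad_alt)[het],
                    y = (ad_alt / (ad_ref + ad_alt))[het],
                    stringsAsFactors = FALSE)
  attr(out, "n_multiallelic") <- sum(multi)
  out
}
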