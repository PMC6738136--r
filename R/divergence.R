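## Allele-aware gene divergence. Two strains' copies of a gene are compared
## column by column on an alignment of their reference sequences; at each
## column every strain offers a set of possible symbols (its reference base
## plus any alternative alleles called there, gaps included for indel
## alleles), and a mutation is recorded only where the two sets are
## disjoint -- i.e. no allelic variation could induce a match.

#' Bundle a gene's reference sequence with its called variants
#'
#' @param seq gene reference sequence (character scalar).
#' @param variants data.frame of variants in gene-local coordinates:
#'   columns `pos` (1-based anchor), `ref`, `alt` (VCF conventions: indels
#'   share their first base with the reference anchor). May be empty or
#'   NULL.
#' @return object of class `allele_set` with pre-expanded per-position
#'   allele information.
#' @export
allele_set <- function(seq, variants = NULL) {
  L <- nchar(seq)
  snp <- list()      # pos -> extra bases
  del_cover <- integer(0) # deletable positions
  ins <- list()      # anchor pos -> inserted strings
  if (!is.null(variants) && nrow(variants) > 0) {
    stopifnot(all(c("pos", "ref", "alt") %in% names(variants)))
    for (i in seq_len(nrow(variants))) {
      p <- variants$pos[i]
      r <- variants$ref[i]; a <- variants$alt[i]
      if (p < 1 || p > L) next
      nr <- nchar(r); na <- nchar(a)
      if (nr == 1 && na == 1) {
        snp[[as.character(p)]] <- union(snp[[as.character(p)]], a)
      } else if (na > nr) { # insertion after anchor
        key <- as.character(p + nr - 1)
        ins[[key]] <- union(ins[[key]], substr(a, nr + 1, na))
      } else if (nr > na) { # deletion of anchor+1 .. anchor+(nr-na)
        del_cover <- union(del_cover, (p + na):(p + nr - 1))
      } else { # MNP: treat as per-base SNPs
        for (k in seq_len(nr)) {
          rb <- substr(r, k, k); ab <- substr(a, k, k)
          if (rb != ab)
            snp[[as.character(p + k - 1)]] <-
              union(snp[[as.character(p + k - 1)]], ab)
        }
      }
    }
  }
  structure(list(seq = seq, length = L, snp = snp,
                 del_cover = del_cover, ins = ins),
            class = "allele_set")
}

# symbol set offered by one strain at an alignment column
column_symbols <- function(aset, char, pos, gap_anchor, gap_offset) {
  if (char != "-") {
    syms <- char
    extra <- aset$snp[[as.character(pos)]]
    if (!is.null(extra)) syms <- c(syms, extra)
    if (pos %in% aset$del_cover) syms <- c(syms, "-")
    return(syms)
  }
  syms <- "-"
  strs <- aset$ins[[as.character(gap_anchor)]]
  if (!is.null(strs)) {
    for (s in strs)
      if (gap_offset >= 1 && gap_offset <= nchar(s))
        syms <- c(syms, substr(s, gap_offset, gap_offset))
  }
  unique(syms)
}

#' Allele-aware pairwise comparison of one gene between two strains
#'
#' Aligns the two reference sequences globally (match +1, mismatch -1, gap
#' opening 2, extension 0.5) unless aligned strings are supplied, then
#' counts the columns at which the two strains' symbol sets are disjoint.
#' The mutation rate divides that count by the alignment length; a gene
#' pair is identical iff it has zero mutations.
#'
#' @param a,b `allele_set` objects for the two strains.
#' @param aligned optional character vector of length 2 with pre-aligned
#'   (gapped) sequences of `a` and `b`.
#' @return list (class `gene_comparison`): `mutations`, `aligned_length`,
#'   `rate`, `identical`, and the column indices of the mutations.
#' @export
compare_gene_pair <- function(a, b, aligned = NULL) {
  stopifnot(inherits(a, "allele_set"), inherits(b, "allele_set"))
  if (is.null(aligned)) {
    aln <- Biostrings::pairwiseAlignment(
      a$seq, b$seq, type = "global", substitutionMatrix = sd_submat(),
      gapOpening = 2, gapExtension = 0.5)
    aligned <- c(as.character(Biostrings::alignedPattern(aln)),
                 as.character(Biostrings::alignedSubject(aln)))
  }
  ca <- strsplit(aligned[1], "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned[2], "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  ## gap bookkeeping: anchor = preceding reference position, offset within run
  gap_off_a <- seq_along(ca) - match(pos_a, pos_a) # 0 at first col of a run
  gap_off_b <- seq_along(cb) - match(pos_b, pos_b)
  candidates <- which(ca != cb | ca == "-" | cb == "-")
  muts <- integer(0)
  for (cc in candidates) {
    sa <- column_symbols(a, ca[cc], pos_a[cc], pos_a[cc], gap_off_a[cc])
    sb <- column_symbols(b, cb[cc], pos_b[cc], pos_b[cc], gap_off_b[cc])
    if (length(intersect(sa, sb)) == 0) muts <- c(muts, cc)
  }
  structure(list(mutations = length(muts), aligned_length = length(ca),
                 rate = length(muts) / length(ca),
                 identical = length(muts) == 0, mutation_columns = muts),
            class = "gene_comparison")
}

#' Per-gene variant profiles
#'
#' Assigns filtered variants to genes by their anchor position (a variant
#' belongs to a gene iff `pos - 1` lies in the 0-based half-open gene
#' interval; variants in overlapping genes count in each) and tallies
#' SNP/insertion/deletion occurrences and per-bp rates. Multi-nucleotide
#' substitutions contribute one SNP per differing base; each alternate
#' allele of a multiallelic record counts separately.
#'
#' @param genes data.frame with `id`, `contig`, `start`, `end` (0-based
#'   half-open) and optionally `category`.
#' @param variants filtered data.frame from [filter_variants()].
#' @return data.frame per gene: counts `n_snp`, `n_ins`, `n_del`, length
#'   and rates, plus the gene's category (or `"unannotated"`).
#' @export
profile_gene_variants <- function(genes, variants) {
  stopifnot(all(c("id", "contig", "start", "end") %in% names(genes)))
  if (!"category" %in% names(genes)) genes$category <- "unannotated"
  n_snp <- n_ins <- n_del <- integer(nrow(genes))
  if (nrow(variants) > 0) {
    alts <- strsplit(variants$alts, ",", fixed = TRUE)
    vl <- data.frame(
      contig = rep(variants$contig, lengths(alts)),
      pos = rep(variants$pos, lengths(alts)),
      ref = rep(variants$ref, lengths(alts)),
      alt = unlist(alts), stringsAsFactors = FALSE)
    vl$type <- suppressWarnings(classify_variant(vl$ref, vl$alt))
    vl <- vl[!is.na(vl$type), , drop = FALSE]
    mnp_units <- function(r, a) {
      sum(strsplit(r, "")[[1]] != strsplit(a, "")[[1]])
    }
    for (gi in seq_len(nrow(genes))) {
      hit <- vl$contig == genes$contig[gi] &
        (vl$pos - 1) >= genes$start[gi] & (vl$pos - 1) < genes$end[gi]
      if (!any(hit)) next
      vv <- vl[hit, , drop = FALSE]
      n_snp[gi] <- sum(vv$type == "SNP") +
        sum(vapply(which(vv$type == "MNP"), function(i)
          mnp_units(vv$ref[i], vv$alt[i]), integer(1)))
      n_ins[gi] <- sum(vv$type == "insertion")
      n_del[gi] <- sum(vv$type == "deletion")
    }
  }
  len <- genes$end - genes$start
  data.frame(id = genes$id, category = genes$category, length = len,
             n_snp = n_snp, n_ins = n_ins, n_del = n_del,
             snp_rate = n_snp / len, ins_rate = n_ins / len,
             del_rate = n_del / len, stringsAsFactors = FALSE)
}

#' Count identical genes per strain pair
#'
#' @param comparisons data.frame with columns `strain_a`, `strain_b`,
#'   `identical` (one row per compared family).
#' @return data.frame per unordered strain pair: `n_compared`,
#'   `n_identical`.
#' @export
count_identical <- function(comparisons) {
  if (nrow(comparisons) == 0)
    return(data.frame(strain_a = character(), strain_b = character(),
                      n_compared = integer(), n_identical = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(pmin(comparisons$strain_a, comparisons$strain_b),
               pmax(comparisons$strain_a, comparisons$strain_b), sep = "|")
  agg <- lapply(split(seq_len(nrow(comparisons)), key), function(ii) {
    data.frame(strain_a = pmin(comparisons$strain_a[ii[1]],
                               comparisons$strain_b[ii[1]]),
               strain_b = pmax(comparisons$strain_a[ii[1]],
                               comparisons$strain_b[ii[1]]),
               n_compared = length(ii),
               n_identical = sum(comparisons$identical[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
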