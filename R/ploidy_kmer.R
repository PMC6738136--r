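## Ploidy from heterozygous k-mer pairs ("smudge" analysis).
##
## A heterozygous SNP produces pairs of k-mers differing at one position; the
## pair's summed coverage is proportional to the genome copy number at the
## locus and the minor-variant fraction encodes the genotype: AB at (2n, 1/2),
## AAB at (3n, 1/3), AAAB at (4n, 1/4), AABB at (4n, 1/2), with n the
## per-copy (haploid) k-mer coverage.

# genotype grid for a given haploid coverage
smudge_grid <- function(nhat) {
  data.frame(genotype = c("AB", "AAB", "AAAB", "AABB"),
             ploidy = c(2L, 3L, 4L, 4L),
             total = nhat * c(2, 3, 4, 4),
             fraction = c(1 / 2, 1 / 3, 1 / 4, 1 / 2),
             stringsAsFactors = FALSE)
}

# standardized squared distances of pairs to every grid center.
# axes: log total coverage and minor fraction, each scaled by the sampling
# width the genotype predicts (Poisson for the total, binomial for the
# fraction), inflated by `dispersion` to allow real-data overdispersion.
smudge_distances <- function(total, fraction, nhat, dispersion = 1.25) {
  g <- smudge_grid(nhat)
  d <- vapply(seq_len(nrow(g)), function(i) {
    s_log <- dispersion / sqrt(g$total[i])
    s_frac <- dispersion *
      sqrt(g$fraction[i] * (1 - g$fraction[i]) / g$total[i])
    ((log(total) - log(g$total[i])) / s_log)^2 +
      ((fraction - g$fraction[i]) / s_frac)^2
  }, numeric(length(total)))
  if (length(total) == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- g$genotype
  d
}

#' Read a k-mer count table
#'
#' Two-column `kmer<TAB>count` TSV (header optional).
#'
#' @param path file path.
#' @return data.frame with `kmer`, `count`.
#' @export
read_kmer_counts <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("kmer", first, ignore.case = TRUE)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(df) <- c("kmer", "count")
  df$count <- as.integer(df$count)
  df
}

#' Count canonical k-mers of a set of sequences
#'
#' @param seqs character vector of DNA sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param k k-mer size (1-31).
#' @return data.frame with `kmer` (canonical) and `count`.
#' @export
count_kmers <- function(seqs, k = 21) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  .kmer_count_cpp(seqs, as.integer(k))
}

#' Find heterozygous k-mer pairs
#'
#' Buckets every canonical k-mer by its sequence with one position
#' wildcarded (strand-aware, at every position, both orientations
#' canonicalized) and emits one pair per bucket holding exactly two k-mers;
#' buckets with three or more members are repeat-ambiguous loci and yield
#' nothing. Pairs are deduplicated across positions and filtered by the
#' coverage floor (`covB >= ci`) and total ceiling (`covA + covB <= cs`).
#'
#' @param kmer_counts data.frame with `kmer` (all the same odd length) and
#'   `count`.
#' @param ci coverage floor on the minor member (default 1).
#' @param cs ceiling on the pair's total coverage (default 10000).
#' @return data.frame of class `kmer_pairs`: `kmerA`, `kmerB`, `covA >=
#'   covB`, `total`, `minor_fraction` in (0, 0.5].
#' @export
find_het_pairs <- function(kmer_counts, ci = 1, cs = 10000) {
  stopifnot(all(c("kmer", "count") %in% names(kmer_counts)))
  klen <- unique(nchar(kmer_counts$kmer))
  if (length(klen) != 1) sd_stop("mixed k-mer lengths in input")
  keep <- kmer_counts$count >= ci
  km <- kmer_counts$kmer[keep]
  ct <- kmer_counts$count[keep]
  idx <- .het_pairs_cpp(km, as.integer(klen))
  a <- idx$i; b <- idx$j
  covA <- pmax(ct[a], ct[b])
  covB <- pmin(ct[a], ct[b])
  swap <- ct[b] > ct[a]
  kmerA <- ifelse(swap, km[b], km[a])
  kmerB <- ifelse(swap, km[a], km[b])
  total <- covA + covB
  ok <- covB >= ci & total <= cs
  out <- data.frame(kmerA = kmerA[ok], kmerB = kmerB[ok],
                    covA = covA[ok], covB = covB[ok], total = total[ok],
                    minor_fraction = (covB / total)[ok],
                    stringsAsFactors = FALSE)
  class(out) <- c("kmer_pairs", "data.frame")
  out
}

# dominant peak of a numeric sample via kernel density
dominant_peak <- function(x) {
  if (length(x) < 2) return(x[1])
  d <- density(x, n = 512, from = max(min(x) - 1, 1))
  d$x[which.max(d$y)]
}

#' Estimate the haploid (per-copy) k-mer coverage from het pairs
#'
#' Candidate haploid coverages are derived from coverage peaks: the dominant
#' total-coverage peak of near-balanced pairs (minor fraction in \[0.4, 0.5\])
#' divided by 2, and the global dominant total peak divided by 2, 3 and 4.
#' Each candidate is scored by the likelihood of the pairs under the
#' genotype grid it implies, and the best-scoring candidate wins; ties go to
#' the larger candidate (the fewest-copies explanation, which resolves the
#' exact AB-versus-AABB grid degeneracy).
#'
#' @param pairs a `kmer_pairs` data.frame.
#' @param min_pairs minimum pairs required (default 100).
#' @return list with `nhat`, the scored `candidates` table, and the peaks
#'   used; below `min_pairs` an insufficient-data sentinel.
#' @export
estimate_haploid_coverage <- function(pairs, min_pairs = 100) {
  n <- nrow(pairs)
  if (n < min_pairs)
    return(insufficient_data("haploid coverage", n, min_pairs))
  t_global <- dominant_peak(pairs$total)
  cand <- t_global / c(2, 3, 4)
  win <- pairs$total[pairs$minor_fraction >= 0.4]
  if (length(win) >= max(20, 0.05 * n))
    cand <- c(dominant_peak(win) / 2, cand)
  cand <- cand[cand > 0]
  ## drop near-duplicates (within 2%)
  cand <- sort(unique(round(cand, 6)), decreasing = TRUE)
  dedup <- c(TRUE, abs(diff(cand)) / cand[-length(cand)] > 0.02)
  cand <- cand[dedup]
  ## classified-pair likelihood: every pair under its nearest grid center
  score <- vapply(cand, function(nh) {
    d <- smudge_distances(pairs$total, pairs$minor_fraction, nh)
    -mean(do.call(pmin, as.data.frame(d))) / 2
  }, numeric(1))
  ## scores are in squared-z/2 units: a grid that merely reinterprets the
  ## same smudges (AB as AABB at half the coverage) scores within ~0.2 of
  ## the truth (its surplus centers soak up tail pairs), while the nearest
  ## genuinely wrong grid is off by >= 0.4 -- so ties within `tie_tol` go
  ## to the larger candidate, the fewest-copies explanation
  tie_tol <- 0.3
  best <- max(score)
  pick <- which(score >= best - tie_tol)[1] # candidates sorted desc
  list(nhat = cand[pick],
       candidates = data.frame(nhat = cand, score = score),
       t_global = t_global)
}

#' Classify het k-mer pairs into genotypes and call ploidy
#'
#' Each pair is assigned the genotype (AB, AAB, AAAB, AABB) minimizing its
#' standardized squared distance in (log total coverage, minor fraction)
#' space to the genotype's expected center given the haploid coverage
#' `nhat`. Pairs whose two best genotype distances differ by less than 5%
#' are counted as unresolved and excluded from the modal vote. The ploidy
#' call is the copy number of the genotype with the most pairs.
#'
#' @param pairs a `kmer_pairs` data.frame.
#' @param nhat haploid k-mer coverage (e.g. from
#'   [estimate_haploid_coverage()]).
#' @return object of class `smudge_result`: genotype counts, unresolved
#'   count, `nhat`, the per-pair assignment, and the called ploidy.
#' @export
classify_pairs <- function(pairs, nhat) {
  stopifnot(is.numeric(nhat), nhat > 0)
  g <- smudge_grid(nhat)
  if (nrow(pairs) == 0)
    return(structure(list(nhat = nhat,
                          genotype_counts = setNames(integer(4), g$genotype),
                          n_unresolved = 0L, call = NA_integer_,
                          assignment = character(0), pairs = pairs),
                     class = "smudge_result"))
  d <- smudge_distances(pairs$total, pairs$minor_fraction, nhat)
  ord1 <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_len(nrow(d)), ord1)]
  d2 <- d
  d2[cbind(seq_len(nrow(d)), ord1)] <- Inf
  ord2 <- max.col(-d2, ties.method = "first")
  second <- d2[cbind(seq_len(nrow(d2)), ord2)]
  unresolved <- abs(second - best) < 0.05 * (best + second + 1e-12)
  assignment <- g$genotype[ord1]
  assignment[unresolved] <- "unresolved"
  counts <- setNames(vapply(g$genotype, function(gt)
    sum(assignment == gt), integer(1)), g$genotype)
  call <- if (sum(counts) == 0) NA_integer_ else
    g$ploidy[which.max(counts)]
  structure(list(nhat = nhat, genotype_counts = counts,
                 n_unresolved = sum(unresolved), call = call,
                 assignment = assignment, pairs = pairs),
            class = "smudge_result")
}

#' @export
print.smudge_result <- function(x, ...) {
  cat(sprintf("<smudge_result: nhat %.1f, call %s; %s; %d unresolved>\n",
              x$nhat,
              if (is.na(x$call)) "ambiguous" else x$call,
              paste(names(x$genotype_counts), x$genotype_counts,
                    sep = "=", collapse = " "),
              x$n_unresolved))
  invisible(x)
}

#' K-mer ploidy estimation end to end
#'
#' Pair discovery, haploid-coverage estimation and genotype classification
#' in one call.
#'
#' @param kmer_counts data.frame with `kmer`, `count` (or a path readable by
#'   [read_kmer_counts()]).
#' @param ci,cs coverage floor and ceiling for pair discovery.
#' @param min_pairs minimum pairs for coverage estimation.
#' @return a `smudge_result` (with the pair table and coverage candidates
#'   attached), or an insufficient-data sentinel.
#' @export
smudge_ploidy <- function(kmer_counts, ci = 1, cs = 10000, min_pairs = 100) {
  if (is.character(kmer_counts)) kmer_counts <- read_kmer_counts(kmer_counts)
  pairs <- find_het_pairs(kmer_counts, ci = ci, cs = cs)
  est <- estimate_haploid_coverage(pairs, min_pairs = min_pairs)
  if (is_insufficient(est)) return(est)
  res <- classify_pairs(pairs, est$nhat)
  res$coverage_candidates <- est$candidates
  res
}
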