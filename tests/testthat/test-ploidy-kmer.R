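test_that("the 2:1 coverage pair is genotype AAB with minor fraction 33%", {
  kc <- data.frame(kmer = c("ATGTC", "ATGTT"), count = c(40L, 20L))
  pr <- find_het_pairs(kc)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$covA, 40)
  expect_equal(pr$covB, 20)
  expect_equal(pr$total, 60)
  expect_equal(pr$minor_fraction, 1 / 3)
  res <- classify_pairs(pr, nhat = 20)
  expect_equal(unname(res$genotype_counts["AAB"]), 1L)
  expect_equal(res$call, 3L)
  expect_equal(round(100 * pr$minor_fraction), 33)
})

test_that("grid classification handles the exact centers", {
  pr_ab <- data.frame(kmerA = "AAAAA", kmerB = "AAAAC", covA = 20, covB = 20,
                      total = 40, minor_fraction = 0.5)
  class(pr_ab) <- c("kmer_pairs", "data.frame")
  expect_equal(classify_pairs(pr_ab, 20)$assignment, "AB")
  pr_4 <- data.frame(kmerA = "AAAAA", kmerB = "AAAAC", covA = 60, covB = 20,
                     total = 80, minor_fraction = 0.25)
  class(pr_4) <- c("kmer_pairs", "data.frame")
  expect_equal(classify_pairs(pr_4, 20)$assignment, "AAAB")
})

test_that("ambiguous buckets and lone k-mers yield no pairs", {
  tri <- data.frame(kmer = c("ATGTC", "ATGTT", "ATGTG"),
                    count = c(30L, 20L, 10L))
  expect_equal(nrow(find_het_pairs(tri)), 0) # three variants at one locus
  lone <- data.frame(kmer = "AAAAA", count = 50L)
  expect_equal(nrow(find_het_pairs(lone)), 0)
})

test_that("pair discovery is invariant under reverse-complementing inputs", {
  set.seed(201)
  anc <- make_ancestor(3e4, 10, c(800, 100), seed = 202)
  st <- derive_strain(anc, strain_spec("RC", 2, mean_coverage = 60, seed = 203))
  km <- simulate_kmer_counts(st, seed = 204)
  base <- find_het_pairs(km, ci = 4)
  flip <- sample(c(TRUE, FALSE), nrow(km), replace = TRUE)
  km2 <- km
  km2$kmer[flip] <- revcomp_str(km2$kmer[flip]) # mixed orientations in
  got <- find_het_pairs(km2, ci = 4)
  key <- function(p) {
    a <- pmin(p$kmerA, revcomp_str(p$kmerA))
    b <- pmin(p$kmerB, revcomp_str(p$kmerB))
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  expect_equal(key(got), key(base))
})

test_that("pair discovery equals the brute-force Hamming-1 scan", {
  set.seed(205)
  anc <- make_ancestor(1.5e4, 6, c(600, 100), seed = 206)
  st <- derive_strain(anc, strain_spec("BF", 3, mean_coverage = 60, seed = 207))
  km <- simulate_kmer_counts(st, k = 15, seed = 208)
  km <- km[seq_len(min(nrow(km), 3000)), ]
  fast <- find_het_pairs(km)
  slow <- oracle_het_pairs(km$kmer)
  key_fast <- sort(paste(pmin(fast$kmerA, fast$kmerB),
                         pmax(fast$kmerA, fast$kmerB)))
  key_slow <- sort(paste(pmin(km$kmer[slow$i], km$kmer[slow$j]),
                         pmax(km$kmer[slow$i], km$kmer[slow$j])))
  expect_gt(length(key_slow), 0)
  expect_equal(key_fast, key_slow)
})

test_that("haploid coverage is recovered from simulated smudges", {
  # diploid at per-copy coverage 25
  st2 <- quick_strain(2, seed = 211, length_bp = 3e5, n_genes = 180)
  km2 <- simulate_kmer_counts(st2, seed = 212)
  est2 <- estimate_haploid_coverage(find_het_pairs(km2))
  expect_gte(est2$nhat, 22)
  expect_lte(est2$nhat, 28)

  # triploid at per-copy coverage 20
  anc <- make_ancestor(3e5, 180, c(1200, 250), seed = 213)
  st3 <- derive_strain(anc, strain_spec("T", 3, mean_coverage = 60, seed = 214))
  km3 <- simulate_kmer_counts(st3, seed = 215)
  est3 <- estimate_haploid_coverage(find_het_pairs(km3))
  expect_gte(est3$nhat, 17)
  expect_lte(est3$nhat, 23)

  empty <- data.frame(kmerA = character(), kmerB = character(),
                      covA = integer(), covB = integer(), total = integer(),
                      minor_fraction = numeric())
  expect_true(is_insufficient(estimate_haploid_coverage(empty)))
})

test_that("a simulated tetraploid smudge calls ploidy 4", {
  st4 <- quick_strain(4, seed = 221, length_bp = 3e5, n_genes = 180)
  km4 <- simulate_kmer_counts(st4, seed = 222)
  res <- smudge_ploidy(km4)
  expect_equal(res$call, 4L)
  top <- names(which.max(res$genotype_counts))
  expect_true(top %in% c("AAAB", "AABB"))
})

test_that("mixed k-mer lengths are rejected", {
  bad <- data.frame(kmer = c("AAAAA", "AAAA"), count = c(1L, 1L))
  expect_error(find_het_pairs(bad), "mixed")
})
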