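test_that("ancestor genomes place non-overlapping genes deterministically", {
  anc <- make_ancestor(1e5, 20, c(1500, 300), seed = 1)
  g <- anc$genes[order(anc$genes$start), ]
  expect_equal(nrow(g), 20)
  expect_true(all(g$start >= 0 & g$end <= 1e5))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)])) # disjoint
  anc2 <- make_ancestor(1e5, 20, c(1500, 300), seed = 1)
  expect_identical(anc, anc2)

  tight <- make_ancestor(3000, 2, c(1000, 0), seed = 7)
  tg <- tight$genes[order(tight$genes$start), ]
  expect_equal(tg$end - tg$start, c(1000, 1000))
  expect_gte(tg$start[2], tg$end[1])

  expect_error(make_ancestor(5000, 10, c(1000, 0), seed = 1),
               "mean gene length")
})

test_that("strain derivation honours rates and records truth faithfully", {
  anc <- make_ancestor(5e4, 25, c(800, 150), seed = 3)
  zero <- strain_spec("Z", 2, het_rate = setNames(rep(0, 11),
                                                  sd_categories()$category),
                      seed = 9)
  st0 <- derive_strain(anc, zero)
  expect_equal(nrow(st0$variants), 0)
  haps <- strain_haplotypes(st0)
  expect_identical(haps[1], haps[2]) # both copies equal the mutated reference
  expect_identical(haps[1], st0$genome)

  st <- derive_strain(anc, strain_spec("S3", 3, mean_coverage = 50, seed = 5))
  expect_true(all(st$variants$j %in% 1:2))
  expect_true(all(st$variants$pos >= 1 & st$variants$pos <= st$length))
  # haplotype 1 never carries a het variant: genome chars match every ref
  refs1 <- substring(st$genome, st$variants$pos, st$variants$pos)
  expect_identical(refs1, substring(st$variants$ref, 1, 1))

  # truth counts equal emitted VCF het records per gene (no error sites)
  vc <- simulate_allele_depths(st, error_sites_fraction = 0, seed = 77)
  emitted <- table(factor(vc$family[!is.na(vc$family)],
                          levels = st$truth$family))
  expect_equal(as.integer(emitted),
               st$truth$n_snp + st$truth$n_ins + st$truth$n_del)
})

test_that("fragmentation emits short contigs and never splits genes", {
  anc <- make_ancestor(5e5, 120, c(1000, 200), seed = 11)
  st <- derive_strain(anc, strain_spec("F", 2, seed = 12))
  asm <- fragment_genome(st, n_contigs = 50, short_contig_fraction = 0.1)
  expect_equal(nrow(asm), 50)
  expect_equal(sum(asm$length), st$length)
  expect_equal(sum(asm$length < 500), 5)
  # genes land entirely inside single contigs
  ci <- findInterval(st$genes$start, asm$start)
  expect_true(all(st$genes$end <= asm$end[ci]))

  single <- fragment_genome(st, n_contigs = 1, short_contig_fraction = 0)
  expect_equal(nrow(single), 1)
  expect_equal(single$length, st$length)
})

test_that("written FASTA/GFF3 round-trip to the truth gene sequences", {
  dir <- withr::local_tempdir()
  anc <- make_ancestor(4e4, 15, c(800, 150), seed = 21)
  st <- derive_strain(anc, strain_spec("RT", 2, seed = 22))
  asm <- fragment_genome(st, n_contigs = 4, short_contig_fraction = 0)
  paths <- write_strain_data(st, asm, dir)
  ctg <- Biostrings::readDNAStringSet(paths["contigs"])
  gff <- rtracklayer::import(paths["gff"], format = "gff3")
  got <- vapply(seq_along(gff), function(i) {
    s <- as.character(ctg[[as.character(GenomicRanges::seqnames(gff)[i])]])
    sub <- substr(s, BiocGenerics::start(gff)[i], BiocGenerics::end(gff)[i])
    if (as.character(BiocGenerics::strand(gff)[i]) == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    else sub
  }, character(1))
  truth_seq <- as.character(Biostrings::readDNAStringSet(paths["genes"]))
  expect_equal(unname(got), unname(truth_seq[gff$ID]))
})

test_that("allele-depth simulation concentrates fractions at j/m", {
  anc <- make_ancestor(3e5, 100, c(1000, 200), seed = 31)
  st <- derive_strain(anc, strain_spec("T4", 4, mean_coverage = 80, seed = 32))
  vc <- simulate_allele_depths(st, overdispersion = 0,
                               error_sites_fraction = 0, seed = 33)
  y <- vc$ad_alt / vc$dp
  for (j in 1:3) {
    sel <- vc$j == j & vc$dp > 0
    expect_lt(abs(mean(y[sel]) - j / 4), 0.02)
  }
  # binomial consistency at Poisson depth: 99.9% CI on each site
  p <- vc$j / 4
  lo <- qbinom(5e-4, vc$dp, p)
  hi <- qbinom(1 - 5e-4, vc$dp, p)
  expect_gt(mean(vc$ad_alt >= lo & vc$ad_alt <= hi), 0.995)
})

test_that("k-mer count simulation is deterministic and reflects het pairs", {
  anc <- make_ancestor(2e4, 8, c(800, 100), seed = 41)
  st0 <- derive_strain(anc, strain_spec(
    "H0", 2, het_rate = setNames(rep(0, 11), sd_categories()$category),
    mean_coverage = 60, seed = 42))
  km0 <- simulate_kmer_counts(st0, seed = 43)
  expect_equal(nrow(find_het_pairs(km0, ci = 4)), 0) # homozygous: no pairs
  expect_lt(abs(median(km0$count) - 60), 6)

  km0b <- simulate_kmer_counts(st0, seed = 43)
  expect_identical(km0, km0b) # same seed, identical table

  st <- derive_strain(anc, strain_spec("H1", 2, mean_coverage = 60, seed = 44))
  expect_gt(nrow(st$variants), 0)
  km <- simulate_kmer_counts(st, seed = 45)
  pr <- find_het_pairs(km, ci = 4)
  expect_gt(nrow(pr), 0)
  # het smudge sits near (2 * 30, 1/2)
  expect_lt(abs(median(pr$total) - 60), 12)
  expect_gt(median(pr$minor_fraction), 0.3)
})

test_that("strain specs validate their invariants", {
  expect_error(strain_spec("X", 5), "ploidy")
  expect_error(strain_spec("X", 2, het_rate = c(unannotated = 0.5)), "rates")
  expect_error(strain_spec("X", 2, mean_coverage = 0), "mean_coverage")
})
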