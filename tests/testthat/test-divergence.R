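test_that("variant profiles count by anchor position inside half-open intervals", {
  genes <- data.frame(id = "g1", contig = "c", start = 100L, end = 1100L,
                      category = "unannotated", stringsAsFactors = FALSE)
  vars <- data.frame(contig = "c", pos = c(151L, 901L, 501L, 1101L),
                     ref = c("A", "C", "ATT", "G"),
                     alts = c("T", "G", "A", "A"),
                     dp = 30L, ad = "20,10", gt = "0/1",
                     stringsAsFactors = FALSE)
  pr <- profile_gene_variants(genes, vars)
  # SNPs at 151 and 901, one deletion at 501; pos 1101 is past the end
  expect_equal(pr$n_snp, 2L)
  expect_equal(pr$n_ins, 0L)
  expect_equal(pr$n_del, 1L)
  expect_equal(pr$snp_rate, 0.002)

  none <- profile_gene_variants(genes, vars[0, ])
  expect_equal(none$n_snp + none$n_ins + none$n_del, 0L)
})

test_that("an allelic variant can reconcile an inter-strain mismatch", {
  # the defining case: ref ACGT with alternative A at the mismatching
  # position versus ref ACGA reconciles to zero mutations
  a <- allele_set("ACGT", data.frame(pos = 4L, ref = "T", alt = "A"))
  b <- allele_set("ACGA")
  cmp <- compare_gene_pair(a, b, aligned = c("ACGT", "ACGA"))
  expect_equal(cmp$mutations, 0L)
  expect_true(cmp$identical)

  # no variants: a plain mismatch is one mutation
  cmp2 <- compare_gene_pair(allele_set("ACGT"), allele_set("ACGA"),
                            aligned = c("ACGT", "ACGA"))
  expect_equal(cmp2$mutations, 1L)
  expect_equal(cmp2$rate, 1 / 4)
  expect_false(cmp2$identical)

  # disjoint allele sets at a column remain a mutation
  a3 <- allele_set("AAGA", data.frame(pos = c(2L, 2L), ref = c("A", "A"),
                                      alt = c("T", "C")))
  b3 <- allele_set("AGGA", data.frame(pos = 2L, ref = "G", alt = "G"))
  cmp3 <- compare_gene_pair(a3, b3, aligned = c("AAGA", "AGGA"))
  expect_equal(cmp3$mutations, 1L)
})

test_that("comparison is symmetric and monotone in added alleles", {
  set.seed(401)
  for (rep in 1:25) {
    L <- sample(30:60, 1)
    sa <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    mk <- function(seq, n) {
      if (n == 0) return(NULL)
      pos <- sample(L, n)
      data.frame(pos = pos,
                 ref = substring(seq, pos, pos),
                 alt = sample(c("A", "C", "G", "T"), n, TRUE),
                 stringsAsFactors = FALSE)
    }
    va <- mk(sa, sample(0:4, 1))
    vb <- mk(sb, sample(0:4, 1))
    ab <- compare_gene_pair(allele_set(sa, va), allele_set(sb, vb),
                            aligned = c(sa, sb))
    ba <- compare_gene_pair(allele_set(sb, vb), allele_set(sa, va),
                            aligned = c(sb, sa))
    expect_equal(ab$mutations, ba$mutations)
    expect_equal(ab$identical, ba$identical)
    # adding an allele can only help
    extra_pos <- sample(L, 1)
    va2 <- rbind(va, data.frame(pos = extra_pos,
                                ref = substring(sa, extra_pos, extra_pos),
                                alt = substring(sb, extra_pos, extra_pos)))
    ab2 <- compare_gene_pair(allele_set(sa, va2), allele_set(sb, vb),
                             aligned = c(sa, sb))
    expect_lte(ab2$mutations, ab$mutations)
  }
})

test_that("mutation counting equals brute-force allele-assignment enumeration", {
  set.seed(402)
  for (rep in 1:60) {
    L <- sample(20:50, 1)
    sa <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    chars <- strsplit(sa, "", fixed = TRUE)[[1]]
    nmut <- sample(0:6, 1)
    mpos <- if (nmut > 0) sample(L, nmut) else integer(0)
    for (p in mpos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    sb <- paste(chars, collapse = "")
    mk <- function(seq, nmax) {
      n <- sample(0:nmax, 1)
      if (n == 0) return(NULL)
      pos <- sample(L, n)
      do.call(rbind, lapply(pos, function(p) data.frame(
        pos = p, ref = substring(seq, p, p),
        alt = sample(c("A", "C", "G", "T"),
                     sample(1:2, 1)), stringsAsFactors = FALSE)))
    }
    va <- mk(sa, 4)
    vb <- mk(sb, 4)
    fast <- compare_gene_pair(allele_set(sa, va), allele_set(sb, vb),
                              aligned = c(sa, sb))$mutations
    slow <- oracle_allele_mutations(sa, va, sb, vb)
    expect_equal(fast, slow)
  }
})

test_that("indel alleles participate through gap columns", {
  # b carries an extra G; a's insertion allele supplies it
  a <- allele_set("ACGT", data.frame(pos = 2L, ref = "C", alt = "CG"))
  b <- allele_set("ACGGT")
  cmp <- compare_gene_pair(a, b, aligned = c("AC-GT", "ACGGT"))
  expect_equal(cmp$mutations, 0L)
  # without the insertion allele the gap column is a mutation
  cmp2 <- compare_gene_pair(allele_set("ACGT"), b,
                            aligned = c("AC-GT", "ACGGT"))
  expect_equal(cmp2$mutations, 1L)
  # a deletion allele on the longer gene matches the gap from the other side
  b_del <- allele_set("ACGGT", data.frame(pos = 2L, ref = "CG", alt = "C"))
  cmp3 <- compare_gene_pair(allele_set("ACGT"), b_del,
                            aligned = c("AC-GT", "ACGGT"))
  expect_equal(cmp3$mutations, 0L)
})

test_that("identical-gene counting aggregates per strain pair", {
  cc <- data.frame(
    family = c("f1", "f2", "f1", "f3"),
    strain_a = c("A", "A", "A", "B"),
    strain_b = c("B", "B", "C", "C"),
    identical = c(TRUE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  ci <- count_identical(cc)
  expect_equal(ci$n_compared, c(2L, 1L, 1L))
  expect_equal(ci$n_identical, c(1L, 1L, 1L))
  expect_equal(nrow(count_identical(cc[0, ])), 0)
})
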