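set.seed(301)
rand_gene <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

test_that("clustering joins near-identical genes and separates fragments", {
  g <- rand_gene(1000)
  genes <- data.frame(id = c("a", "b"), strain = c("s1", "s2"),
                      seq = c(g, mutate_seq(g, 0.05)),
                      stringsAsFactors = FALSE)
  cl <- cluster_genes(genes)
  expect_equal(nrow(cl$representatives), 1)

  # a 700 bp fragment of a 1000 bp gene fails the 0.8 length-ratio screen
  frag <- data.frame(id = c("full", "frag"), strain = "s1",
                     seq = c(g, substr(g, 1, 700)), stringsAsFactors = FALSE)
  cl2 <- cluster_genes(frag)
  expect_equal(nrow(cl2$representatives), 2)

  # a reverse-complemented copy still joins its cluster
  rc <- data.frame(id = c("fwd", "rev"), strain = "s1",
                   seq = c(g, revcomp_str(g)), stringsAsFactors = FALSE)
  expect_equal(nrow(cluster_genes(rc)$representatives), 1)
})

test_that("unrelated genes stay singletons and clustering is order-stable", {
  set.seed(302)
  genes <- data.frame(id = sprintf("g%02d", 1:20), strain = "s1",
                      seq = vapply(rep(900, 20), rand_gene, character(1)),
                      stringsAsFactors = FALSE)
  cl <- cluster_genes(genes)
  expect_equal(nrow(cl$representatives), 20)
  perm <- genes[sample(nrow(genes)), ]
  cl2 <- cluster_genes(perm)
  expect_equal(nrow(cl2$representatives), 20) # same all-singleton partition
  expect_setequal(cl2$members$id, cl$members$id)
})

test_that("consensus follows column majority with ties to the representative", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  base <- rand_gene(60)
  v1 <- base
  substr(v1, 30, 30) <- if (substr(base, 30, 30) == "T") "A" else "T"
  # representative + one A...A member vs one T variant: majority keeps base
  expect_equal(consensus_sequence(c(base, base, v1)), base)
  # two members disagreeing at one column: representative's base wins
  expect_equal(consensus_sequence(c(base, v1)), base)
  # 2-vs-1 majority against the representative flips the column
  expect_equal(consensus_sequence(c(base, v1, v1)), v1)
})

test_that("placement recovers source intervals on both strands", {
  set.seed(303)
  genome <- rand_gene(20000)
  gene_fwd <- substr(genome, 2001, 3200)
  gene_rev <- revcomp_str(substr(genome, 9001, 10100))
  pl <- place_genes(c(f = gene_fwd, r = gene_rev, absent = rand_gene(1000)),
                    c(ctg = genome))
  expect_equal(sort(pl$gene), c("f", "r")) # absent gene not placed
  pf <- pl[pl$gene == "f", ]
  expect_equal(pf$strand, "+")
  expect_equal(pf$start, 2000)
  expect_equal(pf$end, 3200)
  expect_equal(pf$identity, 1)
  pr <- pl[pl$gene == "r", ]
  expect_equal(pr$strand, "-")
  expect_equal(pr$start, 9000)
  expect_equal(pr$end, 10100)

  # 5% scattered substitutions still place with identity ~0.95
  noisy <- mutate_seq(gene_fwd, 0.05)
  pn <- place_genes(c(n = noisy), c(ctg = genome))
  expect_equal(nrow(pn), 1)
  expect_gt(pn$identity, 0.9)
  expect_lt(pn$identity, 0.99)
})

test_that("locus merging uses the 10%-of-shorter overlap rule, same strand only", {
  pl <- data.frame(gene = c("a", "b"), contig = "c", strand = "+",
                   start = c(0L, 900L), end = c(1000L, 1900L),
                   identity = 1, score = 1, stringsAsFactors = FALSE)
  m <- merge_overlapping(pl) # overlap 100 = 10% of 1000: boundary merges
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 1900L)
  expect_equal(m$genes, "a,b")

  pl$strand <- c("+", "-") # opposite strands never merge
  expect_equal(nrow(merge_overlapping(pl)), 2)

  pl2 <- data.frame(gene = c("a", "b"), contig = "c", strand = "+",
                    start = c(0L, 950L), end = c(1000L, 1950L),
                    identity = 1, score = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(merge_overlapping(pl2)), 2) # 5% overlap: kept apart

  # idempotent and order-independent
  pl3 <- data.frame(gene = letters[1:4], contig = "c", strand = "+",
                    start = c(0L, 50L, 5000L, 960L),
                    end = c(1000L, 1050L, 6000L, 1960L),
                    identity = 1, score = 1, stringsAsFactors = FALSE)
  m3 <- merge_overlapping(pl3)
  m3r <- merge_overlapping(pl3[4:1, ])
  expect_equal(m3, m3r)
  again <- data.frame(gene = m3$locus, contig = m3$contig, strand = m3$strand,
                      start = m3$start, end = m3$end, identity = 1,
                      score = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(merge_overlapping(again)), nrow(m3))
})

test_that("families classify as core, shared and exclusive with a Venn identity", {
  loci <- list(
    g1 = data.frame(locus = "l1", contig = "c", strand = "+", start = 0,
                    end = 10, n_members = 2, genes = c("clA,clB", "clC"),
                    stringsAsFactors = FALSE),
    g2 = data.frame(locus = "l1", contig = "c", strand = "+", start = 0,
                    end = 10, n_members = 1, genes = c("clA", "clD"),
                    stringsAsFactors = FALSE),
    g3 = data.frame(locus = "l1", contig = "c", strand = "+", start = 0,
                    end = 10, n_members = 1, genes = "clA",
                    stringsAsFactors = FALSE))
  fam <- classify_shared(loci)
  # clA+clB fused into one family (co-located in g1), present everywhere
  ab <- fam$members[["clA"]]
  expect_equal(fam$members[["clB"]], ab)
  ft <- fam$families
  expect_equal(ft$class[ft$family == ab], "core")
  expect_equal(ft$class[ft$family == fam$members[["clC"]]], "exclusive")
  expect_equal(ft$class[ft$family == fam$members[["clD"]]], "exclusive")
  expect_equal(unname(fam$totals["total"]),
               unname(sum(fam$totals[c("core", "shared", "exclusive")])))
  expect_equal(sum(fam$venn$count), unname(fam$totals["total"]))
})

test_that("gene density divides by the over-500 bp assembly and truncates", {
  expect_equal(gene_density(17315, 49.4e6), 350L)
  expect_equal(gene_density(16915, 54.7e6), 309L)
  expect_equal(gene_density(19494, 52.8e6), 369L)
  expect_equal(gene_density(0, 1e6), 0L)
  # short contigs are excluded from the denominator
  expect_equal(gene_density(100, c(1e6, rep(400, 100))), 100L)
  expect_equal(gene_density(100, c(1e6, 500)), 100L) # 500 bp exactly: excluded
  expect_error(gene_density(10, c(100, 500)), "undefined")
})
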