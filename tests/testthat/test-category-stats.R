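test_that("module completeness follows the miss-at-most-one rule", {
  expect_true(module_complete(c("k1", "k2"), c("k1", "k2")))
  expect_false(module_complete(c("k1", "k2"), "k1"))
  expect_true(module_complete(paste0("k", 1:5), paste0("k", 1:4)))
  expect_false(module_complete(paste0("k", 1:5), paste0("k", 1:3)))
  expect_error(module_complete("k1", "k1"), "at least 2")
})

test_that("module completeness matches brute-force enumeration for sizes 2-6", {
  for (size in 2:6) {
    genes <- paste0("g", seq_len(size))
    masks <- expand.grid(rep(list(c(FALSE, TRUE)), size))
    for (r in seq_len(nrow(masks))) {
      mask <- unlist(masks[r, ])
      expect_identical(module_complete(genes, genes[mask]),
                       oracle_module_complete(size, mask),
                       info = sprintf("size %d mask %s", size,
                                      paste(as.integer(mask), collapse = "")))
    }
  }
})

test_that("modules_completeness summarizes a module table", {
  modules <- data.frame(module = c("M1", "M1", "M2", "M2", "M2"),
                        family = c("a", "b", "c", "d", "e"),
                        stringsAsFactors = FALSE)
  mc <- modules_completeness(modules, present = c("a", "b", "c", "d"))
  expect_equal(mc$complete[mc$module == "M1"], TRUE)
  expect_equal(mc$complete[mc$module == "M2"], TRUE) # 2 of 3 present
  mc2 <- modules_completeness(modules, present = c("a", "c"))
  expect_equal(mc2$complete, c(FALSE, FALSE))
})

sim_profiles <- function(rates_by_strain, n_genes, len = 1000,
                         category = "catX", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(rates_by_strain), function(s) {
    counts <- rpois(n_genes, rates_by_strain[[s]] * len)
    data.frame(gene = sprintf("%s_g%d", s, seq_len(n_genes)), strain = s,
               category = category, snp_rate = counts / len,
               ins_rate = 0, del_rate = 0, stringsAsFactors = FALSE)
  }))
}

test_that("ANOVA path detects a 3x rate shift and respects degeneracy", {
  pr <- sim_profiles(list(A = 0.005, B = 0.015, C = 0.005), 200, seed = 11)
  res <- allelic_variation_tests(pr)
  snp <- res[res$grouping == "catX/snp_rate", ]
  expect_true(snp$significant)

  # identical all-zero rates: degenerate, p reported as 1
  pr0 <- sim_profiles(list(A = 0, B = 0, C = 0), 10, seed = 12)
  res0 <- allelic_variation_tests(pr0)
  expect_true(all(res0$p_value == 1))
  expect_true(all(res0$degenerate))

  # two genes per strain is below the minimum
  pr2 <- sim_profiles(list(A = 0.01, B = 0.01), 2, seed = 13)
  res2 <- allelic_variation_tests(pr2)
  expect_true(all(is.na(res2$p_value)))
})

test_that("matched null distributions stay non-significant at the 1% level", {
  set.seed(14)
  hits <- 0
  for (r in 1:100) {
    pr <- sim_profiles(list(A = 0.01, B = 0.01, C = 0.01), 60, seed = 1000 + r)
    res <- allelic_variation_tests(pr)
    hits <- hits + res$significant[res$grouping == "catX/snp_rate"]
  }
  expect_lte(hits, 3) # 100 replicates at alpha 0.01
})

sim_comparisons <- function(rate_by_pair, n_fam, len = 1000, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(rate_by_pair), function(p) {
    data.frame(family = sprintf("f%03d", seq_len(n_fam)), pair = p,
               category = "catX",
               rate = rpois(n_fam, rate_by_pair[[p]] * len) / len,
               stringsAsFactors = FALSE)
  }))
}

test_that("Kruskal-Wallis flags a pair with doubled divergence", {
  cc <- sim_comparisons(list(`A|B` = 0.02, `A|C` = 0.01, `B|C` = 0.01),
                        150, seed = 21)
  res <- between_strain_tests(cc)
  expect_true(res$kruskal$significant[1])
  expect_true(any(res$posthoc$significant))

  null <- sim_comparisons(list(`A|B` = 0.01, `A|C` = 0.01, `B|C` = 0.01),
                          150, seed = 22)
  resn <- between_strain_tests(null)
  expect_false(resn$kruskal$significant[1])

  empty <- sim_comparisons(list(`A|B` = 0.01), 2, seed = 23)
  expect_null(between_strain_tests(empty)$kruskal)
})

test_that("between-category contrasts use the rank-sum test", {
  set.seed(24)
  pr <- rbind(sim_profiles(list(A = 0.002), 80, category = "low", seed = 25),
              sim_profiles(list(A = 0.02), 80, category = "high", seed = 26))
  res <- category_contrasts(pr)
  expect_equal(nrow(res), 1)
  expect_true(res$significant)
  expect_match(res$test, "rank-sum")
})
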