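trunc01 <- function(y) y[y > 0 & y < 1]

test_that("EM log-likelihood never decreases and the free model nests the fixed ones", {
  set.seed(101)
  datasets <- list(
    dip = trunc01(rnorm(2000, 0.5, 0.05)),
    tri = trunc01(c(rnorm(1000, 1 / 3, 0.04), rnorm(1000, 2 / 3, 0.04))),
    tet = trunc01(c(rnorm(700, 0.25, 0.05), rnorm(700, 0.5, 0.05),
                    rnorm(700, 0.75, 0.05))))
  for (y in datasets) {
    fits <- lapply(2:4, function(m) fit_fixed_mixture(y, m))
    free <- fit_free_mixture(y)
    for (f in fits) {
      expect_true(all(diff(f$ll_trace) > -1e-8)) # monotone EM
      expect_gte(free$logL, f$logL - 1e-6)       # nesting up to tolerance
      expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    }
  }
})

test_that("fixed-mean fits rank the true ploidy highest on clean spectra", {
  set.seed(102)
  y2 <- trunc01(rnorm(10000, 0.5, 0.05))
  fits2 <- vapply(2:4, function(m) fit_fixed_mixture(y2, m)$logL, numeric(1))
  expect_equal(which.max(fits2), 1L)
  pc2 <- call_ploidy(y2)
  expect_equal(pc2$call, 2L)

  y3 <- trunc01(c(rnorm(5000, 1 / 3, 0.04), rnorm(5000, 2 / 3, 0.04)))
  expect_equal(call_ploidy(y3)$call, 3L)

  y4 <- trunc01(c(rnorm(3333, 0.25, 0.05), rnorm(3334, 0.5, 0.05),
                  rnorm(3333, 0.75, 0.05)))
  expect_equal(call_ploidy(y4)$call, 4L)
})

test_that("supports are a normalized, bounded transform of the likelihoods", {
  set.seed(103)
  y <- trunc01(rnorm(3000, 0.5, 0.05))
  pc <- call_ploidy(y)
  expect_equal(sum(pc$supports), 1, tolerance = 1e-12)
  expect_true(all(pc$supports >= 0 & pc$supports <= 1))
  expect_equal(pc$margin,
               unname(sort(pc$supports, decreasing = TRUE)[1] -
                        sort(pc$supports, decreasing = TRUE)[2]))
  expect_gte(pc$margin, pc$margin_threshold)
})

test_that("too little data yields the insufficient-data sentinel", {
  expect_true(is_insufficient(fit_fixed_mixture(0.5, 2)))
  expect_true(is_insufficient(fit_free_mixture(numeric(0))))
  expect_true(is_insufficient(call_ploidy(runif(10))))
  expect_true(is_insufficient(denoise_sites(runif(5))))
})

test_that("denoising strips uniform noise but keeps mode structure", {
  set.seed(104)
  y <- c(rnorm(9000, 0.5, 0.05), runif(1000))
  lab <- c(rep(FALSE, 9000), rep(TRUE, 1000))
  keep <- y > 0 & y < 1
  dn <- denoise_sites(y[keep])
  removed <- logical(sum(keep))
  removed[dn$removed] <- TRUE
  expect_gte(mean(removed[lab[keep]]), 0.70)  # most injected noise goes
  expect_lte(mean(removed[!lab[keep]]), 0.05) # almost no signal lost

  clean <- trunc01(rnorm(2000, 0.5, 0.05))
  dn2 <- denoise_sites(clean)
  expect_lte(dn2$n_removed / length(clean), 0.05)

  # structureless input ends ambiguous (or below the site minimum)
  set.seed(105)
  flat <- runif(3000)
  res <- call_ploidy(flat, denoise = TRUE)
  expect_true(is_insufficient(res) || is.na(res$call))
})

test_that("per-contig calls aggregate by contig length", {
  set.seed(106)
  sites <- rbind(
    data.frame(contig = "big",
               y = trunc01(c(rnorm(300, 1 / 3, 0.04), rnorm(300, 2 / 3, 0.04)))),
    data.frame(contig = "small", y = trunc01(rnorm(400, 0.5, 0.05))),
    data.frame(contig = "tiny", y = trunc01(rnorm(400, 0.5, 0.05))),
    data.frame(contig = "sparse", y = trunc01(rnorm(20, 0.5, 0.05))))
  lens <- c(big = 100000, small = 50000, tiny = 9999, sparse = 60000)
  gs <- contig_ploidy(sites, lens, denoise = FALSE)
  expect_equal(sort(gs$contigs$contig), c("big", "small")) # tiny/sparse excluded
  expect_equal(gs$contigs$call[gs$contigs$contig == "big"], 3L)
  expect_equal(gs$contigs$call[gs$contigs$contig == "small"], 2L)
  expect_equal(unname(gs$length_weighted["3"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(gs$length_weighted["2"]), 1 / 3, tolerance = 1e-12)
  expect_equal(gs$fraction_passing, 1)

  # uniformly diploid contigs give a diploid length fraction of 1
  set.seed(107)
  dsites <- do.call(rbind, lapply(1:3, function(i)
    data.frame(contig = paste0("c", i), y = trunc01(rnorm(300, 0.5, 0.05)))))
  dl <- setNames(rep(50000, 3), paste0("c", 1:3))
  gd <- contig_ploidy(dsites, dl, denoise = FALSE)
  expect_equal(unname(gd$length_weighted["2"]), 1)
})
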