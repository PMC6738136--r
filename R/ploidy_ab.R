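## Ploidy from allele-balance spectra.
##
## At a heterozygous site of a ploidy-m organism whose alternate allele sits
## on j haplotypes, the alternate read fraction y concentrates near j/m. The
## ploidy hypotheses m = 2,3,4 are therefore Gaussian mixtures with means
## fixed at j/m (j = 1..m-1), equal component proportions, and free
## per-component standard deviations; a free 3-component mixture provides
## the likelihood ceiling, and a uniform error component drives denoising.

# core EM on a Gaussian mixture with optional uniform component.
# means/weights may be held fixed; sds always free (floored/capped).
# the iteration itself runs in C++ (.em_gauss_cpp).
em_gauss <- function(y, means, sds, weights, fix_means = TRUE,
                     fix_weights = TRUE, uniform = FALSE, uniform_w = 0.05,
                     max_iter = 500, tol = 1e-6, sd_floor = 1e-3,
                     sd_cap = Inf) {
  fit <- .em_gauss_cpp(as.numeric(y), as.numeric(means), as.numeric(sds),
                       as.numeric(weights), fix_means, fix_weights, uniform,
                       uniform_w, as.integer(max_iter), tol, sd_floor,
                       if (is.finite(sd_cap)) sd_cap else 1e6)
  fit$logL <- fit$ll_trace[length(fit$ll_trace)]
  fit$iterations <- length(fit$ll_trace)
  fit
}

as_y <- function(sites) {
  if (is.data.frame(sites)) {
    if ("y" %in% names(sites)) return(sites$y)
    sd_stop("site data.frame must have a column 'y'")
  }
  as.numeric(sites)
}

#' Fit a fixed-mean mixture for one ploidy hypothesis
#'
#' EM on a Gaussian mixture whose component means are fixed at `j/m`
#' (`j = 1..m-1`) with equal, fixed component proportions; only the
#' per-component standard deviations are estimated (floored at `sd_floor`).
#' The log-likelihood is non-decreasing over EM iterations (kept in
#' `ll_trace`).
#'
#' @param sites numeric vector of alternate fractions in (0,1), or a
#'   data.frame with a `y` column (as from [extract_allele_balance()]).
#' @param m ploidy hypothesis: 2, 3 or 4.
#' @param min_sites minimum observations; below it an insufficient-data
#'   sentinel is returned.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param sd_floor lower bound on component standard deviations.
#' @return object of class `ploidy_mixture` (or `sd_insufficient`).
#' @export
fit_fixed_mixture <- function(sites, m, min_sites = 50, max_iter = 500,
                              tol = 1e-6, sd_floor = 1e-3) {
  stopifnot(m %in% 2:4)
  y <- as_y(sites)
  if (length(y) < min_sites)
    return(insufficient_data(sprintf("fixed mixture m=%d", m), length(y),
                             min_sites))
  K <- m - 1
  fit <- em_gauss(y, means = (1:K) / m, sds = rep(0.08, K),
                  weights = rep(1 / K, K), fix_means = TRUE,
                  fix_weights = TRUE, max_iter = max_iter, tol = tol,
                  sd_floor = sd_floor)
  structure(list(m = m, means = fit$means, sds = fit$sds,
                 weights = fit$weights, logL = fit$logL,
                 ll_trace = fit$ll_trace, n_sites = length(y),
                 iterations = fit$iterations),
            class = "ploidy_mixture")
}

#' Fit the free three-component mixture (likelihood ceiling)
#'
#' Means, proportions and standard deviations all free; three EM starts
#' (grid `{1/4, 1/2, 3/4}`, data quantiles, grid `{1/3, 1/2, 2/3}`) with the
#' best final likelihood kept, so the free fit dominates every fixed-mean
#' hypothesis up to EM tolerance.
#'
#' @inheritParams fit_fixed_mixture
#' @return object of class `ploidy_mixture` with `m = "free"`.
#' @export
fit_free_mixture <- function(sites, min_sites = 50, max_iter = 500,
                             tol = 1e-6, sd_floor = 1e-3) {
  y <- as_y(sites)
  if (length(y) < min_sites)
    return(insufficient_data("free mixture", length(y), min_sites))
  inits <- list(c(0.25, 0.5, 0.75),
                unname(quantile(y, c(0.2, 0.5, 0.8))),
                c(1 / 3, 1 / 2, 2 / 3))
  best <- NULL
  for (mu0 in inits) {
    fit <- em_gauss(y, means = mu0, sds = rep(0.08, 3),
                    weights = rep(1 / 3, 3), fix_means = FALSE,
                    fix_weights = FALSE, max_iter = max_iter, tol = tol,
                    sd_floor = sd_floor)
    if (is.null(best) || fit$logL > best$logL) best <- fit
  }
  structure(list(m = "free", means = best$means, sds = best$sds,
                 weights = best$weights, logL = best$logL,
                 ll_trace = best$ll_trace, n_sites = length(y),
                 iterations = best$iterations),
            class = "ploidy_mixture")
}

#' @export
print.ploidy_mixture <- function(x, ...) {
  cat(sprintf("<ploidy_mixture m=%s: logL %.2f on %d sites, %d EM iters>\n",
              x$m, x$logL, x$n_sites, x$iterations))
  invisible(x)
}

#' Remove allele-balance sites better explained by uniform noise
#'
#' Fits the free three-component mixture augmented with a Uniform(0,1)
#' error component (all weights free) and drops every site whose posterior
#' responsibility is highest for the uniform component. Component standard
#' deviations are capped at `sd_cap`: a mixture mode represents read
#' sampling noise around an allele ratio j/m and is never broader than
#' that, so the cap stops a Gaussian from widening to impersonate the
#' uniform error component.
#'
#' @inheritParams fit_fixed_mixture
#' @param sd_cap upper bound on component standard deviations in the
#'   denoising model (default 0.12).
#' @param min_component_weight Gaussian components whose fitted weight
#'   falls below this are treated as noise shelters and their sites removed
#'   as well (default 0.05): a genuine allele-balance mode at ploidy 2-4
#'   carries at least ~1/5 of the heterozygous sites, so a component
#'   explaining almost nothing is a patch of error sites that locally
#'   mimics a mode.
#' @param noise_posterior uniform-component posterior above which a site is
#'   removed (default 0.25). The sub-0.5 cut is deliberate: error sites kept
#'   in bias every downstream ploidy likelihood, whereas dropping a small
#'   share of genuine sites among thousands costs nothing, so the loss is
#'   asymmetric.
#' @return list with `sites` (the surviving subset, same type as the input),
#'   `removed` (indices of removed sites), `n_removed`, and the fitted
#'   `model`. Below `min_sites` an insufficient-data sentinel.
#' @export
denoise_sites <- function(sites, min_sites = 50, max_iter = 500, tol = 1e-6,
                          sd_cap = 0.12, min_component_weight = 0.05,
                          noise_posterior = 0.25) {
  y <- as_y(sites)
  if (length(y) < min_sites)
    return(insufficient_data("denoise", length(y), min_sites))
  fit <- em_gauss(y, means = c(0.25, 0.5, 0.75), sds = rep(0.08, 3),
                  weights = rep(1 / 3, 3), fix_means = FALSE,
                  fix_weights = FALSE, uniform = TRUE, uniform_w = 0.1,
                  max_iter = max_iter, tol = tol, sd_cap = sd_cap)
  assign_max <- max.col(fit$responsibilities, ties.method = "first")
  camped <- c(fit$weights < min_component_weight, FALSE)
  resp_u <- fit$responsibilities[, ncol(fit$responsibilities)]
  removed <- which(camped[assign_max] | resp_u >= noise_posterior)
  kept <- if (is.data.frame(sites)) sites[setdiff(seq_along(y), removed), , drop = FALSE]
          else y[setdiff(seq_along(y), removed)]
  list(sites = kept, removed = removed, n_removed = length(removed),
       model = fit)
}

#' Call ploidy from an allele-balance spectrum
#'
#' Fits the fixed-mean hypotheses m = 2, 3, 4 (and the free ceiling model),
#' converts log-likelihoods to bounded supports
#' `s_m = exp((logL_m - logL_best) / sqrt(n))` normalized to sum to one, and
#' calls the maximum-support ploidy iff its support exceeds the runner-up by
#' at least `margin_threshold`; otherwise the call is ambiguous (`NA`).
#' The sqrt(n) scaling makes supports comparable across sequences with very
#' different site counts: log-likelihood-ratio noise grows like sqrt(n), so
#' the support gap behaves like a z-score rather than saturating at genome
#' scale or washing out per site.
#'
#' @inheritParams fit_fixed_mixture
#' @param margin_threshold minimum support margin for a definite call
#'   (default 0.10, the study's "at least 10% higher" rule).
#' @param denoise if TRUE, run [denoise_sites()] first.
#' @param scope label stored in the result (e.g. a contig name or
#'   `"genome"`).
#' @return object of class `ploidy_call`: per-hypothesis log-likelihoods,
#'   normalized supports, the called ploidy (or `NA` if ambiguous) and the
#'   margin. Insufficient data propagates as an `sd_insufficient`.
#' @export
call_ploidy <- function(sites, margin_threshold = 0.10, min_sites = 50,
                        denoise = FALSE, scope = "genome") {
  y <- as_y(sites)
  n_removed <- 0L
  if (denoise) {
    dn <- denoise_sites(y, min_sites = min_sites)
    if (is_insufficient(dn)) return(dn)
    y <- dn$sites
    n_removed <- dn$n_removed
  }
  if (length(y) < min_sites)
    return(insufficient_data("ploidy call", length(y), min_sites))
  fits <- lapply(2:4, function(m) fit_fixed_mixture(y, m, min_sites = min_sites))
  free <- fit_free_mixture(y, min_sites = min_sites)
  logL <- vapply(fits, `[[`, numeric(1), "logL")
  names(logL) <- paste0("m", 2:4)
  n <- length(y)
  s <- exp((logL - max(logL)) / sqrt(n))
  s <- s / sum(s)
  ord <- order(s, decreasing = TRUE)
  margin <- s[ord[1]] - s[ord[2]]
  call <- if (margin >= margin_threshold) c(2L, 3L, 4L)[ord[1]] else NA_integer_
  structure(list(scope = scope, n_sites = n, n_denoised = n_removed,
                 logL = logL, logL_free = free$logL,
                 supports = setNames(s, paste0("s", 2:4)),
                 call = call, margin = unname(margin),
                 margin_threshold = margin_threshold,
                 fits = fits, free_fit = free),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call %s: %s (margin %.3f) on %d sites; s2/s3/s4 = %s>\n",
              x$scope,
              if (is.na(x$call)) "ambiguous" else paste0("ploidy ", x$call),
              x$margin, x$n_sites,
              paste(sprintf("%.3f", x$supports), collapse = "/")))
  invisible(x)
}

#' Per-contig ploidy calls with length-normalized aggregation
#'
#' Calls ploidy separately for every contig at least `min_contig_len` long
#' with at least `min_sites` usable sites, then summarizes: for each ploidy
#' level, the fraction of called-contig length assigned to it (the study's
#' contig-length normalization), and the fraction of analyzed contigs whose
#' support margin passed the threshold.
#'
#' @param sites data.frame with columns `contig` and `y`.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param min_contig_len minimum contig length (default 10,000 bp).
#' @param min_sites minimum sites per contig.
#' @param margin_threshold support margin for a definite call.
#' @param denoise if TRUE, denoise the pooled sites once before splitting by
#'   contig.
#' @return object of class `genome_ploidy_summary`: per-contig table,
#'   length-weighted per-ploidy fractions over called contigs, and the
#'   margin pass rate.
#' @export
contig_ploidy <- function(sites, contig_lengths, min_contig_len = 10000,
                          min_sites = 50, margin_threshold = 0.10,
                          denoise = TRUE) {
  stopifnot(is.data.frame(sites), "contig" %in% names(sites))
  if (denoise) {
    dn <- denoise_sites(sites, min_sites = min_sites)
    if (!is_insufficient(dn)) sites <- dn$sites
  }
  eligible <- names(contig_lengths)[contig_lengths >= min_contig_len]
  rows <- list()
  for (ctg in eligible) {
    y <- sites$y[sites$contig == ctg]
    if (length(y) < min_sites) next
    pc <- call_ploidy(y, margin_threshold = margin_threshold,
                      min_sites = min_sites, scope = ctg)
    rows[[ctg]] <- data.frame(
      contig = ctg, length = unname(contig_lengths[ctg]),
      n_sites = pc$n_sites, s2 = unname(pc$supports[1]),
      s3 = unname(pc$supports[2]), s4 = unname(pc$supports[3]),
      call = pc$call, margin = pc$margin, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), length = numeric(), n_sites = integer(),
               s2 = numeric(), s3 = numeric(), s4 = numeric(),
               call = integer(), margin = numeric())
  rownames(tab) <- NULL
  called <- tab[!is.na(tab$call), , drop = FALSE]
  frac <- setNames(numeric(3), c("2", "3", "4"))
  if (nrow(called) > 0) {
    tot <- sum(called$length)
    for (p in c(2, 3, 4))
      frac[as.character(p)] <- sum(called$length[called$call == p]) / tot
  }
  structure(list(contigs = tab,
                 length_weighted = frac,
                 n_analyzed = nrow(tab), n_called = nrow(called),
                 fraction_passing = if (nrow(tab)) nrow(called) / nrow(tab) else NA_real_),
            class = "genome_ploidy_summary")
}

#' @export
print.genome_ploidy_summary <- function(x, ...) {
  cat(sprintf(
    "<genome_ploidy_summary: %d/%d contigs pass the margin rule; length-weighted 2/3/4 = %s>\n",
    x$n_called, x$n_analyzed,
    paste(sprintf("%.2f", x$length_weighted), collapse = "/")))
  invisible(x)
}
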