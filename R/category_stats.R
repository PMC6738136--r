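## Functional-category stratification of mutation statistics, significance
## testing at alpha = 0.01, and KEGG-style module completeness.

#' Is a functional module complete?
#'
#' A two-gene module is complete only if both genes are present; a module of
#' more than two genes may miss at most one.
#'
#' @param required character vector of the module's gene (or KO)
#'   identifiers; at least 2.
#' @param present character vector of identifiers present in the genome.
#' @return logical scalar.
#' @export
module_complete <- function(required, present) {
  required <- unique(required)
  if (length(required) < 2)
    sd_stop("a module must contain at least 2 genes (got %d)",
            length(required))
  missing <- sum(!required %in% present)
  if (length(required) == 2) missing == 0 else missing <= 1
}

#' Evaluate completeness of a module table
#'
#' @param modules data.frame with columns `module` and `family` (one row
#'   per required gene).
#' @param present character vector of present identifiers.
#' @return data.frame per module: size, number present, `complete`.
#' @export
modules_completeness <- function(modules, present) {
  out <- lapply(split(modules$family, modules$module), function(req) {
    req <- unique(req)
    data.frame(size = length(req), n_present = sum(req %in% present),
               complete = module_complete(req, present))
  })
  res <- do.call(rbind, out)
  res$module <- rownames(res)
  rownames(res) <- NULL
  res[, c("module", "size", "n_present", "complete")]
}

# one test result row with degeneracy handling
stat_row <- function(test, grouping, statistic, p, alpha, n, degenerate = FALSE) {
  data.frame(test = test, grouping = grouping,
             statistic = statistic,
             p_value = p, significant = !is.na(p) & p < alpha,
             degenerate = degenerate, n = n, stringsAsFactors = FALSE)
}

#' ANOVA of per-gene variation rates across strains, per category
#'
#' For each functional category and variant type (SNP, insertion,
#' deletion), a one-way ANOVA tests whether per-gene rates differ between
#' strains. Categories with fewer than `min_genes` genes in any strain (or
#' fewer than 2 strains) are skipped with an `insufficient` flag;
#' zero-variance data report p = 1 with a degeneracy flag.
#'
#' @param profiles data.frame with columns `strain`, `category`, and rate
#'   columns `snp_rate`, `ins_rate`, `del_rate` (as from
#'   [profile_gene_variants()] with an added `strain` column).
#' @param alpha significance level (default 0.01).
#' @param min_genes minimum genes per strain per category (default 3).
#' @param p_adjust `"none"` (raw p-values, the default) or `"holm"` for a
#'   family-wise correction across the emitted tests.
#' @return data.frame of test results, one row per category x variant type.
#' @export
allelic_variation_tests <- function(profiles, alpha = 0.01, min_genes = 3,
                                    p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("strain", "category") %in% names(profiles)))
  rows <- list()
  for (cat in sort(unique(profiles$category))) {
    sub <- profiles[profiles$category == cat, , drop = FALSE]
    cnt <- table(sub$strain)
    if (length(cnt) < 2 || any(cnt < min_genes)) {
      for (vt in c("snp_rate", "ins_rate", "del_rate"))
        rows[[paste(cat, vt)]] <- stat_row(
          "one-way ANOVA", paste0(cat, "/", vt), NA_real_, NA_real_,
          alpha, nrow(sub), degenerate = FALSE)
      next
    }
    for (vt in c("snp_rate", "ins_rate", "del_rate")) {
      y <- sub[[vt]]
      g <- factor(sub$strain)
      if (sd(y) == 0) {
        rows[[paste(cat, vt)]] <- stat_row("one-way ANOVA",
                                           paste0(cat, "/", vt), NA_real_,
                                           1.0, alpha, length(y),
                                           degenerate = TRUE)
        next
      }
      fit <- anova(lm(y ~ g))
      rows[[paste(cat, vt)]] <- stat_row(
        "one-way ANOVA", paste0(cat, "/", vt),
        fit$`F value`[1], fit$`Pr(>F)`[1], alpha, length(y))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "holm" && nrow(out) > 0) {
    out$p_value <- p.adjust(out$p_value, "holm")
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}

#' Kruskal-Wallis tests of pairwise divergence across strain pairs
#'
#' Within each category, per-family mutation rates are compared across the
#' strain pairs by a Kruskal-Wallis rank test (the divergence rates are not
#' normally distributed), followed post hoc by Wilcoxon signed-rank tests
#' between strain pairs, paired by gene family (families absent from either
#' group are dropped).
#'
#' @param comparisons data.frame with `family`, `pair` (strain-pair label),
#'   `category`, `rate`.
#' @param alpha significance level (default 0.01).
#' @param min_families minimum families per group (default 3).
#' @param p_adjust `"none"` (raw p-values, the default) or `"holm"`.
#' @return list with `kruskal` (per category) and `posthoc`
#'   (per category x pair-of-pairs signed-rank results).
#' @export
between_strain_tests <- function(comparisons, alpha = 0.01,
                                 min_families = 3,
                                 p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("family", "pair", "category", "rate") %in%
                  names(comparisons)))
  kr <- list()
  ph <- list()
  for (cat in sort(unique(comparisons$category))) {
    sub <- comparisons[comparisons$category == cat, , drop = FALSE]
    cnt <- table(sub$pair)
    if (length(cnt) < 2 || any(cnt < min_families)) next
    if (sd(sub$rate) == 0) {
      kr[[cat]] <- stat_row("Kruskal-Wallis", cat, NA_real_, 1.0, alpha,
                            nrow(sub), degenerate = TRUE)
      next
    }
    kt <- kruskal.test(sub$rate, factor(sub$pair))
    kr[[cat]] <- stat_row("Kruskal-Wallis", cat,
                          unname(kt$statistic), kt$p.value, alpha, nrow(sub))
    prs <- sort(unique(sub$pair))
    for (i in seq_along(prs)) for (jj in seq_along(prs)) {
      if (jj <= i) next
      w <- paired_signed_rank(sub, prs[i], prs[jj], alpha)
      if (!is.null(w)) ph[[paste(cat, prs[i], prs[jj])]] <-
          cbind(category = cat, w)
    }
  }
  adjust <- function(df) {
    if (is.null(df) || p_adjust == "none") return(df)
    df$p_value <- p.adjust(df$p_value, "holm")
    df$significant <- !is.na(df$p_value) & df$p_value < alpha
    df
  }
  list(kruskal = adjust(if (length(kr)) {
    k <- do.call(rbind, kr); rownames(k) <- NULL; k
  } else NULL),
  posthoc = adjust(if (length(ph)) {
    p <- do.call(rbind, ph); rownames(p) <- NULL; p
  } else NULL))
}

# Wilcoxon signed-rank between two groups, paired by family
paired_signed_rank <- function(sub, g1, g2, alpha, min_pairs = 3) {
  a <- sub[sub$pair == g1, c("family", "rate")]
  b <- sub[sub$pair == g2, c("family", "rate")]
  m <- merge(a, b, by = "family")
  if (nrow(m) < min_pairs) return(NULL)
  diffs <- m$rate.x - m$rate.y
  if (all(diffs == 0))
    return(stat_row("Wilcoxon signed-rank", paste(g1, "vs", g2),
                    NA_real_, 1.0, alpha, nrow(m), degenerate = TRUE))
  w <- suppressWarnings(wilcox.test(m$rate.x, m$rate.y, paired = TRUE))
  stat_row("Wilcoxon signed-rank", paste(g1, "vs", g2),
           unname(w$statistic), w$p.value, alpha, nrow(m))
}

#' Between-category rate contrasts within each strain
#'
#' Compares per-gene rate distributions between pairs of functional
#' categories within one strain. Genes belong to exactly one category, so
#' there is no pairing unit between categories; the contrast is therefore
#' an unpaired Wilcoxon rank-sum test.
#'
#' @param profiles as in [allelic_variation_tests()].
#' @param value rate column to compare (default `"snp_rate"`).
#' @param alpha significance level.
#' @param min_genes minimum genes per category.
#' @return data.frame of rank-sum results per strain x category pair.
#' @export
category_contrasts <- function(profiles, value = "snp_rate", alpha = 0.01,
                               min_genes = 3) {
  rows <- list()
  for (st in sort(unique(profiles$strain))) {
    sub <- profiles[profiles$strain == st, , drop = FALSE]
    cats <- sort(unique(sub$category))
    for (i in seq_along(cats)) for (jj in seq_along(cats)) {
      if (jj <= i) next
      x <- sub[[value]][sub$category == cats[i]]
      y <- sub[[value]][sub$category == cats[jj]]
      if (length(x) < min_genes || length(y) < min_genes) next
      if (sd(c(x, y)) == 0) {
        rows[[paste(st, i, jj)]] <- cbind(strain = st, stat_row(
          "Wilcoxon rank-sum", paste(cats[i], "vs", cats[jj]),
          NA_real_, 1.0, alpha, length(x) + length(y), degenerate = TRUE))
        next
      }
      w <- suppressWarnings(wilcox.test(x, y))
      rows[[paste(st, i, jj)]] <- cbind(strain = st, stat_row(
        "Wilcoxon rank-sum", paste(cats[i], "vs", cats[jj]),
        unname(w$statistic), w$p.value, alpha, length(x) + length(y)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
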