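## End-to-end orchestration: variants -> ploidy (two methods) -> gene set ->
## divergence -> category statistics, with TSV reports.

#' Haploid genome size from total DNA content and called ploidy
#'
#' @param total_size total genome size (e.g. Mb from flow cytometry).
#' @param ploidy called ploidy (2, 3 or 4); `NA` (ambiguous) gives `NA`.
#' @return total divided by ploidy, rounded half-up to one decimal.
#' @export
haploid_size <- function(total_size, ploidy) {
  stopifnot(total_size > 0)
  if (is.na(ploidy)) return(NA_real_)
  stopifnot(ploidy %in% 2:4)
  round_half_up(total_size / ploidy, 1)
}

#' Core-genome percentage
#'
#' @param core number of families present in every strain.
#' @param total total number of families.
#' @return percentage rounded half-up to one decimal.
#' @export
shared_fraction <- function(core, total) {
  stopifnot(total > 0, core >= 0, core <= total)
  round_half_up(100 * core / total, 1)
}

default_thresholds <- function() {
  list(min_dp = 8, min_af = 0.10, margin = 0.10, min_contig_len = 10000,
       min_sites = 50, cluster_identity = 0.8, cluster_coverage = 0.8,
       length_ratio = 0.8, place_identity = 0.9, place_coverage = 0.8,
       overlap = 0.10, alpha = 0.01, k = 21, ci = 1, cs = 10000)
}

#' Read / write a flat run configuration
#'
#' `key = value` lines; strain-scoped keys use `strain.<name>.<field>`.
#' Round-trips losslessly through [write_run_config()].
#'
#' @param path file path.
#' @return named list with `strains` (named list of file paths per strain),
#'   `thresholds`, `seed`, `out_dir`, and optional entries (`modules`,
#'   `total_size`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  cfg <- list(strains = list(), thresholds = default_thresholds(),
              total_size = list())
  for (m in kv) {
    if (length(m) != 3) next
    key <- m[2]; val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "strain" && length(parts) == 3) {
      cfg$strains[[parts[2]]][[parts[3]]] <- val
    } else if (parts[1] == "threshold" && length(parts) == 2) {
      cfg$thresholds[[parts[2]]] <- num
    } else if (parts[1] == "total_size" && length(parts) == 2) {
      cfg$total_size[[parts[2]]] <- num
    } else {
      cfg[[key]] <- if (!is.na(num) && key %in% c("seed")) num else val
    }
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  lines <- character(0)
  for (nm in setdiff(names(cfg), c("strains", "thresholds", "total_size")))
    lines <- c(lines, sprintf("%s = %s", nm, cfg[[nm]]))
  for (s in names(cfg$strains))
    for (f in names(cfg$strains[[s]]))
      lines <- c(lines, sprintf("strain.%s.%s = %s", s, f,
                                cfg$strains[[s]][[f]]))
  for (t in names(cfg$thresholds))
    lines <- c(lines, sprintf("threshold.%s = %s", t, cfg$thresholds[[t]]))
  for (t in names(cfg$total_size))
    lines <- c(lines, sprintf("total_size.%s = %s", t, cfg$total_size[[t]]))
  writeLines(lines, path)
  invisible(path)
}

stage <- function(name, strain, expr) {
  tryCatch(expr, error = function(e)
    sd_stop("stage '%s' failed for %s: %s", name, strain, conditionMessage(e)))
}

#' Run the full strain-comparison pipeline
#'
#' Executes, for every strain: variant filtering and allele-balance
#' extraction, genome-wide and per-contig allele-balance ploidy estimation,
#' k-mer smudge ploidy estimation, then cross-strain gene clustering,
#' placement, locus merging, core/shared/exclusive classification, gene
#' density, per-gene variant profiles, allele-aware pairwise divergence and
#' the category-stratified statistics. All tables are written to
#' `cfg$out_dir` (if set) and returned.
#'
#' @param cfg configuration list as from [read_run_config()]: per strain
#'   the file paths `contigs`, `genes`, `gff`, `vcf` and optionally
#'   `kmers`; optional `modules` (module TSV), `total_size` (named Mb
#'   values), `out_dir`, `seed`, and `thresholds` overrides.
#' @return object of class `strain_report`.
#' @export
run_pipeline <- function(cfg) {
  th <- default_thresholds()
  th[names(cfg$thresholds)] <- cfg$thresholds
  strains <- names(cfg$strains)
  if (length(strains) < 1) sd_stop("no strains configured")
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  log_lines <- c(sprintf("straindiverge %s; R %s",
                         as.character(utils::packageVersion("straindiverge")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed = %s", if (is.null(cfg$seed)) "none" else cfg$seed),
                 sprintf("threshold %s = %s", names(th), unlist(th)))
  for (s in strains) {
    for (f in c("contigs", "genes", "gff", "vcf")) {
      p <- cfg$strains[[s]][[f]]
      if (is.null(p) || !file.exists(p))
        sd_stop("missing %s file for strain %s", f, s)
    }
  }

  contigs <- genes_fa <- gff <- filtered <- ab_sites <- list()
  ab_call <- ab_contigs <- kmer_call <- profiles <- list()
  for (s in strains) {
    contigs[[s]] <- stage("read-contigs", s, {
      x <- Biostrings::readDNAStringSet(cfg$strains[[s]]$contigs)
      names(x) <- sub("\\s.*", "", names(x))
      x
    })
    genes_fa[[s]] <- stage("read-genes", s, {
      x <- Biostrings::readDNAStringSet(cfg$strains[[s]]$genes)
      names(x) <- sub("\\s.*", "", names(x))
      x
    })
    gff[[s]] <- stage("read-gff", s, {
      g <- rtracklayer::import(cfg$strains[[s]]$gff, format = "gff3")
      data.frame(id = g$ID, family = if (!is.null(g$family)) g$family else g$ID,
                 category = if (!is.null(g$category)) g$category else "unannotated",
                 contig = as.character(GenomicRanges::seqnames(g)),
                 start = BiocGenerics::start(g) - 1L,
                 end = BiocGenerics::end(g),
                 strand = as.character(BiocGenerics::strand(g)),
                 stringsAsFactors = FALSE)
    })
    filtered[[s]] <- stage("variant-filter", s,
      filter_variants(read_vcf_records(cfg$strains[[s]]$vcf),
                      min_dp = th$min_dp, min_af = th$min_af))
    ab_sites[[s]] <- stage("allele-balance", s,
      extract_allele_balance(filtered[[s]]))
    ab_call[[s]] <- stage("ploidy-ab", s,
      call_ploidy(ab_sites[[s]], margin_threshold = th$margin,
                  min_sites = th$min_sites, denoise = TRUE, scope = s))
    ab_contigs[[s]] <- stage("ploidy-ab-contigs", s,
      contig_ploidy(ab_sites[[s]],
                    setNames(BiocGenerics::width(contigs[[s]]),
                             names(contigs[[s]])),
                    min_contig_len = th$min_contig_len,
                    min_sites = th$min_sites, margin_threshold = th$margin))
    kp <- cfg$strains[[s]]$kmers
    kmer_call[[s]] <- if (!is.null(kp) && file.exists(kp))
      stage("ploidy-kmer", s, smudge_ploidy(kp, ci = th$ci, cs = th$cs))
    else NULL
    profiles[[s]] <- stage("variant-profiles", s, {
      pr <- profile_gene_variants(gff[[s]], filtered[[s]])
      pr$strain <- s
      pr
    })
  }

  ## cross-strain gene set
  pool <- do.call(rbind, lapply(strains, function(s)
    data.frame(id = names(genes_fa[[s]]), strain = s,
               seq = as.character(genes_fa[[s]]), stringsAsFactors = FALSE)))
  clusters <- stage("cluster", "all", cluster_genes(
    pool, identity = th$cluster_identity, length_ratio = th$length_ratio,
    coverage = th$cluster_coverage))
  reps <- setNames(clusters$representatives$seq,
                   clusters$representatives$cluster)
  loci <- placements <- list()
  for (s in strains) {
    placements[[s]] <- stage("place", s, place_genes(
      reps, contigs[[s]], min_identity = th$place_identity,
      min_coverage = th$place_coverage))
    loci[[s]] <- stage("merge", s, merge_overlapping(
      placements[[s]], min_overlap_frac = th$overlap))
  }
  families <- stage("classify", "all", classify_shared(loci))

  density <- vapply(strains, function(s) gene_density(
    nrow(loci[[s]]), BiocGenerics::width(contigs[[s]])), integer(1))

  ## allele-aware pairwise divergence per shared family
  member_cat <- do.call(rbind, lapply(strains, function(s)
    gff[[s]][, c("id", "category")]))
  clu_members <- clusters$members
  clu_cat <- setNames(
    member_cat$category[match(clu_members$id, member_cat$id)],
    clu_members$id)
  comparisons <- stage("divergence", "all",
    pairwise_family_divergence(families, clusters, placements, contigs,
                               filtered, clu_cat, strains))
  ident <- count_identical(comparisons)

  ## statistics
  prof_all <- do.call(rbind, profiles)
  anova_tab <- stage("stats-anova", "all",
    allelic_variation_tests(prof_all, alpha = th$alpha))
  kw <- stage("stats-kruskal", "all", {
    cc <- comparisons
    cc$pair <- paste(cc$strain_a, cc$strain_b, sep = "|")
    between_strain_tests(cc, alpha = th$alpha)
  })

  ## module completeness per strain (on generator family labels when given)
  module_tab <- NULL
  if (!is.null(cfg$modules) && file.exists(cfg$modules)) {
    modules <- read.delim(cfg$modules, stringsAsFactors = FALSE)
    fam_label <- do.call(rbind, lapply(strains, function(s)
      gff[[s]][, c("id", "family")]))
    module_tab <- do.call(rbind, lapply(strains, function(s) {
      placed_cl <- unique(unlist(strsplit(loci[[s]]$genes, ",")))
      member_ids <- clu_members$id[clu_members$cluster %in% placed_cl]
      present <- unique(fam_label$family[fam_label$id %in% member_ids])
      mc <- modules_completeness(modules, present)
      cbind(strain = s, mc)
    }))
  }

  core_pct <- shared_fraction(unname(families$totals["core"]),
                              unname(families$totals["total"]))
  report <- data.frame(
    strain = strains,
    n_contigs = vapply(strains, function(s) length(contigs[[s]]), integer(1)),
    assembly_bp = vapply(strains, function(s) {
      w <- BiocGenerics::width(contigs[[s]]); sum(w[w > 500]) }, numeric(1)),
    n_genes = vapply(strains, function(s) nrow(loci[[s]]), integer(1)),
    gene_density = density,
    ploidy_ab = vapply(strains, function(s) ab_call[[s]]$call, integer(1)),
    ab_margin = vapply(strains, function(s) ab_call[[s]]$margin, numeric(1)),
    ploidy_kmer = vapply(strains, function(s)
      if (is.null(kmer_call[[s]]) || is_insufficient(kmer_call[[s]]))
        NA_integer_ else kmer_call[[s]]$call, integer(1)),
    core_percent = core_pct,
    stringsAsFactors = FALSE)
  report$haploid_size <- vapply(strains, function(s) {
    ts <- cfg$total_size[[s]]
    if (is.null(ts)) NA_real_
    else haploid_size(ts, report$ploidy_ab[report$strain == s])
  }, numeric(1))

  out <- structure(list(
    report = report, thresholds = th, families = families,
    venn = families$venn, loci = loci, placements = placements,
    clusters = clusters, profiles = prof_all, comparisons = comparisons,
    identical = ident, anova = anova_tab, kruskal = kw,
    modules = module_tab, ab_calls = ab_call, ab_contigs = ab_contigs,
    kmer_calls = kmer_call, log = log_lines),
    class = "strain_report")
  if (!is.null(cfg$out_dir)) write_report(out, cfg$out_dir)
  out
}

# allele-aware divergence for every family shared by >= 2 strains
pairwise_family_divergence <- function(families, clusters, placements,
                                       contigs, filtered, clu_cat, strains) {
  fam_of <- families$members # placed cluster id -> family
  clu_members <- clusters$members
  clu_fam <- data.frame(cluster = names(fam_of), family = unname(fam_of),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (fam in families$families$family[families$families$n_genomes >= 2]) {
    cls <- clu_fam$cluster[clu_fam$family == fam]
    per_strain <- list()
    for (s in strains) {
      pl <- placements[[s]]
      pl <- pl[pl$gene %in% cls, , drop = FALSE]
      if (nrow(pl) == 0) next
      pl <- pl[which.max(pl$score), , drop = FALSE]
      seq <- substring(as.character(contigs[[s]][[pl$contig]]),
                       pl$start + 1, pl$end)
      v <- filtered[[s]]
      v <- v[v$contig == pl$contig & (v$pos - 1) >= pl$start &
               (v$pos - 1) < pl$end, , drop = FALSE]
      vars <- NULL
      if (nrow(v) > 0) {
        alts <- strsplit(v$alts, ",", fixed = TRUE)
        vars <- data.frame(pos = rep(v$pos, lengths(alts)) - pl$start,
                           ref = rep(v$ref, lengths(alts)),
                           alt = unlist(alts), stringsAsFactors = FALSE)
      }
      aset <- allele_set(seq, vars)
      if (pl$strand == "-") aset <- revcomp_allele_set(aset)
      per_strain[[s]] <- aset
    }
    sts <- names(per_strain)
    if (length(sts) < 2) next
    ## representative category: first member gene with a known category
    fam_genes <- clu_members$id[clu_members$cluster %in% cls]
    cat <- clu_cat[fam_genes]
    cat <- cat[!is.na(cat)]
    cat <- if (length(cat)) cat[[1]] else "unannotated"
    for (i in seq_along(sts)) for (jj in seq_along(sts)) {
      if (jj <= i) next
      cmp <- compare_gene_pair(per_strain[[sts[i]]], per_strain[[sts[jj]]])
      rows[[paste(fam, sts[i], sts[jj])]] <- data.frame(
        family = fam, strain_a = sts[i], strain_b = sts[jj],
        category = cat, mutations = cmp$mutations,
        aligned_length = cmp$aligned_length, rate = cmp$rate,
        identical = cmp$identical, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(), strain_a = character(),
                      strain_b = character(), category = character(),
                      mutations = integer(), aligned_length = integer(),
                      rate = numeric(), identical = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# strand flip of an allele_set (positions mirrored, alleles complemented)
revcomp_allele_set <- function(aset) {
  L <- aset$length
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  snp <- list()
  for (p in names(aset$snp))
    snp[[as.character(L - as.integer(p) + 1)]] <-
      unname(vapply(aset$snp[[p]], comp1, character(1)))
  ins <- list()
  for (p in names(aset$ins))
    ins[[as.character(L - as.integer(p))]] <-
      unname(vapply(aset$ins[[p]], function(s) revcomp_chr(s), character(1)))
  structure(list(seq = revcomp_chr(aset$seq), length = L, snp = snp,
                 del_cover = L - aset$del_cover + 1, ins = ins),
            class = "allele_set")
}

#' Write the report tables of a pipeline run
#'
#' @param x a `strain_report`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(report = wt(x$report, "report.tsv"),
             venn = wt(x$venn, "venn.tsv"),
             rates = wt(x$profiles, "rates.tsv"),
             comparisons = wt(x$comparisons, "comparisons.tsv"),
             identical = wt(x$identical, "identical.tsv"))
  stats <- rbind(x$anova,
                 if (!is.null(x$kruskal$kruskal)) x$kruskal$kruskal)
  paths["stats"] <- wt(stats, "stats.tsv")
  ploidy <- do.call(rbind, lapply(names(x$ab_contigs), function(s)
    cbind(strain = s, x$ab_contigs[[s]]$contigs)))
  paths["ploidy"] <- wt(ploidy, "ploidy.tsv")
  if (!is.null(x$modules)) paths["modules"] <- wt(x$modules, "modules.tsv")
  writeLines(x$log, file.path(dir, "run.log"))
  invisible(paths)
}

#' @export
print.strain_report <- function(x, ...) {
  cat("<strain_report>\n")
  print(x$report)
  invisible(x)
}
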