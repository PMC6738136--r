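#' Default functional-category table for the synthetic generator
#'
#' Categories mirror the KEGG top-level groups used for mutation
#' stratification, plus an "unannotated" bucket and a group of genes encoding
#' organelle-targeted proteins. Each category carries a sampling weight (its
#' share of genes), a per-bp heterozygosity rate and a per-bp fixed
#' inter-strain divergence rate. Energy metabolism is the most conserved
#' category; unannotated genes are the most variable. The pseudo-category
#' `intergenic` supplies the background rates outside genes.
#'
#' @return data.frame with columns `category`, `weight`, `het_rate`,
#'   `div_rate`.
#' @export
sd_categories <- function() {
  data.frame(
    category = c("energy_metabolism", "carbohydrate_metabolism",
                 "lipid_metabolism", "nucleotide_metabolism",
                 "amino_acid_metabolism", "genetic_information_processing",
                 "signaling_cellular_processes", "secondary_metabolism",
                 "organelle_targeted", "unannotated", "intergenic"),
    weight = c(0.06, 0.08, 0.06, 0.05, 0.08, 0.14, 0.10, 0.06, 0.07, 0.30, 0),
    het_rate = c(0.002, 0.005, 0.005, 0.004, 0.005, 0.010, 0.008, 0.010,
                 0.006, 0.012, 0.006),
    div_rate = c(0.004, 0.009, 0.009, 0.008, 0.009, 0.013, 0.011, 0.015,
                 0.010, 0.018, 0.012),
    stringsAsFactors = FALSE
  )
}

#' Specification of one synthetic strain
#'
#' @param name strain identifier.
#' @param ploidy integer number of haplotype copies, one of 2, 3, 4.
#' @param het_rate named per-category per-bp heterozygosity rates (must
#'   include an `intergenic` entry); a single unnamed number scales the
#'   default table instead.
#' @param divergence named per-category per-bp fixed substitution rates
#'   against the ancestral reference, same conventions as `het_rate`.
#' @param n_exclusive_genes number of strain-exclusive genes to insert.
#' @param mean_coverage expected reads per base (total over haplotypes).
#' @param seed integer random seed for everything derived from this strain.
#' @return object of class `strain_spec`.
#' @export
strain_spec <- function(name, ploidy, het_rate = NULL, divergence = NULL,
                        n_exclusive_genes = 0, mean_coverage = 50, seed = 1) {
  cats <- sd_categories()
  expand <- function(x, default) {
    if (is.null(x)) return(setNames(default, cats$category))
    if (is.null(names(x)) && length(x) == 1)
      return(setNames(default * (x / mean(default[cats$weight > 0])),
                      cats$category))
    out <- setNames(default, cats$category)
    out[names(x)] <- x
    out
  }
  het <- expand(het_rate, cats$het_rate)
  div <- expand(divergence, cats$div_rate)
  if (!ploidy %in% 2:4) sd_stop("ploidy must be 2, 3 or 4 (got %s)", ploidy)
  if (any(het < 0 | het > 0.2) || any(div < 0 | div > 0.2))
    sd_stop("per-bp rates must lie in [0, 0.2]")
  if (mean_coverage <= 0) sd_stop("mean_coverage must be positive")
  structure(list(name = name, ploidy = as.integer(ploidy), het_rate = het,
                 divergence = div,
                 n_exclusive_genes = as.integer(n_exclusive_genes),
                 mean_coverage = mean_coverage, seed = as.integer(seed)),
            class = "strain_spec")
}

#' Generate an ancestral reference genome with non-overlapping genes
#'
#' Produces a random sequence and places `n_genes` non-overlapping gene
#' intervals (0-based, half-open) on random strands, each assigned a
#' functional category by the category weight table. Deterministic under a
#' fixed seed.
#'
#' @param length_bp genome length in bp.
#' @param n_genes number of genes to place.
#' @param gene_length numeric `(mean, sd)` of gene lengths in bp (minimum
#'   length 10 enforced).
#' @param categories category table as from [sd_categories()].
#' @param gc GC content of the random sequence.
#' @param min_gap minimum intergenic gap in bp.
#' @param conserved_fraction fraction of genes under strong purifying
#'   selection: they accumulate no fixed inter-strain substitutions in any
#'   derived strain, so conspecific strains share them identically (real
#'   strain pairs share a few percent of genes with identical sequence).
#' @param seed integer seed.
#' @param max_retries redraw attempts for gene lengths before giving up.
#' @return object of class `sd_ancestor`: the sequence, its gene table
#'   (`family`, `start`, `end`, `strand`, `category`, `conserved`) and the
#'   category table.
#' @export
make_ancestor <- function(length_bp, n_genes, gene_length = c(1500, 300),
                          categories = sd_categories(), gc = 0.53,
                          min_gap = 100, conserved_fraction = 0.08,
                          seed = 1, max_retries = 20) {
  if (length_bp < n_genes * gene_length[1])
    sd_stop("length_bp (%d) below n_genes x mean gene length", length_bp)
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    len <- pmax(10, round(rnorm(n_genes, gene_length[1], gene_length[2])))
    slack <- length_bp - sum(len) - min_gap * (n_genes + 1)
    if (slack >= 0) break
    if (try == max_retries)
      sd_stop("could not place %d genes in %d bp after %d retries",
              n_genes, length_bp, max_retries)
  }
  w <- runif(n_genes + 1)
  gap <- min_gap + floor(slack * w / sum(w))
  start <- cumsum(gap[seq_len(n_genes)]) + cumsum(c(0, len[-n_genes])) # 0-based
  genecat <- categories[categories$weight > 0, ]
  genes <- data.frame(
    family = sprintf("fam%04d", seq_len(n_genes)),
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    category = sample(genecat$category, n_genes, replace = TRUE,
                      prob = genecat$weight),
    conserved = runif(n_genes) < conserved_fraction,
    stringsAsFactors = FALSE
  )
  stopifnot(all(genes$end <= length_bp))
  structure(list(sequence = random_dna(length_bp, gc), length = length_bp,
                 genes = genes, categories = categories,
                 gene_length = gene_length, gc = gc, seed = seed),
            class = "sd_ancestor")
}

# sample mutated base distinct from `ref`
other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
         USE.NAMES = FALSE)
}

# sample per-region event positions (1-based anchors); `rates` is a per-bp
# rate per region row
sample_region_positions <- function(regions, rates) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    wid <- regions$end[i] - regions$start[i]
    if (wid <= 0) next
    n <- rbinom(1, wid, rates[i])
    if (n == 0) next
    pos <- regions$start[i] + sample.int(wid, n) # 1-based within genome
    out[[i]] <- data.frame(pos = sort(pos), region = i)
  }
  do.call(rbind, out)
}

#' Derive a polyploid strain from an ancestral reference
#'
#' Applies, in order: loss of gene families absent from this strain,
#' insertion of strain-exclusive genes, fixed inter-strain substitutions at
#' category-specific rates (on all haplotypes), and heterozygous SNPs/short
#' indels at category-specific rates, each carried by `j` of the `ploidy`
#' haplotypes with `j` uniform on `1..ploidy-1`. Haplotype 1 never carries a
#' heterozygous variant, so it doubles as the collapsed reference assembly
#' that variants are expressed against. Every injected event is recorded in
#' the returned truth tables.
#'
#' @param ancestor an `sd_ancestor`.
#' @param spec a [strain_spec()].
#' @param families character vector of ancestor families present in this
#'   strain (default: all).
#' @param indel_fraction fraction of heterozygous events that are indels
#'   (split evenly between insertions and deletions, lengths 1-10 bp).
#' @return object of class `sd_strain` with the strain genome (haplotype 1),
#'   its gene table, the heterozygous variant table (`pos` is a 1-based
#'   genome anchor) and a per-gene truth table of injected counts.
#' @export
derive_strain <- function(ancestor, spec, families = NULL,
                          indel_fraction = 0.08) {
  stopifnot(inherits(ancestor, "sd_ancestor"), inherits(spec, "strain_spec"))
  set.seed(spec$seed)
  m <- spec$ploidy
  genes <- ancestor$genes
  chars <- strsplit(ancestor$sequence, "", fixed = TRUE)[[1]]

  ## 1. drop families absent from this strain
  if (!is.null(families)) {
    drop <- genes[!genes$family %in% families, ]
    if (nrow(drop) > 0) {
      keep <- rep(TRUE, length(chars))
      for (i in seq_len(nrow(drop))) keep[(drop$start[i] + 1):drop$end[i]] <- FALSE
      newpos <- cumsum(keep)
      genes <- genes[genes$family %in% families, ]
      genes$start <- newpos[genes$start + 1] - 1L
      genes$end <- newpos[genes$end]
      chars <- chars[keep]
    }
  }

  ## 2. insert exclusive genes (appended with random intergenic spacers)
  if (spec$n_exclusive_genes > 0) {
    genecat <- ancestor$categories[ancestor$categories$weight > 0, ]
    for (i in seq_len(spec$n_exclusive_genes)) {
      gl <- max(10, round(rnorm(1, ancestor$gene_length[1],
                                ancestor$gene_length[2])))
      spacer <- random_dna(round(runif(1, 200, 800)), ancestor$gc)
      gseq <- random_dna(gl, ancestor$gc)
      at <- length(chars) + nchar(spacer)
      chars <- c(chars, strsplit(paste0(spacer, gseq), "", fixed = TRUE)[[1]])
      genes <- rbind(genes, data.frame(
        family = sprintf("%s_x%03d", spec$name, i),
        start = at, end = at + gl,
        strand = sample(c("+", "-"), 1),
        category = sample(genecat$category, 1, prob = genecat$weight),
        conserved = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  L <- length(chars)

  ## region table: genes + intergenic complement
  ord <- order(genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  bounds <- c(0, as.vector(rbind(genes$start, genes$end)), L)
  inter <- data.frame(start = bounds[seq(1, length(bounds) - 1, by = 2)],
                      end = bounds[seq(2, length(bounds), by = 2)],
                      category = "intergenic", stringsAsFactors = FALSE)
  inter_keep <- inter[inter$end > inter$start, ]
  regions <- rbind(
    data.frame(start = genes$start, end = genes$end,
               category = genes$category, stringsAsFactors = FALSE),
    inter_keep)
  n_inter <- nrow(inter_keep)
  regions$gene_row <- c(seq_len(nrow(genes)), rep(NA, n_inter))
  div_rates <- c(unname(spec$divergence[genes$category]) *
                   as.numeric(!genes$conserved),
                 rep(unname(spec$divergence["intergenic"]), n_inter))
  het_rates <- c(unname(spec$het_rate[genes$category]),
                 rep(unname(spec$het_rate["intergenic"]), n_inter))

  ## 3. fixed inter-strain substitutions (all haplotypes)
  div <- sample_region_positions(regions, div_rates)
  if (!is.null(div) && nrow(div) > 0) {
    p <- unique(div$pos)
    chars[p] <- other_base(chars[p])
  }

  ## 4. heterozygous events
  het <- sample_region_positions(regions, het_rates)
  variants <- NULL
  if (!is.null(het) && nrow(het) > 0) {
    het <- het[order(het$pos), ]
    n <- nrow(het)
    kind <- sample(c("SNP", "insertion", "deletion"), n, replace = TRUE,
                   prob = c(1 - indel_fraction, indel_fraction / 2,
                            indel_fraction / 2))
    ilen <- sample(1:10, n, replace = TRUE, prob = 0.55^(0:9))
    ilen[kind == "SNP"] <- 0L
    span_end <- het$pos + ifelse(kind == "deletion", ilen, 0L)
    ## prune events whose span collides with the previous kept event
    keep <- logical(n)
    last_end <- -1
    for (i in seq_len(n)) {
      if (het$pos[i] > last_end && span_end[i] <= L) {
        keep[i] <- TRUE
        last_end <- span_end[i]
      }
    }
    het <- het[keep, ]; kind <- kind[keep]; ilen <- ilen[keep]
    n <- nrow(het)
    if (n > 0) {
      ref <- alt <- character(n)
      for (i in seq_len(n)) {
        p <- het$pos[i]
        if (kind[i] == "SNP") {
          ref[i] <- chars[p]
          alt[i] <- other_base(chars[p])
        } else if (kind[i] == "insertion") {
          ref[i] <- chars[p]
          alt[i] <- paste0(chars[p], random_dna(ilen[i], ancestor$gc))
        } else {
          ref[i] <- paste(chars[p:(p + ilen[i])], collapse = "")
          alt[i] <- chars[p]
        }
      }
      j <- sample.int(m - 1, n, replace = TRUE)
      carriers <- vapply(j, function(jj)
        paste(sort(sample(2:m, jj)), collapse = ","), character(1))
      grow <- regions$gene_row[het$region]
      variants <- data.frame(
        pos = het$pos, ref = ref, alt = alt, type = kind, j = j,
        carriers = carriers,
        family = ifelse(is.na(grow), NA, genes$family[grow]),
        category = ifelse(is.na(grow), "intergenic", genes$category[grow]),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(variants))
    variants <- data.frame(pos = integer(), ref = character(),
                           alt = character(), type = character(),
                           j = integer(), carriers = character(),
                           family = character(), category = character(),
                           stringsAsFactors = FALSE)

  genes$id <- sprintf("%s_g%04d", spec$name, seq_len(nrow(genes)))
  vg <- variants[!is.na(variants$family), c("family", "type")]
  cnt <- table(factor(vg$family, levels = genes$family),
               factor(vg$type, levels = c("SNP", "insertion", "deletion")))
  truth <- data.frame(
    family = genes$family, id = genes$id, category = genes$category,
    conserved = genes$conserved,
    length = genes$end - genes$start,
    n_snp = as.integer(cnt[, "SNP"]),
    n_ins = as.integer(cnt[, "insertion"]),
    n_del = as.integer(cnt[, "deletion"]),
    stringsAsFactors = FALSE)

  structure(list(name = spec$name, ploidy = m,
                 genome = paste(chars, collapse = ""), length = L,
                 genes = genes, variants = variants, truth = truth,
                 spec = spec),
            class = "sd_strain")
}

#' @export
print.sd_strain <- function(x, ...) {
  cat(sprintf("<sd_strain %s: ploidy %d, %d bp, %d genes, %d het variants>\n",
              x$name, x$ploidy, x$length, nrow(x$genes), nrow(x$variants)))
  invisible(x)
}

#' Reconstruct the haplotype sequences of a synthetic strain
#'
#' Haplotype 1 is the strain genome itself; haplotypes 2..ploidy carry the
#' heterozygous variants assigned to them.
#'
#' @param strain an `sd_strain`.
#' @return character vector of `ploidy` sequences.
#' @export
strain_haplotypes <- function(strain) {
  stopifnot(inherits(strain, "sd_strain"))
  m <- strain$ploidy
  v <- strain$variants
  haps <- character(m)
  haps[1] <- strain$genome
  carr <- strsplit(v$carriers, ",", fixed = TRUE)
  for (h in seq_len(m)[-1]) {
    ev <- v[vapply(carr, function(cc) as.character(h) %in% cc, logical(1)), ,
            drop = FALSE]
    if (nrow(ev) == 0) { haps[h] <- strain$genome; next }
    chars <- strsplit(strain$genome, "", fixed = TRUE)[[1]]
    snp <- ev[ev$type == "SNP", ]
    chars[snp$pos] <- snp$alt
    s <- paste(chars, collapse = "")
    indel <- ev[ev$type != "SNP", ]
    if (nrow(indel) == 0) { haps[h] <- s; next }
    indel <- indel[order(indel$pos), ]
    pieces <- character(0)
    cur <- 1L
    for (i in seq_len(nrow(indel))) {
      p <- indel$pos[i]
      pieces <- c(pieces, substr(s, cur, p))
      if (indel$type[i] == "insertion") {
        pieces <- c(pieces, substr(indel$alt[i], 2, nchar(indel$alt[i])))
        cur <- p + 1L
      } else { # deletion removes pos+1 .. pos+len
        cur <- p + nchar(indel$ref[i]) # = p + 1 + del_len
      }
    }
    pieces <- c(pieces, substr(s, cur, nchar(s)))
    haps[h] <- paste(pieces, collapse = "")
  }
  haps
}

#' Fragment a strain genome into contigs
#'
#' Breakpoints are placed only in intergenic runs (with a safety margin), so
#' contig boundaries never split a gene. A `short_contig_fraction` of contigs
#' is deliberately made shorter than 500 bp to exercise the assembly-size
#' contig filter downstream.
#'
#' @param strain an `sd_strain`.
#' @param n_contigs number of contigs to emit.
#' @param short_contig_fraction fraction of contigs shorter than 500 bp.
#' @param seed integer seed (default derives from the strain seed).
#' @return object of class `sd_assembly`: data.frame with `contig`, `start`,
#'   `end` (0-based half-open on the strain genome) and `length`, plus the
#'   strain name as an attribute.
#' @export
fragment_genome <- function(strain, n_contigs = 50, short_contig_fraction = 0.1,
                            seed = strain$spec$seed + 1000L) {
  stopifnot(inherits(strain, "sd_strain"), n_contigs >= 1)
  set.seed(seed)
  margin <- 30L
  genes <- strain$genes[order(strain$genes$start), ]
  L <- strain$length
  gaps <- data.frame(start = c(0, genes$end) + margin,
                     end = c(genes$start, L) - margin)
  gaps <- gaps[gaps$end > gaps$start, ]
  n_short <- round(short_contig_fraction * n_contigs)
  breaks <- integer(0)
  used <- rep(FALSE, nrow(gaps))
  if (n_short > 0) {
    wide <- which(gaps$end - gaps$start >= 700)
    if (length(wide) < n_short)
      sd_stop("not enough wide intergenic gaps for %d short contigs", n_short)
    pick <- sample(wide, n_short)
    for (g in pick) {
      d <- round(runif(1, 120, 450))
      b1 <- round(runif(1, gaps$start[g], gaps$end[g] - d))
      breaks <- c(breaks, b1, b1 + d)
    }
    used[pick] <- TRUE
  }
  n_rest <- n_contigs - 1L - 2L * n_short
  if (n_rest < 0)
    sd_stop("n_contigs too small for short_contig_fraction")
  if (n_rest > 0) {
    cand_gaps <- which(!used)
    pos <- unlist(lapply(cand_gaps, function(g)
      seq.int(gaps$start[g], gaps$end[g] - 1L)))
    pos <- setdiff(pos, unlist(lapply(breaks, function(b) (b - 500):(b + 500))))
    chosen <- integer(0)
    pos <- sample(pos)
    for (p in pos) {
      if (length(chosen) == n_rest) break
      if (all(abs(chosen - p) > 800)) chosen <- c(chosen, p)
    }
    if (length(chosen) < n_rest)
      sd_stop("could not place %d contig breakpoints", n_rest)
    breaks <- c(breaks, chosen)
  }
  breaks <- sort(unique(breaks))
  start <- c(0L, breaks)
  end <- c(breaks, L)
  asm <- data.frame(
    contig = sprintf("%s_ctg%04d", strain$name, seq_along(start)),
    start = start, end = end, length = end - start,
    stringsAsFactors = FALSE)
  ## sanity: no gene split
  gi <- findInterval(genes$start, asm$start)
  stopifnot(all(genes$end <= asm$end[gi]))
  structure(asm, class = c("sd_assembly", "data.frame"),
            strain = strain$name)
}

# map 1-based genome positions to (contig, local 1-based position)
map_to_contigs <- function(pos, assembly) {
  idx <- findInterval(pos - 1L, assembly$start)
  data.frame(contig = assembly$contig[idx],
             pos = pos - assembly$start[idx],
             stringsAsFactors = FALSE)
}

#' Simulate per-site read depths and allele depths for heterozygous sites
#'
#' Site depth is negative binomial around the mean coverage (Poisson when
#' `overdispersion = 0`); the alternate-allele depth is binomial with success
#' probability `j / ploidy` where `j` is the number of carrier haplotypes. A
#' fraction of additional error sites receives an alternate fraction uniform
#' on (0,1) to exercise the denoising step downstream.
#'
#' @param strain an `sd_strain`.
#' @param assembly optional `sd_assembly`; when given, sites are expressed in
#'   contig coordinates (otherwise on a single genome-length sequence named
#'   after the strain).
#' @param mean_coverage mean site depth (defaults to the strain spec).
#' @param overdispersion negative-binomial overdispersion of depth (0 =
#'   Poisson).
#' @param error_sites_fraction number of error sites as a fraction of true
#'   heterozygous sites.
#' @param seed integer seed.
#' @param file optional path; when given a VCF v4.2 file (FORMAT GT:AD:DP) is
#'   written.
#' @return data.frame of simulated sites (class `sd_vcf_sim`) with depths,
#'   allele depths, genotypes and truth annotations.
#' @export
simulate_allele_depths <- function(strain, assembly = NULL,
                                   mean_coverage = strain$spec$mean_coverage,
                                   overdispersion = 0.1,
                                   error_sites_fraction = 0.05,
                                   seed = strain$spec$seed + 2000L,
                                   file = NULL) {
  stopifnot(inherits(strain, "sd_strain"))
  set.seed(seed)
  m <- strain$ploidy
  v <- strain$variants
  n <- nrow(v)
  rdepth <- function(k) {
    if (overdispersion > 0) rnbinom(k, mu = mean_coverage, size = 1 / overdispersion)
    else rpois(k, mean_coverage)
  }
  dp <- rdepth(n)
  ad_alt <- rbinom(n, dp, v$j / m)
  gt <- vapply(v$j, function(jj)
    paste(c(rep("0", m - jj), rep("1", jj)), collapse = "/"), character(1))
  sim <- data.frame(gpos = v$pos, ref = v$ref, alt = v$alt, type = v$type,
                    j = v$j, dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt,
                    gt = gt, is_error = FALSE, family = v$family,
                    category = v$category, stringsAsFactors = FALSE)
  n_err <- round(error_sites_fraction * n)
  if (n_err > 0) {
    cand <- setdiff(sample.int(strain$length, n_err * 2), v$pos)
    epos <- sort(cand[seq_len(min(n_err, length(cand)))])
    eref <- substring(strain$genome, epos, epos)
    ok <- eref %in% c("A", "C", "G", "T")
    epos <- epos[ok]; eref <- eref[ok]
    edp <- rdepth(length(epos))
    ead <- round(edp * runif(length(epos)))
    sim <- rbind(sim, data.frame(
      gpos = epos, ref = eref, alt = other_base(eref), type = "error",
      j = NA_integer_, dp = edp, ad_ref = edp - ead, ad_alt = ead,
      gt = "0/1", is_error = TRUE, family = NA_character_,
      category = NA_character_, stringsAsFactors = FALSE))
  }
  if (is.null(assembly)) {
    sim$contig <- strain$name
    sim$pos <- sim$gpos
    contig_len <- setNames(strain$length, strain$name)
  } else {
    mp <- map_to_contigs(sim$gpos, assembly)
    sim$contig <- mp$contig
    sim$pos <- mp$pos
    contig_len <- setNames(assembly$length, assembly$contig)
  }
  sim <- sim[order(match(sim$contig, names(contig_len)), sim$pos), ]
  rownames(sim) <- NULL
  class(sim) <- c("sd_vcf_sim", "data.frame")
  if (!is.null(file)) write_vcf(sim, contig_len, strain$name, file)
  sim
}

#' Write simulated variant sites as VCF v4.2
#'
#' @param sim data.frame from [simulate_allele_depths()].
#' @param contig_lengths named vector of contig lengths.
#' @param sample_name sample column name.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(sim, contig_lengths, sample_name, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=straindiverge-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP\t%s:%d,%d:%d",
                 sim$contig, sim$pos, sim$ref, sim$alt, sim$gt,
                 sim$ad_ref, sim$ad_alt, sim$dp)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Simulate canonical k-mer counts from the strain haplotypes
#'
#' Each haplotype contributes its k-mer multiplicity at a per-copy coverage
#' of `mean_coverage / ploidy`; observed counts are Poisson around the summed
#' expectation. K-mers are canonical (lexicographic minimum of the k-mer and
#' its reverse complement).
#'
#' @param strain an `sd_strain`.
#' @param mean_coverage total coverage (defaults to the strain spec).
#' @param k odd k-mer size (<= 31).
#' @param seed integer seed.
#' @param file optional path for a two-column `kmer<TAB>count` TSV.
#' @return data.frame with columns `kmer` and `count` (zero counts dropped).
#' @export
simulate_kmer_counts <- function(strain,
                                 mean_coverage = strain$spec$mean_coverage,
                                 k = 21, seed = strain$spec$seed + 3000L,
                                 file = NULL) {
  stopifnot(inherits(strain, "sd_strain"))
  if (k %% 2 == 0 || k > 31) sd_stop("k must be odd and <= 31")
  set.seed(seed)
  haps <- strain_haplotypes(strain)
  tab <- .kmer_count_cpp(haps, as.integer(k))
  lambda <- tab$count * (mean_coverage / strain$ploidy)
  obs <- rpois(length(lambda), lambda)
  out <- data.frame(kmer = tab$kmer[obs > 0], count = obs[obs > 0],
                    stringsAsFactors = FALSE)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  out
}

#' Simulate a bare allele-balance spectrum
#'
#' Observation-level shortcut used for ploidy-model calibration: `n_sites`
#' heterozygous sites with carrier count `j` uniform on `1..ploidy-1`,
#' alternate depth binomial at fixed total depth, plus a fraction of
#' uniform-noise sites.
#'
#' @param ploidy true ploidy (2, 3 or 4).
#' @param n_sites number of sites.
#' @param depth fixed site depth.
#' @param noise fraction of sites replaced by Uniform(0,1) alternate
#'   fractions.
#' @param seed integer seed.
#' @return data.frame with `y` (alternate fraction in (0,1)), `depth`, and
#'   logical `is_noise`.
#' @export
simulate_allele_balance <- function(ploidy, n_sites = 5000, depth = 50,
                                    noise = 0.05, seed = 1) {
  stopifnot(ploidy %in% 2:4)
  set.seed(seed)
  j <- sample.int(ploidy - 1, n_sites, replace = TRUE)
  y <- rbinom(n_sites, depth, j / ploidy) / depth
  is_noise <- rep(FALSE, n_sites)
  n_noise <- round(noise * n_sites)
  if (n_noise > 0) {
    idx <- sample.int(n_sites, n_noise)
    y[idx] <- runif(n_noise)
    is_noise[idx] <- TRUE
  }
  keep <- y > 0 & y < 1
  data.frame(y = y[keep], depth = depth, is_noise = is_noise[keep])
}

## ---- writers for the on-disk dataset -------------------------------------

#' Write a synthetic strain to standard files
#'
#' Emits contig FASTA, gene GFF3 (1-based, contig coordinates, with `ID`,
#' `family` and `category` attributes), strand-oriented gene FASTA, a
#' gene-to-category TSV and the per-gene truth table.
#'
#' @param strain an `sd_strain`.
#' @param assembly an `sd_assembly` for the strain.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_strain_data <- function(strain, assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- strain$name
  paths <- c(
    contigs = file.path(dir, paste0(nm, ".contigs.fasta")),
    gff = file.path(dir, paste0(nm, ".genes.gff3")),
    genes = file.path(dir, paste0(nm, ".genes.fasta")),
    categories = file.path(dir, paste0(nm, ".categories.tsv")),
    truth = file.path(dir, paste0(nm, ".truth.tsv")))
  ctg <- Biostrings::DNAStringSet(substring(strain$genome,
                                            assembly$start + 1, assembly$end))
  names(ctg) <- assembly$contig
  Biostrings::writeXStringSet(ctg, paths["contigs"])
  genes <- strain$genes
  ci <- findInterval(genes$start, assembly$start)
  gr <- GenomicRanges::GRanges(
    seqnames = assembly$contig[ci],
    ranges = IRanges::IRanges(start = genes$start - assembly$start[ci] + 1L,
                              end = genes$end - assembly$start[ci]),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$id
  gr$family <- genes$family
  gr$category <- genes$category
  rtracklayer::export(gr, paths["gff"], format = "gff3")
  gseq <- substring(strain$genome, genes$start + 1, genes$end)
  neg <- genes$strand == "-"
  gseq[neg] <- revcomp_chr(gseq[neg])
  gss <- Biostrings::DNAStringSet(gseq)
  names(gss) <- genes$id
  Biostrings::writeXStringSet(gss, paths["genes"])
  write.table(data.frame(id = genes$id, family = genes$family,
                         category = genes$category),
              paths["categories"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(strain$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

# build synthetic functional modules (2-6 families each, within category)
make_gene_modules <- function(families, categories, n_modules = 40) {
  df <- data.frame(family = families, category = categories,
                   stringsAsFactors = FALSE)
  out <- list()
  mid <- 0
  for (cat in unique(df$category)) {
    fams <- sample(df$family[df$category == cat])
    while (length(fams) >= 2 && mid < n_modules) {
      sz <- min(sample(2:6, 1), length(fams))
      if (sz < 2) break
      mid <- mid + 1
      out[[mid]] <- data.frame(module = sprintf("M%03d", mid),
                               family = fams[seq_len(sz)],
                               stringsAsFactors = FALSE)
      fams <- fams[-seq_len(sz)]
    }
    if (mid >= n_modules) break
  }
  do.call(rbind, out)
}

#' Generate a complete multi-strain synthetic dataset
#'
#' The `paper-like` preset emulates the study design at desk scale: three
#' strains of ploidy 2, 3 and 4 sharing a 1 Mb haploid core, ~68.5% of gene
#' families present in all strains, ~80.8% shared by at least two, and the
#' tetraploid carrying the largest exclusive complement. The `mini` preset is
#' a fast small-genome variant of the same design for smoke tests.
#'
#' @param out_dir optional directory; when given, all standard files (FASTA,
#'   GFF3, VCF, k-mer TSV, category/module/truth tables) are written there.
#' @param preset `"paper-like"`, `"mini"` or `"micro"` (decreasing genome
#'   size; `micro` is a seconds-scale smoke configuration).
#' @param seed integer master seed; all strain seeds derive from it.
#' @param write_kmers,write_vcfs logical; skip the heavier outputs if FALSE.
#' @return list with the ancestor, per-strain `sd_strain` objects,
#'   assemblies, the module table, the family presence truth, and (when
#'   `out_dir` is given) the file paths.
#' @export
simulate_strain_set <- function(out_dir = NULL,
                                preset = c("paper-like", "mini", "micro"),
                                seed = 1, write_kmers = !is.null(out_dir),
                                write_vcfs = !is.null(out_dir)) {
  preset <- match.arg(preset)
  p <- switch(preset,
    "paper-like" = list(L = 1e6, n_genes = 600, gene_length = c(1200, 250),
                        n_core = 509, n_pair = c(30, 30, 31),
                        n_excl = c(23, 26, 94), n_contigs = 60, coverage = 50),
    "mini" = list(L = 2e5, n_genes = 120, gene_length = c(1000, 200),
                  n_core = 102, n_pair = c(6, 6, 6),
                  n_excl = c(5, 5, 18), n_contigs = 20, coverage = 40),
    "micro" = list(L = 6e4, n_genes = 30, gene_length = c(800, 150),
                   n_core = 24, n_pair = c(2, 2, 2),
                   n_excl = c(1, 1, 4), n_contigs = 8, coverage = 40))
  set.seed(seed)
  anc <- make_ancestor(p$L, p$n_genes, p$gene_length, seed = seed)
  fams <- sample(anc$genes$family)
  core <- fams[seq_len(p$n_core)]
  rest <- fams[-seq_len(p$n_core)]
  stopifnot(length(rest) == sum(p$n_pair))
  pairs <- list(`12` = rest[seq_len(p$n_pair[1])],
                `13` = rest[p$n_pair[1] + seq_len(p$n_pair[2])],
                `23` = rest[p$n_pair[1] + p$n_pair[2] + seq_len(p$n_pair[3])])
  present <- list(c(core, pairs$`12`, pairs$`13`),
                  c(core, pairs$`12`, pairs$`23`),
                  c(core, pairs$`13`, pairs$`23`))
  ploidies <- c(2L, 3L, 4L)
  names <- c("ST2", "ST3", "ST4")
  strains <- assemblies <- vcfs <- kmers <- vector("list", 3)
  names(strains) <- names(assemblies) <- names
  paths <- list()
  for (i in 1:3) {
    sp <- strain_spec(names[i], ploidies[i],
                      n_exclusive_genes = p$n_excl[i],
                      mean_coverage = p$coverage, seed = seed + i * 101L)
    st <- derive_strain(anc, sp, families = present[[i]])
    asm <- fragment_genome(st, n_contigs = p$n_contigs)
    strains[[i]] <- st
    assemblies[[i]] <- asm
    if (!is.null(out_dir)) {
      paths[[names[i]]] <- write_strain_data(st, asm, out_dir)
      if (write_vcfs) {
        vp <- file.path(out_dir, paste0(names[i], ".vcf"))
        simulate_allele_depths(st, asm, file = vp)
        paths[[names[i]]]["vcf"] <- vp
      }
      if (write_kmers) {
        kp <- file.path(out_dir, paste0(names[i], ".kmers.tsv"))
        simulate_kmer_counts(st, file = kp)
        paths[[names[i]]]["kmers"] <- kp
      }
    }
  }
  all_fams <- unique(unlist(lapply(strains, function(s) s$genes$family)))
  cats <- unlist(unname(lapply(strains, function(s)
    setNames(s$genes$category, s$genes$family))))
  cats <- cats[!duplicated(names(cats))]
  modules <- make_gene_modules(all_fams, cats[all_fams])
  presence <- do.call(rbind, lapply(names, function(nm)
    data.frame(strain = nm, family = strains[[nm]]$genes$family,
               stringsAsFactors = FALSE)))
  truth_class <- tapply(presence$strain, presence$family, length)
  family_truth <- data.frame(
    family = names(truth_class),
    n_strains = as.integer(truth_class),
    class = c("exclusive", "shared", "core")[as.integer(truth_class)],
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "modules.tsv")
    write.table(modules, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    fp <- file.path(out_dir, "families.truth.tsv")
    write.table(family_truth, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$modules <- mp
    paths$family_truth <- fp
  }
  list(ancestor = anc, strains = strains, assemblies = assemblies,
       modules = modules, family_truth = family_truth, preset = preset,
       seed = seed, paths = paths)
}
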