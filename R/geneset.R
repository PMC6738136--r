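## Pan-genome gene-set construction: pool predicted genes across strains,
## cluster them greedily (cd-hit-est style thresholds), place the cluster
## representatives back on every genome with a seeded local aligner, merge
## same-strand overlapping placements, and classify families as core /
## shared / exclusive.

sd_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# identity and coverages of a local alignment
aln_stats <- function(aln, len_pattern, len_subject) {
  cols <- Biostrings::nchar(aln) # alignment length incl. gaps
  ident <- Biostrings::nmatch(aln) / cols
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  covp <- (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) / len_pattern
  covs <- (BiocGenerics::end(s) - BiocGenerics::start(s) + 1) / len_subject
  list(identity = ident, cov_pattern = covp, cov_subject = covs)
}

# unique k-mer set of a sequence, for the word screen
word_set <- function(seq, w = 8) {
  n <- nchar(seq)
  if (n < w) return(character(0))
  unique(substring(seq, 1:(n - w + 1), w:n))
}

#' Greedy incremental gene clustering
#'
#' cd-hit-est style: genes are sorted by length (descending); each gene
#' joins the first existing cluster whose representative it matches with
#' local-alignment identity >= `identity`, alignment coverage >=
#' `coverage` of both sequences and length ratio >= `length_ratio`;
#' otherwise it founds a new cluster. Both strands are tried. A shared-word
#' screen (8-mers) prunes the candidate representatives before alignment.
#'
#' @param genes data.frame with columns `id`, `strain`, `seq`.
#' @param identity minimum alignment identity (default 0.8).
#' @param length_ratio minimum short/long length ratio (default 0.8).
#' @param coverage minimum alignment coverage of each sequence (default
#'   0.8).
#' @param word_frac minimum fraction of the candidate's words shared for the
#'   screen (default 0.08).
#' @return object of class `gene_clusters`: the input table with a `cluster`
#'   column, plus representative ids and sequences per cluster.
#' @export
cluster_genes <- function(genes, identity = 0.8, length_ratio = 0.8,
                          coverage = 0.8, word_frac = 0.08) {
  stopifnot(all(c("id", "seq") %in% names(genes)), nrow(genes) >= 1)
  genes <- genes[order(-nchar(genes$seq), genes$id), , drop = FALSE]
  rownames(genes) <- NULL
  n <- nrow(genes)
  lens <- nchar(genes$seq)
  words <- lapply(genes$seq, word_set)
  words_rc <- lapply(revcomp_chr(genes$seq), word_set)
  submat <- sd_submat()
  rep_idx <- integer(0) # indices of representatives, in founding order
  cluster <- integer(n)
  for (i in seq_len(n)) {
    assigned <- 0L
    wi <- words[[i]]; wi_rc <- words_rc[[i]]
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (lens[i] / lens[r] < length_ratio) next # genes sorted, lens[i]<=lens[r]
      fwd <- mean(wi %in% words[[r]]) >= word_frac
      rc <- !fwd && mean(wi_rc %in% words[[r]]) >= word_frac
      if (!fwd && !rc) next
      qseq <- if (fwd) genes$seq[i] else revcomp_chr(genes$seq[i])
      aln <- Biostrings::pairwiseAlignment(
        qseq, genes$seq[r], type = "local", substitutionMatrix = submat,
        gapOpening = 2, gapExtension = 0.5)
      st <- aln_stats(aln, lens[i], lens[r])
      if (st$identity >= identity && st$cov_pattern >= coverage &&
          st$cov_subject >= coverage) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      rep_idx <- c(rep_idx, i)
      assigned <- length(rep_idx)
    }
    cluster[i] <- assigned
  }
  genes$cluster <- sprintf("cl%05d", cluster)
  reps <- data.frame(cluster = sprintf("cl%05d", seq_along(rep_idx)),
                     id = genes$id[rep_idx], seq = genes$seq[rep_idx],
                     stringsAsFactors = FALSE)
  structure(list(members = genes, representatives = reps),
            class = "gene_clusters")
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat(sprintf("<gene_clusters: %d genes in %d clusters>\n",
              nrow(x$members), nrow(x$representatives)))
  invisible(x)
}

#' Column-wise majority consensus of a gene cluster
#'
#' Members are anchored to the representative by pairwise global alignment;
#' for every representative position the majority symbol over the members
#' (including the representative, gaps counted) wins, ties going to the
#' representative's base; majority-gap positions are dropped. Insertions
#' relative to the representative are ignored. Singletons return their own
#' sequence.
#'
#' @param seqs character vector of member sequences; the first element is
#'   the representative.
#' @return consensus sequence (character scalar).
#' @export
consensus_sequence <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  rep_seq <- seqs[1]
  if (length(seqs) == 1) return(rep_seq)
  L <- nchar(rep_seq)
  rep_chars <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
  votes <- matrix("", nrow = length(seqs), ncol = L)
  votes[1, ] <- rep_chars
  submat <- sd_submat()
  for (i in seq_along(seqs)[-1]) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[i], rep_seq, type = "global", substitutionMatrix = submat,
      gapOpening = 2, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- sa != "-"
    votes[i, ] <- pa[keep]
  }
  cons <- vapply(seq_len(L), function(j) {
    tab <- table(votes[, j])
    top <- names(tab)[tab == max(tab)]
    if (rep_chars[j] %in% top) rep_chars[j] else top[1]
  }, character(1))
  paste(cons[cons != "-"], collapse = "")
}

#' Place genes on a genome by seeded local alignment
#'
#' Exact-match seed words from each gene are located on the contigs (both
#' strands); seed hits sharing a diagonal nominate candidate windows, which
#' are refined by local alignment. The best placement per gene passing
#' `min_identity` and `min_coverage` (of the gene) is kept.
#'
#' @param gene_seqs named character vector of gene sequences.
#' @param contigs named character vector (or `DNAStringSet`) of contigs.
#' @param min_identity minimum alignment identity (default 0.9).
#' @param min_coverage minimum gene coverage by the alignment (default
#'   0.8).
#' @param seed_width exact seed word length (default 24).
#' @param seed_step spacing of seed words along the gene (default 80).
#' @return data.frame of placements: `gene`, `contig`, `strand`, `start`,
#'   `end` (0-based half-open, forward strand), `identity`, `score`.
#' @export
place_genes <- function(gene_seqs, contigs, min_identity = 0.9,
                        min_coverage = 0.8, seed_width = 24, seed_step = 80) {
  if (methods::is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  stopifnot(!is.null(names(gene_seqs)), !is.null(names(contigs)))
  subj <- Biostrings::DNAStringSet(contigs)
  submat <- sd_submat()
  ## build seed dictionary over both strands of every gene
  seeds <- list()
  for (g in names(gene_seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") gene_seqs[[g]] else revcomp_chr(gene_seqs[[g]])
      L <- nchar(s)
      if (L < seed_width) next
      offs <- unique(c(seq(1, L - seed_width + 1, by = seed_step),
                       L - seed_width + 1))
      seeds[[length(seeds) + 1]] <- data.frame(
        gene = g, strand = strand, off = offs,
        word = substring(s, offs, offs + seed_width - 1),
        stringsAsFactors = FALSE)
    }
  }
  seeds <- do.call(rbind, seeds)
  ok <- !grepl("[^ACGT]", seeds$word)
  seeds <- seeds[ok, , drop = FALSE]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$word))
  placements <- list()
  for (ctg in names(contigs)) {
    hits <- Biostrings::matchPDict(pd, subj[[ctg]])
    cnt <- S4Vectors::elementNROWS(hits)
    hit_idx <- which(cnt > 0)
    if (length(hit_idx) == 0) next
    hit_tab <- data.frame(
      seed = rep(hit_idx, cnt[hit_idx]),
      pos = unlist(lapply(hit_idx, function(i) IRanges::start(hits[[i]]))))
    hit_tab$gene <- seeds$gene[hit_tab$seed]
    hit_tab$strand <- seeds$strand[hit_tab$seed]
    hit_tab$diag <- hit_tab$pos - seeds$off[hit_tab$seed]
    key <- paste(hit_tab$gene, hit_tab$strand)
    for (ks in unique(key)) {
      sub <- hit_tab[key == ks, , drop = FALSE]
      g <- sub$gene[1]; strand <- sub$strand[1]
      glen <- nchar(gene_seqs[[g]])
      ## cluster diagonals within half a gene length
      dg <- sort(unique(sub$diag))
      grp <- cumsum(c(1, diff(dg) > glen / 2))
      band_support <- tapply(seq_along(dg), grp, function(ii)
        sum(sub$diag %in% dg[ii]))
      ## refine the best-supported bands (at most 2)
      for (b in names(sort(band_support, decreasing = TRUE))[
             seq_len(min(2, length(band_support)))]) {
        diag0 <- median(dg[grp == as.integer(b)])
        w0 <- max(1, floor(diag0 - 0.1 * glen))
        w1 <- min(nchar(contigs[[ctg]]), ceiling(diag0 + 1.15 * glen))
        if (w1 - w0 + 1 < seed_width) next
        qseq <- if (strand == "+") gene_seqs[[g]] else revcomp_chr(gene_seqs[[g]])
        aln <- Biostrings::pairwiseAlignment(
          qseq, substring(contigs[[ctg]], w0, w1), type = "local",
          substitutionMatrix = submat, gapOpening = 2, gapExtension = 0.5)
        st <- aln_stats(aln, glen, w1 - w0 + 1)
        if (st$identity < min_identity || st$cov_pattern < min_coverage) next
        salh <- Biostrings::subject(aln)
        placements[[length(placements) + 1]] <- data.frame(
          gene = g, contig = ctg, strand = strand,
          start = w0 + BiocGenerics::start(salh) - 2L, # 0-based
          end = w0 + BiocGenerics::end(salh) - 1L,
          identity = st$identity, score = Biostrings::score(aln),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(placements) == 0)
    return(data.frame(gene = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  pl <- do.call(rbind, placements)
  ## best placement per gene
  pl <- pl[order(pl$gene, -pl$score), , drop = FALSE]
  pl <- pl[!duplicated(pl$gene), , drop = FALSE]
  rownames(pl) <- NULL
  pl
}

#' Merge same-strand overlapping placements into loci
#'
#' Two placements merge iff they lie on the same contig and strand and
#' overlap by at least `min_overlap_frac` of the shorter placement's length
#' (boundary inclusive); merging is transitive. Merged loci keep the union
#' interval and all member genes. Idempotent and independent of input
#' order.
#'
#' @param placements data.frame from [place_genes()].
#' @param min_overlap_frac overlap threshold as a fraction of the shorter
#'   placement (default 0.10).
#' @return data.frame of loci: `locus`, `contig`, `strand`, `start`, `end`,
#'   `n_members`, `genes` (comma-separated member ids).
#' @export
merge_overlapping <- function(placements, min_overlap_frac = 0.10) {
  if (nrow(placements) == 0)
    return(data.frame(locus = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  pl <- placements[order(placements$contig, placements$strand,
                         placements$start, placements$gene), , drop = FALSE]
  rownames(pl) <- NULL
  n <- nrow(pl)
  uf <- union_find(n)
  for (grp_key in unique(paste(pl$contig, pl$strand))) {
    idx <- which(paste(pl$contig, pl$strand) == grp_key)
    ir <- IRanges::IRanges(start = pl$start[idx] + 1L, end = pl$end[idx])
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    sel <- qh < sh
    qh <- qh[sel]; sh <- sh[sel]
    if (length(qh) == 0) next
    ovw <- IRanges::width(IRanges::pintersect(ir[qh], ir[sh]))
    shorter <- pmin(IRanges::width(ir[qh]), IRanges::width(ir[sh]))
    merge_it <- ovw >= min_overlap_frac * shorter
    for (e in which(merge_it)) uf$union(idx[qh[e]], idx[sh[e]])
  }
  comp <- uf$components()
  loci <- lapply(split(seq_len(n), comp), function(ii) {
    data.frame(contig = pl$contig[ii[1]], strand = pl$strand[ii[1]],
               start = min(pl$start[ii]), end = max(pl$end[ii]),
               n_members = length(ii),
               genes = paste(sort(pl$gene[ii]), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$contig, out$strand, out$start), , drop = FALSE]
  out$locus <- sprintf("locus%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus", "contig", "strand", "start", "end", "n_members", "genes")]
}

#' Classify gene families as core, shared or exclusive across genomes
#'
#' Clusters co-occurring in one merged locus (in any genome) are unified
#' into a single family; a family is present in a genome iff any of its
#' clusters has a surviving placement there. Families present in all
#' genomes are core, in several (but not all) shared, in exactly one
#' exclusive.
#'
#' @param loci_by_genome named list (one element per genome) of merged-locus
#'   data.frames from [merge_overlapping()].
#' @return object of class `gene_families`: family table with presence
#'   sets, Venn region counts and the summary partition.
#' @export
classify_shared <- function(loci_by_genome) {
  stopifnot(is.list(loci_by_genome), !is.null(names(loci_by_genome)))
  genomes <- names(loci_by_genome)
  all_ids <- sort(unique(unlist(lapply(loci_by_genome, function(l)
    unlist(strsplit(l$genes, ",", fixed = TRUE))))))
  uf <- union_find(length(all_ids))
  idx_of <- setNames(seq_along(all_ids), all_ids)
  for (l in loci_by_genome) {
    for (gg in strsplit(l$genes, ",", fixed = TRUE)) {
      if (length(gg) > 1)
        for (i in seq_along(gg)[-1]) uf$union(idx_of[[gg[1]]], idx_of[[gg[i]]])
    }
  }
  comp <- uf$components()
  fam_of <- setNames(sprintf("fam%05d", match(comp, sort(unique(comp)))),
                     all_ids)
  presence <- lapply(genomes, function(g) {
    ids <- unlist(strsplit(loci_by_genome[[g]]$genes, ",", fixed = TRUE))
    unique(fam_of[ids])
  })
  names(presence) <- genomes
  fams <- sort(unique(fam_of))
  pres_mat <- vapply(genomes, function(g) fams %in% presence[[g]],
                     logical(length(fams)))
  if (length(fams) == 1) pres_mat <- matrix(pres_mat, nrow = 1,
                                            dimnames = list(NULL, genomes))
  n_pres <- rowSums(pres_mat)
  cls <- ifelse(n_pres == length(genomes), "core",
                ifelse(n_pres == 1, "exclusive", "shared"))
  family_table <- data.frame(
    family = fams,
    presence = apply(pres_mat, 1, function(r) paste(genomes[r], collapse = ",")),
    n_genomes = n_pres, class = cls, stringsAsFactors = FALSE)
  venn_key <- apply(pres_mat, 1, function(r) paste(genomes[r], collapse = "&"))
  venn <- as.data.frame(table(venn_key), stringsAsFactors = FALSE)
  names(venn) <- c("region", "count")
  venn$percent <- round_half_up(100 * venn$count / length(fams), 1)
  structure(list(families = family_table, members = fam_of,
                 venn = venn, genomes = genomes,
                 totals = c(total = length(fams),
                            core = sum(cls == "core"),
                            shared = sum(cls == "shared"),
                            exclusive = sum(cls == "exclusive"))),
            class = "gene_families")
}

#' @export
print.gene_families <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<gene_families: %d total; %d core, %d shared, %d exclusive over %s>\n",
              t["total"], t["core"], t["shared"], t["exclusive"],
              paste(x$genomes, collapse = ", ")))
  invisible(x)
}

#' Gene density per megabase of assembly
#'
#' `d = n_genes / sum(contig lengths > 500 bp) * 1e6`, truncated to an
#' integer (contigs of at most 500 bp are excluded from the assembly size).
#'
#' @param n_genes number of genes.
#' @param contig_lengths numeric vector of contig lengths in bp.
#' @return integer genes per Mb.
#' @export
gene_density <- function(n_genes, contig_lengths) {
  stopifnot(n_genes >= 0)
  bp <- sum(contig_lengths[contig_lengths > 500])
  if (bp <= 0) sd_stop("no contig longer than 500 bp: gene density undefined")
  as.integer(n_genes / bp * 1e6)
}
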