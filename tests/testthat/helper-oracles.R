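# Independent brute-force oracles used to validate the fast implementations.

revcomp_str <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "",
                                           fixed = TRUE)[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# canonical-aware Hamming distance between two equal-length k-mers:
# min of the plain distance and the distance to the reverse complement
canon_hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  cr <- strsplit(revcomp_str(b), "", fixed = TRUE)[[1]]
  min(sum(ca != cb), sum(ca != cr))
}

# all-vs-all Hamming-1 scan with the exactly-two-per-wildcard-slot rule:
# a candidate pair (differing at one position) survives iff no third k-mer
# matches either member at that same wildcard slot (in either orientation).
oracle_het_pairs <- function(kmers) {
  k <- nchar(kmers[1])
  n <- length(kmers)
  mat <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  rcm <- do.call(rbind, strsplit(revcomp_str(kmers), "", fixed = TRUE))
  # wildcard keys of every k-mer at every position, canonical over strand
  slot_key <- function(chars_f, chars_r, p) {
    f <- chars_f; f[p] <- "N"
    r <- chars_r; r[k - p + 1] <- "N"
    fs <- paste(f, collapse = ""); rs <- paste(r, collapse = "")
    if (fs < rs || (fs == rs && p <= k - p + 1))
      paste0(fs, "@", p) else paste0(rs, "@", k - p + 1)
  }
  keys <- vector("list", n)
  for (i in seq_len(n))
    keys[[i]] <- vapply(seq_len(k), function(p) slot_key(mat[i, ], rcm[i, ], p),
                        character(1))
  slot_count <- table(unlist(keys))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    fi <- mat[i, ]
    for (j in (i + 1):n) {
      d_f <- sum(fi != mat[j, ])
      d_r <- sum(fi != rcm[j, ])
      if (min(d_f, d_r) != 1) next
      shared <- intersect(keys[[i]], keys[[j]])
      if (length(shared) >= 1 && any(slot_count[shared] == 2))
        pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  if (length(pairs) == 0)
    return(data.frame(i = integer(), j = integer()))
  out <- unique(do.call(rbind, pairs))
  data.frame(i = out[, 1], j = out[, 2])
}

# brute-force allele-aware mutation count for two equal-length genes with
# SNP-only variants: minimum Hamming distance over every joint assignment
# of one allele (reference or alternative) per variant site and strain.
oracle_allele_mutations <- function(seq_a, vars_a, seq_b, vars_b) {
  build_choices <- function(seq, vars) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    choices <- list()
    if (!is.null(vars) && nrow(vars) > 0) {
      for (p in unique(vars$pos))
        choices[[as.character(p)]] <-
          unique(c(chars[p], vars$alt[vars$pos == p]))
    }
    list(chars = chars, choices = choices)
  }
  assignments <- function(b) {
    ps <- as.integer(names(b$choices))
    if (length(ps) == 0) return(list(b$chars))
    grids <- expand.grid(b$choices, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grids)), function(r) {
      ch <- b$chars
      ch[ps] <- unlist(grids[r, ])
      ch
    })
  }
  aa <- assignments(build_choices(seq_a, vars_a))
  bb <- assignments(build_choices(seq_b, vars_b))
  best <- Inf
  for (x in aa) for (y in bb) best <- min(best, sum(x != y))
  best
}

# truth table of the module-completeness rule by explicit enumeration
oracle_module_complete <- function(size, present_mask) {
  n_present <- sum(present_mask)
  if (size == 2) n_present == 2 else n_present >= size - 1
}

# adjusted Rand index between two labelings of the same items
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
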