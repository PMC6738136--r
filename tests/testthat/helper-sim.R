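# Shared simulation shortcuts for the tests.

# variant-record data.frame (as read_vcf_records would produce) from the
# output of simulate_allele_depths
records_from_sim <- function(vc) {
  data.frame(contig = vc$contig, pos = vc$pos, ref = vc$ref, alts = vc$alt,
             dp = vc$dp, ad = paste(vc$ad_ref, vc$ad_alt, sep = ","),
             gt = vc$gt, stringsAsFactors = FALSE)
}

# one derived strain at the paper-like scale used for ploidy recovery checks
quick_strain <- function(ploidy, seed, length_bp = 1e6, n_genes = 600,
                         coverage = 50) {
  anc <- make_ancestor(length_bp, n_genes, c(1200, 250), seed = seed)
  derive_strain(anc, strain_spec(paste0("S", ploidy), ploidy,
                                 mean_coverage = coverage, seed = seed + 1))
}

# pipeline config for a written-out synthetic strain set
config_for_set <- function(set, dir, ...) {
  strains <- lapply(set$strains, function(s) list(
    contigs = file.path(dir, paste0(s$name, ".contigs.fasta")),
    genes = file.path(dir, paste0(s$name, ".genes.fasta")),
    gff = file.path(dir, paste0(s$name, ".genes.gff3")),
    vcf = file.path(dir, paste0(s$name, ".vcf")),
    kmers = file.path(dir, paste0(s$name, ".kmers.tsv"))))
  c(list(strains = strains, modules = file.path(dir, "modules.tsv")),
    list(...))
}
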