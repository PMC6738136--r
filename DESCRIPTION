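Package: straindiverge
Title: Intraspecific Genome Variation and Ploidy Analysis for Polyploid
    Microbial Eukaryote Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing conspecific strains of polyploid microbial
    eukaryotes from assembled contigs, variant calls and raw-read k-mer
    counts. Estimates ploidy two independent ways (fixed-mean Gaussian
    mixtures on allele-balance spectra with a uniform-component denoiser,
    and heterozygous k-mer pair "smudge" analysis), applies depth and
    allele-fraction variant filters, clusters predicted genes across
    strains into families with core/shared/exclusive classification and
    gene-density summaries, counts allele-aware pairwise gene mutations,
    and stratifies mutation rates by functional category with ANOVA,
    Kruskal-Wallis and Wilcoxon tests plus KEGG-style module completeness.
    Includes a synthetic polyploid multi-strain data generator with known
    ground truth that writes the standard formats (FASTA, GFF3, VCF, TSV)
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
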