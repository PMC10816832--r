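Package: hybridGWAS
Title: Mixed-Model GWAS and Breeding Analytics for Inter-Heterotic-Group
    Maize Hybrid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis for F1 hybrid populations built
    by crossing two complementary heterotic groups of inbred lines.  Deduces
    hybrid genotypes from inbred parents and a cross design, builds additive,
    dominance and four epistatic genomic kinship matrices, fits the polygenic
    background by restricted maximum likelihood (KinA and KinADE models),
    scans single-marker additive/dominance effects and pairwise epistatic
    effects with effective-marker Bonferroni thresholds, decomposes the
    phenotypic variance explained by significant loci, and provides breeding
    analytics: favorable-genotype accumulation regression, group allele
    frequencies, heterozygosity enrichment in phenotype tails,
    one-genotype-missing-site (OGMS) counting and mating-strategy comparison.
    Includes a seeded synthetic-data generator (diverged founder groups,
    partial factorial crosses, phenotypes with known additive, dominance and
    epistatic architecture) so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
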