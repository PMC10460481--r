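Package: kmerdepth
Title: Alignment-Free Estimation of Sequencing Depth and Error Rate
        from Marker k-mers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Estimates next-generation-sequencing depth of coverage and
        per-nucleotide sequencing error rate directly from unmapped reads by
        counting a pre-filtered set of unique, Hamming-isolated, well-spaced
        marker ("tag") k-mers together with deliberately mismatched "error"
        k-mers. Provides the list-building filters (multi-assembly uniqueness,
        Hamming-distance isolation, window spacing), set-restricted k-mer
        counting over FASTQ input, depth and error-rate estimators with a
        Poisson-tail cutoff that removes contaminant-inflated k-mers, and a
        read simulator with a substitution/N error model and foreign-DNA
        contamination mixtures for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, Biostrings, jsonlite, optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, Coverage, QualityControl, Software
RoxygenNote: 7.3.3
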