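# Builds inst/extdata/genome_quality_synthetic.tsv: a synthetic
# CheckM2-style quality table for a 96-culture sequencing run, with 94
# clean assemblies and exactly two failing the QC rule (contamination > 90
# or completeness < 50). Deterministic; run from the package root.
set.seed(20251230)
n <- 96
ids <- sprintf("culture%03d", seq_len(n))
completeness <- round(runif(n, 92, 100), 2)
contamination <- round(runif(n, 0, 4), 2)
# the two impure/partial cultures
completeness[37] <- 81.35; contamination[37] <- 95.21  # high contamination
completeness[62] <- 32.48; contamination[62] <- 1.07   # low completeness
tab <- data.frame(genome_id = ids, completeness = completeness,
                  contamination = contamination)
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "inst/extdata/genome_quality_synthetic.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
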