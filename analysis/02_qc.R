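#!/usr/bin/env Rscript
# Functional-barcode QC of the corrupted library copy against its clean
# source: reading frame, internal stop codons (vertebrate mitochondrial
# code) and alignment-based indel screening, scored against the generator's
# truth table. A clean COI product should show neither stops nor indels.

suppressMessages(library(leptobarcode))

lib <- read_metadata(read_fasta("results/library.fasta"),
                     "results/meta.tsv")
refs <- lib[lib$role == "reference", ]
corr <- read_fasta("results/library_corrupted.fasta")
truth <- read.table("results/truth_corrupted.tsv", header = TRUE,
                    sep = "\t")

qc <- qc_barcodes(corr, references = refs)
write.table(qc, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

stopifnot(identical(qc$id, truth$id))
clean <- !truth$has_stop & !truth$has_indel
cat(sprintf("records screened: %d (%d clean, %d stop, %d indel by truth)\n",
            nrow(qc), sum(clean), sum(truth$has_stop),
            sum(truth$has_indel)))
cat(sprintf("stop-codon sensitivity:  %.1f%%\n",
            100 * mean(qc$has_internal_stop[truth$has_stop])))
cat(sprintf("indel sensitivity:       %.1f%%\n",
            100 * mean(qc$indel_flag[truth$has_indel])))
cat(sprintf("false positives (clean): %d\n",
            sum(qc$has_internal_stop[clean] | qc$indel_flag[clean])))
cat(sprintf("modal length: %d bp; frames used: %s\n",
            as.integer(names(which.max(table(qc$length)))),
            paste(names(table(qc$frame)), collapse = ", ")))
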