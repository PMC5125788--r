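#!/usr/bin/env Rscript
# Identification of the 60 query barcodes: similarity search against the
# reference library, tiered rank assignment (species >= 98%, genus 92-98%,
# family 85-92%), and single-position diagnostic-character classification,
# both scored against the generator's truth table.

suppressMessages(library(leptobarcode))

lib <- read_metadata(read_fasta("results/library.fasta"),
                     "results/meta.tsv")
refs <- lib[lib$role == "reference", ]
queries <- read_metadata(read_fasta("results/queries.fasta"),
                         "results/meta.tsv")
truth <- read.table("results/truth_queries.tsv", header = TRUE, sep = "\t",
                    na.strings = c("NA", ""))

rows <- lapply(seq_len(nrow(queries)), function(i) {
  q <- queries[i, , drop = FALSE]
  assign_rank(best_hits(q, refs, k = 10))
})
assg <- do.call(rbind, rows)
write.table(assg, "results/assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

stopifnot(identical(assg$query_id, truth$id))
cat(sprintf("rank recovery: %.1f%% of %d queries\n",
            100 * mean(assg$rank == truth$expected_rank), nrow(assg)))
print(table(assigned = assg$rank, expected = truth$expected_rank))

consp <- truth$expected_rank == "species"
cat(sprintf("species-level accuracy on conspecific queries: %.1f%%\n",
            100 * mean(assg$rank[consp] == "species" &
                         assg$taxon[consp] == truth$species[consp])))

diagn <- learn_diagnostics(refs)
write.table(as.data.frame(diagn), "results/diagnostics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
calls <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
  classify_by_characters(queries[i, , drop = FALSE], diagn)
}))
write.table(calls, "results/character_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("diagnostic columns: %d over %d species (mean %.1f/species)\n",
            nrow(diagn), length(attr(diagn, "species")),
            nrow(diagn) / length(attr(diagn, "species"))))
char_ok <- !is.na(calls$call[consp]) &
  calls$call[consp] == truth$species[consp]
cat(sprintf("character-classifier accuracy on conspecific queries: %.1f%%\n",
            100 * mean(char_ok)))
cat(sprintf("(no-calls on conspecific queries: %d)\n",
            sum(is.na(calls$call[consp]))))
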