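#!/usr/bin/env Rscript
# Build the study dataset: a hierarchical synthetic COI reference library
# (5 families x 2 genera x 3 species x 4 specimens, 657 bp) plus 60 query
# barcodes covering the three identification situations (conspecific,
# novel species, novel genus), and a 30%-corrupted copy for the QC stage.
# Everything downstream (02-06) reads the files written here.

suppressMessages(library(leptobarcode))

out <- "results"
dir.create(out, showWarnings = FALSE)

lib <- simulate_library(taxonomy_spec(5, 2, 3, 4),
                        divergence_spec(0.005, 0.05, 0.10, 0.15,
                                        seq_length = 657),
                        seed = 42)
qs <- simulate_queries(lib$records, n_conspecific = 30,
                       n_novel_species = 15, n_novel_genus = 15, seed = 43)
corr <- inject_artifacts(lib$records[lib$records$role == "reference", ],
                         indel_rate = 0.3, stop_rate = 0.3, seed = 44)

write_fasta(lib$records, file.path(out, "library.fasta"))
write_fasta(qs$records, file.path(out, "queries.fasta"))
write_fasta(corr$records, file.path(out, "library_corrupted.fasta"))
write_metadata(rbind(lib$records, qs$records), file.path(out, "meta.tsv"))
for (nm in c("library", "queries", "corrupted")) {
  tt <- switch(nm, library = lib$truth, queries = qs$truth,
               corrupted = corr$truth)
  write.table(tt, file.path(out, paste0("truth_", nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

cat(sprintf("library: %d records (%d references + outgroup), %d bp\n",
            nrow(lib$records), sum(lib$records$role == "reference"),
            unique(nchar(lib$records$sequence))))
cat(sprintf("queries: %d (%s)\n", nrow(qs$records),
            paste(names(table(qs$truth$expected_rank)),
                  table(qs$truth$expected_rank), collapse = ", ")))
cat(sprintf("corrupted copy: %d with stops, %d with indels\n",
            sum(corr$truth$has_stop), sum(corr$truth$has_indel)))
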