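#!/usr/bin/env Rscript
# Neighbour-joining tree of references + queries from uncorrected
# p-distances, 100 column-resampling bootstrap replicates, rooted on the
# synthetic outgroup; then species-level monophyly on the unrooted tree.
# (100 replicates keep this driver quick; the pipeline default is 1000.)

suppressMessages(library(leptobarcode))

lib <- read_metadata(read_fasta("results/library.fasta"),
                     "results/meta.tsv")
queries <- read_metadata(read_fasta("results/queries.fasta"),
                         "results/meta.tsv")
pool <- rbind(lib, queries)

tr <- bootstrap_support(pool, n_reps = 100, seed = 45)
write_newick(tr, "results/nj_bootstrap.nwk")
rt <- root_on_outgroup(tr, "Outgroup1")
write_newick(rt, "results/nj_rooted.nwk")

# species groups include conspecific queries (they are members of the
# species); novel-lineage queries branch beside the clusters, not inside
refs <- lib[lib$role == "reference", ]
mono <- vapply(sort(unique(refs$species)), function(sp) {
  is_monophyletic(tr, pool$id[!is.na(pool$species) & pool$species == sp])
}, logical(1))
write.table(data.frame(species = names(mono), monophyletic = mono),
            "results/monophyly.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

supp <- suppressWarnings(as.numeric(tr$node.label))
supp <- supp[!is.na(supp)]
cat(sprintf("tree over %d tips; %d internal edges with supports\n",
            length(tr$tip.label), length(supp)))
cat(sprintf("reference species monophyletic: %d/%d\n", sum(mono),
            length(mono)))
cat(sprintf("median bootstrap support: %.0f%%; support >= 95%%: %d edges\n",
            median(supp), sum(supp >= 95)))
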