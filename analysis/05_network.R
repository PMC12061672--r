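#!/usr/bin/env Rscript
# Stage 5: the haplotype network.
#
# One representative per haplotype (from the gapped alignment of stage 4),
# pairwise nucleotide changes (substitutions + one change per indel block),
# minimum spanning tree with equally parsimonious alternative links, and the
# central haplotype.

suppressPackageStartupMessages(library(dmcc))
aligned <- read_fasta("results/coicoii_aligned.fa", marker = "COICOII")
assignments <- read.delim("results/haplotype_assignments.tsv")

first <- !duplicated(assignments$name)
reps <- aligned$residues[match(assignments$sample_id[first],
                               aligned$sample_id)]
labels <- assignments$name[first]
sizes <- as.integer(table(assignments$name)[labels])

m <- pairwise_changes(reps)
dimnames(m) <- list(labels, labels)
net <- build_network(m, node_labels = labels, node_sizes = sizes)
edges <- network_edges(net)
write.table(edges, "results/network_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(nodes = net$nodes, edges = edges),
                     "results/network.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("%d haplotype nodes, %d primary edges, %d secondary link(s)\n",
            nrow(net$nodes), sum(edges$is_primary), sum(!edges$is_primary)))
cat(sprintf("central haplotype: %s\n", central_haplotype(net)))
cat(sprintf("primary edge weights (nucleotide changes): %s\n",
            paste(sort(edges$weight[edges$is_primary]), collapse = ", ")))
cat("wrote results/network_edges.tsv, results/network.json\n")
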