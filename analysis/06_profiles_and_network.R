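#!/usr/bin/env Rscript
# Stage 6: subfamily profile HMMs from column slices of the master
# alignment, symmetrised Kullback-Leibler distances between them, the NJ
# tree of the groups, and the all-pairs similarity network.

library(domevol)

out <- "results/analysis/06_profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
aln <- alignment_matrix(read_fasta("results/analysis/01_simdata/alignment.fasta"))
groups <- read.delim("results/analysis/01_simdata/groups.tsv")
gmap <- setNames(groups$group, groups$taxon)

hmms <- lapply(split(groups$taxon, groups$group), function(tx)
  build_hmm(aln[tx, , drop = FALSE]))
tr <- hmm_tree(hmms)
ape::write.tree(tr, file.path(out, "hmm_nj_tree.nwk"))
write.table(round(attr(tr, "distances"), 4),
            file.path(out, "hmm_kl_distances.tsv"), sep = "\t", quote = FALSE)
cat("Pairwise symmetrised KL distances between group HMMs:\n")
print(round(attr(tr, "distances"), 3))
cat("NJ tree of groups:", ape::write.tree(tr), "\n")

seqs <- apply(aln, 1, paste, collapse = "")
net <- similarity_network(seqs, groups = gmap)
export_network(net, graphml_path = file.path(out, "network.graphml"),
               edgelist_path = file.path(out, "network_edges.tsv"))
g1 <- gmap[net$edges$id1]; g2 <- gmap[net$edges$id2]
cat(sprintf("Similarity network: %d nodes, %d edges at e <= %.0e; median within-group e = %.2e, between-group e = %.2e\n",
            nrow(net$nodes), nrow(net$edges), net$evalue_cutoff,
            median(net$edges$evalue[g1 == g2]),
            median(net$edges$evalue[g1 != g2])))
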