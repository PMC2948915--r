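#!/usr/bin/env Rscript
# Stage 3: guilt-by-association gene-context analysis.
#
# Anchored on the motif-scan hits from stage 2, retrieves the three upstream
# and three downstream genes of every anchor gene across all genomes, counts
# cross-genome (anchor cluster, neighbor cluster) associations ranked by
# lineage conservation, predicts operons (same-strand runs, gaps <= 100 bp)
# and divergently encoded flanking genes, and reports domain fusions.
# Expected finding: the planted arCOG_ublA ~ arCOG_partnerX association tops
# the ranking, present in 8 of 10 genomes across all five lineages.

suppressMessages(library(ublcontext))

out <- "results/analysis"
hits <- utils::read.delim(file.path(out, "motif_hits.tsv"))
anchors <- hits$cluster_id
assignments <- read_cluster_table(file.path(out, "clusters.tsv"))
lineage_map <- read_lineage_map(file.path(out, "lineages.tsv"))

gfils <- list.files(file.path(out, "genomes"), pattern = "\\.gff3$",
                    full.names = TRUE)
genomes <- lapply(gfils, function(f)
  read_genome(f, sub("\\.gff3$", ".faa", f),
              genome_id = sub("\\.gff3$", "", basename(f))))
for (i in seq_along(genomes))
  genomes[[i]]$lineage <- lineage_map[[genomes[[i]]$genome_id]]

nbs <- list()
for (g in genomes) {
  sel <- assignments$genome_id == g$genome_id &
    assignments$cluster_id %in% anchors
  for (gene in unique(assignments$gene_id[sel]))
    nbs[[length(nbs) + 1L]] <- extract_neighborhood(g, gene, k = 3)
}
assoc <- count_associations(nbs, assignments, lineage_map)
flat <- assoc
flat$genomes <- vapply(assoc$genomes, paste, character(1), collapse = ",")
flat$lineages <- vapply(assoc$lineages, paste, character(1), collapse = ",")
utils::write.table(flat, file.path(out, "assoc.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message("Neighborhoods around ", length(nbs), " anchor genes; top associations:")
top <- utils::head(assoc[assoc$neighbor_cluster != "UNASSIGNED", ], 3)
for (i in seq_len(nrow(top)))
  message(sprintf("  %s ~ %s: %d genomes, %d lineages, %d occurrences",
                  top$anchor_cluster[i], top$neighbor_cluster[i],
                  top$n_genomes[i], top$n_lineages[i],
                  top$occurrence_count[i]))

ops <- do.call(rbind, lapply(genomes, function(g)
  predict_operons(g$replicons[[1]], d_max = 100)))
fus <- detect_fusions(assignments)
fus_flat <- fus
fus_flat$domain_clusters <- vapply(fus$domain_clusters, paste, character(1),
                                   collapse = ",")
utils::write.table(fus_flat, file.path(out, "fusions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sum(ops$n_genes >= 2), " multi-gene operons; ",
        nrow(fus), " fusion candidates (multi-domain genes).")
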