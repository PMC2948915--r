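#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset with known ground truth.
#
# Ten single-replicon genomes (200 genes each, five archaeal lineages) over a
# background pool of 100 ortholog clusters, with one planted anchor-neighbor
# gene association at frequency 0.8; four cluster alignments, two of which
# are small families with strongly conserved C-terminal doublets (GG and CC)
# and two decoys (unconserved, or conserved but > 200 aa); and one alignment
# evolved under JTT on a known 6-taxon tree. Everything downstream
# (02-05) consumes the files written here.

suppressMessages(library(ublcontext))

seed <- 1L
out <- "results/analysis"
dir.create(file.path(out, "genomes"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "alignments"), showWarnings = FALSE)

cfg <- demo_config(seed)
sim <- generate_genomes(cfg$sim)

for (g in sim$genomes)
  write_genome(g, file.path(out, "genomes", paste0(g$genome_id, ".gff3")),
               file.path(out, "genomes", paste0(g$genome_id, ".faa")))
write_cluster_table(sim$assignments, file.path(out, "clusters.tsv"))
utils::write.table(
  data.frame(genome_id = names(sim$lineage_map),
             lineage = unname(sim$lineage_map)),
  file.path(out, "lineages.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

fams <- lapply(cfg$motif_families, function(mf)
  generate_motif_family(mf$cluster_id, mf$n_members, mf$length, mf$motif,
                        mf$conservation,
                        seed = seed + match(mf$cluster_id,
                          vapply(cfg$motif_families, `[[`, character(1),
                                 "cluster_id"))))
for (f in fams)
  write_alignment(f, file.path(out, "alignments", paste0(f$cluster_id, ".fa")))

tree_aln <- evolve_alignment(cfg$tree_spec, cfg$tree_sites, seed = seed,
                             cluster_id = "tree_family")
write_alignment(tree_aln, file.path(out, "alignments", "tree_family.fa"))

truth <- sim$truth$associations[[1]]
writeLines(c(
  sprintf("planted association: %s ~ %s", truth$anchor, truth$neighbor),
  sprintf("planted in %d genomes: %s", length(truth$genomes),
          paste(sort(truth$genomes), collapse = ", ")),
  sprintf("planted GG family: arCOG_ublA (conservation 0.95, 90 aa)"),
  sprintf("planted CC family: arCOG_ublB (conservation 0.90, 110 aa)"),
  sprintf("planted absence: arCOG_ublB missing from G04, G08"),
  sprintf("tree: %s", cfg$tree_spec)),
  file.path(out, "ground_truth.txt"))

message("Simulated ", length(sim$genomes), " genomes, ",
        nrow(sim$assignments), " cluster assignments, ",
        length(fams) + 1L, " alignments -> ", out)
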