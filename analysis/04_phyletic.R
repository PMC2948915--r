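#!/usr/bin/env Rscript
# Stage 4: phyletic (presence/absence) patterns.
#
# Builds the cluster x genome presence matrix in lineage-map order and asks
# the two questions the comparative analysis needs: from which genomes is
# each candidate Ubl family absent, and which clusters show a distribution
# complementary to a given family. Expected finding: arCOG_ublB is absent
# from exactly G04 and G08 (the planted absence); arCOG_ublA is confined to
# the 8 genomes carrying the planted association.

suppressMessages(library(ublcontext))

out <- "results/analysis"
assignments <- read_cluster_table(file.path(out, "clusters.tsv"))
lineage_map <- read_lineage_map(file.path(out, "lineages.tsv"))
hits <- utils::read.delim(file.path(out, "motif_hits.tsv"))

mat <- build_matrix(assignments, names(lineage_map))
write_phyletic_matrix(mat, file.path(out, "phyletic_matrix.tsv"))

queried <- intersect(hits$cluster_id, mat$clusters)
absences <- absence_report(mat, queried)
utils::write.table(
  data.frame(cluster_id = names(absences),
             absent_genomes = vapply(absences, paste, character(1),
                                     collapse = ",")),
  file.path(out, "absences.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

message("Phyletic matrix: ", length(mat$clusters), " clusters x ",
        length(mat$genomes), " genomes")
for (cl in names(absences))
  message(sprintf("  %s absent from: %s", cl,
                  if (length(absences[[cl]]))
                    paste(absences[[cl]], collapse = ", ") else "(none)"))

# complementary-pattern query relative to the first queried family
if (length(queried)) {
  a <- absences[[queried[1]]]
  if (length(a)) {
    comp <- pattern_query(mat, required_present = a,
                          required_absent = setdiff(mat$genomes, a))
    message("clusters complementary to ", queried[1], ": ",
            if (length(comp)) paste(comp, collapse = ", ") else "(none)")
  }
}
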