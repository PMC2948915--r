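# Synthetic-data generators with known ground truth. Every generator is a
# pure function of its configuration and seed; the truth objects they return
# are sufficient to compute the exact expected output of the motif scan, the
# neighborhood analysis and the phyletic queries on the generated data.

.random_protein <- function(len) {
  paste(sample(AA_LEVELS, len, replace = TRUE), collapse = "")
}

#' Simulation configuration for synthetic genomes
#'
#' Defaults emulate a compact ortholog-cluster dataset: 10 genomes of 200
#' genes each over a background pool of 100 clusters, with gene lengths
#' uniform on 80-400 aa (so a 200 aa size filter has both sides populated)
#' and intergenic gaps uniform on 0-200 bp (so a 100 bp operon threshold
#' splits some same-strand runs and not others). Genomes are spread over five
#' archaeal lineage labels.
#'
#' @param seed Integer seed; every draw derives from it.
#' @param n_genomes,genes_per_genome,n_clusters Dataset dimensions.
#' @param planted_associations List of lists with elements `anchor`,
#'   `neighbor`, `f` (frequency in (0,1]), `max_offset` (<= neighborhood k).
#' @param planted_absences List of lists with `cluster` and `absent` (genome
#'   ids the cluster must be missing from); the cluster is added to every
#'   other genome.
#' @param lineages Lineage label per genome (recycled); default five archaeal
#'   orders.
#' @param bernoulli If `TRUE`, association planting draws each genome with
#'   probability `f` (distributional mode); default `FALSE` plants in exactly
#'   `ceiling(f * n_genomes)` genomes so expected counts are exact.
#' @param circular If `TRUE`, replicons are circular (exercises neighborhood
#'   wrap-around).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_genomes = 10L, genes_per_genome = 200L,
                       n_clusters = 100L, planted_associations = list(),
                       planted_absences = list(),
                       lineages = c("Sulfolobales", "Halobacteria",
                                    "Thermococcales", "Methanococcales",
                                    "Thermoproteales"),
                       bernoulli = FALSE, circular = FALSE) {
  for (pa in planted_associations) {
    stopifnot(pa$f > 0, pa$f <= 1, pa$max_offset >= 1)
    if (pa$f * n_genomes < 1)
      warning("association frequency implies < 1 genome; one genome used")
  }
  structure(list(seed = as.integer(seed), n_genomes = n_genomes,
                 genes_per_genome = genes_per_genome, n_clusters = n_clusters,
                 planted_associations = planted_associations,
                 planted_absences = planted_absences,
                 lineages = rep_len(lineages, n_genomes),
                 bernoulli = bernoulli, circular = circular),
            class = "SimConfig")
}

#' Generate synthetic genomes with planted neighborhood associations
#'
#' Each genome is one replicon of `genes_per_genome` genes with random
#' strands, lengths and intergenic gaps; every gene carries one background
#' cluster assignment drawn uniformly from the pool. For each planted
#' association, an anchor gene and a neighbor gene within `max_offset`
#' positions of it are relabeled with the association's clusters in the
#' selected genomes (exactly `ceiling(f * n)` genomes, or Bernoulli draws in
#' `bernoulli` mode). Planted absences add the named cluster as an extra
#' (multi-domain) assignment on one random gene of every genome outside the
#' absence set.
#'
#' @param config A [sim_config()].
#' @return List: `genomes` (list of [genome()]), `assignments` (data.frame),
#'   `lineage_map` (named vector), and `truth` recording exact placements.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  genome_ids <- sprintf("G%02d", seq_len(config$n_genomes))
  lineage_map <- stats::setNames(config$lineages, genome_ids)
  pool <- sprintf("bg%04d", seq_len(config$n_clusters))
  genomes <- vector("list", config$n_genomes)
  assign_rows <- vector("list", config$n_genomes)
  truth_assoc <- list()
  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[gi]
    ng <- config$genes_per_genome
    aa_len <- sample(80:400, ng, replace = TRUE)
    gaps <- sample(0:200, ng, replace = TRUE)
    nt_len <- 3L * (aa_len + 1L)
    starts <- cumsum(c(1L, nt_len[-ng] + gaps[-ng] + 1L))
    df <- data.frame(gene_id = sprintf("%s_g%04d", gid, seq_len(ng)),
                     start = starts, end = starts + nt_len - 1L,
                     strand = sample(c("+", "-"), ng, replace = TRUE),
                     protein = vapply(aa_len, .random_protein, character(1)),
                     stringsAsFactors = FALSE)
    clusters <- sample(pool, ng, replace = TRUE)
    genomes[[gi]] <- genome(gid, list(replicon(
      paste0(gid, "_chr"), df,
      topology = if (config$circular) "circular" else "linear")),
      lineage = lineage_map[[gid]])
    assign_rows[[gi]] <- data.frame(genome_id = gid, gene_id = df$gene_id,
                                    cluster_id = clusters,
                                    dom_start = 1L, dom_end = aa_len,
                                    stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, assign_rows)
  # plant associations by relabeling cluster assignments
  used <- list()  # per genome, gene indices already claimed by a planting
  for (pa in config$planted_associations) {
    chosen <- if (config$bernoulli) {
      genome_ids[stats::runif(config$n_genomes) < pa$f]
    } else {
      sample(genome_ids, max(1L, ceiling(pa$f * config$n_genomes)))
    }
    placements <- list()
    for (gid in chosen) {
      ng <- config$genes_per_genome
      taken <- used[[gid]]
      repeat {
        a_idx <- sample((pa$max_offset + 1L):(ng - pa$max_offset), 1L)
        off <- sample(c(-(pa$max_offset:1), 1:pa$max_offset), 1L)
        n_idx <- a_idx + off
        if (!any(c(a_idx, n_idx) %in% taken)) break
      }
      used[[gid]] <- c(taken, a_idx, n_idx)
      a_gene <- sprintf("%s_g%04d", gid, a_idx)
      n_gene <- sprintf("%s_g%04d", gid, n_idx)
      assignments$cluster_id[assignments$genome_id == gid &
                             assignments$gene_id == a_gene] <- pa$anchor
      assignments$cluster_id[assignments$genome_id == gid &
                             assignments$gene_id == n_gene] <- pa$neighbor
      placements[[gid]] <- list(anchor_gene = a_gene, neighbor_gene = n_gene,
                                offset = off)
    }
    truth_assoc[[paste(pa$anchor, pa$neighbor, sep = "~")]] <-
      list(anchor = pa$anchor, neighbor = pa$neighbor,
           genomes = chosen, placements = placements)
  }
  # plant phyletic absences as extra assignments on existing genes
  truth_abs <- list()
  for (pb in config$planted_absences) {
    present <- setdiff(genome_ids, pb$absent)
    for (gid in present) {
      gene <- sprintf("%s_g%04d", gid,
                      sample(config$genes_per_genome, 1L))
      len <- nchar(genome_genes(genomes[[match(gid, genome_ids)]])$protein[
        match(gene, genome_genes(genomes[[match(gid, genome_ids)]])$gene_id)])
      assignments <- rbind(assignments,
                           data.frame(genome_id = gid, gene_id = gene,
                                      cluster_id = pb$cluster,
                                      dom_start = 1L, dom_end = len,
                                      stringsAsFactors = FALSE))
    }
    truth_abs[[pb$cluster]] <- list(cluster = pb$cluster,
                                    absent = sort(pb$absent),
                                    present = sort(present))
  }
  rownames(assignments) <- NULL
  list(genomes = genomes, assignments = assignments,
       lineage_map = lineage_map,
       truth = list(associations = truth_assoc, absences = truth_abs))
}

#' Generate a protein family alignment with a planted C-terminal doublet
#'
#' Members are random proteins of identical length (a gap-free alignment);
#' exactly `round(conservation * n_members)` members (deterministic count,
#' chosen by a seeded draw) have their final two residues set to `motif`,
#' the rest end in random residues that do not spell any of the standard
#' doublets (GG/CC), so the planted conservation is exact.
#'
#' @param cluster_id Cluster id for the alignment.
#' @param n_members Number of member sequences.
#' @param length Sequence length in amino acids (>= 3).
#' @param motif Two-residue terminal motif, e.g. `"GG"` or `"CC"`.
#' @param conservation Fraction of members carrying the motif, in [0, 1].
#' @param seed Integer seed.
#' @return A [cluster_alignment()] with attribute `"truth"` (which members
#'   carry the motif).
#' @export
generate_motif_family <- function(cluster_id, n_members, length, motif,
                                  conservation, seed = 1L) {
  stopifnot(length >= 3L, nchar(motif) == 2L,
            conservation >= 0, conservation <= 1)
  set.seed(seed)
  n_mot <- round(conservation * n_members)
  carriers <- sort(sample(n_members, n_mot))
  mchars <- strsplit(toupper(motif), "")[[1L]]
  non_doublet_tail <- function() {
    repeat {
      tail2 <- sample(AA_LEVELS, 2L, replace = TRUE)
      if (!paste(tail2, collapse = "") %in% c("GG", "CC", motif))
        return(tail2)
    }
  }
  seqs <- vapply(seq_len(n_members), function(i) {
    body <- sample(AA_LEVELS, length - 2L, replace = TRUE)
    tail2 <- if (i %in% carriers) mchars else non_doublet_tail()
    paste(c(body, tail2), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s_m%03d", cluster_id, seq_len(n_members))
  aln <- cluster_alignment(cluster_id, seqs)
  attr(aln, "truth") <- list(carriers = carriers, motif = motif,
                             conservation_exact = n_mot / n_members)
  aln
}

#' Evolve a gap-free protein alignment along a tree under JTT
#'
#' The root sequence is drawn from the JTT equilibrium frequencies and
#' mutated along each branch according to the JTT transition probabilities,
#' site by site (no indels, no rate heterogeneity).
#'
#' @param tree_newick Newick string or `phylo` with branch lengths.
#' @param L Number of sites.
#' @param seed Integer seed.
#' @param cluster_id Id for the resulting alignment.
#' @return A [cluster_alignment()] over the tree's tips.
#' @export
evolve_alignment <- function(tree_newick, L, seed = 1L, cluster_id = "sim") {
  phy <- if (inherits(tree_newick, "phylo")) tree_newick
         else ape::read.tree(text = tree_newick)
  stopifnot(!is.null(phy$edge.length))
  set.seed(seed)
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  phy <- ape::reorder.phylo(phy, "cladewise")   # parents before children
  states <- matrix(NA_integer_, ntot, L)
  root <- ntip + 1L
  pi0 <- jtt_frequencies()
  states[root, ] <- sample.int(20L, L, replace = TRUE, prob = pi0)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    P <- jtt_transition_prob(phy$edge.length[e])
    parent_states <- states[p, ]
    child <- integer(L)
    for (s in 1:20) {
      idx <- which(parent_states == s)
      if (length(idx))
        child[idx] <- sample.int(20L, length(idx), replace = TRUE,
                                 prob = P[s, ])
    }
    states[ch, ] <- child
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(AA_LEVELS[states[i, ]], collapse = ""), character(1))
  names(seqs) <- phy$tip.label
  cluster_alignment(cluster_id, seqs)
}
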