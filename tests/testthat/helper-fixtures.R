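AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# write a small GFF3 + protein FASTA pair; genes is a data.frame with
# gene_id/start/end/strand/protein, record order taken as given
write_gff3_fixture <- function(genes,
                               dir = withr::local_tempdir(
                                 .local_envir = parent.frame()),
                               replicon_id = "chr1", circular = FALSE) {
  gff <- file.path(dir, "toy.gff3")
  faa <- file.path(dir, "toy.faa")
  rep_len <- if (nrow(genes)) max(genes$end) else 1000L
  lines <- c("##gff-version 3",
             sprintf("%s\ttoy\tregion\t1\t%d\t.\t+\t.\tID=%s%s",
                     replicon_id, rep_len, replicon_id,
                     if (circular) ";Is_circular=true" else ""))
  for (i in seq_len(nrow(genes)))
    lines <- c(lines, sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                              replicon_id, genes$start[i], genes$end[i],
                              genes$strand[i], genes$gene_id[i]))
  writeLines(lines, gff)
  with_prot <- genes[nzchar(genes$protein), , drop = FALSE]
  writeLines(as.vector(rbind(paste0(">", with_prot$gene_id),
                             with_prot$protein)), faa)
  list(gff = gff, faa = faa)
}

toy_genes <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             start = c(10L, 400L, 900L), end = c(300L, 800L, 1400L),
             strand = c("+", "-", "+"),
             protein = c("MKLV*", "MAACDE", "MGG"),
             stringsAsFactors = FALSE)
}

# replicon of n genes with given strands and intergenic gaps (length n-1);
# each gene 300 bp, first starts at 1
toy_replicon <- function(strands, gaps = rep(50L, length(strands) - 1L),
                         topology = "linear", id = "chrT") {
  n <- length(strands)
  starts <- integer(n); starts[1] <- 1L
  if (n > 1) for (i in 2:n) starts[i] <- starts[i - 1] + 300L + gaps[i - 1]
  replicon(id, data.frame(gene_id = paste0("t", seq_len(n)),
                          start = starts, end = starts + 299L,
                          strand = strands, protein = "",
                          stringsAsFactors = FALSE),
           topology = topology)
}

# random gap-containing alignment for consensus property tests
random_alignment <- function(n_seq, n_col, gap_prob = 0.2,
                             cluster_id = "rand") {
  m <- matrix(sample(c(AA20, rep("-", round(20 * gap_prob / (1 - gap_prob)))),
                     n_seq * n_col, replace = TRUE), n_seq, n_col)
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- paste0("s", seq_len(n_seq))
  cluster_alignment(cluster_id, seqs)
}

# independent per-column consensus oracle: plain counting with table()
oracle_consensus <- function(aln, plurality_min) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  n <- nrow(m)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gap_frac <- sum(col == "-") / n
    res_tab <- table(col[col != "-"])
    if (!length(res_tab)) return(list(ch = "-", cons = 0, gf = gap_frac))
    best <- sort(names(res_tab)[res_tab == max(res_tab)])[1]
    frac <- res_tab[[best]] / n
    ch <- if (frac >= plurality_min) best
          else if (gap_frac > 0.5) "-" else tolower(best)
    list(ch = ch, cons = frac, gf = gap_frac)
  })
  list(consensus = vapply(res, `[[`, character(1), "ch"),
       conservation = vapply(res, `[[`, numeric(1), "cons"),
       gap_fraction = vapply(res, `[[`, numeric(1), "gf"))
}

# index-arithmetic neighborhood oracle: expected neighbor gene indices
# (0-based) for an anchor at 0-based index a on an n-gene replicon
oracle_neighborhood <- function(n, a, k, circular) {
  if (!circular) {
    up <- a - seq_len(k); up <- up[up >= 0]
    down <- a + seq_len(k); down <- down[down <= n - 1]
  } else {
    up <- (a - seq_len(k)) %% n
    down <- (a + seq_len(k)) %% n
  }
  setdiff(unique(c(up, down)), a)
}

# exhaustive likelihood oracle for the unrooted 4-taxon tree
# ((t1,t2)5,(t3,t4)6) with edges tA,tB,t56,tC,tD; states NA = gap
oracle_quartet_lik <- function(states, lens) {
  pi0 <- jtt_frequencies()
  PA <- jtt_transition_prob(lens[1]); PB <- jtt_transition_prob(lens[2])
  P56 <- jtt_transition_prob(lens[3])
  PC <- jtt_transition_prob(lens[4]); PD <- jtt_transition_prob(lens[5])
  tipf <- function(P, i, s) if (is.na(s)) 1 else P[i, s]
  tot <- 0
  for (i in 1:20) for (j in 1:20)
    tot <- tot + pi0[i] * tipf(PA, i, states[1]) * tipf(PB, i, states[2]) *
      P56[i, j] * tipf(PC, j, states[3]) * tipf(PD, j, states[4])
  unname(log(tot))
}

quartet_tree <- function(lens) {
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  tr <- ape::unroot(tr)
  # unrooted edges: (5,1),(5,2),(5,6),(6,3),(6,4) after unroot
  ord <- apply(tr$edge, 1, paste, collapse = "-")
  want <- c("5-1" = lens[1], "5-2" = lens[2], "5-6" = lens[3],
            "6-3" = lens[4], "6-4" = lens[5])
  tr$edge.length <- unname(want[ord])
  tr
}

same_topology <- function(a, b) {
  isTRUE(ape::all.equal.phylo(ape::unroot(a), ape::unroot(b),
                              use.edge.length = FALSE))
}

# map each edge of an unrooted tree to its canonical tip-set split key
# (side not containing the alphabetically first taxon), value = edge length
edge_lengths_by_split <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(po$tip.label)
  below <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- po$tip.label[i]
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1]]] <- c(below[[po$edge[e, 1]]], below[[po$edge[e, 2]]])
  anchor <- sort(po$tip.label)[1]
  keys <- vapply(seq_len(nrow(po$edge)), function(e) {
    side <- below[[po$edge[e, 2]]]
    if (anchor %in% side) side <- setdiff(po$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  stats::setNames(po$edge.length, keys)
}

# all 15 binary unrooted topologies on 5 taxa
all_topologies_5 <- function(labels) {
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = labels)
  lapply(trees, function(t) { t$edge.length <- rep(0.3, nrow(t$edge)); t })
}
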