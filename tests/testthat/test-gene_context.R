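test_that("linear neighborhoods truncate at replicon ends", {
  r <- toy_replicon(rep("+", 20))
  g <- genome("G1", list(r), lineage = "Sulfolobales")
  nb <- extract_neighborhood(g, "t11", k = 3)   # 0-based index 10
  expect_identical(nb$upstream$index, c(9L, 8L, 7L))
  expect_identical(nb$downstream$index, c(11L, 12L, 13L))

  nb0 <- extract_neighborhood(g, "t1", k = 3)
  expect_identical(nrow(nb0$upstream), 0L)
  expect_identical(nb0$downstream$index, 1:3)

  expect_error(extract_neighborhood(g, "nope"), "not found")
})

test_that("circular neighborhoods wrap without duplicating genes", {
  r <- toy_replicon(rep("+", 5), topology = "circular")
  g <- genome("G1", list(r))
  nb <- extract_neighborhood(g, "t1", k = 3)    # anchor index 0 of 5
  got <- c(nb$upstream$index, nb$downstream$index)
  expect_length(got, 4L)                         # 4 distinct neighbors
  expect_false(any(duplicated(got)))
  expect_false(0L %in% got)
  expect_setequal(got, oracle_neighborhood(5, 0, 3, circular = TRUE))
})

test_that("neighborhood membership equals the index-arithmetic oracle", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(3:25, 1)
    k <- sample(1:4, 1)
    circ <- sample(c(TRUE, FALSE), 1)
    a <- sample(n, 1) - 1L
    r <- toy_replicon(sample(c("+", "-"), n, TRUE),
                      topology = if (circ) "circular" else "linear")
    g <- genome("G", list(r))
    nb <- extract_neighborhood(g, paste0("t", a + 1L), k = k)
    got <- c(nb$upstream$index, nb$downstream$index)
    expect_false(any(duplicated(got)))
    expect_setequal(got, oracle_neighborhood(n, a, k, circ))
  }
})

make_assign <- function(genome_id, gene_ids, clusters) {
  data.frame(genome_id = genome_id, gene_id = gene_ids, cluster_id = clusters,
             dom_start = NA_integer_, dom_end = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("association counting dedupes genomes but keeps raw occurrences", {
  # one genome, two anchor paralogs (t2, t6), both adjacent to cluster X
  r <- toy_replicon(rep("+", 8))
  g <- genome("G1", list(r), lineage = "Halobacteria")
  assign <- make_assign("G1", paste0("t", 1:8),
                        c("X", "ANC", "bg1", "bg2", "X", "ANC", "bg3", "bg4"))
  nbs <- list(extract_neighborhood(g, "t2", k = 1),
              extract_neighborhood(g, "t6", k = 1))
  lm <- c(G1 = "Halobacteria")
  rec <- count_associations(nbs, assign, lm)
  x <- rec[rec$neighbor_cluster == "X", ]
  expect_identical(x$n_genomes, 1L)
  expect_identical(x$occurrence_count, 2L)
  expect_identical(x$n_lineages, 1L)
  # conservation of counts: total occurrences == total assigned neighbors
  expect_identical(sum(rec$occurrence_count),
                   sum(vapply(nbs, function(nb)
                     nrow(nb$upstream) + nrow(nb$downstream), integer(1))))
})

test_that("unassigned neighbors fall into the UNASSIGNED pseudo-cluster", {
  r <- toy_replicon(rep("+", 3))
  g <- genome("G1", list(r))
  assign <- make_assign("G1", c("t2"), c("ANC"))
  nbs <- list(extract_neighborhood(g, "t2", k = 1))
  rec <- count_associations(nbs, assign, c(G1 = "Sulfolobales"))
  expect_identical(unique(rec$neighbor_cluster), "UNASSIGNED")
  expect_identical(sum(rec$occurrence_count), 2L)
})

test_that("planted associations surface with the exact genome count", {
  cfg <- sim_config(seed = 9L, n_genomes = 10L, genes_per_genome = 60L,
                    n_clusters = 50L,
                    planted_associations = list(
                      list(anchor = "ANC", neighbor = "NBR",
                           f = 0.8, max_offset = 3L)))
  sim <- generate_genomes(cfg)
  expect_length(sim$truth$associations$`ANC~NBR`$genomes, 8L)
  nbs <- list()
  for (g in sim$genomes) {
    sel <- sim$assignments$genome_id == g$genome_id &
      sim$assignments$cluster_id == "ANC"
    for (gene in sim$assignments$gene_id[sel])
      nbs[[length(nbs) + 1L]] <- extract_neighborhood(g, gene, k = 3)
  }
  rec <- count_associations(nbs, sim$assignments, sim$lineage_map)
  expect_identical(rec$neighbor_cluster[1L], "NBR")
  expect_identical(rec$n_genomes[1L], 8L)
})

test_that("lineage conservation is the distinct-lineage count", {
  lm <- c(G1 = "Sulfolobales", G2 = "Sulfolobales", G3 = "Sulfolobales",
          G4 = "Halobacteria")
  expect_identical(
    score_lineage_conservation(list(genomes = c("G1", "G2", "G3")), lm), 1L)
  expect_identical(
    score_lineage_conservation(list(genomes = c("G1", "G4")), lm), 2L)
  expect_identical(
    score_lineage_conservation(list(genomes = character(0)), lm), 0L)
  expect_error(
    score_lineage_conservation(list(genomes = c("G1", "G9")), lm), "unmapped")
})

test_that("operons are maximal same-strand runs with short gaps", {
  alt <- toy_replicon(c("+", "-", "+", "-"))
  ops <- predict_operons(alt, d_max = 100)
  expect_identical(nrow(ops), 4L)
  expect_true(all(ops$n_genes == 1L))

  four <- toy_replicon(rep("+", 4), gaps = c(30L, 45L, 20L))
  ops <- predict_operons(four, d_max = 100)
  expect_identical(nrow(ops), 1L)
  expect_identical(ops$n_genes, 4L)
  expect_identical(ops$member_indices[[1]], 0:3)

  split <- toy_replicon(c("+", "+"), gaps = 500L)
  expect_identical(nrow(predict_operons(split, d_max = 100)), 2L)
})

test_that("divergently encoded flanking genes are flagged head-to-head only", {
  # minus-strand gene preceding a plus-strand operon: divergent
  r <- toy_replicon(c("-", "+", "+", "+"), gaps = c(80L, 10L, 10L))
  op <- predict_operons(r, d_max = 100)
  op_plus <- op[op$strand == "+", ]
  flagged <- flag_divergent(op_plus, r)
  expect_identical(flagged$gene_id, "t1")

  # co-oriented flank: nothing flagged
  r2 <- toy_replicon(c("+", "+", "+", "+"), gaps = c(500L, 10L, 10L))
  op2 <- predict_operons(r2, d_max = 100)
  expect_identical(nrow(flag_divergent(op2[2, ], r2)), 0L)

  # operon at the replicon edge: only the existing side inspected
  r3 <- toy_replicon(c("+", "+", "-"), gaps = c(10L, 10L))
  op3 <- predict_operons(r3, d_max = 100)
  expect_identical(nrow(flag_divergent(op3[1, ], r3)), 0L)

  # minus-strand operon followed by a plus-strand gene: divergent
  r4 <- toy_replicon(c("-", "-", "+"), gaps = c(10L, 200L))
  op4 <- predict_operons(r4, d_max = 100)
  flagged4 <- flag_divergent(op4[op4$strand == "-", ][1, ], r4)
  expect_identical(flagged4$gene_id, "t3")
})

test_that("domain fusions are detected, ordered and overlap-flagged", {
  asg <- data.frame(
    genome_id = "G1",
    gene_id = c("f1", "f1", "solo", "ov", "ov", "nc", "nc"),
    cluster_id = c("Cgi121Cluster", "UblCluster", "bg",
                   "A", "B", "P", "Q"),
    dom_start = c(95L, 1L, 1L, 1L, 60L, NA, NA),
    dom_end = c(250L, 80L, 100L, 100L, 200L, NA, NA),
    stringsAsFactors = FALSE)
  expect_warning(fus <- detect_fusions(asg, min_sep = 10),
                 "lacks domain coordinates")
  expect_identical(nrow(fus), 3L)
  f1 <- fus[fus$gene_id == "f1", ]
  expect_identical(f1$domain_clusters[[1]], c("UblCluster", "Cgi121Cluster"))
  expect_false(f1$overlap_flag)
  expect_true(fus$overlap_flag[fus$gene_id == "ov"])     # overlap 41 > 10
  expect_true(is.na(fus$overlap_flag[fus$gene_id == "nc"]))
  expect_false("solo" %in% fus$gene_id)
})

test_that("anchoring on every gene yields a symmetric co-occurrence matrix", {
  set.seed(303)
  for (rep in 1:4) {
    n <- sample(5:10, 1)
    circ <- rep %% 2 == 0
    r <- toy_replicon(sample(c("+", "-"), n, TRUE),
                      topology = if (circ) "circular" else "linear")
    g <- genome("G", list(r))
    asg <- make_assign("G", paste0("t", 1:n),
                       sample(c("c1", "c2", "c3"), n, TRUE))
    nbs <- lapply(paste0("t", 1:n), function(id)
      extract_neighborhood(g, id, k = 2))
    rec <- count_associations(nbs, asg, c(G = "Sulfolobales"))
    for (i in seq_len(nrow(rec))) {
      mirror <- rec$occurrence_count[
        rec$anchor_cluster == rec$neighbor_cluster[i] &
          rec$neighbor_cluster == rec$anchor_cluster[i]]
      expect_identical(mirror, rec$occurrence_count[i])
    }
  }
})

test_that("planted pairs rank first whenever f*n >= 4 over 20 seeds", {
  for (s in 1:20) {
    cfg <- sim_config(seed = 2000 + s, n_genomes = 8L, genes_per_genome = 80L,
                      n_clusters = 60L,
                      planted_associations = list(
                        list(anchor = "ANC", neighbor = "NBR", f = 0.6,
                             max_offset = 3L)))
    sim <- generate_genomes(cfg)
    nbs <- list()
    for (g in sim$genomes) {
      sel <- sim$assignments$genome_id == g$genome_id &
        sim$assignments$cluster_id == "ANC"
      for (gene in sim$assignments$gene_id[sel])
        nbs[[length(nbs) + 1L]] <- extract_neighborhood(g, gene, k = 3)
    }
    rec <- count_associations(nbs, sim$assignments, sim$lineage_map)
    expect_identical(rec$neighbor_cluster[1], "NBR")
    expect_identical(rec$n_genomes[1],
                     length(sim$truth$associations$`ANC~NBR`$genomes))
  }
})
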