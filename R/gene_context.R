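# Gene-neighborhood ("guilt by association") analysis: +/-k windows around
# anchor genes, cross-genome association counting ranked by lineage
# conservation, operon and divergent-gene prediction, and domain-fusion
# detection from multi-domain cluster assignments.

#' Extract the +/-k gene neighborhood of an anchor gene
#'
#' Upstream/downstream are defined on replicon coordinate order (not relative
#' to the anchor's strand); strands are carried along so callers can
#' reinterpret. Linear replicons truncate at the ends; circular replicons wrap
#' around. On small circular replicons where the two sides would meet, genes
#' are claimed once in order of increasing distance (upstream side first at
#' equal distance), so no gene appears twice and the anchor never reappears.
#'
#' @param g A [genome()].
#' @param gene_id Anchor gene id (must exist in `g`).
#' @param k Window half-width in genes; default 3.
#' @return Object of class `Neighborhood`: `anchor` (one-row data.frame),
#'   `upstream` and `downstream` data.frames ordered nearest first,
#'   `genome_id`, `replicon_id`.
#' @export
extract_neighborhood <- function(g, gene_id, k = 3L) {
  stopifnot(inherits(g, "Genome"), k >= 1L)
  rep_hit <- NULL
  for (r in g$replicons) if (gene_id %in% r$genes$gene_id) { rep_hit <- r; break }
  if (is.null(rep_hit))
    stop("anchor gene ", gene_id, " not found in genome ", g$genome_id)
  genes <- rep_hit$genes
  n <- nrow(genes)
  a <- which(genes$gene_id == gene_id)        # 1-based row of anchor
  up_rows <- integer(0); down_rows <- integer(0)
  if (rep_hit$topology == "linear") {
    up_rows <- a - seq_len(min(k, a - 1L))   # a-1, a-2, ... nearest first
    down_rows <- a + seq_len(min(k, n - a))
  } else {
    taken <- a
    for (d in seq_len(k)) {
      u <- ((a - 1L - d) %% n) + 1L
      if (!(u %in% taken)) { up_rows <- c(up_rows, u); taken <- c(taken, u) }
      dn <- ((a - 1L + d) %% n) + 1L
      if (!(dn %in% taken)) { down_rows <- c(down_rows, dn); taken <- c(taken, dn) }
    }
  }
  structure(list(anchor = genes[a, , drop = FALSE],
                 upstream = genes[up_rows, , drop = FALSE],
                 downstream = genes[down_rows, , drop = FALSE],
                 genome_id = g$genome_id, replicon_id = rep_hit$replicon_id),
            class = "Neighborhood")
}

# cluster ids assigned to one gene of one genome ("UNASSIGNED" when none)
.gene_clusters <- function(assignments, genome_id, gene_id) {
  cl <- assignments$cluster_id[assignments$genome_id == genome_id &
                               assignments$gene_id == gene_id]
  if (!length(cl)) "UNASSIGNED" else unique(cl)
}

#' Count cross-genome neighborhood associations
#'
#' For every (anchor cluster, neighbor cluster) pair, accumulates the set of
#' genomes where the pair co-occurs in at least one neighborhood, the set of
#' lineages those genomes belong to, and the raw number of co-occurrences.
#' A genome contributes at most once to the genome set however many paralogous
#' anchors it carries; `occurrence_count` keeps the raw tally. Within one
#' neighborhood a neighbor cluster is counted once per neighbor gene carrying
#' it. Records are ranked by lineage count, then genome count (associations
#' recurring in several independent lineages are the evolutionarily conserved
#' ones), then ids for determinism.
#'
#' @param neighborhoods List of [extract_neighborhood()] results.
#' @param assignments Cluster assignment data.frame ([read_cluster_table()]).
#' @param lineage_map Named lineage vector keyed by genome_id
#'   ([read_lineage_map()]).
#' @return data.frame with columns `anchor_cluster`, `neighbor_cluster`,
#'   `n_genomes`, `n_lineages`, `occurrence_count` and list-columns `genomes`,
#'   `lineages`.
#' @export
count_associations <- function(neighborhoods, assignments, lineage_map) {
  rows <- list()
  for (nb in neighborhoods) {
    stopifnot(inherits(nb, "Neighborhood"))
    anchor_cl <- .gene_clusters(assignments, nb$genome_id, nb$anchor$gene_id)
    if (identical(anchor_cl, "UNASSIGNED"))
      stop("anchor gene ", nb$anchor$gene_id, " has no cluster assignment")
    nbr <- rbind(nb$upstream, nb$downstream)
    if (!nrow(nbr)) next
    for (i in seq_len(nrow(nbr))) {
      nbr_cl <- .gene_clusters(assignments, nb$genome_id, nbr$gene_id[i])
      for (ac in anchor_cl) for (nc in nbr_cl)
        rows[[length(rows) + 1L]] <- c(ac, nc, nb$genome_id)
    }
  }
  if (!length(rows)) {
    return(data.frame(anchor_cluster = character(0),
                      neighbor_cluster = character(0),
                      n_genomes = integer(0), n_lineages = integer(0),
                      occurrence_count = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("anchor_cluster", "neighbor_cluster", "genome_id")
  key <- paste(df$anchor_cluster, df$neighbor_cluster, sep = "\r")
  agg <- lapply(split(df, key), function(d) {
    gset <- sort(unique(d$genome_id))
    lset <- sort(unique(unname(lineage_map[gset])))
    lset <- lset[!is.na(lset)]
    data.frame(anchor_cluster = d$anchor_cluster[1L],
               neighbor_cluster = d$neighbor_cluster[1L],
               n_genomes = length(gset), n_lineages = length(lset),
               occurrence_count = nrow(d), stringsAsFactors = FALSE,
               genomes = I(list(gset)), lineages = I(list(lset)))
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$n_lineages, -out$n_genomes,
                   out$anchor_cluster, out$neighbor_cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lineage-conservation score of one association record
#'
#' The number of distinct lineages among the genomes supporting the record:
#' associations recurring across independent lineages are treated as
#' evolutionarily conserved rather than lineage-specific idiosyncrasies.
#'
#' @param record One row of the [count_associations()] output (or any object
#'   with a `genomes` set).
#' @param lineage_map Named lineage vector keyed by genome_id.
#' @return Integer lineage count (0 for an empty genome set).
#' @export
score_lineage_conservation <- function(record, lineage_map) {
  gset <- if (is.data.frame(record)) record$genomes[[1L]] else record$genomes
  if (!length(gset)) return(0L)
  lin <- lineage_map[gset]
  if (anyNA(lin)) stop("unmapped genome(s): ",
                       paste(gset[is.na(lin)], collapse = ", "))
  length(unique(unname(lin)))
}

#' Predict operons as same-strand runs with short intergenic gaps
#'
#' A predicted operon is a maximal run of consecutive same-strand genes whose
#' intergenic gaps (next start minus previous end minus 1) are all at most
#' `d_max`. Divergently oriented neighbors always split runs.
#'
#' @param rep A [replicon()].
#' @param d_max Maximum intergenic gap in bp; default 100 (a common
#'   prokaryotic operon heuristic).
#' @return data.frame with one row per operon: `replicon_id`, `strand`,
#'   `first_index`, `last_index`, `n_genes` and list-column `member_indices`
#'   (0-based gene indices).
#' @export
predict_operons <- function(rep, d_max = 100L) {
  stopifnot(inherits(rep, "Replicon"))
  genes <- rep$genes
  n <- nrow(genes)
  if (!n) return(data.frame(replicon_id = character(0), strand = character(0),
                            first_index = integer(0), last_index = integer(0),
                            n_genes = integer(0)))
  brk <- logical(n - 1L)
  if (n > 1L) {
    same <- genes$strand[-n] == genes$strand[-1L]
    gap <- genes$start[-1L] - genes$end[-n] - 1L
    brk <- !(same & gap <= d_max)
  }
  run_id <- cumsum(c(TRUE, brk))
  ops <- lapply(split(seq_len(n), run_id), function(rows) {
    data.frame(replicon_id = rep$replicon_id, strand = genes$strand[rows[1L]],
               first_index = genes$index[rows[1L]],
               last_index = genes$index[rows[length(rows)]],
               n_genes = length(rows), stringsAsFactors = FALSE,
               member_indices = I(list(genes$index[rows])))
  })
  out <- do.call(rbind, ops)
  rownames(out) <- NULL
  out
}

#' Flag genes divergently encoded next to an operon
#'
#' Inspects the genes immediately flanking an operon and returns those in
#' head-to-head orientation with it, i.e. transcribed away from the operon
#' from a shared intergenic region: for a plus-strand operon the immediately
#' preceding minus-strand gene, for a minus-strand operon the immediately
#' following plus-strand gene. At a linear replicon edge only the existing
#' side is inspected.
#'
#' @param operon One row of [predict_operons()] output.
#' @param rep The replicon the operon lies on.
#' @return data.frame of flagged flanking genes (possibly zero rows).
#' @export
flag_divergent <- function(operon, rep) {
  stopifnot(inherits(rep, "Replicon"))
  genes <- rep$genes
  out <- genes[0, , drop = FALSE]
  if (operon$strand == "+") {
    i <- which(genes$index == operon$first_index) - 1L
    if (i >= 1L && genes$strand[i] == "-") out <- genes[i, , drop = FALSE]
  } else {
    i <- which(genes$index == operon$last_index) + 1L
    if (i <= nrow(genes) && genes$strand[i] == "+") out <- genes[i, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Detect domain fusions from multi-domain cluster assignments
#'
#' Genes carrying two or more cluster assignments are reported as fusion
#' candidates, with domains ordered by start coordinate. `overlap_flag` is set
#' when any two successive domains overlap by more than `min_sep` amino acids
#' (suggesting conflicting rather than tandem domain calls). Multi-assigned
#' genes missing domain coordinates are still reported, with `overlap_flag`
#' `NA` and a warning.
#'
#' @param assignments Cluster assignment data.frame.
#' @param min_sep Overlap tolerance in amino acids; default 10.
#' @return data.frame with `genome_id`, `gene_id`, `n_domains`,
#'   `domain_clusters` (list-column, ordered by `dom_start`), `overlap_flag`.
#' @export
detect_fusions <- function(assignments, min_sep = 10L) {
  key <- paste(assignments$genome_id, assignments$gene_id, sep = "\r")
  out <- lapply(split(assignments, key), function(d) {
    if (nrow(d) < 2L) return(NULL)
    if (anyNA(d$dom_start)) {
      warning("multi-assigned gene ", d$gene_id[1L], " in ", d$genome_id[1L],
              " lacks domain coordinates; overlap_flag unset")
      d <- d[order(d$dom_start, d$cluster_id, na.last = TRUE), , drop = FALSE]
      flag <- NA
    } else {
      d <- d[order(d$dom_start, d$dom_end, d$cluster_id), , drop = FALSE]
      ov <- d$dom_end[-nrow(d)] - d$dom_start[-1L] + 1L
      flag <- any(ov > min_sep)
    }
    data.frame(genome_id = d$genome_id[1L], gene_id = d$gene_id[1L],
               n_domains = nrow(d), overlap_flag = flag,
               stringsAsFactors = FALSE,
               domain_clusters = I(list(d$cluster_id)))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(genome_id = character(0), gene_id = character(0),
                      n_domains = integer(0), overlap_flag = logical(0))
  else out <- out[order(out$genome_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
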