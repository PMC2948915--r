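#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Construct a replicon
#'
#' A replicon is an ordered, stranded set of gene models on one DNA molecule.
#' Genes are sorted by start coordinate (ties broken by end, then gene_id) and
#' assigned consecutive 0-based indices in that order.
#'
#' @param replicon_id Character scalar.
#' @param genes data.frame with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and optionally `protein` (amino-acid string, possibly empty).
#' @param topology `"linear"` or `"circular"`; drives neighborhood wrap-around.
#' @return Object of class `Replicon`: list with `replicon_id`, `topology` and
#'   the sorted, indexed `genes` data.frame.
#' @export
replicon <- function(replicon_id, genes, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L)
  if (is.null(genes$protein)) genes$protein <- ""
  genes <- genes[, c("gene_id", "start", "end", "strand", "protein")]
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id on replicon ", replicon_id)
    if (any(genes$start < 1) || any(genes$end < genes$start))
      stop("invalid gene coordinates on replicon ", replicon_id)
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
  }
  genes$index <- if (nrow(genes)) seq_len(nrow(genes)) - 1L else integer(0)
  rownames(genes) <- NULL
  structure(list(replicon_id = replicon_id, topology = topology, genes = genes),
            class = "Replicon")
}

#' Construct a genome
#'
#' @param genome_id Character scalar, unique within a dataset.
#' @param replicons List of [replicon()] objects.
#' @param lineage Lineage label (e.g. `"Sulfolobales"`, `"Halobacteria"`).
#' @return Object of class `Genome`.
#' @export
genome <- function(genome_id, replicons, lineage = NA_character_) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  stopifnot(all(vapply(replicons, inherits, logical(1), "Replicon")))
  names(replicons) <- vapply(replicons, `[[`, character(1), "replicon_id")
  all_ids <- unlist(lapply(replicons, function(r) r$genes$gene_id))
  if (anyDuplicated(all_ids))
    stop("duplicate gene_id across replicons of genome ", genome_id)
  structure(list(genome_id = genome_id, lineage = lineage,
                 replicons = replicons),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  n <- sum(vapply(x$replicons, function(r) nrow(r$genes), integer(1)))
  cat(sprintf("Genome %s (%s): %d replicon(s), %d genes\n",
              x$genome_id, x$lineage, length(x$replicons), n))
  invisible(x)
}

#' All genes of a genome as one table
#'
#' @param g A `Genome`.
#' @return data.frame with one row per gene and a `replicon_id` column.
#' @export
genome_genes <- function(g) {
  stopifnot(inherits(g, "Genome"))
  out <- lapply(g$replicons, function(r) {
    if (!nrow(r$genes)) return(NULL)
    cbind(replicon_id = r$replicon_id, r$genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(replicon_id = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0),
                      index = integer(0))
  rownames(out) <- NULL
  out
}

#' Read a genome from GFF3 + protein FASTA
#'
#' CDS (or `gene`) features provide coordinates and strand; protein sequences
#' are matched to features by ID. A `region` feature with an `Is_circular=true`
#' attribute marks its replicon as circular; the default topology is linear.
#' Trailing stop characters (`*`) on proteins are stripped. A feature without
#' a protein record triggers a warning and keeps an empty protein (RNA genes).
#'
#' @param gff3_path Path to a GFF3 file.
#' @param fasta_path Path to a protein FASTA keyed by gene_id (first word of
#'   the header). May be `NULL` when no proteins are available.
#' @param genome_id Genome identifier; defaults to the GFF3 file stem.
#' @param lineage Optional lineage label.
#' @return A [genome()] object; genes ordered by start within each replicon.
#' @export
read_genome <- function(gff3_path, fasta_path = NULL,
                        genome_id = sub("\\.gff3?$", "", basename(gff3_path)),
                        lineage = NA_character_) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  prot <- character(0)
  if (!is.null(fasta_path)) {
    aa <- Biostrings::readAAStringSet(fasta_path)
    prot <- sub("\\*$", "", as.character(aa))
    names(prot) <- sub("\\s.*$", "", names(aa))
    if (anyDuplicated(names(prot)))
      stop("duplicate protein id in ", fasta_path)
  }
  meta <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(meta$type)
  circ_by_seq <- character(0)
  is_region <- type %in% c("region", "chromosome")
  if (any(is_region) && "Is_circular" %in% names(meta)) {
    circ <- tolower(as.character(meta$Is_circular[is_region])) %in% "true"
    circ_by_seq <- stats::setNames(ifelse(circ, "circular", "linear"),
                                   as.character(GenomicRanges::seqnames(gr))[is_region])
  }
  # files annotating both gene and CDS rows describe each locus twice;
  # CDS carries the coding coordinates, so it wins when present
  keep <- if (any(type == "CDS")) type == "CDS" else type == "gene"
  gr <- gr[keep]
  meta <- meta[keep, , drop = FALSE]
  ids <- as.character(meta$ID)
  if (all(is.na(ids)) && length(gr)) stop("GFF3 features lack ID attributes")
  if (anyDuplicated(ids)) stop("duplicate gene_id in ", gff3_path)
  seqn <- as.character(GenomicRanges::seqnames(gr))
  reps <- lapply(unique(seqn), function(rid) {
    sel <- seqn == rid
    df <- data.frame(gene_id = ids[sel],
                     start = GenomicRanges::start(gr)[sel],
                     end = GenomicRanges::end(gr)[sel],
                     strand = as.character(GenomicRanges::strand(gr))[sel],
                     stringsAsFactors = FALSE)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
    pp <- prot[df$gene_id]
    missing <- is.na(pp)
    if (any(missing) && length(prot))
      warning("no protein for gene(s) ", paste(df$gene_id[missing], collapse = ", "),
              "; keeping empty protein")
    pp[is.na(pp)] <- ""
    df$protein <- unname(pp)
    topo <- if (!is.na(circ_by_seq[rid]) && length(circ_by_seq))
      circ_by_seq[[rid]] else "linear"
    replicon(rid, df, topology = topo)
  })
  genome(genome_id, reps, lineage = lineage)
}

#' Write a genome to GFF3 + protein FASTA
#'
#' Inverse of [read_genome()]: emits one `region` feature per replicon
#' (carrying `Is_circular=true` for circular replicons) plus one CDS per gene,
#' and a protein FASTA for genes with non-empty proteins. Output ordering is
#' deterministic (replicon, then gene index), so writes are bit-stable.
#'
#' @param g A `Genome`.
#' @param gff3_path,fasta_path Output paths; `fasta_path = NULL` skips FASTA.
#' @return Invisibly, `g`.
#' @export
write_genome <- function(g, gff3_path, fasta_path = NULL) {
  stopifnot(inherits(g, "Genome"))
  grs <- lapply(g$replicons, function(r) {
    rep_len <- if (nrow(r$genes)) max(r$genes$end) else 1L
    region <- GenomicRanges::GRanges(
      r$replicon_id, IRanges::IRanges(1L, rep_len), strand = "+")
    S4Vectors::mcols(region)$type <- "region"
    S4Vectors::mcols(region)$ID <- r$replicon_id
    S4Vectors::mcols(region)$Is_circular <-
      if (r$topology == "circular") "true" else NA_character_
    S4Vectors::mcols(region)$phase <- NA_integer_
    if (!nrow(r$genes)) return(region)
    cds <- GenomicRanges::GRanges(
      r$replicon_id, IRanges::IRanges(r$genes$start, r$genes$end),
      strand = r$genes$strand)
    S4Vectors::mcols(cds)$type <- "CDS"
    S4Vectors::mcols(cds)$ID <- r$genes$gene_id
    S4Vectors::mcols(cds)$Is_circular <- NA_character_
    S4Vectors::mcols(cds)$phase <- 0L
    c(region, cds)
  })
  gr <- do.call(c, unname(grs))
  if (is.null(gr)) gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$type <- factor(S4Vectors::mcols(gr)$type)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  if (!is.null(fasta_path)) {
    genes <- genome_genes(g)
    genes <- genes[nzchar(genes$protein), , drop = FALSE]
    aa <- Biostrings::AAStringSet(stats::setNames(genes$protein, genes$gene_id))
    Biostrings::writeXStringSet(aa, fasta_path)
  }
  invisible(g)
}

#' Read an ortholog-cluster assignment table
#'
#' Expects a TSV with header columns `genome_id`, `gene_id`, `cluster_id` and
#' optional `dom_start`, `dom_end` (1-based amino-acid coordinates of the
#' domain covered by the cluster). A gene may appear on multiple rows with
#' different clusters: multi-domain proteins keep one row per domain, which is
#' what fusion detection consumes. Rows whose domain interval is inverted
#' (`dom_start > dom_end`) are rejected with a warning.
#'
#' @param tsv_path Path to the table.
#' @return data.frame of assignments (`genome_id`, `gene_id`, `cluster_id`,
#'   `dom_start`, `dom_end`; coordinates `NA` when absent).
#' @export
read_cluster_table <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("genome_id", "gene_id", "cluster_id")
  if (!all(need %in% names(df)))
    stop("cluster table must have columns ", paste(need, collapse = ", "))
  if (is.null(df$dom_start)) df$dom_start <- NA_integer_
  if (is.null(df$dom_end)) df$dom_end <- NA_integer_
  df <- df[, c(need, "dom_start", "dom_end")]
  bad <- !is.na(df$dom_start) & !is.na(df$dom_end) & df$dom_start > df$dom_end
  if (any(bad)) {
    warning(sum(bad), " assignment row(s) rejected: dom_start > dom_end")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a cluster assignment table
#' @param assignments data.frame as returned by [read_cluster_table()].
#' @param tsv_path Output path.
#' @export
write_cluster_table <- function(assignments, tsv_path) {
  utils::write.table(assignments, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(assignments)
}

#' Read a genome-to-lineage map
#'
#' @param tsv_path TSV with columns `genome_id`, `lineage`. Row order fixes
#'   the genome ordering used by phyletic reports.
#' @return Named character vector: lineage keyed by genome_id.
#' @export
read_lineage_map <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "lineage") %in% names(df)))
    stop("lineage map must have columns genome_id, lineage")
  if (any(!nzchar(df$lineage))) stop("empty lineage label")
  stats::setNames(df$lineage, df$genome_id)
}

#' Construct a cluster alignment
#'
#' @param cluster_id Cluster identifier.
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the 20 amino acids plus gap. `.` gaps are normalized to `-`.
#' @return Object of class `ClusterAlignment` with `n_columns` set.
#' @export
cluster_alignment <- function(cluster_id, seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- chartr(".", "-", toupper(seqs))
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("ragged alignment for cluster ", cluster_id,
         ": lengths ", paste(sort(w), collapse = ", "))
  structure(list(cluster_id = cluster_id, seqs = seqs, n_columns = w),
            class = "ClusterAlignment")
}

#' Read an aligned FASTA as a cluster alignment
#'
#' @param fasta_path Path to aligned protein FASTA (equal-length records).
#' @param cluster_id Cluster id; defaults to the file stem.
#' @return A [cluster_alignment()].
#' @export
read_alignment <- function(fasta_path,
                           cluster_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  aa <- Biostrings::readBStringSet(fasta_path)
  seqs <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  cluster_alignment(cluster_id, seqs)
}

#' Write a cluster alignment as aligned FASTA
#' @param aln A `ClusterAlignment`.
#' @param fasta_path Output path.
#' @export
write_alignment <- function(aln, fasta_path) {
  stopifnot(inherits(aln, "ClusterAlignment"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(aln$seqs), fasta_path)
  invisible(aln)
}

# character matrix view of an alignment (rows = members, columns = positions)
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "ClusterAlignment"))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}
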