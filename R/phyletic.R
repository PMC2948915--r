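# Phyletic (presence/absence) pattern analysis over ortholog clusters.
# Presence is binary: the arguments these patterns support ("family X is
# missing only from several methanogens", complementary distributions of two
# related families) are about which genomes encode a family at all, not about
# copy number.

#' Build a cluster-by-genome presence/absence matrix
#'
#' @param assignments Cluster assignment data.frame ([read_cluster_table()]).
#' @param genomes Character vector of genome ids fixing column order (usually
#'   the lineage-map order so reports group by lineage).
#' @return Object of class `PhyleticMatrix`: logical matrix `present` with
#'   cluster rows (sorted) and genome columns, plus `clusters`, `genomes`.
#'   Genomes with no assignment get all-FALSE columns; an assignment naming a
#'   genome outside `genomes` is an error.
#' @export
build_matrix <- function(assignments, genomes) {
  stopifnot(is.character(genomes), !anyDuplicated(genomes))
  unknown <- setdiff(unique(assignments$genome_id), genomes)
  if (length(unknown))
    stop("assignments reference unknown genome(s): ",
         paste(unknown, collapse = ", "))
  clusters <- sort(unique(assignments$cluster_id))
  m <- matrix(FALSE, length(clusters), length(genomes),
              dimnames = list(clusters, genomes))
  if (nrow(assignments))
    m[cbind(match(assignments$cluster_id, clusters),
            match(assignments$genome_id, genomes))] <- TRUE
  structure(list(clusters = clusters, genomes = genomes, present = m),
            class = "PhyleticMatrix")
}

#' @export
print.PhyleticMatrix <- function(x, ...) {
  cat(sprintf("PhyleticMatrix: %d clusters x %d genomes (%.0f%% filled)\n",
              length(x$clusters), length(x$genomes),
              100 * mean(x$present)))
  invisible(x)
}

#' Report the genomes each cluster is absent from
#'
#' @param mat A [build_matrix()] result.
#' @param cluster_set Clusters to report on (must exist in `mat`).
#' @return Named list: per cluster, the genomes where it is absent, in the
#'   matrix's genome order (empty vector for ubiquitous clusters).
#' @export
absence_report <- function(mat, cluster_set) {
  stopifnot(inherits(mat, "PhyleticMatrix"))
  unknown <- setdiff(cluster_set, mat$clusters)
  if (length(unknown))
    stop("unknown cluster(s): ", paste(unknown, collapse = ", "))
  out <- lapply(cluster_set, function(cl) mat$genomes[!mat$present[cl, ]])
  stats::setNames(out, cluster_set)
}

#' Query clusters by a required presence/absence pattern
#'
#' Returns the clusters present in every genome of `required_present` and
#' absent from every genome of `required_absent`; used e.g. to find families
#' with distributions complementary to a given family.
#'
#' @param mat A [build_matrix()] result.
#' @param required_present,required_absent Disjoint genome sets (possibly
#'   empty; both empty returns all clusters).
#' @return Character vector of cluster ids in matrix row order.
#' @export
pattern_query <- function(mat, required_present = character(0),
                          required_absent = character(0)) {
  stopifnot(inherits(mat, "PhyleticMatrix"))
  if (length(intersect(required_present, required_absent)))
    stop("required_present and required_absent overlap")
  unknown <- setdiff(c(required_present, required_absent), mat$genomes)
  if (length(unknown))
    stop("unknown genome(s): ", paste(unknown, collapse = ", "))
  ok <- rep(TRUE, length(mat$clusters))
  if (length(required_present))
    ok <- ok & rowSums(mat$present[, required_present, drop = FALSE]) ==
      length(required_present)
  if (length(required_absent))
    ok <- ok & rowSums(mat$present[, required_absent, drop = FALSE]) == 0
  mat$clusters[ok]
}

#' Write a phyletic matrix as a 0/1 TSV
#'
#' @param mat A `PhyleticMatrix`.
#' @param tsv_path Output path; clusters as rows, genomes as columns.
#' @export
write_phyletic_matrix <- function(mat, tsv_path) {
  stopifnot(inherits(mat, "PhyleticMatrix"))
  df <- data.frame(cluster_id = mat$clusters,
                   matrix(as.integer(mat$present), nrow(mat$present),
                          dimnames = list(NULL, mat$genomes)),
                   check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mat)
}
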