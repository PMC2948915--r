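# Consensus reconstruction and C-terminal doublet scanning.
#
# Ubiquitin-like proteins carry a functionally essential double-glycine (GG)
# motif at the C-terminus (a double-cysteine CC variant occurs in some
# halobacterial families). Families of small proteins whose alignment
# consensus ends in a conserved GG/CC doublet are therefore strong Ubl
# candidates; this module reconstructs per-cluster consensus profiles and
# screens them for such termini.

#' Build a consensus profile for a cluster alignment
#'
#' Per column, the plurality residue is the most frequent non-gap character
#' (ties broken alphabetically). Its frequency is computed over all members,
#' gaps included, so a gappy column can never look conserved. The consensus
#' character is the plurality residue in uppercase when its frequency reaches
#' `plurality_min`, `-` when gaps dominate the column (> 50%), and the
#' lowercase plurality residue otherwise (weak consensus).
#'
#' @param aln A [cluster_alignment()].
#' @param plurality_min Minimum all-rows frequency for a strong (uppercase)
#'   consensus call; in (0, 1].
#' @return Object of class `ConsensusProfile`: `cluster_id`, parallel vectors
#'   `consensus`, `conservation`, `gap_fraction` (one entry per column) and
#'   `n_members`.
#' @export
build_consensus <- function(aln, plurality_min = 0.5) {
  stopifnot(inherits(aln, "ClusterAlignment"),
            plurality_min > 0, plurality_min <= 1)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  cons_char <- character(ncol(m))
  cons_frac <- numeric(ncol(m))
  gap_frac <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    is_gap <- col == "-"
    gap_frac[j] <- mean(is_gap)
    res <- col[!is_gap]
    if (!length(res)) {
      cons_char[j] <- "-"
      cons_frac[j] <- 0
      next
    }
    tab <- table(res)
    top <- sort(names(tab)[tab == max(tab)])[1L]   # alphabetical tie-break
    frac <- tab[[top]] / n
    cons_frac[j] <- frac
    cons_char[j] <- if (frac >= plurality_min) top
                    else if (gap_frac[j] > 0.5) "-"
                    else tolower(top)
  }
  structure(list(cluster_id = aln$cluster_id, consensus = cons_char,
                 conservation = cons_frac, gap_fraction = gap_frac,
                 n_members = n),
            class = "ConsensusProfile")
}

#' @export
print.ConsensusProfile <- function(x, ...) {
  cat(sprintf("ConsensusProfile %s: %d columns, %d members\n%s\n",
              x$cluster_id, length(x$consensus), x$n_members,
              paste(x$consensus, collapse = "")))
  invisible(x)
}

#' Trim majority-gap terminal columns from a consensus profile
#'
#' Alignment overhangs (columns occupied by few members) would otherwise shift
#' the apparent C-terminus, so leading and trailing columns with gap fraction
#' above 0.5 are removed before the terminal doublet is read. Interior columns
#' are never touched.
#'
#' @param profile A `ConsensusProfile`.
#' @return The trimmed profile; empty (zero columns) with a warning when every
#'   column is majority-gap.
#' @export
trim_terminal_gap_columns <- function(profile) {
  stopifnot(inherits(profile, "ConsensusProfile"))
  keep <- profile$gap_fraction <= 0.5
  if (!any(keep)) {
    warning("all columns are majority-gap for cluster ", profile$cluster_id,
            "; empty profile returned")
    idx <- integer(0)
  } else {
    idx <- seq(which(keep)[1L], max(which(keep)))
  }
  profile$consensus <- profile$consensus[idx]
  profile$conservation <- profile$conservation[idx]
  profile$gap_fraction <- profile$gap_fraction[idx]
  profile
}

#' Test a trimmed profile for a conserved C-terminal doublet
#'
#' A hit requires the final two consensus characters to be strong (uppercase)
#' calls spelling one of `motifs`, with both columns conserved at
#' `cons_min` or better.
#'
#' @param profile A trimmed `ConsensusProfile`.
#' @param motifs Character vector of 2-mers to accept (default GG and CC).
#' @param cons_min Minimum per-column conservation for both terminal columns.
#' @param median_length Optional median ungapped member length to record on
#'   the hit (filled by [scan_clusters()]).
#' @return A one-row data.frame (`cluster_id`, `motif`, `cons1`, `cons2`,
#'   `median_len`, `n_members`) or `NULL` when there is no hit.
#' @export
detect_cterminal_doublet <- function(profile, motifs = c("GG", "CC"),
                                     cons_min = 0.8, median_length = NA_real_) {
  stopifnot(inherits(profile, "ConsensusProfile"))
  nc <- length(profile$consensus)
  if (nc < 2L) {
    message("profile for cluster ", profile$cluster_id,
            " has fewer than 2 columns; no doublet test")
    return(NULL)
  }
  last2 <- profile$consensus[c(nc - 1L, nc)]
  if (any(last2 != toupper(last2)) || any(last2 == "-")) return(NULL)
  doublet <- paste(last2, collapse = "")
  cons <- profile$conservation[c(nc - 1L, nc)]
  if (!(doublet %in% motifs) || any(cons < cons_min)) return(NULL)
  data.frame(cluster_id = profile$cluster_id, motif = doublet,
             cons1 = cons[1L], cons2 = cons[2L],
             median_len = median_length, n_members = profile$n_members,
             stringsAsFactors = FALSE)
}

# median ungapped member length of an alignment
median_member_length <- function(aln) {
  stats::median(nchar(gsub("-", "", aln$seqs, fixed = TRUE)))
}

#' Scan cluster alignments for small families with conserved GG/CC termini
#'
#' Runs the discovery pipeline per cluster: build the consensus, trim
#' majority-gap termini, and test the final doublet. Clusters whose median
#' ungapped member length is `max_len` or more are excluded before motif
#' testing (the target families are small proteins; the median is robust to
#' fusion outliers).
#'
#' @param alignments List of [cluster_alignment()] objects.
#' @param max_len Length cutoff in amino acids (families with median length
#'   `>= max_len` are skipped); default 200.
#' @param cons_min,plurality_min,motifs Passed to the per-cluster steps.
#' @return data.frame of hits sorted by `cluster_id` (zero rows when none).
#' @export
scan_clusters <- function(alignments, max_len = 200, cons_min = 0.8,
                          plurality_min = 0.5, motifs = c("GG", "CC")) {
  hits <- lapply(alignments, function(aln) {
    med <- median_member_length(aln)
    if (med >= max_len) return(NULL)
    prof <- suppressWarnings(
      trim_terminal_gap_columns(build_consensus(aln, plurality_min)))
    detect_cterminal_doublet(prof, motifs = motifs, cons_min = cons_min,
                             median_length = med)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), motif = character(0),
                      cons1 = numeric(0), cons2 = numeric(0),
                      median_len = numeric(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
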