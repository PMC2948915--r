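# Protein maximum-likelihood phylogenetics under the JTT model:
# informative-position selection, ML pairwise distances, a neighbor-joining
# starting tree, Felsenstein pruning with per-site log-likelihoods, cyclic
# branch-length optimization, nearest-neighbor-interchange (NNI) hill
# climbing, and RELL bootstrap supports.
#
# Trees are ape "phylo" objects (unrooted trees stored rooted at a basal
# multifurcation, as ape does); all likelihoods are for the unrooted tree,
# which by reversibility of JTT is independent of the rooting used for the
# pruning pass.

#' Select informative alignment positions
#'
#' A column is kept when its gap fraction is at most `max_gap_frac` and it is
#' parsimony-informative: at least two distinct residues each occurring in at
#' least two sequences. The selection used for a tree is recorded so that the
#' analysis is reproducible.
#'
#' @param aln A [cluster_alignment()].
#' @param max_gap_frac Maximum tolerated per-column gap fraction; default 0.5.
#' @return Object of class `SiteSet`: `cluster_id`, `columns` (1-based,
#'   strictly increasing), `n_alignment_columns`, `max_gap_frac`.
#' @export
select_informative_positions <- function(aln, max_gap_frac = 0.5) {
  m <- alignment_matrix(aln)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- col == "-"
    if (mean(gaps) > max_gap_frac) return(FALSE)
    tab <- table(col[!gaps])
    sum(tab >= 2L) >= 2L
  }, logical(1))
  if (!any(keep))
    stop("no informative positions selected; consider raising max_gap_frac ",
         "or using a longer alignment")
  structure(list(cluster_id = aln$cluster_id, columns = which(keep),
                 n_alignment_columns = aln$n_columns,
                 max_gap_frac = max_gap_frac),
            class = "SiteSet")
}

#' Write selected columns as a TSV (0-based indices)
#' @param siteset A `SiteSet`.
#' @param tsv_path Output path; one 0-based column index per row.
#' @export
write_siteset <- function(siteset, tsv_path) {
  stopifnot(inherits(siteset, "SiteSet"))
  utils::write.table(data.frame(column = siteset$columns - 1L), tsv_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(siteset)
}

#' Pairwise maximum-likelihood distance under JTT
#'
#' Maximizes the likelihood sum(log(pi_i * P_ij(t))) over the columns where
#' both sequences have residues, for t in [0, 10]. Exactly symmetric in its
#' arguments by reversibility.
#'
#' @param seq1,seq2 Aligned amino-acid strings of equal length (gaps `-`).
#' @return ML distance in expected substitutions per site.
#' @export
jtt_distance <- function(seq1, seq2) {
  s1 <- aa_to_state(strsplit(seq1, "")[[1L]])
  s2 <- aa_to_state(strsplit(seq2, "")[[1L]])
  stopifnot(length(s1) == length(s2))
  ok <- !is.na(s1) & !is.na(s2)
  if (!any(ok)) stop("no shared non-gap columns")
  s1 <- s1[ok]; s2 <- s2[ok]
  if (all(s1 == s2)) return(0)
  N <- matrix(0, 20, 20)
  tab <- table(factor(s1, levels = 1:20), factor(s2, levels = 1:20))
  N[] <- as.numeric(tab)
  # reversibility makes log(pi_i P_ij) symmetric, so symmetrizing the count
  # matrix leaves the objective unchanged and makes d(a, b) = d(b, a) exact
  N <- (N + t(N)) / 2
  lpi <- log(jtt_frequencies())
  f <- function(t) {
    P <- jtt_transition_prob(t)
    sum(N * (lpi + log(pmax(P, 1e-300))))
  }
  opt <- stats::optimize(f, c(1e-8, 10), maximum = TRUE, tol = 1e-7)
  # the optimum can sit at the lower boundary for near-identical pairs
  if (f(1e-8) >= opt$objective) return(1e-8)
  opt$maximum
}

#' All pairwise JTT ML distances of an alignment
#'
#' @param aln A [cluster_alignment()].
#' @param siteset Optional `SiteSet` restricting the columns used.
#' @return Symmetric distance matrix with member dimnames.
#' @export
jtt_distance_matrix <- function(aln, siteset = NULL) {
  seqs <- aln$seqs
  if (!is.null(siteset)) {
    m <- alignment_matrix(aln)[, siteset$columns, drop = FALSE]
    seqs <- stats::setNames(apply(m, 1, paste, collapse = ""), names(aln$seqs))
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- jtt_distance(seqs[[i]], seqs[[j]])
  D
}

#' Neighbor-joining starting tree
#'
#' Standard neighbor joining on a distance matrix, used as the distance-based
#' starting tree for local rearrangement. Negative branch lengths produced by
#' the agglomeration are clamped to zero. With two taxa the result is the
#' single connecting edge (represented in ape form as two half-length edges
#' meeting at a degree-2 node; their sum is the pairwise distance).
#'
#' @param D Symmetric non-negative distance matrix with taxon dimnames.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) >= 2L, isTRUE(all.equal(D, t(D))), all(D >= 0))
  if (nrow(D) == 2L) {
    phy <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                          edge.length = rep(D[1, 2] / 2, 2),
                          tip.label = rownames(D), Nnode = 1L),
                     class = "phylo", order = "cladewise")
    return(phy)
  }
  phy <- ape::nj(stats::as.dist(D))
  phy$edge.length[phy$edge.length < 0] <- 0
  ape::unroot(phy)
}

## ---- likelihood machinery ----------------------------------------------

# pattern-compressed likelihood data for an alignment restricted to a SiteSet
make_lik_data <- function(aln, siteset = NULL) {
  m <- alignment_matrix(aln)
  cols <- if (is.null(siteset)) seq_len(ncol(m)) else siteset$columns
  m <- m[, cols, drop = FALSE]
  st <- matrix(aa_to_state(m), nrow(m), ncol(m), dimnames = dimnames(m))
  key <- apply(st, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pat_of_site <- match(key, key[upat])
  states <- st[, upat, drop = FALSE]
  weights <- tabulate(pat_of_site, nbins = sum(upat))
  # 20 x npat tip partials: unit vector for a residue, ones for missing
  tip_part <- lapply(seq_len(nrow(states)), function(i) {
    p <- matrix(0, 20, ncol(states))
    s <- states[i, ]
    p[cbind(s[!is.na(s)], which(!is.na(s)))] <- 1
    p[, is.na(s)] <- 1
    p
  })
  names(tip_part) <- rownames(states)
  list(tip_part = tip_part, weights = weights, pat_of_site = pat_of_site,
       n_sites = length(pat_of_site), n_pat = length(weights),
       taxa = rownames(states))
}

# check tree/alignment agreement and return the tree with numeric tip order
.check_taxa <- function(phy, lik) {
  if (!setequal(phy$tip.label, lik$taxa))
    stop("tree taxa do not match alignment members")
  phy
}

# adjacency structure of a phylo object: per node, integer vectors of
# neighboring nodes and the edge row connecting them
.adjacency <- function(phy) {
  ntot <- length(phy$tip.label) + phy$Nnode
  nbr <- vector("list", ntot)
  edg <- vector("list", ntot)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    nbr[[a]] <- c(nbr[[a]], b); edg[[a]] <- c(edg[[a]], e)
    nbr[[b]] <- c(nbr[[b]], a); edg[[b]] <- c(edg[[b]], e)
  }
  list(nbr = nbr, edg = edg)
}

# rooted traversal orders (parent arrays) from a chosen root
.orient <- function(adj, root, ntot) {
  parent <- integer(ntot); parent[root] <- 0L
  parent_edge <- integer(ntot)
  order <- integer(0)
  stack <- root
  seen <- logical(ntot); seen[root] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, u)
    ns <- adj$nbr[[u]]; es <- adj$edg[[u]]
    for (i in seq_along(ns)) if (!seen[ns[i]]) {
      seen[ns[i]] <- TRUE
      parent[ns[i]] <- u; parent_edge[ns[i]] <- es[i]
      stack <- c(stack, ns[i])
    }
  }
  list(preorder = order, postorder = rev(order), parent = parent,
       parent_edge = parent_edge)
}

# scaled partial: list(mat = 20 x npat, logs = scalar log scale factor)
.scaled <- function(m, logs) {
  sc <- max(m)
  if (sc <= 0 || !is.finite(sc)) sc <- 1
  list(mat = m / sc, logs = logs + log(sc))
}

# "down" partials of every node viewed from the pruning root: the conditional
# likelihood of the data below each node, scaled. Returns the orientation too.
.down_partials <- function(phy, lik, root = length(phy$tip.label) + 1L) {
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  adj <- .adjacency(phy)
  ori <- .orient(adj, root, ntot)
  ones <- matrix(1, 20, lik$n_pat)
  down <- vector("list", ntot)
  for (u in ori$postorder) {
    mat <- if (u <= ntip) lik$tip_part[[phy$tip.label[u]]] else ones
    logs <- 0
    for (i in seq_along(adj$nbr[[u]])) {
      v <- adj$nbr[[u]][i]
      if (v == ori$parent[u]) next
      e <- adj$edg[[u]][i]
      P <- jtt_transition_prob(phy$edge.length[e])
      mat <- mat * (P %*% down[[v]]$mat)
      logs <- logs + down[[v]]$logs
    }
    down[[u]] <- .scaled(mat, logs)
  }
  list(down = down, adj = adj, ori = ori, ntip = ntip)
}

# per-pattern log-likelihood at the pruning root
.root_loglik_pat <- function(dp, root) {
  part <- dp$down[[root]]
  log(colSums(jtt_frequencies() * part$mat)) + part$logs
}

#' Per-site log-likelihoods of a tree under JTT
#'
#' Felsenstein pruning over the 20 amino-acid states with JTT
#' exchangeabilities and equilibrium frequencies; the rate matrix is
#' normalized to one expected substitution per site, gaps are missing data
#' (all-ones partials). The result does not depend on where the pruning pass
#' is rooted (reversibility).
#'
#' @param phy `phylo` tree whose tip labels are alignment members, with branch
#'   lengths set.
#' @param aln A [cluster_alignment()].
#' @param siteset Optional `SiteSet`; default uses every column.
#' @return Numeric vector of natural-log likelihoods, one per (selected)
#'   site, with attribute `"loglik"` = their sum.
#' @export
site_loglik <- function(phy, aln, siteset = NULL) {
  lik <- make_lik_data(aln, siteset)
  .check_taxa(phy, lik)
  root <- length(phy$tip.label) + 1L
  dp <- .down_partials(phy, lik, root)
  lp_pat <- .root_loglik_pat(dp, root)
  out <- lp_pat[lik$pat_of_site]
  attr(out, "loglik") <- sum(out)
  out
}

#' Total log-likelihood of a tree
#' @inheritParams site_loglik
#' @return Scalar natural-log likelihood.
#' @export
tree_loglik <- function(phy, aln, siteset = NULL) {
  sum(site_loglik(phy, aln, siteset))
}

# log-likelihood as a function of one edge length, given fixed partials on
# both sides of that edge; A and D are "rest of tree" / "subtree" partials
.edge_loglik_fun <- function(A, D, weights, pi0) {
  base <- A$logs + D$logs
  function(t) {
    P <- jtt_transition_prob(t)
    lik <- colSums((pi0 * A$mat) * (P %*% D$mat))
    sum(weights * (log(lik) + base))
  }
}

#' Optimize branch lengths by cyclic univariate ascent
#'
#' Visits every branch in turn, maximizing the tree log-likelihood in that
#' branch's length (all partials on either side held fixed, so each step is
#' exact coordinate ascent and the log-likelihood never decreases), and
#' repeats until a full cycle improves the log-likelihood by less than `tol`.
#'
#' @param phy `phylo` with initial branch lengths.
#' @param aln,siteset As in [site_loglik()].
#' @param tol Convergence tolerance on the log-likelihood; default 1e-6.
#' @param max_cycles Cap on optimization cycles; default 20.
#' @param bounds Branch-length search interval; default `c(1e-8, 10)`.
#' @return The tree with optimized `edge.length` and attribute `"loglik"`.
#' @export
optimize_branch_lengths <- function(phy, aln, siteset = NULL, tol = 1e-6,
                                    max_cycles = 20L, bounds = c(1e-8, 10)) {
  lik <- make_lik_data(aln, siteset)
  .check_taxa(phy, lik)
  pi0 <- jtt_frequencies()
  ntip <- length(phy$tip.label)
  ones <- matrix(1, 20, lik$n_pat)
  cur <- -Inf
  for (cycle in seq_len(max_cycles)) {
    prev <- cur
    for (e in seq_len(nrow(phy$edge))) {
      u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
      # condition on everything but edge e: down-partials rooted at u give
      # the subtree side D directly; the rest-of-tree side A is the product
      # of u's other incoming messages (exact coordinate ascent step)
      dp <- .down_partials(phy, lik, root = u)
      mat <- if (u <= ntip) lik$tip_part[[phy$tip.label[u]]] else ones
      logs <- 0
      for (i in seq_along(dp$adj$nbr[[u]])) {
        w <- dp$adj$nbr[[u]][i]
        if (w == v) next
        P <- jtt_transition_prob(phy$edge.length[dp$adj$edg[[u]][i]])
        mat <- mat * (P %*% dp$down[[w]]$mat)
        logs <- logs + dp$down[[w]]$logs
      }
      A <- .scaled(mat, logs)
      D <- dp$down[[v]]
      f <- .edge_loglik_fun(A, D, lik$weights, pi0)
      old_ll <- f(phy$edge.length[e])
      opt <- stats::optimize(f, bounds, maximum = TRUE, tol = 1e-6)
      cand <- c(opt$maximum, bounds[1L])
      vals <- c(opt$objective, f(bounds[1L]))
      best <- which.max(vals)
      if (vals[best] > old_ll) {
        phy$edge.length[e] <- cand[best]
        cur <- vals[best]
      } else cur <- old_ll
    }
    if (cur - prev < tol) break
  }
  attr(phy, "loglik") <- cur
  phy
}

#' Nearest-neighbor-interchange alternatives of a tree
#'
#' For each internal branch the two alternative subtree exchanges are
#' generated (branch lengths are carried over unchanged and should be
#' re-optimized by the caller).
#'
#' @param phy Unrooted binary `phylo`.
#' @return List of `phylo` trees (2 per internal branch).
#' @export
nni_neighbors <- function(phy) {
  ntip <- length(phy$tip.label)
  E <- phy$edge
  internal <- which(E[, 1L] > ntip & E[, 2L] > ntip)
  out <- list()
  for (e in internal) {
    u <- E[e, 1L]; v <- E[e, 2L]
    vkids <- which(E[, 1L] == v)            # edge rows to v's two children
    urow <- setdiff(which(E[, 1L] == u), e)[1L]  # one other child edge of u
    for (vk in vkids[1:2]) {
      newE <- E
      newE[urow, 2L] <- E[vk, 2L]
      newE[vk, 2L] <- E[urow, 2L]
      np <- phy
      np$edge <- newE
      attr(np, "order") <- NULL
      np <- ape::reorder.phylo(np, "cladewise")
      out[[length(out) + 1L]] <- np
    }
  }
  out
}

#' Hill-climbing NNI search for the maximum-likelihood topology
#'
#' Local rearrangement of a starting tree: from the branch-length-optimized
#' start, all NNI alternatives of the current tree are scored (with a short
#' branch-length re-optimization), the best is fully re-optimized, and it is
#' accepted only if it improves the log-likelihood; repeated to a local
#' optimum. The returned log-likelihood is never below the start's.
#'
#' @param phy Starting tree (e.g. from [nj_tree()]).
#' @param aln,siteset As in [site_loglik()].
#' @param tol Minimal log-likelihood improvement to accept a move.
#' @param score_cycles Optimization cycles used when screening candidate
#'   moves (the accepted tree is always fully optimized); default 2.
#' @param max_iter Cap on accepted moves; default 50.
#' @return ML tree with attribute `"loglik"`.
#' @export
nni_search <- function(phy, aln, siteset = NULL, tol = 1e-4,
                       score_cycles = 2L, max_iter = 50L) {
  cur <- optimize_branch_lengths(phy, aln, siteset)
  cur_ll <- attr(cur, "loglik")
  for (it in seq_len(max_iter)) {
    nbrs <- nni_neighbors(cur)
    if (!length(nbrs)) break
    scores <- vapply(nbrs, function(nb) {
      attr(optimize_branch_lengths(nb, aln, siteset,
                                   max_cycles = score_cycles), "loglik")
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] <= cur_ll + tol) break
    cand <- optimize_branch_lengths(nbrs[[best]], aln, siteset)
    if (attr(cand, "loglik") <= cur_ll + tol) break
    cur <- cand
    cur_ll <- attr(cand, "loglik")
  }
  attr(cur, "loglik") <- cur_ll
  cur
}

#' RELL bootstrap supports over a candidate tree set
#'
#' Resampling-estimated-log-likelihood bootstrap: per replicate, site indices
#' are resampled with replacement, each candidate's resampled log-likelihood
#' is the weighted sum of its per-site log-likelihoods, and the replicate is
#' awarded to the best candidate (exact ties split equally). No tree is
#' re-optimized, which is what makes 10,000 replicates cheap.
#'
#' @param per_site_logliks Matrix with one row per candidate tree and one
#'   column per site (all candidates scored on the same sites).
#' @param n_replicates Number of bootstrap replicates; default 10000.
#' @param seed Optional integer seed for reproducible resampling.
#' @return Numeric vector of per-candidate supports in percent (sums to 100).
#' @export
rell_bootstrap <- function(per_site_logliks, n_replicates = 10000L,
                           seed = NULL) {
  L <- as.matrix(per_site_logliks)
  if (!ncol(L)) stop("empty site set")
  if (!is.null(seed)) set.seed(seed)
  ncand <- nrow(L)
  wins <- numeric(ncand)
  done <- 0L
  while (done < n_replicates) {
    nb <- min(2000L, n_replicates - done)
    counts <- stats::rmultinom(nb, ncol(L), rep(1 / ncol(L), ncol(L)))
    scores <- L %*% counts                       # ncand x nb
    for (r in seq_len(nb)) {
      s <- scores[, r]
      top <- which(s >= max(s) - 1e-9)
      wins[top] <- wins[top] + 1 / length(top)
    }
    done <- done + nb
  }
  100 * wins / n_replicates
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal branch splits the taxa in two; splits are canonicalized as
#' the sorted tip-label set on the side not containing the alphabetically
#' first taxon, joined with `|`.
#'
#' @param phy A `phylo` tree.
#' @return Character vector of canonical split keys.
#' @export
tree_bipartitions <- function(phy) {
  ntip <- length(phy$tip.label)
  phy <- ape::reorder.phylo(phy, "postorder")
  ntot <- ntip + phy$Nnode
  below <- vector("list", ntot)
  for (i in seq_len(ntip)) below[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  anchor <- sort(phy$tip.label)[1L]
  splits <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    side <- below[[phy$edge[e, 2L]]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(phy$tip.label, side)
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Map RELL candidate supports onto the branches of a reference tree
#'
#' A replicate (candidate) supports a bipartition when the candidate tree
#' contains it, so each internal branch of the reference receives the summed
#' support of the candidates containing its bipartition.
#'
#' @param ref Reference `phylo` (normally the ML tree).
#' @param candidates List of candidate `phylo` trees (same taxa).
#' @param candidate_support Percent supports from [rell_bootstrap()].
#' @return data.frame with `bipartition` and `support` (percent) per internal
#'   branch of `ref`.
#' @export
rell_branch_support <- function(ref, candidates, candidate_support) {
  stopifnot(length(candidates) == length(candidate_support))
  cand_splits <- lapply(candidates, tree_bipartitions)
  ref_splits <- tree_bipartitions(ref)
  support <- vapply(ref_splits, function(s) {
    sum(candidate_support[vapply(cand_splits, function(cs) s %in% cs,
                                 logical(1))])
  }, numeric(1))
  data.frame(bipartition = ref_splits, support = unname(support),
             stringsAsFactors = FALSE)
}

#' Full tree protocol: distances, NJ start, NNI search, RELL supports
#'
#' Runs the complete phylogeny stage on one alignment: informative-position
#' selection, JTT ML distance matrix, neighbor-joining starting tree, NNI
#' local rearrangement, and RELL bootstrap over the ML tree plus its NNI
#' neighborhood as the candidate set. Branch supports are attached to the
#' returned tree as integer-rounded percentage node labels.
#'
#' @param aln A [cluster_alignment()] (>= 3 members for a resolved tree).
#' @param max_gap_frac Passed to [select_informative_positions()].
#' @param n_replicates RELL replicates; default 10000.
#' @param seed Integer seed for the bootstrap resampling.
#' @return List: `tree` (ML `phylo`, node labels = supports), `siteset`,
#'   `loglik`, `candidate_support`, `branch_support`.
#' @export
build_supported_tree <- function(aln, max_gap_frac = 0.5,
                                 n_replicates = 10000L, seed = 1L) {
  ss <- select_informative_positions(aln, max_gap_frac)
  D <- jtt_distance_matrix(aln, ss)
  start <- nj_tree(D)
  ml <- nni_search(start, aln, ss)
  cands <- c(list(ml), lapply(nni_neighbors(ml), function(nb)
    optimize_branch_lengths(nb, aln, ss)))
  L <- do.call(rbind, lapply(cands, function(tr) {
    as.numeric(site_loglik(tr, aln, ss))
  }))
  supp <- rell_bootstrap(L, n_replicates = n_replicates, seed = seed)
  br <- rell_branch_support(ml, cands, supp)
  out_tree <- ml
  # annotate internal nodes with their branch support where identifiable
  splits <- tree_bipartitions(ml)
  node_lab <- rep("", ml$Nnode)
  ntip <- length(ml$tip.label)
  po <- ape::reorder.phylo(ml, "postorder")
  below <- vector("list", ntip + ml$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- ml$tip.label[i]
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1L]]] <- c(below[[po$edge[e, 1L]]],
                                 below[[po$edge[e, 2L]]])
  anchor <- sort(ml$tip.label)[1L]
  for (nd in (ntip + 1L):(ntip + ml$Nnode)) {
    side <- below[[nd]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(ml$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    hit <- match(key, br$bipartition)
    if (!is.na(hit)) node_lab[nd - ntip] <- as.character(round(br$support[hit]))
  }
  out_tree$node.label <- node_lab
  list(tree = out_tree, siteset = ss, loglik = attr(ml, "loglik"),
       candidate_support = supp, branch_support = br)
}
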