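test_that("informative-position selection requires two residues twice", {
  aln <- cluster_alignment("s", c(a = "AAC", b = "AAC", c = "GAG",
                                  d = "GGG"))
  # col1 {A,A,G,G}: informative; col2 {A,A,G,G->A?}: {A,A,A,G} singleton;
  # col3 {C,C,G,G}: informative
  ss <- select_informative_positions(aln)
  expect_identical(ss$columns, c(1L, 3L))

  mono <- cluster_alignment("m", c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_error(select_informative_positions(mono), "no informative")

  gappy <- cluster_alignment("g", c(a = "A-", b = "A-", c = "G-", d = "G-"))
  expect_identical(select_informative_positions(gappy)$columns, 1L)
})

test_that("JTT building blocks are a proper reversible model", {
  P <- jtt_transition_prob(0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12, ignore_attr = TRUE)
  pi0 <- jtt_frequencies()
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
  # detailed balance and rate normalization
  expect_equal(pi0 * P, t(pi0 * P), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(-sum(pi0 * diag(jtt_rate_matrix())), 1, tolerance = 1e-12)
  expect_equal(jtt_transition_prob(0), diag(20), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pairwise ML distance matches a fine grid search and is symmetric", {
  a <- paste(rep("ARNDLK", 40), collapse = "")
  expect_identical(jtt_distance(a, a), 0)

  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")
  aln <- evolve_alignment(tr, 1500, seed = 21)
  s1 <- aln$seqs[["A"]]; s2 <- aln$seqs[["B"]]
  d <- jtt_distance(s1, s2)
  expect_identical(d, jtt_distance(s2, s1))
  # independent grid oracle over the same objective
  st1 <- match(strsplit(s1, "")[[1]], AA20)
  st2 <- match(strsplit(s2, "")[[1]], AA20)
  obj <- function(t) {
    P <- jtt_transition_prob(t)
    sum(log(jtt_frequencies()[st1] * P[cbind(st1, st2)]))
  }
  grid <- seq(1e-4, 1.5, by = 1e-4)
  gbest <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(d, gbest, tolerance = 1e-3)

  expect_error(jtt_distance("---A", "A---"), "no shared")
})

test_that("neighbor joining recovers additive trees and handles n = 2", {
  true <- ape::read.tree(
    text = "((A:0.11,B:0.23):0.15,(C:0.09,D:0.31):0.07,E:0.41);")
  nt <- nj_tree(ape::cophenetic.phylo(true))
  expect_true(same_topology(true, nt))
  # additive distances are reproduced exactly by the recovered tree
  expect_equal(ape::cophenetic.phylo(nt)[rownames(ape::cophenetic.phylo(true)),
                                         colnames(ape::cophenetic.phylo(true))],
               ape::cophenetic.phylo(true), tolerance = 1e-8)

  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- nj_tree(D2)
  expect_identical(ape::Ntip(t2), 2L)
  expect_equal(sum(t2$edge.length), 0.4)

  t3 <- nj_tree(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                       dimnames = list(LETTERS[1:3], LETTERS[1:3])))
  expect_identical(ape::Ntip(t3), 3L)
})

test_that("pruning equals exhaustive state enumeration on quartets", {
  set.seed(77)
  for (i in 1:25) {
    lens <- runif(5, 0.02, 1.5)
    tr <- quartet_tree(lens)
    states <- sample(c(1:20, NA), 4, replace = TRUE)
    chars <- ifelse(is.na(states), "-", AA20[states])
    aln <- cluster_alignment("q", stats::setNames(chars, paste0("t", 1:4)))
    mine <- site_loglik(tr, aln)
    expect_equal(as.numeric(mine), oracle_quartet_lik(states, lens),
                 tolerance = 1e-10)
  }
})

test_that("two-taxon limits and all-gap sites behave as theory says", {
  tr <- ape::read.tree(text = "(A:0.00000001,B:0.00000001);")
  aln <- cluster_alignment("p", c(A = "A", B = "A"))
  expect_equal(as.numeric(site_loglik(tr, aln)),
               log(jtt_frequencies()[["A"]]), tolerance = 1e-6)
  gap <- cluster_alignment("g", c(A = "-", B = "-"))
  expect_equal(as.numeric(site_loglik(tr, gap)), 0, tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting and leaf order", {
  set.seed(31)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(5))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    aln <- evolve_alignment(tr, 120, seed = 600 + i)
    base <- tree_loglik(tr, aln)
    for (tip in tr$tip.label[1:3]) {
      rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_equal(tree_loglik(rr, aln), base, tolerance = 1e-10)
    }
    perm <- sample(names(aln$seqs))
    aln2 <- cluster_alignment(aln$cluster_id, aln$seqs[perm])
    expect_equal(tree_loglik(tr, aln2), base, tolerance = 1e-10)
  }
})

test_that("independent likelihood implementation agrees (phangorn oracle)", {
  skip_if_not_installed("phangorn")
  set.seed(32)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.9)
  aln <- evolve_alignment(tr, 250, seed = 33)
  pd <- phangorn::phyDat(do.call(rbind, strsplit(aln$seqs, "")), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT")
  expect_equal(tree_loglik(tr, aln), fit$logLik, tolerance = 1e-8)
})

test_that("branch optimization is monotone and consistent with distances", {
  tr <- ape::read.tree(text = "(A:0.2,B:0.2);")
  aln <- evolve_alignment(ape::read.tree(text = "(A:0.35,B:0.35);"),
                          2000, seed = 41)
  opt <- optimize_branch_lengths(tr, aln)
  expect_equal(sum(opt$edge.length),
               jtt_distance(aln$seqs[["A"]], aln$seqs[["B"]]),
               tolerance = 1e-3)

  true <- ape::read.tree(
    text = "((A:0.3,B:0.2):0.25,(C:0.15,D:0.35):0.3,E:0.4);")
  aln5 <- evolve_alignment(true, 2000, seed = 42)
  start <- true
  start$edge.length <- rep(0.1, nrow(start$edge))
  ll_start <- tree_loglik(start, aln5)
  opt5 <- optimize_branch_lengths(start, aln5)
  expect_gt(attr(opt5, "loglik"), ll_start)
  expect_equal(attr(opt5, "loglik"), tree_loglik(opt5, aln5),
               tolerance = 1e-8)
  # an already-optimal tree is a fixed point
  again <- optimize_branch_lengths(opt5, aln5)
  expect_equal(again$edge.length, opt5$edge.length, tolerance = 1e-3)
  expect_lt(abs(attr(again, "loglik") - attr(opt5, "loglik")), 1e-4)
})

test_that("branch lengths are recovered from simulated data", {
  true <- ape::read.tree(
    text = "((A:0.3,B:0.2):0.25,(C:0.15,D:0.35):0.3,(E:0.25,F:0.2):0.2);")
  aln <- evolve_alignment(true, 5000, seed = 55)
  fit <- optimize_branch_lengths(true, aln)
  expect_true(all(abs(fit$edge.length - true$edge.length) /
                    true$edge.length < 0.15))
})

test_that("NNI search fixes a wrong quartet and is a fixed point at the optimum", {
  true <- ape::read.tree(text = "((A:0.3,B:0.3):0.4,(C:0.3,D:0.3):0.1);")
  aln <- evolve_alignment(true, 1500, seed = 61)
  wrong <- ape::read.tree(text = "((A:0.3,C:0.3):0.3,(B:0.3,D:0.3):0.1);")
  wrong <- ape::unroot(wrong)
  ml <- nni_search(wrong, aln)
  expect_true(same_topology(ml, true))
  # exhaustive 3-topology oracle: the NNI result beats both alternatives
  alts <- nni_neighbors(ml)
  for (alt in alts) {
    expect_lt(attr(optimize_branch_lengths(alt, aln), "loglik"),
              attr(ml, "loglik") + 1e-6)
  }
  again <- nni_search(ml, aln)
  expect_true(same_topology(again, ml))
  expect_gte(attr(again, "loglik"), attr(ml, "loglik") - 1e-6)
})

test_that("RELL supports behave at the edges and sum to 100", {
  expect_equal(rell_bootstrap(matrix(rnorm(50), 1), 500, seed = 1), 100)

  L <- matrix(rep(rnorm(80), 2), 2, byrow = TRUE)
  s <- rell_bootstrap(L, 10000, seed = 2)
  expect_equal(s[1], 50, tolerance = 0.01)   # exact ties split equally
  expect_equal(sum(s), 100)

  dom <- rbind(rep(-1, 60), rep(-2, 60))
  expect_equal(rell_bootstrap(dom, 1000, seed = 3), c(100, 0))

  set.seed(4)
  L3 <- matrix(rnorm(300), 3)
  expect_equal(sum(rell_bootstrap(L3, 2000, seed = 5)), 100)
  expect_error(rell_bootstrap(matrix(numeric(0), 1, 0)), "empty site")
})

test_that("candidate supports map onto reference bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  t3 <- ape::read.tree(text = "((A,B),(C,E),D);")
  br <- rell_branch_support(t1, list(t1, t2, t3), c(70, 20, 10))
  # splits are canonicalized as the side without taxon A, so the A|B split
  # is keyed "C|D|E"; t1 and t3 both contain it
  expect_equal(br$support[br$bipartition == "C|D|E"], 80)
  expect_equal(br$support[br$bipartition == "C|D"], 70)  # only t1
})
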