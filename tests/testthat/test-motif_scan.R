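test_that("consensus matches the brute-force per-column counter", {
  set.seed(101)
  for (i in 1:30) {
    aln <- random_alignment(sample(2:12, 1), sample(5:60, 1),
                            gap_prob = runif(1, 0, 0.45))
    pmin <- sample(c(0.3, 0.5, 0.8), 1)
    prof <- build_consensus(aln, plurality_min = pmin)
    orc <- oracle_consensus(aln, pmin)
    expect_identical(prof$consensus, orc$consensus)
    expect_equal(prof$conservation, orc$conservation)
    expect_equal(prof$gap_fraction, orc$gap_fraction)
  }
})

test_that("consensus handles identity, plurality and all-gap columns", {
  aln <- cluster_alignment("id", c(a = "ACDG", b = "ACDG", c = "ACDG"))
  prof <- build_consensus(aln)
  expect_identical(paste(prof$consensus, collapse = ""), "ACDG")
  expect_equal(prof$conservation, rep(1, 4))

  aln <- cluster_alignment("plur", c(a = "A", b = "A", c = "G"))
  prof <- build_consensus(aln, plurality_min = 0.5)
  expect_identical(prof$consensus, "A")
  expect_equal(prof$conservation, 2 / 3)

  aln <- cluster_alignment("gap", c(a = "-", b = "-", c = "-"))
  prof <- build_consensus(aln)
  expect_identical(prof$consensus, "-")
  expect_equal(prof$conservation, 0)
  # conservation can never exceed the non-gap fraction
  set.seed(7)
  aln <- random_alignment(8, 40, gap_prob = 0.4)
  prof <- build_consensus(aln)
  expect_true(all(prof$conservation <= 1 - prof$gap_fraction + 1e-12))
})

test_that("terminal majority-gap columns are trimmed, interior kept", {
  aln <- cluster_alignment("t", c(a = "-AGG-", b = "AA-GG", c = "-AGG-",
                                  d = "-AGG-"))
  prof <- build_consensus(aln)
  trimmed <- trim_terminal_gap_columns(prof)
  # first and last columns are 75% gap; interior column 3 (50% would stay,
  # here 25%) is untouched
  expect_length(trimmed$consensus, 3L)
  expect_true(all(trimmed$gap_fraction <= 0.5))

  no_gap <- build_consensus(cluster_alignment("n", c(a = "MKGG", b = "MKGG")))
  expect_identical(trim_terminal_gap_columns(no_gap), no_gap)

  all_gap <- build_consensus(cluster_alignment("g", c(a = "--", b = "--")))
  expect_warning(out <- trim_terminal_gap_columns(all_gap), "majority-gap")
  expect_length(out$consensus, 0L)
})

test_that("the terminal doublet test needs a strong conserved GG/CC", {
  mk <- function(seqs) trim_terminal_gap_columns(
    build_consensus(cluster_alignment("x", seqs)))
  hit <- detect_cterminal_doublet(
    mk(c(a = "MVSGG", b = "MVSGG", c = "MVSGG", d = "MVAGG")), cons_min = 0.8)
  expect_identical(hit$motif, "GG")
  expect_equal(hit$cons1, 1)

  expect_null(detect_cterminal_doublet(
    mk(c(a = "MVSGA", b = "MVSGA", c = "MVSGA")), cons_min = 0.8))

  # second column conserved below threshold: G(1.0), then G at 0.4
  weak <- mk(c(a = "MKGG", b = "MKGG", c = "MKGA", d = "MKGC", e = "MKGD"))
  expect_null(detect_cterminal_doublet(weak, cons_min = 0.8))

  one_col <- build_consensus(cluster_alignment("s", c(a = "G", b = "G")))
  expect_message(out <- detect_cterminal_doublet(one_col), "fewer than 2")
  expect_null(out)
})

test_that("scan excludes large families and recovers exactly the planted ones", {
  planted <- lapply(1:3, function(i)
    generate_motif_family(sprintf("ubl%02d", i), 25, 90, "GG", 0.95,
                          seed = 300 + i))
  # small but unconserved (dec01-04) and large but perfectly conserved
  # (dec05-07) families must both be rejected
  decoys <- lapply(1:7, function(i)
    generate_motif_family(sprintf("dec%02d", i), 25,
                          if (i <= 4) 120 else 250, "GG",
                          if (i <= 4) 0.3 else 0.95, seed = 400 + i))
  hits <- scan_clusters(c(planted, decoys), max_len = 200, cons_min = 0.8)
  expect_identical(hits$cluster_id, c("ubl01", "ubl02", "ubl03"))
  expect_true(all(hits$motif == "GG"))
  expect_true(all(hits$median_len < 200))
})

test_that("raising cons_min removes hits only; raising max_len adds only", {
  set.seed(55)
  fams <- lapply(1:12, function(i)
    generate_motif_family(sprintf("f%02d", i), 20,
                          sample(c(100, 150, 220, 300), 1),
                          sample(c("GG", "CC"), 1), runif(1, 0.4, 1),
                          seed = 500 + i))
  base <- scan_clusters(fams, max_len = 200, cons_min = 0.7)
  stricter <- scan_clusters(fams, max_len = 200, cons_min = 0.9)
  expect_true(all(stricter$cluster_id %in% base$cluster_id))
  wider <- scan_clusters(fams, max_len = 350, cons_min = 0.7)
  expect_true(all(base$cluster_id %in% wider$cluster_id))
})
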