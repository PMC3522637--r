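test_that("fitch_length matches textbook cases", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 1)
  expect_equal(fitch_length(tr, c(A = "0", B = "1", C = "0", D = "1")), 2)
  expect_equal(fitch_length(tr, c(A = "A", B = "A", C = "A", D = "A")), 0)
  expect_error(fitch_length(tr, c(A = "0", B = "0", C = "1")), "absent")
})

test_that("fitch_length equals brute force on random trees and columns", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    k <- sample(2:4, 1)
    col <- random_column(tr$tip.label, as.character(0:(k - 1)))
    expect_equal(fitch_length(tr, col),
                 oracle_fitch_length(tr, col, as.character(0:(k - 1))),
                 info = paste("case", i))
  }
})

test_that("matrix_length sums per-column lengths; constants contribute 0", {
  set.seed(11)
  tr <- random_tree(6)
  m <- random_morph(tr$tip.label, n_char = 12, k = 3)
  per_col <- vapply(seq_len(ncol(m)), function(j)
    fitch_length(tr, stats::setNames(as.character(unclass(m)[, j]),
                                     rownames(m))), integer(1))
  expect_equal(matrix_length(tr, m), sum(per_col))

  const <- morph_matrix(matrix(1L, 6, 3, dimnames = list(tr$tip.label, NULL)))
  expect_equal(matrix_length(tr, const), 0)
  empty <- morph_matrix(matrix(integer(0), 6, 0,
                               dimnames = list(tr$tip.label, NULL)))
  expect_equal(matrix_length(tr, empty), 0)
})

test_that("matrix_length is invariant under re-rooting", {
  set.seed(12)
  tr <- random_tree(7)
  aln <- evolve_sequences(simulate_yule_tree(7, height = 0.3,
                                             tip_prefix = "x"), L = 60)
  rownames(aln) <- tr$tip.label  # same taxa, arbitrary assignment
  aln <- seq_alignment(unclass(aln))
  base <- matrix_length(tr, aln)
  for (tip in tr$tip.label[1:3]) {
    rer <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(matrix_length(rer, aln), base)
  }
})

test_that("fitch_length agrees with phangorn on DNA columns", {
  skip_if_not_installed("phangorn")
  set.seed(13)
  tr <- random_tree(8)
  aln <- evolve_sequences(simulate_yule_tree(8, height = 0.4), L = 40)
  rownames(aln) <- tr$tip.label
  aln <- seq_alignment(unclass(aln))
  pd <- phangorn::phyDat(unclass(aln), type = "DNA")
  expect_equal(matrix_length(tr, aln),
               phangorn::fitch(ape::unroot(tr), pd))
})

test_that("parsimony-informative site counting follows the definition", {
  aln <- seq_alignment(rbind(t1 = c("A", "A", "A", "G", "A"),
                             t2 = c("A", "A", "C", "G", "-"),
                             t3 = c("C", "A", "C", "T", "A"),
                             t4 = c("C", "C", "A", "T", "?")))
  # col1: A2 C2 -> informative; col2: A3 C1 no; col3: A2 C2 yes;
  # col4: G2 T2 yes; col5: A2 only -> no
  expect_equal(count_informative_sites(aln), 3)

  # col1 informative (0 twice, 1 twice); col2 not (only state 1 recurs)
  m <- morph_matrix(rbind(a = c(0L, 0L), b = c(0L, 1L),
                          c = c(1L, NA), d = c(1L, 1L)))
  expect_equal(count_informative_sites(m), 1)
})

test_that("informative-site counting matches enumeration on random data", {
  set.seed(14)
  for (i in 1:25) {
    m <- random_morph(paste0("s", 1:8), n_char = 20, k = 3, p_missing = 0.2)
    expected <- sum(vapply(seq_len(ncol(m)), function(j) {
      tb <- table(unclass(m)[, j], useNA = "no")
      sum(tb >= 2) >= 2
    }, logical(1)))
    expect_equal(count_informative_sites(m), expected)
  }
})

test_that("ancestral reconstruction returns forced and resolved cases", {
  tr2 <- parse_newick("(A,B);")
  ar <- ancestral_states(tr2, morph_matrix(rbind(A = 0L, B = 1L)))
  expect_equal(ar$mpr_sets[3, 1], "01")  # root set {0,1}
  expect_equal(ar$length, 1)

  tr4 <- parse_newick("((A,B),(C,D));")
  m <- morph_matrix(matrix(c(0L, 0L, 1L, 1L), 4,
                           dimnames = list(c("A", "B", "C", "D"), NULL)))
  ar4 <- ancestral_states(tr4, m)
  sets <- ar4$mpr_sets[5:7, 1]
  expect_true("0" %in% sets && "1" %in% sets)  # each cherry resolved
  expect_equal(ar4$length, 1)
})

test_that("MPR node sets equal brute-force optimal-labeling sets", {
  set.seed(303)
  for (i in 1:200) {
    tr <- random_tree(6)
    k <- sample(2:3, 1)
    col <- random_column(tr$tip.label, as.character(0:(k - 1)),
                         p_missing = 0.15)
    ar <- ancestral_states(tr, morph_matrix(matrix(
      as.integer(col[tr$tip.label]), ncol = 1,
      dimnames = list(tr$tip.label, NULL))))
    oracle <- oracle_mpr_sets(tr, col, as.character(0:(k - 1)))
    ntip <- 6
    for (v in (ntip + 1):(ntip + tr$Nnode)) {
      got <- strsplit(ar$mpr_sets[v, 1], "")[[1]]
      expect_equal(sort(got), oracle[[v]],
                   info = paste("case", i, "node", v))
    }
  }
})

test_that("single resolution attains minimum length and sums to it", {
  set.seed(404)
  for (i in 1:100) {
    tr <- random_tree(sample(4:8, 1))
    m <- random_morph(tr$tip.label, n_char = sample(3:10, 1), k = 3,
                      p_missing = 0.1)
    tw <- branch_changes(tr, m)
    expect_equal(sum(tw$steps, na.rm = TRUE), matrix_length(tr, m),
                 info = paste("case", i))
  }
})

test_that("branch changes localize a single variable character on a cherry", {
  tr <- parse_newick("((A,B),(C,D));")
  m <- morph_matrix(matrix(c(1L, 0L, 0L, 0L), 4,
                           dimnames = list(c("A", "B", "C", "D"), NULL)))
  tw <- branch_changes(tr, m)
  st <- branch_steps(tw)
  expect_equal(sum(st$steps), 1)
  changed <- st$child[st$steps == 1]
  expect_equal(tr$tip.label[changed], "A")

  const <- morph_matrix(matrix(2L, 4, 5,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_true(all(branch_steps(branch_changes(tr, const))$steps == 0))
})

test_that("consensus reproduces strict and majority behavior", {
  t1 <- parse_newick("((A,B),(C,D));")
  expect_equal(write_newick(consensus_tree(list(t1, t1, t1), "strict")),
               write_newick(t1))

  quartets <- list(parse_newick("((A,B),(C,D));"),
                   parse_newick("((A,C),(B,D));"),
                   parse_newick("((A,D),(B,C));"))
  expect_equal(write_newick(consensus_tree(quartets, "strict")),
               "(A,B,C,D);")

  t2 <- parse_newick("((A,C),(B,D));")
  maj <- consensus_tree(list(t1, t1, t2), "majority")
  expect_equal(write_newick(maj), "((A,B)66.7,(C,D)66.7);")
})

test_that("consensus agrees with ape's consensus on random tree sets", {
  set.seed(21)
  for (i in 1:10) {
    trees <- replicate(5, random_tree(6, labels = paste0("s", 1:6)),
                       simplify = FALSE)
    mine <- consensus_tree(trees, "strict")
    ref <- ape::consensus(trees, rooted = TRUE)
    expect_true(same_topology(mine, ref))
  }
})
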