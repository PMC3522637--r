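test_that("exhaustive search enumerates (2n-5)!! topologies", {
  aln5 <- seq_alignment(c(a = "AATT", b = "AATA", c = "TTAA", d = "TTAC",
                          e = "TAGG"))
  res <- exhaustive_search(aln5)
  expect_equal(res$n_examined, 15)
  expect_true(all(vapply(res$trees, inherits, logical(1), "phylo")))

  aln4 <- seq_alignment(c(a = "AA", b = "AA", c = "TT", d = "TT"))
  expect_equal(exhaustive_search(aln4)$n_examined, 3)
})

test_that("all-constant data ties every topology at score zero", {
  aln <- seq_alignment(c(a = "AAA", b = "AAA", c = "AAA", d = "AAA",
                         e = "AAA"))
  res <- exhaustive_search(aln)
  expect_equal(res$best_score, 0)
  expect_equal(length(res$trees), 15)
})

test_that("too many taxa for exhaustive search raises a guiding error", {
  set.seed(6)
  aln <- evolve_sequences(simulate_yule_tree(10, height = 0.3), L = 30)
  expect_error(exhaustive_search(aln), "nni_search")
})

test_that("exhaustive search recovers a strongly supported true topology", {
  set.seed(55)
  hits <- 0
  for (i in 1:100) {
    # uniform branch lengths: every internal edge carries real signal
    tr <- random_tree(6)
    tr$edge.length <- rep(0.05, nrow(tr$edge))
    aln <- evolve_sequences(tr, L = 500)
    res <- exhaustive_search(aln)
    if (any(vapply(res$trees, same_topology,
                   logical(1), t2 = ape::root(ape::unroot(tr),
                                              outgroup = sort(tr$tip.label)[1],
                                              resolve.root = TRUE))))
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("NNI search never worsens the start and honors max_rounds = 0", {
  set.seed(66)
  tr <- simulate_yule_tree(7, height = 0.4)
  aln <- evolve_sequences(tr, L = 100)
  start <- random_tree(7, labels = tr$tip.label)
  s0 <- matrix_length(start, aln)
  res <- nni_search(aln, start = start)
  expect_lte(res$best_score, s0)

  frozen <- nni_search(aln, start = start, max_rounds = 0)
  expect_equal(frozen$best_score, s0)
})

test_that("bootstrap is deterministic under a fixed seed", {
  set.seed(77)
  aln <- evolve_sequences(simulate_yule_tree(5, height = 0.4), L = 60)
  b1 <- bootstrap_support(aln, n_reps = 30, seed = 9)
  b2 <- bootstrap_support(aln, n_reps = 30, seed = 9)
  expect_identical(write_newick(b1), write_newick(b2))
})

test_that("unanimous data yields 100% support on every clade", {
  aln <- seq_alignment(c(a = "AAAAA", b = "AAAAA", c = "TTTTT",
                         d = "TTTTT"))
  bs <- bootstrap_support(aln, n_reps = 50, seed = 2)
  sup <- node_support(bs)
  expect_true(all(sup$bs[!is.na(sup$bs)] == 100))
  expect_gte(sum(!is.na(sup$bs)), 1)
})

test_that("bootstrap frequencies are stable across seeds to within 5 points", {
  set.seed(88)
  tr <- simulate_yule_tree(5, height = 0.4)
  aln <- evolve_sequences(tr, L = 300)
  b1 <- bootstrap_support(aln, n_reps = 500, seed = 1)
  b2 <- bootstrap_support(aln, n_reps = 500, seed = 2)
  descendants_of <- function(tree, v) {
    ntip <- length(tree$tip.label)
    if (v <= ntip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, descendants_of, tree = tree))
  }
  clade_support <- function(tree) {
    ntip <- length(tree$tip.label)
    sup <- node_support(tree)
    out <- numeric(0)
    for (v in setdiff((ntip + 1):(ntip + tree$Nnode), ntip + 1)) {
      key <- paste(sort(tree$tip.label[descendants_of(tree, v)]),
                   collapse = "|")
      out[key] <- sup$bs[sup$node == v]
    }
    out
  }
  f1 <- clade_support(b1); f2 <- clade_support(b2)
  shared <- intersect(names(f1), names(f2))
  expect_gte(length(shared), 1)
  ok <- !is.na(f1[shared]) & !is.na(f2[shared])
  expect_true(all(abs(f1[shared][ok] - f2[shared][ok]) < 5 + 1e-9))
})
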