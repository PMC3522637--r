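test_that("cladistic distance counts internal nodes on the path", {
  cherry <- parse_newick("(A,B);")
  expect_equal(cladistic_distance_matrix(cherry)["A", "B"], 1)

  bal <- parse_newick("((A,B),(C,D));")
  cd <- cladistic_distance_matrix(bal)
  expect_equal(cd["A", "B"], 1)
  expect_equal(cd["A", "C"], 3)
  expect_equal(cd["C", "D"], 1)
})

test_that("cladistic distance matches a graph-walk oracle on random trees", {
  set.seed(111)
  for (i in 1:100) {
    tr <- random_tree(sample(4:10, 1))
    cd <- cladistic_distance_matrix(tr)
    pairs <- utils::combn(tr$tip.label, 2)
    j <- sample(ncol(pairs), 1)
    a <- pairs[1, j]; b <- pairs[2, j]
    expect_equal(cd[a, b], oracle_path_internal_nodes(tr, a, b),
                 info = paste("case", i))
  }
})

test_that("patristic distance sums branch steps along the path", {
  cherry <- parse_newick("(A,B);")
  tw <- cherry
  tw$steps <- c(2, 3, NA)  # A, B, root
  expect_equal(patristic_distance_matrix(tw)["A", "B"], 5)

  zero <- cherry
  zero$steps <- c(0, 0, NA)
  expect_equal(unname(unclass(patristic_distance_matrix(zero))),
               matrix(0, 2, 2))

  bad <- cherry
  bad$steps <- c(2, NA, NA)
  expect_error(patristic_distance_matrix(bad), "missing step count")
})

test_that("patristic distances decompose through the MRCA", {
  set.seed(222)
  for (i in 1:50) {
    tr <- random_tree(sample(5:8, 1))
    m <- random_morph(tr$tip.label, n_char = 10, k = 3)
    tw <- branch_changes(tr, m)
    pd <- patristic_distance_matrix(tw)
    # root-path sums: d(i,j) must equal d(i->mrca) + d(mrca->j)
    st <- branch_steps(tw)
    steps_above <- stats::setNames(st$steps, st$child)
    parv <- stats::setNames(st$parent, st$child)
    to_root <- function(v) {
      s <- 0; v <- as.character(v)
      while (v %in% names(parv)) { s <- s + steps_above[[v]]
        v <- as.character(parv[[v]]) }
      s
    }
    labs <- tr$tip.label
    a <- sample(labs, 1); b <- sample(setdiff(labs, a), 1)
    mn <- mrca_node(tr, c(a, b))
    d_am <- to_root(match(a, labs)) - to_root(mn)
    d_bm <- to_root(match(b, labs)) - to_root(mn)
    expect_equal(pd[a, b], d_am + d_bm, info = paste("case", i))
  }
})

test_that("combination weights behave degenerately and linearly", {
  labs <- c("A", "B")
  cd <- dist_matrix(matrix(c(0, 1, 1, 0), 2, dimnames = list(labs, labs)))
  pd <- dist_matrix(matrix(c(0, 5, 5, 0), 2, dimnames = list(labs, labs)))
  expect_identical(unclass(combine_distances(cd, pd, 1, 0)), unclass(cd))
  expect_identical(unclass(combine_distances(cd, pd, 0, 1)), unclass(pd))
  expect_equal(unclass(combine_distances(cd, pd))["A", "B"], 6)

  set.seed(3)
  w <- runif(4)
  lhs <- unclass(combine_distances(cd, pd, w[1], w[2])) +
    unclass(combine_distances(cd, pd, w[3], w[4]))
  rhs <- unclass(combine_distances(cd, pd, w[1] + w[3], w[2] + w[4]))
  expect_equal(lhs, rhs)

  pd2 <- dist_matrix(matrix(c(0, 5, 5, 0), 2,
                            dimnames = list(c("A", "X"), c("A", "X"))))
  expect_error(combine_distances(cd, pd2, 1, 1), "label mismatch")
  expect_error(combine_distances(cd, pd, 0, 0), "positive")
})

test_that("UPGMA reproduces the hand-worked three-taxon case", {
  labs <- c("A", "B", "C")
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, dimnames = list(labs, labs))
  res <- upgma(dist_matrix(m))
  expect_equal(res$heights, c(1, 3))
  expect_equal(write_newick(res$tree), "((A:1,B:1):2,C:3);")
})

test_that("UPGMA is ultrametric and refuses saturated entries", {
  set.seed(33)
  x <- matrix(runif(36, 0.1, 1), 6)
  x <- x + t(x); diag(x) <- 0
  dimnames(x) <- list(letters[1:6], letters[1:6])
  res <- upgma(dist_matrix(x))
  depths <- ape::node.depth.edgelength(res$tree)
  tipd <- depths[seq_len(6)]
  expect_lt(max(tipd) - min(tipd), 1e-9)

  x[1, 2] <- x[2, 1] <- NA
  expect_error(upgma(dist_matrix(x)), "saturated")
})

test_that("UPGMA recovers clock-tree topologies from their distances", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    tr <- simulate_yule_tree(n, height = 1)
    dm <- dist_matrix(ape::cophenetic.phylo(tr))
    res <- upgma(dm)
    expect_true(same_topology(res$tree, tr), info = paste("case", i))
  }
})

test_that("UPGMA agrees with hclust average linkage on generic matrices", {
  set.seed(55)
  x <- matrix(runif(64, 0.2, 2), 8)
  x <- x + t(x); diag(x) <- 0
  dimnames(x) <- list(letters[1:8], letters[1:8])
  res <- upgma(dist_matrix(x))
  hc <- stats::hclust(stats::as.dist(x), method = "average")
  expect_equal(sort(res$heights), sort(hc$height / 2), tolerance = 1e-10)
})

test_that("full patrocladistic analysis equals its manual composition", {
  set.seed(66)
  tr <- random_tree(6)
  m <- random_morph(tr$tip.label, n_char = 12, k = 2, p_missing = 0)
  pa <- patrocladistic_analysis(tr, m)

  tw <- branch_changes(tr, m)
  cd <- cladistic_distance_matrix(tw)
  pd <- patristic_distance_matrix(tw)
  comb <- combine_distances(cd, pd)
  expect_identical(unclass(pa$cladistic), unclass(cd))
  expect_identical(unclass(pa$patristic), unclass(pd))
  expect_identical(unclass(pa$combined), unclass(comb))
  expect_equal(write_newick(pa$patrocladogram$tree),
               write_newick(upgma(comb)$tree))

  # display matrix: cladistic lower-left, patristic upper-right
  expect_equal(pa$display[lower.tri(pa$display)],
               unclass(cd)[lower.tri(cd)])
  expect_equal(pa$display[upper.tri(pa$display)],
               unclass(pd)[upper.tri(pd)])
})

test_that("constant data reduces the analysis to cladistic distances", {
  tr <- random_tree(5)
  const <- morph_matrix(matrix(0L, 5, 4, dimnames = list(tr$tip.label,
                                                         NULL)))
  pa <- patrocladistic_analysis(tr, const)
  expect_equal(unclass(pa$combined), unclass(pa$cladistic))
  expect_true(all(unclass(pa$patristic) == 0))
})

test_that("planted intruders stay embedded among focal taxa", {
  # the smallest patrocladogram cluster holding an intruder must contain
  # focal members and no outgroup taxon: intruders remain embedded
  for (s in 1:10) {
    sc <- make_paraphyly_scenario(seed = s)
    pa <- patrocladistic_analysis(sc$tree, sc$morphology)
    ptree <- pa$patrocladogram$tree
    ntip <- length(ptree$tip.label)
    parv <- rep(NA_integer_, ntip + ptree$Nnode)
    parv[ptree$edge[, 2]] <- ptree$edge[, 1]
    for (intr in sc$intruders) {
      v <- parv[match(intr, ptree$tip.label)]
      repeat {
        tips <- ape::extract.clade(ptree, v)$tip.label
        others <- setdiff(tips, intr)
        if (length(others)) break
        v <- parv[v]
      }
      expect_gt(length(intersect(others, sc$focal)), 0,
                label = paste("seed", s, intr, "focal neighbors"))
      expect_length(intersect(others, sc$outgroup), 0)
    }
  }
})
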