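# ---- synthetic data generation -----------------------------------------------
#
# Generators emulating the statistical structure of a small-genus molecular +
# morphological study: Yule trees, Kimura 2-parameter sequence evolution
# (matching the distance estimator, so parameter recovery is a closed loop),
# symmetric k-state Mk morphological characters, and a planted paraphyly
# scenario in which "intruder" taxa sit inside two distinct subclades of a
# focal clade and share a convergently derived character state.

#' Simulate a Yule (pure-birth) tree
#'
#' Lineages split at rate `birth` per lineage; the process stops at `n`
#' tips and runs one further exponential waiting time so tip branches have
#' positive length. Branch lengths are in expected substitutions per site
#' once multiplied by a process rate.
#'
#' @param n number of tips (>= 2).
#' @param birth per-lineage birth rate (> 0).
#' @param seed optional RNG seed (recorded as attribute `"seed"`).
#' @param tip_prefix prefix for tip labels (`t1`, `t2`, ... by default).
#' @param height optional total tree height to rescale to.
#' @return a rooted binary `phylo` tree with branch lengths.
#' @export
simulate_yule_tree <- function(n, birth = 1, seed = NULL, tip_prefix = "t",
                               height = NULL) {
  stopifnot(n >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages; each has a parent node id and a birth time
  nodes_parent <- c(NA_integer_, 1L, 1L)  # node 1 = root, splits at t = 0
  nodes_btime <- c(0, 0, 0)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n) {
    t <- t + stats::rexp(1, rate = birth * length(active))
    i <- active[sample.int(length(active), 1L)]
    k <- length(nodes_parent)
    nodes_parent <- c(nodes_parent, i, i)
    nodes_btime <- c(nodes_btime, t, t)
    active <- c(setdiff(active, i), k + 1L, k + 2L)
  }
  t_end <- t + stats::rexp(1, rate = birth * n)
  ntot <- length(nodes_parent)
  is_tip <- !(seq_len(ntot) %in% nodes_parent)
  # renumber: tips 1..n (in creation order), internals n+1.. (root first)
  tip_ids <- which(is_tip)
  int_ids <- which(!is_tip)
  map <- integer(ntot)
  map[tip_ids] <- seq_len(n)
  map[int_ids] <- n + seq_along(int_ids)
  parent <- nodes_parent
  edge <- cbind(map[parent[-1L]], map[-1L])
  # branch length = child's end time - birth time of the branch
  end_time <- ifelse(is_tip, t_end, NA)
  for (i in int_ids) {
    kidset <- which(nodes_parent == i)
    end_time[i] <- nodes_btime[kidset[1L]]
  }
  elen <- (end_time - nodes_btime)[-1L]
  ord <- order(map[-1L])
  tree <- list(edge = edge, tip.label = paste0(tip_prefix, seq_len(n)),
               Nnode = n - 1L, edge.length = elen)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  if (!is.null(height) && t_end > 0)
    tree$edge.length <- tree$edge.length * (height / t_end)
  attr(tree, "seed") <- seed
  validate_tree(tree)
}

# K2P per-branch substitution probabilities for branch length d (expected
# substitutions per site) and transition/transversion rate ratio kappa:
# P(transition), P(each transversion)
.k2p_probs <- function(d, kappa) {
  ts <- 0.25 + 0.25 * exp(-4 * d / (kappa + 2)) -
    0.5 * exp(-2 * d * (kappa + 1) / (kappa + 2))
  tv <- 0.25 - 0.25 * exp(-4 * d / (kappa + 2))
  c(ts = ts, tv = tv)
}

# partner tables: transition partner and the two transversion partners
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Evolve DNA sequences on a tree under the K2P model
#'
#' The root sequence is uniform over A/C/G/T; each branch applies the Kimura
#' two-parameter substitution process with transition/transversion rate
#' ratio `kappa`, with branch lengths scaled by `rate` so that the expected
#' number of substitutions per site on a branch is `rate * length`.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param L number of sites.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param rate per-site rate multiplier applied to branch lengths.
#' @param seed optional RNG seed.
#' @return a [seq_alignment()] over the tree's tips.
#' @export
evolve_sequences <- function(tree, L = 1000, kappa = 2, rate = 1,
                             seed = NULL) {
  stopifnot(L >= 1, kappa > 0, rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  validate_tree(tree)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  nn <- n_tips(tree) + tree$Nnode
  seqs <- matrix(NA_character_, nn, L)
  seqs[root_node(tree), ] <- sample(bases, L, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    d <- rate * tr$edge.length[e]
    pr <- .k2p_probs(d, kappa)
    parent <- seqs[u, ]
    child <- parent
    u01 <- stats::runif(L)
    # event classes: transition, transversion 1, transversion 2
    cls <- (u01 < pr["ts"]) + 2 * (u01 >= pr["ts"] & u01 < pr["ts"] +
                                     pr["tv"]) +
      3 * (u01 >= pr["ts"] + pr["tv"] & u01 < pr["ts"] + 2 * pr["tv"])
    ts_idx <- which(cls == 1)
    child[ts_idx] <- .TS_PARTNER[parent[ts_idx]]
    for (w in 1:2) {
      idx <- which(cls == w + 1)
      child[idx] <- vapply(parent[idx],
                           function(b) .TV_PARTNERS[[b]][w], character(1))
    }
    seqs[v, ] <- child
  }
  m <- seqs[seq_len(n_tips(tree)), , drop = FALSE]
  rownames(m) <- tree$tip.label
  seq_alignment(m)
}

#' Evolve unordered morphological characters under the Mk model
#'
#' Each character evolves independently under the symmetric `k`-state
#' Markov process; the root state is uniform. `rate` is the expected number
#' of changes per character per unit branch length.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param n_char number of characters.
#' @param k number of states per character (2..10; coded `0..k-1`).
#' @param rate expected changes per character per unit branch length.
#' @param seed optional RNG seed.
#' @return a [morph_matrix()] over the tree's tips.
#' @export
evolve_morphology <- function(tree, n_char = 45, k = 2, rate = 1,
                              seed = NULL) {
  stopifnot(n_char >= 1, k >= 2, k <= 10, rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  validate_tree(tree)
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths", call. = FALSE)
  nn <- n_tips(tree) + tree$Nnode
  st <- matrix(NA_integer_, nn, n_char)
  st[root_node(tree), ] <- sample.int(k, n_char, replace = TRUE) - 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    t1 <- rate * tr$edge.length[e]
    p_same <- 1 / k + (1 - 1 / k) * exp(-k * t1 / (k - 1))
    stay <- stats::runif(n_char) < p_same
    shift <- sample.int(k - 1L, n_char, replace = TRUE)
    st[v, ] <- ifelse(stay, st[u, ], (st[u, ] + shift) %% k)
  }
  m <- st[seq_len(n_tips(tree)), , drop = FALSE]
  rownames(m) <- tree$tip.label
  morph_matrix(m)
}

#' Build a planted-paraphyly scenario
#'
#' Emulates the situation in which a narrowly circumscribed focal genus is
#' paraphyletic: a focal clade of `n_focal` taxa (labels `F...`) contains
#' `n_intruders` intruder taxa (labels `I...`) grafted inside distinct
#' subclades, with a distant outgroup clade (labels `O...`). A binary
#' "convergent" character assigns the derived state to each intruder and
#' its sister leaf, so the derived state requires at least two independent
#' parsimony gains on the true tree. DNA and morphological matrices are
#' evolved on the true tree.
#'
#' @param n_focal focal-clade taxa (>= 6).
#' @param n_intruders intruders placed round-robin into the two basal focal
#'   subclades (default 2).
#' @param n_outgroup outgroup taxa (>= 2).
#' @param L sites in the DNA alignment.
#' @param kappa transition/transversion rate ratio.
#' @param n_char,k_states,morph_rate morphological matrix settings.
#' @param focal_height tree height of the focal clade in expected
#'   substitutions per site.
#' @param outgroup_depth extra stem depth separating the outgroup.
#' @param seed RNG seed (drives every random choice).
#' @return list of class `paraphyly_scenario`: `tree` (true rooted tree with
#'   branch lengths), `alignment`, `morphology`, `convergent` (named binary
#'   character vector), `focal` (labels), `intruders`, `outgroup`,
#'   `subclade_of` (which basal focal subclade each intruder entered), and
#'   `seed`.
#' @export
make_paraphyly_scenario <- function(n_focal = 12, n_intruders = 2,
                                    n_outgroup = 4, L = 1000, kappa = 2,
                                    n_char = 45, k_states = 2,
                                    morph_rate = 8,
                                    focal_height = 0.05,
                                    outgroup_depth = 0.15, seed = 1) {
  stopifnot(n_focal >= 6, n_intruders >= 1, n_outgroup >= 2)
  set.seed(seed)
  focal_tree <- simulate_yule_tree(n_focal, tip_prefix = "F",
                                   height = focal_height)
  out_tree <- simulate_yule_tree(n_outgroup, tip_prefix = "O",
                                 height = focal_height / 2)
  # two basal subclades of the focal clade = the root's two child subtrees
  kids <- children_list(focal_tree)[[root_node(focal_tree)]]
  dt <- descendant_tips(focal_tree)
  sub1 <- focal_tree$tip.label[dt[[kids[1L]]]]
  sub2 <- focal_tree$tip.label[dt[[kids[2L]]]]
  subclades <- list(sub1, sub2)
  # graft each intruder onto a random leaf branch of its subclade
  tree <- focal_tree
  hosts <- character(n_intruders)
  sub_of <- integer(n_intruders)
  for (i in seq_len(n_intruders)) {
    sub_of[i] <- ((i - 1L) %% 2L) + 1L
    host <- sample(subclades[[sub_of[i]]], 1L)
    hosts[i] <- host
    tree <- .graft_sister(tree, host, paste0("I", i))
  }
  # attach the outgroup below the focal clade
  og <- out_tree
  f_nwk <- .subtree_newick(tree)
  o_nwk <- .subtree_newick(og)
  stem_f <- outgroup_depth
  stem_o <- outgroup_depth + focal_height - focal_height / 2
  full <- parse_newick(paste0("(", f_nwk, ":", stem_f, ",", o_nwk, ":",
                              stem_o, ");"))
  aln <- evolve_sequences(full, L = L, kappa = kappa)
  morph <- evolve_morphology(full, n_char = n_char, k = k_states,
                             rate = morph_rate)
  conv <- stats::setNames(rep("0", n_tips(full)), full$tip.label)
  for (i in seq_len(n_intruders)) {
    conv[paste0("I", i)] <- "1"
    conv[hosts[i]] <- "1"
  }
  structure(list(tree = full, alignment = aln, morphology = morph,
                 convergent = conv,
                 focal = paste0("F", seq_len(n_focal)),
                 intruders = paste0("I", seq_len(n_intruders)),
                 outgroup = paste0("O", seq_len(n_outgroup)),
                 subclade_of = sub_of, hosts = hosts, seed = seed),
            class = "paraphyly_scenario")
}

#' @export
print.paraphyly_scenario <- function(x, ...) {
  cat("Planted paraphyly scenario (seed ", x$seed, "): ",
      length(x$focal), " focal + ", length(x$intruders), " intruder + ",
      length(x$outgroup), " outgroup taxa\n", sep = "")
  invisible(x)
}

# newick of a tree with branch lengths, no trailing semicolon
.subtree_newick <- function(tree) {
  sub(";$", "", write_newick(tree))
}

# graft a new tip as sister to an existing leaf, splitting its branch at the
# midpoint; the new tip's branch length keeps the tree ultrametric
.graft_sister <- function(tree, host, new_label) {
  hid <- match(host, tree$tip.label)
  elen <- tree$edge.length[match(hid, tree$edge[, 2L])]
  nwk <- write_newick(tree)
  # replace "host:len" with "(host:len/2,new:len/2):len/2"
  half <- elen / 2
  old <- paste0(host, ":", format(elen, digits = 10, scientific = FALSE,
                                  trim = TRUE))
  new <- paste0("(", host, ":", format(half, digits = 10,
                                       scientific = FALSE, trim = TRUE),
                ",", new_label, ":", format(half, digits = 10,
                                            scientific = FALSE,
                                            trim = TRUE), "):",
                format(half, digits = 10, scientific = FALSE, trim = TRUE))
  nwk2 <- sub(old, new, nwk, fixed = TRUE)
  if (identical(nwk, nwk2))
    stop("internal error: could not graft onto ", host, call. = FALSE)
  parse_newick(nwk2)
}
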