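# Independent oracles and random fixture generators. The oracles enumerate
# or walk structures directly and share no code with the package internals
# they check.

# random rooted binary tree over given labels (ape's generator)
random_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = sample(labels))
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr
}

# random character column: named vector of states over an alphabet, with
# optional missing entries
random_column <- function(labels, alphabet, p_missing = 0.1) {
  x <- sample(alphabet, length(labels), replace = TRUE)
  x[runif(length(labels)) < p_missing] <- NA
  stats::setNames(x, labels)
}

random_morph <- function(labels, n_char, k = 3, p_missing = 0.05) {
  m <- matrix(sample(0:(k - 1), length(labels) * n_char, replace = TRUE),
              nrow = length(labels), dimnames = list(labels, NULL))
  m[matrix(runif(length(m)) < p_missing, nrow(m))] <- NA
  morph_matrix(m)
}

# --- brute-force small parsimony -------------------------------------------
# Enumerates every assignment of alphabet states to internal nodes (and to
# leaves with missing observations) and counts changed edges.

.oracle_setup <- function(tree, column, alphabet) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  leaf_states <- lapply(seq_len(ntip), function(i) {
    s <- column[[tree$tip.label[i]]]
    if (is.na(s) || s %in% c("?", "-")) alphabet else s
  })
  free <- c(which(vapply(leaf_states, length, 1L) > 1L),
            (ntip + 1L):nn)
  list(nn = nn, ntip = ntip, leaf_states = leaf_states, free = free)
}

.oracle_labelings <- function(tree, column, alphabet) {
  su <- .oracle_setup(tree, column, alphabet)
  grids <- rep(list(alphabet), length(su$free))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  edges <- tree$edge
  fixed <- rep(NA_character_, su$nn)
  for (i in seq_len(su$ntip))
    if (length(su$leaf_states[[i]]) == 1L) fixed[i] <- su$leaf_states[[i]]
  lab_len <- function(assign_row) {
    lab <- fixed
    lab[su$free] <- unlist(assign_row)
    sum(lab[edges[, 1]] != lab[edges[, 2]])
  }
  lens <- apply(combos, 1, lab_len)
  list(combos = combos, lens = lens, free = su$free, fixed = fixed,
       min = min(lens))
}

oracle_fitch_length <- function(tree, column, alphabet) {
  .oracle_labelings(tree, column, alphabet)$min
}

# per-node set of states taken in at least one minimum-length labeling
oracle_mpr_sets <- function(tree, column, alphabet) {
  ol <- .oracle_labelings(tree, column, alphabet)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  best <- ol$combos[ol$lens == ol$min, , drop = FALSE]
  sets <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (v %in% ol$free) {
      j <- match(v, ol$free)
      sets[[v]] <- sort(unique(unlist(best[, j])))
    } else sets[[v]] <- ol$fixed[v]
  }
  sets
}

# minimum origins of focal state over minimum-length labelings
# (branch gains + 1 when the root carries the focal state)
oracle_min_origins <- function(tree, column, alphabet, focal) {
  ol <- .oracle_labelings(tree, column, alphabet)
  best <- ol$combos[ol$lens == ol$min, , drop = FALSE]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- tree$edge
  gains <- apply(best, 1, function(row) {
    lab <- ol$fixed
    lab[ol$free] <- unlist(row)
    sum(lab[edges[, 1]] != focal & lab[edges[, 2]] == focal) +
      (lab[root] == focal)
  })
  min(gains)
}

# --- graph-walk path oracles -------------------------------------------------

# number of internal nodes on the path between two tips, by explicit
# root-path comparison
oracle_path_internal_nodes <- function(tree, a, b) {
  par <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  path_up <- function(v) {
    p <- v
    while (!is.na(par[v])) { v <- par[v]; p <- c(p, v) }
    p
  }
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- path_up(ia); pb <- path_up(ib)
  common <- intersect(pa, pb)
  mrca <- common[1]
  nodes <- c(setdiff(pa, c(common, ia)), setdiff(pb, c(common, ib)), mrca)
  length(nodes)
}

# clade sets as canonical strings (topology comparison helper)
clade_strings <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  par <- rep(NA_integer_, nn)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  tips_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    sort(unlist(lapply(kids, tips_under)))
  }
  ids <- setdiff((ntip + 1L):nn, ntip + 1L)
  sort(vapply(ids, function(v) paste(tips_under(v), collapse = "|"),
              character(1)))
}

same_topology <- function(t1, t2) {
  identical(clade_strings(t1), clade_strings(t2))
}
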