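# ---- desk-scale maximum-parsimony tree search --------------------------------
#
# Unrooted topologies are enumerated / rearranged on an edge-matrix
# representation with a basal trifurcation (the usual rooted encoding of an
# unrooted binary tree); parsimony length is root-invariant, and the
# Hartigan count rule scores the trifurcation exactly. Search results are
# returned as trees rooted on the edge of the lexicographically smallest
# taxon, which makes clade sets comparable across replicates.

# score an edge-matrix tree: total parsimony length over all columns
.score_edges <- function(edges, nleaf, masks, alpha) {
  nn <- max(edges)
  nc <- ncol(masks)
  V <- matrix(0L, nn, nc)
  V[seq_len(nleaf), ] <- masks[seq_len(nleaf), , drop = FALSE]
  kids <- vector("list", nn)
  for (e in seq_len(nrow(edges)))
    kids[[edges[e, 1L]]] <- c(kids[[edges[e, 1L]]], edges[e, 2L])
  root <- nleaf + 1L
  # iterative preorder; reversed it is a postorder
  stack <- root; ord <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (c0 in kids[[v]]) if (c0 > nleaf) stack <- c(stack, c0)
  }
  total <- 0
  for (v in rev(ord)) {
    ch <- kids[[v]]
    if (length(ch) == 2L) {
      a <- bitwAnd(V[ch[1L], ], V[ch[2L], ])
      z <- a == 0L
      V[v, ] <- ifelse(z, bitwOr(V[ch[1L], ], V[ch[2L], ]), a)
      total <- total + sum(z)
    } else {
      cnt <- matrix(0L, 10L, nc)
      for (c0 in ch) for (b in 1:10) {
        bit <- bitwShiftL(1L, b - 1L)
        cnt[b, ] <- cnt[b, ] + (bitwAnd(V[c0, ], bit) > 0L)
      }
      K <- do.call(pmax, lapply(1:10, function(b) cnt[b, ]))
      vm <- integer(nc)
      for (b in 1:10) vm <- vm + bitwShiftL(1L, b - 1L) * (cnt[b, ] == K)
      V[v, ] <- vm
      total <- total + sum(length(ch) - K)
    }
  }
  total
}

# convert an edge-matrix tree to a phylo rooted on the smallest taxon's edge
.edges_to_phylo <- function(edges, taxa) {
  nleaf <- length(taxa)
  tr <- list(edge = edges, tip.label = taxa, Nnode = max(edges) - nleaf)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  rooted <- ape::root(tr, outgroup = sort(taxa)[1], resolve.root = TRUE)
  rooted$node.label <- NULL
  rooted
}

# topology identity key (label-canonical newick, no lengths)
.topo_key <- function(tree) {
  tree$edge.length <- NULL
  tree$node.label <- NULL
  write_newick(tree)
}

# enumerate all unrooted topologies over cm$taxa by stepwise insertion,
# keeping every score-optimal edge matrix
.exhaustive_from_masks <- function(cm) {
  taxa <- cm$taxa
  n <- length(taxa)
  base <- cbind(rep(n + 1L, 3L), 1:3)
  best <- Inf; optima <- list(); examined <- 0L
  visit <- function(edges) {
    examined <<- examined + 1L
    sc <- .score_edges(edges, n, cm$masks, cm$alpha)
    if (sc < best) { best <<- sc; optima <<- list(edges) }
    else if (sc == best) optima[[length(optima) + 1L]] <<- edges
  }
  recurse <- function(edges, k, next_int) {
    if (k == n) return(visit(edges))
    leaf <- k + 1L
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      recurse(rbind(edges[-e, , drop = FALSE],
                    c(u, next_int), c(next_int, v), c(next_int, leaf)),
              k + 1L, next_int + 1L)
    }
  }
  if (n == 3L) visit(base) else recurse(base, 3L, n + 2L)
  list(best_score = best, optima = optima, examined = examined)
}

# greedy random-addition starting tree (edge representation)
.random_addition_start <- function(cm) {
  taxa <- cm$taxa
  n <- length(taxa)
  ord <- sample.int(n)
  edges <- cbind(rep(n + 1L, 3L), ord[1:3])
  next_int <- n + 2L
  for (k in seq(4L, length.out = max(0L, n - 3L))) {
    leaf <- ord[k]
    bsc <- Inf; bed <- NULL
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      cand <- rbind(edges[-e, , drop = FALSE],
                    c(u, next_int), c(next_int, v), c(next_int, leaf))
      sc <- .score_edges(cand, n, cm$masks, cm$alpha)
      if (sc < bsc) { bsc <- sc; bed <- cand }
    }
    edges <- bed
    next_int <- next_int + 1L
  }
  edges
}

# all NNI neighbors of an edge-matrix tree (basal trifurcation kept):
# for each internal edge (u,v), swap each child of v with one fixed
# non-v child of u — exactly the two alternative pairings around the edge
.nni_neighbors <- function(edges, nleaf) {
  kids <- split(edges[, 2L], edges[, 1L])
  out <- list()
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    if (v <= nleaf) next
    A <- kids[[as.character(v)]]
    b1 <- setdiff(kids[[as.character(u)]], v)[1L]
    for (a in A) {
      ne <- edges
      ne[ne[, 1L] == v & ne[, 2L] == a, ] <- c(v, b1)
      ne[ne[, 1L] == u & ne[, 2L] == b1, ] <- c(u, a)
      out[[length(out) + 1L]] <- ne
    }
  }
  out
}

# NNI hill climb from a given edge matrix; returns final state
.nni_climb <- function(edges, cm, max_rounds) {
  n <- length(cm$taxa)
  cur <- .score_edges(edges, n, cm$masks, cm$alpha)
  examined <- 1L
  rounds <- 0L
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    nb <- .nni_neighbors(edges, n)
    scs <- vapply(nb, .score_edges, numeric(1),
                  nleaf = n, masks = cm$masks, alpha = cm$alpha)
    examined <- examined + length(nb)
    if (!length(scs) || min(scs) >= cur) break
    pick <- which.min(scs)
    edges <- nb[[pick]]
    cur <- scs[pick]
  }
  list(edges = edges, score = cur, examined = examined)
}

# convert a rooted phylo (any rooting) to the basal-trifurcation edge form
.phylo_to_edges <- function(tree, taxa) {
  tr <- ape::unroot(tree)
  n <- length(taxa)
  map <- c(match(tr$tip.label, taxa), n + seq_len(tr$Nnode))
  edge <- tr$edge
  edge[] <- map[edge]
  edge
}

#' Exhaustive maximum-parsimony search
#'
#' Evaluates every unrooted binary topology — (2n-5)!! of them for n taxa —
#' by stepwise insertion and returns all topologies attaining the minimum
#' parsimony length.
#'
#' @param data a [seq_alignment()], [morph_matrix()] or [combine_data()]
#'   result; its taxa define the tip set.
#' @param max_taxa guard on problem size (at most 9).
#' @return object of class `search_result`: `best_score`, `trees` (list of
#'   optimal trees, rooted on the smallest taxon's edge), `n_examined`.
#' @examples
#' aln <- seq_alignment(c(a = "AAT", b = "AAT", c = "TTA", d = "TTA",
#'                        e = "TAA"))
#' exhaustive_search(aln)$n_examined  # 15 topologies for 5 taxa
#' @export
exhaustive_search <- function(data, max_taxa = 9) {
  cm <- build_column_masks(data)
  n <- length(cm$taxa)
  if (n < 3L) stop("need at least three taxa", call. = FALSE)
  if (n > min(max_taxa, 9L))
    stop("too many taxa (", n, ") for exhaustive search; use nni_search()",
         call. = FALSE)
  res <- .exhaustive_from_masks(cm)
  structure(list(best_score = res$best_score,
                 trees = lapply(res$optima, .edges_to_phylo, taxa = cm$taxa),
                 n_examined = res$examined),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Parsimony search:", x$n_examined, "topologies examined; best score",
      x$best_score, "attained by", length(x$trees), "tree(s)\n")
  invisible(x)
}

#' NNI hill-climbing parsimony search
#'
#' Nearest-neighbor-interchange hill climbing, by default from a greedy
#' random-addition starting tree. The score never increases between rounds
#' and the search stops at a local optimum or after `max_rounds`.
#'
#' @inheritParams exhaustive_search
#' @param start optional rooted `phylo` starting tree; when `NULL` a greedy
#'   random-addition tree is built (set the RNG seed for reproducibility).
#' @param max_rounds maximum number of improvement rounds; `0` returns the
#'   starting tree unchanged.
#' @return a `search_result` (see [exhaustive_search()]); `trees` holds the
#'   distinct best-scoring topologies in the final neighborhood.
#' @export
nni_search <- function(data, start = NULL, max_rounds = 50) {
  cm <- build_column_masks(data)
  n <- length(cm$taxa)
  if (n < 4L) stop("need at least four taxa", call. = FALSE)
  edges <- if (is.null(start)) {
    .random_addition_start(cm)
  } else {
    miss <- setdiff(start$tip.label, cm$taxa)
    if (length(miss))
      stop("start tree taxa absent from data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    .phylo_to_edges(start, cm$taxa)
  }
  fin <- .nni_climb(edges, cm, max_rounds)
  cand <- c(list(fin$edges),
            if (max_rounds > 0) .nni_neighbors(fin$edges, n))
  scs <- vapply(cand, .score_edges, numeric(1),
                nleaf = n, masks = cm$masks, alpha = cm$alpha)
  trees <- lapply(cand[scs == fin$score], .edges_to_phylo, taxa = cm$taxa)
  trees <- trees[!duplicated(vapply(trees, .topo_key, character(1)))]
  structure(list(best_score = fin$score, trees = trees,
                 n_examined = fin$examined),
            class = "search_result")
}

#' Nonparametric bootstrap support for parsimony trees
#'
#' Columns are resampled with replacement; each replicate is analyzed with
#' the chosen search; the strict consensus of the replicate's optimal trees
#' contributes its clades; clade frequencies are reported as percentages on
#' the majority-rule consensus across replicates.
#'
#' @inheritParams exhaustive_search
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed recorded in the result; identical seeds give
#'   identical output.
#' @param search `"exhaustive"` (taxa <= 9) or `"nni"`.
#' @return a rooted majority-rule consensus `phylo` whose internal-node
#'   labels are bootstrap percentages, with attribute `"seed"`.
#' @export
bootstrap_support <- function(data, n_reps = 100, seed = 1,
                              search = c("exhaustive", "nni")) {
  search <- match.arg(search)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  cm <- build_column_masks(data)
  n <- length(cm$taxa)
  if (search == "exhaustive" && n > 9L)
    stop("too many taxa for exhaustive bootstrap; use search = \"nni\"",
         call. = FALSE)
  L <- ncol(cm$masks)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    cmr <- list(masks = cm$masks[, cols, drop = FALSE],
                alpha = cm$alpha[cols], taxa = cm$taxa)
    trees <- if (search == "exhaustive") {
      res <- .exhaustive_from_masks(cmr)
      lapply(res$optima, .edges_to_phylo, taxa = cm$taxa)
    } else {
      fin <- .nni_climb(.random_addition_start(cmr), cmr, max_rounds = 50)
      list(.edges_to_phylo(fin$edges, cm$taxa))
    }
    reps[[r]] <- if (length(trees) == 1L) trees[[1]]
    else consensus_tree(trees, "strict")
  }
  cons <- consensus_tree(reps, "majority", threshold = 0.5)
  attr(cons, "seed") <- seed
  validate_tree(cons)
  cons
}
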