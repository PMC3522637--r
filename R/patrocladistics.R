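# ---- patrocladistic analysis -------------------------------------------------
#
# Patrocladistic classification combines two distance matrices read off one
# cladogram: the cladistic distance (number of internal nodes separating two
# taxa — sister taxa are 1 apart) captures branching order, the patristic
# distance (sum of apomorphic step changes along the path, from a parsimony
# reconstruction of the data on the cladogram) captures divergence. Their
# weighted sum, clustered by UPGMA, is the patrocladogram.

#' Cladistic distance matrix of a cladogram
#'
#' Entry (i, j) is the number of internal nodes on the path between leaves i
#' and j (sister taxa are at distance 1). By construction the root is
#' counted whenever the path crosses it; an alternative branch-count
#' distance (number of edges on the path) is available via `count`.
#'
#' @param cladogram a rooted `phylo` tree (binary or multifurcating) with at
#'   least two leaves.
#' @param count `"nodes"` (default) or `"branches"`.
#' @return a [dist_matrix()].
#' @examples
#' cladistic_distance_matrix(parse_newick("((A,B),(C,D));"))
#' @export
cladistic_distance_matrix <- function(cladogram, count = c("nodes",
                                                           "branches")) {
  count <- match.arg(count)
  validate_tree(cladogram)
  n <- n_tips(cladogram)
  if (n < 2L) stop("need at least two leaves", call. = FALSE)
  dep <- node_depths(cladogram)
  dt <- descendant_tips(cladogram)
  labs <- cladogram$tip.label
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- mrca_node(cladogram, labs[c(i, j)])
    edges <- dep[i] + dep[j] - 2 * dep[a]
    m[i, j] <- m[j, i] <- if (count == "nodes") edges - 1 else edges
  }
  dist_matrix(m)
}

#' Patristic distance matrix from per-branch step counts
#'
#' Entry (i, j) is the sum of apomorphic step changes on the branches of the
#' i-j path. The tree must carry step counts (see [branch_changes()]).
#'
#' @param tree_with_changes a rooted `phylo` tree whose `$steps` are set.
#' @return a [dist_matrix()].
#' @export
patristic_distance_matrix <- function(tree_with_changes) {
  tree <- tree_with_changes
  validate_tree(tree)
  if (is.null(tree$steps))
    stop("tree carries no branch step counts; run branch_changes() first",
         call. = FALSE)
  nn <- n_tips(tree) + tree$Nnode
  need <- setdiff(seq_len(nn), root_node(tree))
  bad <- need[is.na(tree$steps[need])]
  if (length(bad))
    stop("missing step count on branch above node ",
         paste(bad, collapse = ", "), call. = FALSE)
  # cumulative steps from the root to every node
  cum <- rep(NA_real_, nn)
  cum[root_node(tree)] <- 0
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2L]
    cum[v] <- cum[tr$edge[e, 1L]] + tree$steps[v]
  }
  n <- n_tips(tree)
  labs <- tree$tip.label
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- mrca_node(tree, labs[c(i, j)])
    m[i, j] <- m[j, i] <- cum[i] + cum[j] - 2 * cum[a]
  }
  dist_matrix(m)
}

#' Combine cladistic and patristic distance matrices
#'
#' Entrywise weighted sum `w_c * cd + w_p * pd`; with `standardize = TRUE`
#' each matrix is first divided by its maximum entry.
#'
#' @param cd,pd [dist_matrix()] objects with identical label order.
#' @param w_c,w_p nonnegative weights (default 1 and 1 — equal weighting);
#'   their sum must be positive.
#' @param standardize divide each matrix by its maximum entry first.
#' @return a [dist_matrix()].
#' @export
combine_distances <- function(cd, pd, w_c = 1, w_p = 1,
                              standardize = FALSE) {
  stopifnot(inherits(cd, "dist_matrix"), inherits(pd, "dist_matrix"),
            w_c >= 0, w_p >= 0)
  if (w_c + w_p <= 0) stop("w_c + w_p must be positive", call. = FALSE)
  if (!identical(rownames(cd), rownames(pd))) {
    d1 <- setdiff(rownames(cd), rownames(pd))
    d2 <- setdiff(rownames(pd), rownames(cd))
    stop("label mismatch between matrices",
         if (length(d1)) paste0("; only in first: ",
                                paste(d1, collapse = ", ")),
         if (length(d2)) paste0("; only in second: ",
                                paste(d2, collapse = ", ")),
         if (!length(d1) && !length(d2)) "; same labels, different order",
         call. = FALSE)
  }
  a <- unclass(cd); b <- unclass(pd)
  if (standardize) {
    if (max(a) > 0) a <- a / max(a)
    if (max(b) > 0) b <- b / max(b)
  }
  dist_matrix(w_c * a + w_p * b)
}

#' UPGMA clustering into an ultrametric tree
#'
#' Average-linkage agglomeration: the merge height is half the mean
#' between-cluster distance; cluster-to-cluster distances are member-count-
#' weighted averages (the "unweighted" pair-group method). Ties are broken
#' by the lexicographically smallest pair of cluster labels (a cluster is
#' labeled by its smallest member), so the result is deterministic.
#'
#' @param dm a [dist_matrix()] with at least two taxa and no `NA`
#'   (saturated) entries.
#' @return object of class `patrocladogram`: list with `tree` (ultrametric
#'   rooted `phylo` with branch lengths), `heights` (merge heights), and
#'   `dist` (the input matrix).
#' @examples
#' dm <- dist_matrix(matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'                   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' upgma(dm)$heights  # 1, 3
#' @export
upgma <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (anyNA(dm))
    stop("distance matrix contains saturated/undefined entries; impute or ",
         "drop those taxa before clustering", call. = FALSE)
  n <- nrow(dm)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  labs <- rownames(dm)
  d <- unclass(dm)
  # active clusters: label (smallest member), size, newick fragment, height
  cl <- data.frame(label = labs, size = 1, height = 0,
                   stringsAsFactors = FALSE)
  frag <- as.list(labs)
  act <- seq_len(n)
  heights <- numeric(0)
  while (length(act) > 1L) {
    # find minimum distance pair among active clusters, lexicographic ties
    bi <- bj <- NA_integer_; bd <- Inf
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in seq(ii + 1L, length(act))) {
        i <- act[ii]; j <- act[jj]
        dij <- d[i, j]
        lab <- sort(c(cl$label[i], cl$label[j]))
        if (dij < bd - 1e-12) {
          bd <- dij; bi <- i; bj <- j
        } else if (abs(dij - bd) <= 1e-12) {
          cur <- sort(c(cl$label[bi], cl$label[bj]))
          if (lab[1] < cur[1] || (lab[1] == cur[1] && lab[2] < cur[2])) {
            bi <- i; bj <- j
          }
        }
      }
    }
    h <- bd / 2
    heights <- c(heights, h)
    ord <- order(c(cl$label[bi], cl$label[bj]))
    pair <- c(bi, bj)[ord]
    newfrag <- paste0("(",
                      frag[[pair[1]]], ":", format(h - cl$height[pair[1]],
                                                   digits = 12),
                      ",",
                      frag[[pair[2]]], ":", format(h - cl$height[pair[2]],
                                                   digits = 12),
                      ")")
    # UPGMA update: size-weighted average distance to the merged cluster
    si <- cl$size[bi]; sj <- cl$size[bj]
    for (k in act) {
      if (k == bi || k == bj) next
      d[bi, k] <- d[k, bi] <- (si * d[bi, k] + sj * d[bj, k]) / (si + sj)
    }
    cl$label[bi] <- min(cl$label[bi], cl$label[bj])
    cl$size[bi] <- si + sj
    cl$height[bi] <- h
    frag[[bi]] <- newfrag
    act <- setdiff(act, bj)
  }
  tree <- parse_newick(paste0(frag[[act]], ";"))
  structure(list(tree = tree, heights = heights, dist = dm),
            class = "patrocladogram")
}

#' @export
print.patrocladogram <- function(x, ...) {
  cat("Patrocladogram over", n_tips(x$tree), "taxa; root height",
      format(max(x$heights)), "\n")
  cat(write_newick(x$tree), "\n")
  invisible(x)
}

#' Full patrocladistic analysis of a cladogram and data matrix
#'
#' Pipeline composition: parsimony branch changes on the cladogram, the
#' cladistic and patristic distance matrices, their weighted combination,
#' and UPGMA clustering. All intermediates are returned, including a single
#' square display matrix with the cladistic distances in the lower-left and
#' the patristic distances in the upper-right triangle.
#'
#' @param cladogram a rooted `phylo` tree (the reference cladogram).
#' @param data a [morph_matrix()] or [seq_alignment()] over the same taxa.
#' @inheritParams combine_distances
#' @return list of class `patrocladistic_analysis`: `cladistic`,
#'   `patristic`, `combined` ([dist_matrix()] objects), `display` (mixed
#'   lower/upper matrix), `tree_with_changes`, and `patrocladogram`.
#' @export
patrocladistic_analysis <- function(cladogram, data, w_c = 1, w_p = 1,
                                    standardize = FALSE) {
  twc <- branch_changes(cladogram, data)
  cd <- cladistic_distance_matrix(twc)
  pd <- patristic_distance_matrix(twc)
  comb <- combine_distances(cd, pd, w_c = w_c, w_p = w_p,
                            standardize = standardize)
  disp <- unclass(cd)
  disp[upper.tri(disp)] <- unclass(pd)[upper.tri(disp)]
  structure(list(cladistic = cd, patristic = pd, combined = comb,
                 display = disp, tree_with_changes = twc,
                 patrocladogram = upgma(comb)),
            class = "patrocladistic_analysis")
}

#' @export
print.patrocladistic_analysis <- function(x, ...) {
  cat("Patrocladistic analysis of", nrow(x$combined), "taxa\n")
  print(x$patrocladogram)
  invisible(x)
}
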