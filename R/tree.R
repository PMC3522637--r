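# ---- rooted-tree utilities on ape's "phylo" representation -------------------
#
# Trees throughout the package are rooted "phylo" objects (ape). Two optional
# annotations ride along:
#   * node supports: numeric internal-node labels, interpreted as bootstrap
#     percentages when > 1 and posterior probabilities when <= 1;
#   * per-branch step counts: tree$steps, a numeric vector indexed by CHILD
#     node id (steps[v] = changes on the branch above v; NA at the root).
# Indexing steps by child id keeps them valid under edge reordering.

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

#' List children of every node
#'
#' @param tree a rooted `phylo` tree.
#' @return a list of integer vectors, one per node id (tips have length 0).
#' @keywords internal
children_list <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(nn)) out[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    out[[p]] <- c(out[[p]], tree$edge[e, 2L])
  }
  out
}

parent_vec <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  par <- rep(NA_integer_, nn)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# node ids in postorder (children before parents), tips included
postorder_ids <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  c(tr$edge[, 2L][!duplicated(tr$edge[, 2L])], root_node(tree))
}

# tips descending from each node, as a list of integer tip-id vectors
descendant_tips <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  kids <- children_list(tree)
  out <- vector("list", nn)
  for (v in postorder_ids(tree)) {
    out[[v]] <- if (v <= n_tips(tree)) v else
      sort(unlist(out[kids[[v]]], use.names = FALSE))
  }
  out
}

# depth of every node in edges from the root
node_depths <- function(tree) {
  nn <- n_tips(tree) + tree$Nnode
  par <- parent_vec(tree)
  d <- rep(NA_real_, nn)
  d[root_node(tree)] <- 0
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    d[tr$edge[e, 2L]] <- d[tr$edge[e, 1L]] + 1
  }
  d
}

#' Validate a rooted phylogenetic tree
#'
#' Checks the structural invariants assumed throughout the package: a single
#' root, unique non-empty leaf labels, and (when present) nonnegative integer
#' branch step counts and in-range support annotations.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label", call. = FALSE)
  tab <- tabulate(tree$edge[, 2L], nbins = n_tips(tree) + tree$Nnode)
  roots <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree must have exactly one root", call. = FALSE)
  if (any(tab > 1L)) stop("node with more than one parent", call. = FALSE)
  if (!is.null(tree$steps)) {
    s <- tree$steps[!is.na(tree$steps)]
    if (any(s < 0) || any(s != round(s)))
      stop("branch step counts must be nonnegative integers", call. = FALSE)
  }
  sup <- node_support(tree)
  if (any(sup$bs < 0 | sup$bs > 100, na.rm = TRUE))
    stop("bootstrap support outside [0,100]", call. = FALSE)
  if (any(sup$pp < 0 | sup$pp > 1, na.rm = TRUE))
    stop("posterior probability outside [0,1]", call. = FALSE)
  invisible(tree)
}

#' Node support annotations
#'
#' Numeric internal-node labels are interpreted by magnitude: values greater
#' than 1 are bootstrap percentages (BS), values in [0, 1] are posterior
#' probabilities (PP) — the usual dual annotation convention on published
#' trees.
#'
#' @param tree a `phylo` object, possibly with `node.label`.
#' @return a data frame with one row per internal node: `node` (id), `bs`,
#'   `pp` (NA where absent).
#' @export
node_support <- function(tree) {
  nint <- tree$Nnode
  ids <- n_tips(tree) + seq_len(nint)
  bs <- rep(NA_real_, nint)
  pp <- rep(NA_real_, nint)
  if (!is.null(tree$node.label)) {
    val <- suppressWarnings(as.numeric(tree$node.label))
    bs[!is.na(val) & val > 1] <- val[!is.na(val) & val > 1]
    pp[!is.na(val) & val <= 1] <- val[!is.na(val) & val <= 1]
  }
  data.frame(node = ids, bs = bs, pp = pp)
}

#' Parse a Newick string into a rooted tree
#'
#' Internal-node labels that parse as numbers are kept as support annotations
#' (see [node_support()]). The input must be balanced and carry a single
#' trailing semicolon; malformed input fails with the offending character
#' position.
#'
#' @param text a single Newick string.
#' @return a validated rooted `phylo` tree.
#' @examples
#' tr <- parse_newick("((A,B)96,C);")
#' node_support(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at position ", i,
             ": unbalanced ')'", call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error at position ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  semis <- which(chars == ";")
  if (length(semis) != 1L || semis != nchar(trimws(text)))
    stop("newick parse error: expected a single trailing ';'", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("newick parse error: unreadable tree string", call. = FALSE)
  validate_tree(tree)
}

# smallest tip label below each node (canonical ordering key)
.min_desc_label <- function(tree) {
  dt <- descendant_tips(tree)
  vapply(dt, function(ix) min(tree$tip.label[ix]), character(1))
}

#' Serialize a tree to canonical Newick
#'
#' Output is deterministic: at every node the children are ordered by their
#' smallest descendant leaf label, so topologically identical trees always
#' serialize identically. Support labels and branch lengths are written when
#' present.
#'
#' @param tree a rooted `phylo` tree.
#' @param digits significant digits for branch lengths.
#' @return a Newick string ending in `";"`.
#' @examples
#' write_newick(parse_newick("((B,A),C);"))  # "((A,B),C);"
#' @export
write_newick <- function(tree, digits = 10) {
  validate_tree(tree)
  kids <- children_list(tree)
  key <- .min_desc_label(tree)
  elen <- rep(NA_real_, n_tips(tree) + tree$Nnode)
  if (!is.null(tree$edge.length))
    elen[tree$edge[, 2L]] <- tree$edge.length
  nlab <- rep("", tree$Nnode)
  if (!is.null(tree$node.label)) nlab <- as.character(tree$node.label)
  fmt_len <- function(v) {
    if (is.na(v)) "" else paste0(":", format(v, digits = digits,
                                             scientific = FALSE, trim = TRUE))
  }
  rec <- function(v) {
    if (v <= n_tips(tree)) {
      paste0(tree$tip.label[v], fmt_len(elen[v]))
    } else {
      ord <- kids[[v]][order(key[kids[[v]]])]
      lab <- nlab[v - n_tips(tree)]
      if (is.na(lab)) lab <- ""
      paste0("(", paste(vapply(ord, rec, character(1)), collapse = ","), ")",
             lab, fmt_len(elen[v]))
    }
  }
  paste0(rec(root_node(tree)), ";")
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a rooted `phylo` tree.
#' @param tips character vector of leaf labels (all must be in the tree).
#' @return the node id of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  ix <- match(tips, tree$tip.label)
  if (anyNA(ix))
    stop("taxa not in tree: ", paste(tips[is.na(ix)], collapse = ", "),
         call. = FALSE)
  if (length(ix) == 1L) return(ix)
  dt <- descendant_tips(tree)
  par <- parent_vec(tree)
  v <- ix[1]
  while (!all(ix %in% dt[[v]])) v <- par[v]
  v
}

# internal: all non-trivial clades of a rooted tree, as sorted label vectors
clade_sets <- function(tree, include_root = FALSE) {
  dt <- descendant_tips(tree)
  ids <- n_tips(tree) + seq_len(tree$Nnode)
  if (!include_root) ids <- setdiff(ids, root_node(tree))
  lapply(ids, function(v) sort(tree$tip.label[dt[[v]]]))
}

# set per-branch step counts (vector indexed by child node id)
set_branch_steps <- function(tree, steps_by_child) {
  tree$steps <- steps_by_child
  tree
}

#' Per-branch step counts of a tree
#'
#' @param tree a `phylo` tree previously annotated by [branch_changes()].
#' @return data frame with `parent`, `child`, `steps` per edge.
#' @export
branch_steps <- function(tree) {
  if (is.null(tree$steps))
    stop("tree carries no branch step counts; run branch_changes() first",
         call. = FALSE)
  data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
             steps = tree$steps[tree$edge[, 2L]])
}
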