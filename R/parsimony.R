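# ---- public small-parsimony operations ---------------------------------------

# coerce a user-facing column (named character vector of states) to masks
.column_to_masks <- function(column, type = c("auto", "dna", "morph")) {
  type <- match.arg(type)
  if (is.null(names(column)) || anyDuplicated(names(column)))
    stop("column must be a named vector with unique taxon names",
         call. = FALSE)
  x <- toupper(as.character(column))
  x[is.na(x) | x %in% c("?", "-", "N")] <- NA
  if (type == "auto")
    type <- if (all(is.na(x) | x %in% c("A", "C", "G", "T", IUPAC_AMBIG)))
      "dna" else "morph"
  if (type == "dna") {
    m <- matrix(x, ncol = 1, dimnames = list(names(column), NULL))
    m[is.na(m)] <- "?"
    build_column_masks(seq_alignment(m))
  } else {
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v) & !is.na(x)))
      stop("invalid state symbol in column: ",
           paste(unique(x[is.na(v) & !is.na(x)]), collapse = ", "),
           call. = FALSE)
    m <- matrix(v, ncol = 1, dimnames = list(names(column), NULL))
    build_column_masks(morph_matrix(m))
  }
}

#' Fitch parsimony length of one character on a tree
#'
#' Minimum number of unordered, unweighted state changes needed to explain a
#' single character on a rooted tree. Missing observations (`NA`, `?`, `-`,
#' `N`, IUPAC ambiguity codes) carry the full state set.
#'
#' @param tree a rooted `phylo` tree.
#' @param column named character vector of states (DNA bases or digit codes);
#'   names are taxon labels and must cover the tree's tips.
#' @return integer step count.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch_length(tr, c(A = "0", B = "0", C = "1", D = "1"))  # 1
#' @export
fitch_length <- function(tree, column) {
  cm <- .masks_for_tree(tree, .column_to_masks(column))
  as.integer(.fitch_pass(tree, cm$masks, cm$alpha)$len)
}

#' Total parsimony length of a data matrix on a tree
#'
#' @param tree a rooted `phylo` tree.
#' @param data a [seq_alignment()], [morph_matrix()] or [combine_data()]
#'   result; taxa must cover the tree's tips.
#' @return integer total step count (sum of per-column Fitch lengths).
#' @export
matrix_length <- function(tree, data) {
  cm <- build_column_masks(data)
  if (ncol(cm$masks) == 0L) return(0L)
  cm <- .masks_for_tree(tree, cm)
  as.integer(sum(.fitch_pass(tree, cm$masks, cm$alpha)$len))
}

#' Count parsimony-informative columns
#'
#' A column is parsimony informative when at least two states are each
#' observed in at least two taxa; gaps, `?`, `N` and ambiguity codes are not
#' states.
#'
#' @param data a [seq_alignment()] or [morph_matrix()].
#' @return integer count of informative columns.
#' @export
count_informative_sites <- function(data) {
  obs <- if (inherits(data, "seq_alignment")) {
    x <- unclass(data)
    x[!(x %in% c("A", "C", "G", "T"))] <- NA
    x
  } else if (inherits(data, "morph_matrix")) {
    matrix(as.character(unclass(data)), nrow = nrow(data))
  } else stop("unsupported data type", call. = FALSE)
  sum(vapply(seq_len(ncol(obs)), function(j) {
    tb <- table(obs[, j])
    sum(tb >= 2L) >= 2L
  }, logical(1)))
}

#' Parsimony ancestral state reconstruction
#'
#' Computes, per character, the most-parsimonious state set of every node
#' (Fitch downpass plus Hartigan uppass, exact on multifurcations) and
#' optionally a single deterministic resolution in which every node takes its
#' parent's state whenever that is compatible with minimum length (delaying
#' changes toward the tips), together with per-branch change indicators.
#'
#' @param tree a rooted `phylo` tree.
#' @param data a [morph_matrix()] (or [seq_alignment()]).
#' @param resolution `"sets"` for most-parsimonious state sets only, or
#'   `"single"` to add the deterministic single assignment and branch change
#'   indicators.
#' @return object of class `ancestral_recon`: list with `mpr_sets` (node x
#'   character matrix of state-set strings), `length` (total steps),
#'   `per_column_length`, and under `"single"` also `states` (node x
#'   character single-state matrix) and `changes` (node x character logical;
#'   row v = change on the branch above node v).
#' @export
ancestral_states <- function(tree, data, resolution = c("sets", "single")) {
  resolution <- match.arg(resolution)
  validate_tree(tree)
  cm <- .masks_for_tree(tree, build_column_masks(data))
  fp <- .fitch_pass(tree, cm$masks, cm$alpha, need_sets = TRUE)
  nn <- n_tips(tree) + tree$Nnode
  out <- list(tree = tree,
              mpr_sets = .decode_masks(fp$F, cm$states),
              per_column_length = as.integer(fp$len),
              length = as.integer(sum(fp$len)),
              resolution = resolution)
  if (resolution == "single") {
    S <- .fitch_traceback(tree, fp$V)
    par <- parent_vec(tree)
    chg <- matrix(FALSE, nn, ncol(S))
    for (v in seq_len(nn)) {
      if (!is.na(par[v])) chg[v, ] <- S[v, ] != S[par[v], ]
    }
    out$states <- .decode_masks(S, cm$states)
    out$changes <- chg
  }
  structure(out, class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("Parsimony ancestral reconstruction:", ncol(x$mpr_sets),
      "characters, total length", x$length, "steps\n")
  invisible(x)
}

#' Per-branch apomorphic step counts
#'
#' Annotates each branch of the tree with the number of character-state
#' changes assigned to it under the deterministic parent-state-preferring
#' resolution of the most-parsimonious reconstruction. The counts sum to
#' [matrix_length()].
#'
#' @inheritParams ancestral_states
#' @return the tree with `$steps` set (indexed by child node id; see
#'   [branch_steps()]).
#' @export
branch_changes <- function(tree, data) {
  ar <- ancestral_states(tree, data, resolution = "single")
  steps <- rowSums(ar$changes)
  steps[root_node(tree)] <- NA_real_
  set_branch_steps(tree, steps)
}

#' Strict or majority-rule consensus of rooted trees
#'
#' @param trees list of rooted `phylo` trees over the same tip set.
#' @param kind `"strict"` (clades present in every tree) or `"majority"`
#'   (clades in more than `threshold` of the trees, annotated with their
#'   percentage frequency as node labels).
#' @param threshold majority fraction (default 0.5, strict inequality).
#' @return a rooted `phylo` consensus tree.
#' @examples
#' ts <- list(parse_newick("((A,B),(C,D));"), parse_newick("((A,B),(C,D));"),
#'            parse_newick("((A,C),(B,D));"))
#' write_newick(consensus_tree(ts, "majority"))
#' @export
consensus_tree <- function(trees, kind = c("strict", "majority"),
                           threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), tips))
      stop("trees must share an identical tip set", call. = FALSE)
  keyify <- function(s) paste(s, collapse = "\r")
  counts <- new.env(parent = emptyenv())
  for (t in trees) {
    for (cl in clade_sets(t)) {
      k <- keyify(cl)
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  n <- length(trees)
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- if (kind == "strict") freq == n else freq / n > threshold
  clades <- lapply(strsplit(keys[keep], "\r"), identity)
  freqs <- freq[keep]
  .build_from_clades(tips, clades, 100 * freqs / n,
                     label = (kind == "majority"))
}

# assemble a rooted tree from a compatible (nested) set of clades
.build_from_clades <- function(tips, clades, freqs = NULL, label = FALSE) {
  ord <- order(-vapply(clades, length, integer(1)))
  sets <- c(list(tips), clades[ord])
  nfreq <- c(NA_real_,
             if (is.null(freqs)) rep(NA_real_, length(clades)) else freqs[ord])
  # parent = smallest strict superset among earlier (larger) sets
  parent_of <- rep(NA_integer_, length(sets))
  for (i in seq_along(sets)[-1]) {
    best <- 1L
    for (j in seq_len(i - 1L)[-1]) {
      if (length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[j]]) < length(sets[[best]]))
        best <- j
    }
    parent_of[i] <- best
  }
  kids <- lapply(seq_along(sets), function(i) which(parent_of == i))
  rec <- function(i) {
    covered <- unlist(lapply(kids[[i]], function(j) sets[[j]]))
    parts <- c(lapply(kids[[i]], rec),
               lapply(setdiff(sets[[i]], covered),
                      function(tp) list(str = tp, min = tp)))
    parts <- parts[order(vapply(parts, `[[`, character(1), "min"))]
    lab <- if (label && i > 1L && !is.na(nfreq[i]))
      formatC(round(nfreq[i], 1), format = "fg") else ""
    list(str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                 collapse = ","), ")", lab),
         min = min(vapply(parts, `[[`, character(1), "min")))
  }
  parse_newick(paste0(rec(1L)$str, ";"))
}
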