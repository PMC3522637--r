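# ---- monophyly diagnosis and character-state origins -------------------------

#' Assess monophyly of a taxon set on a rooted tree
#'
#' A set is monophyletic when it equals the full leaf set under its most
#' recent common ancestor. Leaves under the MRCA that are not in the set are
#' reported as intruders ("nested within" taxa); set members absent from the
#' tree are reported, not silently dropped. Paraphyly versus polyphyly is
#' not adjudicated — that requires character polarity — so the verdict is
#' simply `"monophyletic"` or `"non-monophyletic"`.
#'
#' @param tree a rooted `phylo` tree.
#' @param focal character vector of taxon labels (non-empty; at least one
#'   must be in the tree).
#' @return object of class `clade_report`: `focal`, `mrca` (node id),
#'   `verdict`, `intruders`, `missing`.
#' @examples
#' assess_monophyly(parse_newick("((A,X),B);"), c("A", "B"))
#' @export
assess_monophyly <- function(tree, focal) {
  validate_tree(tree)
  stopifnot(length(focal) >= 1L)
  focal <- unique(focal)
  missing <- setdiff(focal, tree$tip.label)
  present <- setdiff(focal, missing)
  if (!length(present))
    stop("no focal taxon present in the tree", call. = FALSE)
  m <- mrca_node(tree, present)
  under <- tree$tip.label[descendant_tips(tree)[[m]]]
  intruders <- setdiff(under, focal)
  verdict <- if (!length(intruders) && !length(missing))
    "monophyletic" else "non-monophyletic"
  structure(list(focal = focal, mrca = m, verdict = verdict,
                 intruders = sort(intruders), missing = sort(missing)),
            class = "clade_report")
}

#' @export
print.clade_report <- function(x, ...) {
  cat("Focal set (", length(x$focal), " taxa): ", x$verdict, "\n", sep = "")
  if (length(x$intruders))
    cat("  intruders under MRCA:", paste(x$intruders, collapse = ", "), "\n")
  if (length(x$missing))
    cat("  missing from tree:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Minimum number of independent origins of a character state
#'
#' Over all most-parsimonious reconstructions of the character on the tree,
#' finds the minimum number of branches on which the focal state is gained
#' (parent not focal, child focal). The root contributes one extra origin
#' when it is resolved to the focal state in the witnessing reconstruction;
#' `origins` includes that root contribution, `branch_gains` counts branch
#' gains only, and `root_focal` flags it.
#'
#' @param tree a rooted `phylo` tree.
#' @param column named character vector of states (see [fitch_length()]).
#' @param focal_state the state whose origins are counted; must be observed
#'   in at least one leaf.
#' @return object of class `origin_report`: `origins`, `branch_gains`,
#'   `root_focal`, `length` (Fitch steps), and `witness` (a named vector of
#'   node states attaining both minima).
#' @examples
#' col <- c(A = "1", B = "0", C = "1", D = "0", E = "0", F = "0")
#' tr <- parse_newick("(((((A,B),C),D),E),F);")
#' min_state_origins(tr, col, "1")$origins  # 2
#' @export
min_state_origins <- function(tree, column, focal_state) {
  validate_tree(tree)
  cm <- .masks_for_tree(tree, .column_to_masks(column))
  states <- cm$states[[1]]
  fb <- match(as.character(focal_state), states)
  fmask <- bitwShiftL(1L, fb - 1L)
  leafmask <- cm$masks[, 1L]
  singles <- leafmask[bitwAnd(leafmask, leafmask - 1L) == 0L]
  if (is.na(fb) || !any(singles == fmask))
    stop("focal state '", focal_state, "' not observed in any leaf",
         call. = FALSE)
  nb <- 10L
  alphabet <- which(bitwAnd(cm$alpha[1L], bitwShiftL(1L, 0:(nb - 1L))) > 0L)
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  kids <- children_list(tree)
  # lexicographic DP: C = min changes below node given its state,
  # G = min focal gains on edges below, among min-change sub-labelings
  C <- matrix(Inf, nn, nb)
  G <- matrix(Inf, nn, nb)
  pickt <- array(NA_integer_, c(nn, nb, nn))  # witness back-pointers
  for (v in postorder_ids(tree)) {
    if (v <= ntip) {
      for (s in alphabet) {
        if (bitwAnd(leafmask[v], bitwShiftL(1L, s - 1L)) > 0L) {
          C[v, s] <- 0; G[v, s] <- 0
        }
      }
    } else {
      for (s in alphabet) {
        ctot <- 0; gtot <- 0
        for (w in kids[[v]]) {
          cc <- C[w, alphabet] + (alphabet != s)
          gg <- G[w, alphabet] + (s != fb & alphabet == fb)
          cmin <- min(cc)
          sel <- which(cc == cmin)
          gmin <- min(gg[sel])
          tpick <- alphabet[sel[which(gg[sel] == gmin)[1L]]]
          ctot <- ctot + cmin; gtot <- gtot + gmin
          pickt[v, s, w] <- tpick
        }
        C[v, s] <- ctot; G[v, s] <- gtot
      }
    }
  }
  rt <- root_node(tree)
  len <- min(C[rt, ])
  roots <- which(C[rt, ] == len)
  tot <- G[rt, roots] + (roots == fb)
  rs <- roots[which.min(tot)]
  origins <- min(tot)
  # reconstruct witness labeling
  wit <- rep(NA_integer_, nn)
  wit[rt] <- rs
  for (v in rev(postorder_ids(tree))) {
    if (v <= ntip) next
    for (w in kids[[v]]) wit[w] <- pickt[v, wit[v], w]
  }
  witness <- states[wit]
  names(witness) <- c(tree$tip.label, paste0("node", (ntip + 1L):nn))
  branch_gains <- origins - (rs == fb)
  structure(list(origins = as.integer(origins),
                 branch_gains = as.integer(branch_gains),
                 root_focal = rs == fb,
                 length = as.integer(len),
                 focal_state = as.character(focal_state),
                 witness = witness),
            class = "origin_report")
}

#' @export
print.origin_report <- function(x, ...) {
  cat("State '", x$focal_state, "': at least ", x$origins,
      " independent origin(s) (", x$branch_gains, " branch gain(s)",
      if (x$root_focal) " + ancestral at root", ") over ", x$length,
      "-step reconstructions\n", sep = "")
  invisible(x)
}

#' Synapomorphies supporting each clade
#'
#' For every internal node, lists the characters whose most-parsimonious
#' reconstruction places an unambiguous change on the branch subtending the
#' node: both the node's and its parent's most-parsimonious state sets are
#' singletons and differ, so the change occurs in every optimal
#' reconstruction.
#'
#' @param tree a rooted `phylo` tree.
#' @param data a [morph_matrix()] (or [seq_alignment()]).
#' @return data frame with `node`, `character`, `from`, `to`, and `clade`
#'   (comma-separated leaf labels of the supported clade).
#' @export
synapomorphy_table <- function(tree, data) {
  validate_tree(tree)
  ar <- ancestral_states(tree, data, resolution = "sets")
  sets <- ar$mpr_sets
  par <- parent_vec(tree)
  dt <- descendant_tips(tree)
  rows <- list()
  ids <- setdiff(seq_len(nrow(sets)), root_node(tree))
  ids <- ids[ids > n_tips(tree)]
  cn <- colnames(data)
  if (is.null(cn)) cn <- as.character(seq_len(ncol(sets)))
  for (v in ids) {
    for (j in seq_len(ncol(sets))) {
      a <- sets[par[v], j]; b <- sets[v, j]
      if (nchar(a) == 1L && nchar(b) == 1L && a != b) {
        rows[[length(rows) + 1L]] <- data.frame(
          node = v, character = cn[j], from = a, to = b,
          clade = paste(sort(tree$tip.label[dt[[v]]]), collapse = ","))
      }
    }
  }
  if (!length(rows))
    return(data.frame(node = integer(0), character = character(0),
                      from = character(0), to = character(0),
                      clade = character(0)))
  do.call(rbind, rows)
}
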