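# ---- small-parsimony engine --------------------------------------------------
#
# Character columns are encoded as integer bitmasks over the column's state
# alphabet (DNA: A=1, C=2, G=4, T=8; morphology: state s -> bit s+1). A leaf
# with a gap, '?', N or ambiguity code carries the full state set of its
# column — gaps are coded as missing data. Counting uses Hartigan's
# generalization of the Fitch downpass, which is exact on multifurcating
# nodes (including the basal trifurcation of unrooted-tree representations):
# at a node whose children carry state sets with per-state child counts c(s),
# K = max c(s), the node's preliminary set is {s : c(s) = K}, the "runner-up"
# set is {s : c(s) = K - 1}, and the length increment is (#children - K).
# On binary nodes this reduces to the classic intersection/union rule.

.DNA_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# lowest set bit of a positive integer
.lowbit <- function(x) bitwAnd(x, -x)

# bit index (1-based) of a power of two
.bitpos <- function(x) as.integer(round(log2(x))) + 1L

#' Encode data columns as parsimony state-set bitmasks
#'
#' @param data a [seq_alignment()], [morph_matrix()] or mixed matrix from
#'   [combine_data()].
#' @return list with `masks` (taxa x columns integer matrix), `alpha`
#'   (per-column alphabet mask), `states` (per-column character vector of
#'   state labels, position = bit index), `taxa`.
#' @keywords internal
build_column_masks <- function(data) {
  if (inherits(data, "mixed_matrix")) {
    a <- build_column_masks(data$aln)
    m <- build_column_masks(data$morph)
    if (!identical(sort(a$taxa), sort(m$taxa)))
      stop("mixed matrix parts must share taxa", call. = FALSE)
    mm <- m$masks[a$taxa, , drop = FALSE]
    return(list(masks = cbind(a$masks, mm),
                alpha = c(a$alpha, m$alpha),
                states = c(a$states, m$states),
                taxa = a$taxa))
  }
  if (inherits(data, "seq_alignment")) {
    x <- unclass(data)
    masks <- matrix(15L, nrow(x), ncol(x), dimnames = dimnames(x))
    for (s in names(.DNA_BITS)) masks[x == s] <- .DNA_BITS[[s]]
    alpha <- rep(15L, ncol(x))
    states <- rep(list(c("A", "C", "G", "T")), ncol(x))
  } else if (inherits(data, "morph_matrix")) {
    x <- unclass(data)
    masks <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
    masks[!is.na(x)] <- bitwShiftL(1L, x[!is.na(x)])
    alpha <- integer(ncol(x))
    for (j in seq_len(ncol(x))) {
      a <- Reduce(bitwOr, masks[, j], 0L)
      if (a == 0L) a <- 1L  # all-missing column: dummy single state
      alpha[j] <- a
      masks[masks[, j] == 0L, j] <- a
    }
    states <- rep(list(as.character(0:9)), ncol(x))
  } else stop("unsupported data type for parsimony", call. = FALSE)
  list(masks = masks, alpha = alpha, states = states,
       taxa = rownames(masks))
}

# reorder leaf mask rows to a tree's tips, erroring on absent taxa
.masks_for_tree <- function(tree, cm) {
  miss <- setdiff(tree$tip.label, cm$taxa)
  if (length(miss))
    stop("taxa in tree absent from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cm$masks <- cm$masks[tree$tip.label, , drop = FALSE]
  cm$taxa <- tree$tip.label
  cm
}

# Hartigan downpass (and optional uppass) on a phylo tree.
# Returns per-column lengths and, if need_sets, V/H/F bitmask matrices over
# all nodes. alpha recycled over columns.
.fitch_pass <- function(tree, masks, alpha, need_sets = FALSE) {
  ntip <- n_tips(tree)
  nn <- ntip + tree$Nnode
  nc <- ncol(masks)
  kids <- children_list(tree)
  post <- postorder_ids(tree)
  internals <- post[post > ntip]
  V <- matrix(0L, nn, nc)
  V[seq_len(ntip), ] <- masks
  H <- if (need_sets) matrix(0L, nn, nc) else NULL
  len <- numeric(nc)
  for (v in internals) {
    ch <- kids[[v]]
    if (length(ch) == 2L) {
      m1 <- V[ch[1L], ]; m2 <- V[ch[2L], ]
      a <- bitwAnd(m1, m2)
      o <- bitwOr(m1, m2)
      z <- a == 0L
      V[v, ] <- ifelse(z, o, a)
      len <- len + z
      if (need_sets)
        H[v, ] <- ifelse(z, bitwXor(alpha, bitwAnd(alpha, o)),
                         bitwXor(m1, m2))
    } else {
      nb <- 10L
      cnt <- matrix(0L, nb, nc)
      for (c0 in ch) {
        mv <- V[c0, ]
        for (b in seq_len(nb)) {
          bit <- bitwShiftL(1L, b - 1L)
          cnt[b, ] <- cnt[b, ] + (bitwAnd(mv, bit) > 0L)
        }
      }
      K <- do.call(pmax, lapply(seq_len(nb), function(b) cnt[b, ]))
      vmask <- integer(nc); hmask <- integer(nc)
      for (b in seq_len(nb)) {
        bit <- bitwShiftL(1L, b - 1L)
        vmask <- vmask + bit * (cnt[b, ] == K)
        hmask <- hmask + bit * (cnt[b, ] == K - 1L)
      }
      V[v, ] <- vmask
      len <- len + length(ch) - K
      if (need_sets)
        H[v, ] <- bitwAnd(hmask, alpha)
    }
  }
  out <- list(len = len, V = V)
  if (need_sets) {
    # Hartigan uppass: most-parsimonious state sets F per internal node
    F <- matrix(0L, nn, nc)
    rt <- root_node(tree)
    F[rt, ] <- V[rt, ]
    pre <- rev(internals)
    par <- parent_vec(tree)
    for (v in pre) {
      if (v == rt) next
      Fu <- F[par[v], ]; Vv <- V[v, ]
      sub <- bitwAnd(Fu, Vv) == Fu
      F[v, ] <- ifelse(sub, Fu, bitwOr(Vv, bitwAnd(Fu, H[v, ])))
    }
    F[seq_len(ntip), ] <- masks
    out$H <- H
    out$F <- F
  }
  out
}

# Deterministic single most-parsimonious assignment: the root takes the
# smallest state in its downpass set; every other node takes its parent's
# state when that state is in its own downpass set (delaying changes,
# DELTRAN-like), otherwise its smallest downpass state. Guaranteed to attain
# the minimum length.
.fitch_traceback <- function(tree, V) {
  ntip <- n_tips(tree)
  nn <- nrow(V)
  nc <- ncol(V)
  par <- parent_vec(tree)
  rt <- root_node(tree)
  S <- matrix(0L, nn, nc)
  S[rt, ] <- .lowbit(V[rt, ])
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
    keep <- bitwAnd(S[u, ], V[v, ]) > 0L
    S[v, ] <- ifelse(keep, S[u, ], .lowbit(V[v, ]))
  }
  S
}

# decode a bitmask (or single-bit) matrix to state-label strings
.decode_masks <- function(M, states) {
  out <- matrix("", nrow(M), ncol(M))
  for (j in seq_len(ncol(M))) {
    lab <- states[[j]]
    for (b in seq_along(lab)) {
      bit <- bitwShiftL(1L, b - 1L)
      hit <- bitwAnd(M[, j], bit) > 0L
      out[hit, j] <- paste0(out[hit, j], lab[b])
    }
  }
  out
}
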