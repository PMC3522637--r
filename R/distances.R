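# ---- genetic distances -------------------------------------------------------
#
# p-distance and Kimura 2-parameter distance under pairwise deletion: a site
# is compared only if both rows show an unambiguous base (A/C/G/T). Gaps,
# '?', N and IUPAC ambiguity letters are excluded. K2P separates transitions
# (A<->G, C<->T; proportion P) from transversions (proportion Q):
#
#   d = -1/2 * ln(1 - 2P - Q) - 1/4 * ln(1 - 2Q)
#
# When either log argument is <= 0 the pair is saturated and the distance is
# the NA sentinel (carried through matrices, refused by UPGMA).

PURINES <- c("A", "G")

.comparable <- function(a, b) {
  ok <- c("A", "C", "G", "T")
  (a %in% ok) & (b %in% ok)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' @param a,b equal-length character vectors (or single strings) of aligned
#'   bases.
#' @param deletion site-filtering rule; only `"pairwise"` is implemented:
#'   sites with a gap, `?`, `N` or ambiguity code in either row are skipped.
#' @return proportion of differing sites among compared sites.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' p_distance("AC-T", "ACGT")  # 0 over 3 compared sites
#' @export
p_distance <- function(a, b, deletion = "pairwise") {
  deletion <- match.arg(deletion)
  ab <- .as_rows(a, b)
  cmp <- .comparable(ab$a, ab$b)
  if (!any(cmp))
    stop("undefined distance: zero comparable sites", call. = FALSE)
  sum(ab$a[cmp] != ab$b[cmp]) / sum(cmp)
}

.as_rows <- function(a, b) {
  if (is.character(a) && length(a) == 1L && nchar(a) > 1L)
    a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L && nchar(b) > 1L)
    b <- strsplit(b, "")[[1]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b))
    stop("sequences of unequal length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  list(a = a, b = b)
}

#' Kimura 2-parameter distance components
#'
#' @inheritParams p_distance
#' @return a list of class `k2p_components`: `P` (transition proportion),
#'   `Q` (transversion proportion), `L_eff` (sites compared after pairwise
#'   deletion), `d` (distance; `NA` when saturated), `saturated` flag.
#' @examples
#' k2p_components("ACGT", "ACGT")$d  # 0
#' @export
k2p_components <- function(a, b) {
  ab <- .as_rows(a, b)
  cmp <- .comparable(ab$a, ab$b)
  L <- sum(cmp)
  if (L == 0L)
    stop("undefined distance: zero comparable sites", call. = FALSE)
  x <- ab$a[cmp]; y <- ab$b[cmp]
  diff <- x != y
  ts <- diff & ((x %in% PURINES) == (y %in% PURINES))
  P <- sum(ts) / L
  Q <- sum(diff & !ts) / L
  k2p_from_PQ(P, Q, L)
}

#' K2P distance from transition/transversion proportions
#'
#' @param P,Q transition and transversion proportions of compared sites.
#' @param L_eff number of compared sites (metadata only).
#' @return a `k2p_components` object (see [k2p_components()]).
#' @export
k2p_from_PQ <- function(P, Q, L_eff = NA_integer_) {
  stopifnot(P >= 0, Q >= 0, P + Q <= 1)
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  sat <- a1 <= 0 || a2 <= 0
  d <- if (sat) NA_real_ else -0.5 * log(a1) - 0.25 * log(a2)
  structure(list(P = P, Q = Q, L_eff = L_eff, d = d, saturated = sat),
            class = "k2p_components")
}

#' @export
print.k2p_components <- function(x, ...) {
  cat(sprintf("K2P: P=%.4f Q=%.4f L=%s d=%s%s\n", x$P, x$Q,
              format(x$L_eff), format(x$d),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln a [seq_alignment()] with at least two taxa.
#' @param model `"p"` (uncorrected) or `"k2p"`.
#' @return a [dist_matrix()]; saturated K2P pairs are `NA`.
#' @export
pairwise_matrix <- function(aln, model = c("p", "k2p")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "seq_alignment"))
  n <- nrow(aln)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  undef <- character(0)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    d <- tryCatch({
      if (model == "p") p_distance(aln[i, ], aln[j, ])
      else k2p_components(aln[i, ], aln[j, ])$d
    }, error = function(e) {
      undef <<- c(undef, paste0(rownames(aln)[i], "/", rownames(aln)[j]))
      NA_real_
    })
    m[i, j] <- m[j, i] <- d
  }
  if (length(undef))
    stop("undefined distance for pair(s): ", paste(undef, collapse = ", "),
         call. = FALSE)
  dist_matrix(m)
}

#' Mean within- or between-group distance
#'
#' Within-group: mean over all unordered member pairs (needs >= 2 members).
#' Between-group: mean over all cross pairs of two disjoint groups.
#'
#' @param dm a [dist_matrix()].
#' @param g1 character vector of taxa (first group).
#' @param g2 optional character vector (second group); omit for within-group.
#' @return the mean distance (numeric scalar).
#' @export
group_mean_distance <- function(dm, g1, g2 = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  miss <- setdiff(c(g1, g2), rownames(dm))
  if (length(miss))
    stop("taxa not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(g2)) {
    if (length(g1) < 2L)
      stop("within-group mean needs at least two members", call. = FALSE)
    sub <- unclass(dm)[g1, g1, drop = FALSE]
    return(mean(sub[upper.tri(sub)]))
  }
  if (length(intersect(g1, g2)))
    stop("groups overlap: ", paste(intersect(g1, g2), collapse = ", "),
         call. = FALSE)
  if (!length(g1) || !length(g2)) stop("empty group", call. = FALSE)
  mean(unclass(dm)[g1, g2, drop = FALSE])
}
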